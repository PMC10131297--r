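# Shared fixtures, built once per test run and cached.

.fx <- new.env(parent = emptyenv())

fx_species <- function() {
  if (is.null(.fx$tab)) .fx$tab <- load_species_table()
  .fx$tab
}

# Synthesized life history + Leslie matrix for one species.
fx_lh <- function(abbr = "SH") {
  key <- paste0("lh_", abbr)
  if (is.null(.fx[[key]])) {
    tab <- fx_species()
    lh <- synthesize_life_history(tab[tab$abbr == abbr, ])
    .fx[[key]] <- list(lh = lh, L = build_leslie(lh))
  }
  .fx[[key]]
}

# Calibrated survival feedback for one species.
fx_cal <- function(abbr = "SH", c_exponent = 2) {
  key <- paste0("cal_", abbr, "_", c_exponent)
  if (is.null(.fx[[key]])) {
    f <- fx_lh(abbr)
    .fx[[key]] <- calibrate_feedback(f$lh, f$L, c_exponent = c_exponent,
                                     rng_seed = 11)
  }
  .fx[[key]]
}

# A fully prepared species (feedback + harvest + null-catastrophe ramp).
fx_prep <- function(abbr = "SH") {
  key <- paste0("prep_", abbr)
  if (is.null(.fx[[key]])) {
    tab <- fx_species()
    i <- match(abbr, tab$abbr)
    .fx[[key]] <- prepare_species(tab[i, ], c("i", "ii", "iv", "v", "ix"),
                                  base_seed = 11, species_idx = i,
                                  cfg = run_config())
  }
  .fx[[key]]
}

# A tiny two-age life history with lambda = 1 (deterministic toy).
fx_toy_lh <- function(K = 1000) {
  structure(list(species = list(abbr = "toy", q_yr = 60),
                 omega = 1L, maturity = 1L,
                 S = c(0.5, 0), m = c(0, 2),
                 terminal_survival_zeroed = TRUE,
                 D = K / 250000, A = 250000, K = K),
            class = "life_history")
}

# Acceptance-scale study, shared by the acceptance criteria tests:
# all 21 species at 200 reps for scenarios iii and iv; the
# generation-length-spanning subset at 200 reps for ii, viii, ix.
fx_acceptance <- function() {
  if (is.null(.fx$acc)) {
    seed <- 20240901
    tab <- fx_species()
    cfg <- run_config(base_seed = seed)
    dc <- density_coefficient(tab$mass_kg, cfg$lh_config)
    span6 <- c("DM", "SH", "DN", "VU", "MR", "GN")
    preps <- list()
    for (si in seq_len(nrow(tab))) {
      ab <- tab$abbr[si]
      need <- c("ii", "iii", "iv")
      if (ab %in% span6) need <- c(need, "viii", "ix")
      preps[[ab]] <- prepare_species(tab[si, ], need, base_seed = seed,
                                     species_idx = si, cfg = cfg,
                                     density_coef = dc)
    }
    run1 <- function(p, sc) analyze_batch(run_scenario(p, sc, 200L, seed))
    p6 <- preps[span6]
    .fx$acc <- list(
      seed = seed, span6 = span6, preps = preps,
      ii = run1(p6, "ii"),
      viii = run1(p6, "viii"),
      ix = run1(p6, "ix"),
      iii = run1(preps, "iii"),
      iv = run1(preps, "iv"))
  }
  .fx$acc
}
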