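#' Load the 21-species life-history target table
#'
#' Reads the packaged table of test species: two-letter abbreviation,
#' taxonomic/functional group, mean adult body mass (kg), generation length
#' GL (years) and projection length q (years).  Projection lengths equal 40
#' generations rounded to whole years, so q ranges from 92 (DM, GL 2.3) to
#' 800 (GN, GL 20) with a median of 324 years across the 21 species.
#'
#' @param path Optional path to an alternative CSV with the same columns
#'   (`abbr,group,mass_kg,GL_yr,q_yr`); defaults to the packaged fixture.
#' @return A data.frame of class `species_table` with one row per species.
#' @examples
#' sp <- load_species_table()
#' nrow(sp)            # 21
#' median(sp$q_yr)     # 324
#' @export
load_species_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "species_table.csv",
                        package = "feedbacksim", mustWork = FALSE)
  }
  if (!nzchar(path) || !file.exists(path)) {
    stop("species table fixture not found: ", path)
  }
  tab <- read.csv(path, stringsAsFactors = FALSE)
  needed <- c("abbr", "group", "mass_kg", "GL_yr", "q_yr")
  if (!identical(names(tab), needed)) {
    stop("species table is garbled; expected columns ",
         paste(needed, collapse = ","))
  }
  if (anyNA(tab) || any(tab$mass_kg <= 0) || any(tab$GL_yr <= 0)) {
    stop("species table contains missing or non-positive values")
  }
  bad <- abs(tab$q_yr - round(40 * tab$GL_yr)) > 1
  if (any(bad)) {
    stop("projection length q inconsistent with 40 generations for: ",
         paste(tab$abbr[bad], collapse = ", "))
  }
  class(tab) <- c("species_table", "data.frame")
  tab
}

#' Write a species target table
#'
#' Writes the table in the same CSV layout read by [load_species_table()],
#' so a written table round-trips to identical records.
#'
#' @param tab A `species_table` data.frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_species_table <- function(tab, path) {
  write.csv(as.data.frame(tab), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Species with the terminal Leslie cell zeroed (S_omega = 0): the common
# wombat, the thylacine and the devil, which would otherwise accumulate
# unrealistically old individuals.
TERMINAL_ZERO_SPECIES <- c("VU", "TH", "SH")
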