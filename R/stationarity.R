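#' Return times of an abundance series to its long-term mean
#'
#' The series mean N-bar (a proxy for carrying capacity) is crossed
#' repeatedly by a fluctuating series; each crossing m yields a return time
#' T_R,m = SC_m + SF_m, where SC_m counts the complete yearly steps since
#' the previous crossing (zero when crossings occur on consecutive steps;
#' the first segment counts from the series start) and SF_m is the
#' within-step fraction at which the mean is crossed, by linear
#' interpolation: SF = (N_p - N_bar) / (N_p - N_a) with N_p and N_a the
#' abundances before and after the crossing.  An exact tie N_t = N_bar
#' counts as a crossing completed at that step with SF = 1 (the
#' interpolation is 0/0 there).
#'
#' @param N_t Numeric abundance series (length >= 2).
#' @return Numeric vector of return times, one per crossing.
#' @examples
#' return_times(c(12, 8, 11, 9))  # 0.5, 2/3, 0.5
#' @export
return_times <- function(N_t) {
  N_t <- N_t[!is.na(N_t)]
  if (length(N_t) < 2) stop("series too short for return times")
  nbar <- mean(N_t)
  d <- N_t - nbar
  if (all(d == 0)) stop("constant series: return times undefined")
  TRs <- numeric(0)
  sc <- 0
  side <- sign(d[1])
  if (side == 0) side <- sign(d[d != 0][1])  # tie at start: take first side
  for (t in 2:length(N_t)) {
    cur <- sign(d[t])
    if (cur == 0) {
      TRs <- c(TRs, sc + 1)
      sc <- 0
      side <- -side
    } else if (cur != side) {
      sf <- (N_t[t - 1] - nbar) / (N_t[t - 1] - N_t[t])
      TRs <- c(TRs, sc + sf)
      sc <- 0
      side <- cur
    } else {
      sc <- sc + 1
    }
  }
  TRs
}

#' Return-time statistics and the stationarity index
#'
#' Mean and variance (denominator M - 1) of the return times, and the
#' stationarity index mean/variance.  A small index (mean much smaller
#' than the variance) marks a highly nonstationary series; equal return
#' times give zero variance and an infinite index.  With fewer than two
#' crossings the variance (and index) are not computable and are `NA`.
#'
#' @param TRs Return times from [return_times()], or an abundance series
#'   (in which case return times are computed first).
#' @return A list of class `return_time_stats`: `mean_TR`, `var_TR`, `M`,
#'   `index`, `computable`.
#' @export
stationarity_index <- function(TRs) {
  M <- length(TRs)
  if (M < 1) {
    return(structure(list(mean_TR = NA_real_, var_TR = NA_real_, M = 0L,
                          index = NA_real_, computable = FALSE),
                     class = "return_time_stats"))
  }
  mean_TR <- mean(TRs)
  if (M < 2) {
    return(structure(list(mean_TR = mean_TR, var_TR = NA_real_, M = M,
                          index = NA_real_, computable = FALSE),
                     class = "return_time_stats"))
  }
  var_TR <- sum((TRs - mean_TR)^2) / (M - 1)
  index <- if (var_TR == 0) Inf else mean_TR / var_TR
  structure(list(mean_TR = mean_TR, var_TR = var_TR, M = as.integer(M),
                 index = index, computable = TRUE),
            class = "return_time_stats")
}

#' @export
print.return_time_stats <- function(x, ...) {
  cat(sprintf(
    "Return times: M = %d, mean = %.4g, var = %.4g, index = %.4g%s\n",
    x$M, x$mean_TR, x$var_TR, x$index,
    if (is.finite(x$index) && x$index < 1) " (highly nonstationary)" else ""))
  invisible(x)
}
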