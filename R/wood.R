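#' Wood incomplete-gamma lactation curve
#'
#' Daily milk yield at day-in-milk t under the Wood curve,
#' `W(t) = a t^b exp(-c t)` with `a = exp(k)`, evaluated in its log-linear
#' form `W(t) = exp(k + b log(t) - c t)`. The domain starts at t = 1
#' (`log(1) = 0`), matching the daily summation convention used throughout
#' the package.
#'
#' @param t day in milk, `t >= 1` (vectorised).
#' @param k log-scale intercept (`k = log a`).
#' @param b unitless power coefficient (rise).
#' @param c per-day exponential decay rate.
#' @return daily yield in kg/day, strictly positive.
#' @examples
#' wood_daily(40, k = log(5), b = 0.2, c = 0.005)
#' @export
wood_daily <- function(t, k, b, c) {
  if (any(t < 1)) stop("day in milk 't' must be >= 1")
  exp(k + b * log(t) - c * t)
}

#' Lactation-curve shape descriptors
#'
#' Peak day (`b/c`), peak yield and persistency for a Wood curve. Persistency
#' is reported as the ratio of yield at day `L` to peak yield, in `[0, 1]`
#' for curves peaking before `L`. A flat curve (`b = 0`, `c = 0`) is handled
#' by an explicit degenerate rule: peak day 1, peak yield `exp(k)`,
#' persistency 1.
#'
#' @param k,b,c Wood parameters; a peak requires `b > 0`, `c > 0`.
#' @param L lactation length in days (default 280).
#' @return list with `peak_day`, `peak_yield`, `persistency`.
#' @export
wood_descriptors <- function(k, b, c, L = 280) {
  k <- unname(k); b <- unname(b); c <- unname(c)
  if (b == 0 && c == 0) {
    return(list(peak_day = 1, peak_yield = exp(k), persistency = 1))
  }
  if (b <= 0 || c <= 0) {
    stop("curve has no interior peak: requires b > 0 and c > 0")
  }
  peak_day <- b / c
  peak_yield <- wood_daily(max(peak_day, 1), k, b, c)
  list(peak_day = peak_day,
       peak_yield = peak_yield,
       persistency = wood_daily(L, k, b, c) / peak_yield)
}

#' Total lactation yield under a Wood curve
#'
#' Sums the noise-free daily Wood yields over days 1..L. Vectorised over
#' parameter triples: `k`, `b`, `c` may be equal-length vectors, giving one
#' total per triple.
#'
#' @param k,b,c Wood parameters (vectors of common length).
#' @param L lactation length in days.
#' @return numeric vector of total yields (kg).
#' @export
wood_total <- function(k, b, c, L = 280) {
  t <- seq_len(L)
  if (length(k) == 1L) {
    return(sum(wood_daily(t, k, b, c)))
  }
  # n x L matrix of daily yields; rowSums gives totals
  M <- exp(outer(k, rep(1, L)) + outer(b, log(t)) - outer(c, t))
  rowSums(M)
}

#' Daily yields for a matrix of cows
#'
#' @param params matrix/data.frame with columns k, b, c (one row per cow).
#' @param L lactation length.
#' @return n x L matrix of noise-free daily yields.
#' @keywords internal
wood_daily_matrix <- function(params, L = 280) {
  t <- seq_len(L)
  k <- params[, "k"]; b <- params[, "b"]; c <- params[, "c"]
  exp(outer(as.numeric(k), rep(1, L)) + outer(as.numeric(b), log(t)) -
        outer(as.numeric(c), t))
}
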