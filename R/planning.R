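#' Sire reliability from a daughter average
#'
#' Selection-index reliability of a sire proven on `d` daughters whose
#' lactation yields are estimated under a recording protocol that inflates
#' the residual variance by `sigma_delta2`:
#' `R = d h2 / (4 + (d - 1) h2 + 4 sigma_delta2 / sigma_p2)`.
#'
#' @param d number of daughters (> 0, may be fractional).
#' @param h2 heritability of true lactation yield, in (0, 1).
#' @param sigma_delta2 increase in residual variance due to the recording
#'   protocol (kg^2): the variance of (estimated - true) yield.
#' @param sigma_p2 phenotypic variance of true yield (kg^2).
#' @return reliability in (0, 1).
#' @examples
#' reliability(19, h2 = 0.2, sigma_delta2 = 0, sigma_p2 = 1)  # 0.5
#' @export
reliability <- function(d, h2, sigma_delta2 = 0, sigma_p2 = 1) {
  stopifnot(d > 0, h2 > 0, h2 < 1, sigma_delta2 >= 0, sigma_p2 > 0)
  d * h2 / (4 + (d - 1) * h2 + 4 * sigma_delta2 / sigma_p2)
}

#' Daughters required for a target sire reliability
#'
#' Closed-form inversion of [reliability()]:
#' `d = R (4 - h2 + 4 sigma_delta2 / sigma_p2) / (h2 (1 - R))`. With a
#' perfect recording protocol (`sigma_delta2 = 0`), `h2 = 0.2` and
#' `R = 0.5`, 19 daughters are required.
#'
#' @param R target reliability, in (0, 1).
#' @inheritParams reliability
#' @return required daughters (continuous; round up for an integer
#'   allocation).
#' @export
daughters_required <- function(R, h2, sigma_delta2 = 0, sigma_p2 = 1) {
  stopifnot(R > 0, R < 1, h2 > 0, h2 < 1, sigma_delta2 >= 0, sigma_p2 > 0)
  R * (4 - h2 + 4 * sigma_delta2 / sigma_p2) / (h2 * (1 - R))
}

#' Sires testable within a recording budget
#'
#' Number of sires that can be progeny-tested when `budget` test-day
#' records are available in total, each proven sire needs `d` daughters and
#' each daughter contributes `m` test days: `budget / (m * d)`. The default
#' budget, 7500 = 30 farms x 25 cows x 10 monthly records, reflects a
#' national recording scheme.
#'
#' @param d daughters required per sire.
#' @param m test-day records per lactation.
#' @param budget total test-day records available.
#' @return number of sires (continuous).
#' @export
sires_testable <- function(d, m, budget = 7500) {
  stopifnot(d > 0, m > 0, budget > 0)
  budget / (m * d)
}

#' Progeny-testing planning table across recording regimes
#'
#' One row per regime: the accuracy of its yield estimates (bias and
#' sigma_delta from [score_estimates()]) translated into the daughters
#' required per sire at the target reliability and the number of sires
#' testable within the budget. The phenotypic variance is taken empirically
#' from the simulated true yields.
#'
#' @param reports named list of `accuracy_report`s (one per regime).
#' @param m named/positional integer vector: test days per lactation for
#'   each regime.
#' @param true_yield numeric vector of simulated true yields (defines
#'   `sigma_p2`).
#' @param h2 heritability of true yield (default 0.2).
#' @param R target reliability (default 0.5).
#' @param budget total test-day records (default 7500).
#' @param integer_daughters if `TRUE`, round daughters up to the next whole
#'   animal before computing sires.
#' @return data.frame: `regime`, `m`, `bias`, `sigma_delta`, `daughters`,
#'   `sires`; attribute `sigma_p2`.
#' @export
plan_table <- function(reports, m, true_yield, h2 = 0.2, R = 0.5,
                       budget = 7500, integer_daughters = FALSE) {
  if (length(reports) != length(m)) stop("'reports' and 'm' lengths differ")
  sigma_p2 <- stats::var(true_yield)
  if (!is.finite(sigma_p2) || sigma_p2 <= 0) stop("missing or degenerate sigma_p2")
  rows <- lapply(seq_along(reports), function(i) {
    rp <- reports[[i]]
    d <- daughters_required(R, h2, rp$sigma_delta^2, sigma_p2)
    if (integer_daughters) d <- ceiling(d)
    data.frame(regime = names(reports)[i] %||% as.character(i),
               m = m[[i]], bias = rp$bias, sigma_delta = rp$sigma_delta,
               daughters = d, sires = sires_testable(d, m[[i]], budget),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "sigma_p2") <- sigma_p2
  attr(out, "h2") <- h2
  attr(out, "R") <- R
  attr(out, "budget") <- budget
  out
}
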