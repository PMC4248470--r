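#' Test-day schedules
#'
#' A test-day schedule is a strictly increasing set of days in milk (DIM)
#' within `[1, L]` at which yields are recorded, with a label. The equally
#' spaced conventions are: weekly = days 7, 14, ..., 280 (40 TD);
#' monthly = days 10, 40, ..., 280 (10 TD); quarterly = days 10, 100, 190,
#' 280 (4 TD).
#'
#' @param days integer DIM, distinct, within `[1, L]`.
#' @param label schedule label (e.g. `"monthly"` or `"tdsr:17"`).
#' @param L lactation length.
#' @return integer vector of sorted days of class `td_schedule` with a
#'   `label` attribute.
#' @export
td_schedule <- function(days, label = "custom", L = 280) {
  days <- as.integer(days)
  if (anyDuplicated(days)) stop("schedule days must be distinct")
  if (any(days < 1 | days > L)) stop("schedule days must lie in [1, L]")
  structure(sort(days), label = label, class = "td_schedule")
}

#' @rdname td_schedule
#' @param which one of `"weekly"`, `"monthly"`, `"quarterly"`, `"daily"`.
#' @export
standard_schedule <- function(which = c("weekly", "monthly", "quarterly", "daily"),
                              L = 280) {
  which <- match.arg(which)
  days <- switch(which,
                 weekly = seq(7L, L, by = 7L),
                 monthly = seq(10L, L, by = 30L),
                 quarterly = c(10L, 100L, 190L, 280L),
                 daily = seq_len(L))
  td_schedule(days[days <= L], label = which, L = L)
}

#' Subset simulated daily yields to a test-day schedule
#'
#' Extracts the stored (noisy) daily yields of every cow at the schedule
#' days. No re-simulation takes place: the records carry the same noise
#' realization as the population they come from.
#'
#' @param pop a [simulate_population()] result.
#' @param schedule a [td_schedule()] (or integer day vector).
#' @return data.frame with columns `cow`, `dim`, `yield` (one row per cow
#'   x day), with the schedule label as attribute `label`.
#' @export
subset_testdays <- function(pop, schedule) {
  days <- as.integer(schedule)
  if (any(days < 1 | days > pop$L)) stop("schedule day out of range [1, L]")
  if (anyDuplicated(days)) stop("schedule days must be distinct")
  days <- sort(days)
  n <- length(pop$cows)
  out <- data.frame(
    cow = rep(pop$cows, each = length(days)),
    dim = rep(days, times = n),
    yield = as.vector(t(pop$yields[, days, drop = FALSE])),
    stringsAsFactors = FALSE)
  attr(out, "label") <- attr(schedule, "label") %||% "custom"
  attr(out, "L") <- pop$L
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
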