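#' Draw a coverage-guaranteed batch of random test-day sampling regimes
#'
#' Repeatedly draws regimes of `m` distinct days uniformly without
#' replacement from the pool (each stored sorted) until every pool day
#' appears in at least `min_coverage` regimes. Duplicate regimes are kept:
#' they are distinct draws.
#'
#' @param pool integer vector of candidate DIM.
#' @param m regime size (days per lactation), `m <= length(pool)`.
#' @param min_coverage minimum number of regimes each pool day must appear
#'   in (default 25).
#' @param seed optional integer seed.
#' @return list of sorted integer day vectors.
#' @export
draw_tdsr_batch <- function(pool, m, min_coverage = 25, seed = NULL) {
  pool <- sort(unique(as.integer(pool)))
  if (length(pool) < m) stop("pool smaller than regime size 'm'")
  if (!is.null(seed)) set.seed(seed)
  counts <- stats::setNames(integer(length(pool)), pool)
  batch <- list()
  while (any(counts < min_coverage)) {
    draw <- sort(sample(pool, m))
    batch[[length(batch) + 1L]] <- draw
    counts[as.character(draw)] <- counts[as.character(draw)] + 1L
  }
  batch
}

#' Evaluate one sampling regime by MSEP of Wood-model yield estimates
#'
#' Subsets the population's stored records to the regime days, fits the
#' Wood curve and computes the mean square error of prediction against the
#' simulated true yields. The default fitting mode is the empirical-Bayes
#' hierarchical fit (see [fit_wood()]), applied directly to the stored
#' daily-yield matrix: every regime re-fits the curve model for all cows,
#' which the vectorised Gauss-Newton passes make cheap enough to repeat
#' thousands of times.
#'
#' @param tdsr integer vector of regime days.
#' @param pop a [simulate_population()] result.
#' @param mode fitting mode, see [fit_wood()].
#' @return list: `msep`, `n` (cows scored), `estimates` (named vector).
#' @export
evaluate_tdsr <- function(tdsr, pop, mode = c("hierarchical", "percow")) {
  mode <- match.arg(mode)
  days <- sort(as.integer(tdsr))
  if (any(days < 1 | days > pop$L)) stop("regime day outside the lactation")
  Y <- pop$yields[, days, drop = FALSE]
  B <- if (mode == "percow") loglin_ols(Y, days) else eb_fit_block(Y, days)
  est <- stats::setNames(wood_total(B[, 1], B[, 2], B[, 3], pop$L),
                         rownames(Y))
  # per-cow fit failure: non-finite or implausible total (a cow cannot
  # plausibly sustain 3x its best observed day over the whole lactation)
  cap <- 3 * pop$L * apply(Y, 1, max)
  failed <- !is.finite(est) | est < 0 | est > cap
  est <- est[!failed]
  delta <- est - pop$true_yield[names(est)]
  list(msep = mean(delta^2), n = length(est), estimates = est,
       n_failed = sum(failed))
}

#' Per-day mean MSEP ranking and quarter-pool elimination
#'
#' Averages each pool day's MSEP over all evaluated regimes containing it,
#' ranks days from the most inaccurate (highest mean MSEP) down, and
#' removes the worst quarter: `ceiling(n/4)` days are dropped, keeping
#' `floor(3n/4)`. Ties in mean MSEP are broken by removing the later DIM
#' first.
#'
#' @param pool integer vector of current pool days.
#' @param tdsrs list of regimes (integer day vectors) drawn from the pool.
#' @param mseps numeric MSEP per regime.
#' @return list: `pool` (kept days, sorted), `removed`,
#'   `per_day_mean_msep` (named numeric over the input pool).
#' @export
rank_and_prune <- function(pool, tdsrs, mseps) {
  pool <- sort(as.integer(pool))
  day_of <- rep(seq_along(tdsrs), lengths(tdsrs))
  all_days <- unlist(tdsrs)
  mean_msep <- tapply(mseps[day_of], all_days, mean)
  per_day <- stats::setNames(rep(NA_real_, length(pool)), pool)
  per_day[names(mean_msep)] <- mean_msep
  n_remove <- ceiling(length(pool) / 4)
  # worst first; ties broken by later DIM removed first
  ord <- order(-per_day, -pool)
  removed <- pool[ord[seq_len(n_remove)]]
  list(pool = sort(setdiff(pool, removed)), removed = sort(removed),
       per_day_mean_msep = per_day)
}

#' Iterative pool-elimination search for strategic sampling regimes
#'
#' Runs the loop: draw coverage-guaranteed random regimes of `m` days from
#' the current pool, score each by Wood-model MSEP, average MSEP per day,
#' and discard the worst quarter of the pool before the next loop (the
#' final loop only evaluates). Starting from all 280 DIM, ten loops shrink
#' the pool through 280, 210, 157, ..., 27 to 20 days. The best regime
#' (lowest MSEP) is tracked across all loops — it need not come from the
#' last loop.
#'
#' Optionally each regime's EBV ranking agreement with the true EBVs is
#' recorded: the mixed-model equations are factorised once (the
#' coefficient matrix does not depend on the phenotypes), so per-regime
#' EBVs reduce to triangular solves.
#'
#' @param pop a [simulate_population()] result.
#' @param m days per regime (4, 5 or 6 typical).
#' @param loops number of loops (default 10).
#' @param min_coverage per-day coverage requirement (default 25).
#' @param seed optional master seed (one substream per loop).
#' @param mode regime fitting mode, see [evaluate_tdsr()].
#' @param track_ebv if `TRUE`, also record each regime's Top-k overlap with
#'   the true EBVs.
#' @param h2 heritability used for the BLUP evaluation when
#'   `track_ebv = TRUE` (default 0.2).
#' @param k Top-k size (default 100).
#' @param max_fail_frac regimes whose fit fails for more than this fraction
#'   of cows are discarded and logged, not scored.
#' @return list of class `tdsr_search`: `loops` (per-loop list with `pool`,
#'   `tdsrs`, `msep`, `median_msep`, `per_day_mean_msep`, optional
#'   `top_overlap`), `best` (list `days`, `msep`, `loop`), `trace`
#'   (data.frame loop, tdsr_id, days, msep, optional top_overlap),
#'   `m`, `discarded` (count of unscored regimes).
#' @export
run_search <- function(pop, m, loops = 10, min_coverage = 25, seed = NULL,
                       mode = "hierarchical", track_ebv = FALSE, h2 = 0.2,
                       k = 100, max_fail_frac = 0.1) {
  if (loops < 1) stop("'loops' must be >= 1")
  pool <- seq_len(pop$L)
  seeds <- if (is.null(seed)) rep(list(NULL), loops) else
    as.list(derive_seeds(seed, paste0("loop", seq_len(loops))))
  solver <- NULL
  true_top <- NULL
  if (track_ebv) {
    solver <- blup_solver(pop$ped, pop$cows, h2 = h2)
    ebv_true <- solver(pop$true_yield)
    true_top <- ebv_true
  }
  n_cows <- length(pop$cows)
  loop_out <- vector("list", loops)
  best <- list(days = NULL, msep = Inf, loop = NA_integer_)
  trace <- list()
  discarded <- 0L
  for (l in seq_len(loops)) {
    if (length(pool) < m) stop("pool fell below regime size 'm' at loop ", l)
    tdsrs <- draw_tdsr_batch(pool, m, min_coverage, seed = seeds[[l]])
    msep <- rep(NA_real_, length(tdsrs))
    overlap <- if (track_ebv) rep(NA_integer_, length(tdsrs)) else NULL
    for (j in seq_along(tdsrs)) {
      ev <- tryCatch(evaluate_tdsr(tdsrs[[j]], pop, mode = mode),
                     error = function(e) NULL)
      if (is.null(ev) || ev$n < (1 - max_fail_frac) * n_cows) {
        discarded <- discarded + 1L
        next
      }
      msep[j] <- ev$msep
      if (track_ebv && ev$n == n_cows) {
        ebv_j <- solver(ev$estimates)
        overlap[j] <- top_k_overlap(ebv_j, true_top, k = k)
      }
    }
    ok <- !is.na(msep)
    res <- rank_and_prune(pool, tdsrs[ok], msep[ok])
    jbest <- which.min(msep)
    if (length(jbest) && msep[jbest] < best$msep) {
      best <- list(days = tdsrs[[jbest]], msep = msep[jbest], loop = l)
    }
    trace[[l]] <- data.frame(
      loop = l, tdsr_id = seq_along(tdsrs),
      days = vapply(tdsrs, paste, character(1), collapse = ";"),
      msep = msep, stringsAsFactors = FALSE)
    if (track_ebv) trace[[l]]$top_overlap <- overlap
    loop_out[[l]] <- list(pool = pool, tdsrs = tdsrs, msep = msep,
                          median_msep = stats::median(msep, na.rm = TRUE),
                          per_day_mean_msep = res$per_day_mean_msep)
    if (track_ebv) loop_out[[l]]$top_overlap <- overlap
    if (l < loops) pool <- res$pool
  }
  structure(list(loops = loop_out, best = best,
                 trace = do.call(rbind, trace), m = m,
                 discarded = discarded),
            class = "tdsr_search")
}

#' @export
print.tdsr_search <- function(x, ...) {
  med <- vapply(x$loops, `[[`, numeric(1), "median_msep")
  cat("TDSR search (m =", x$m, ",", length(x$loops), "loops)\n")
  cat("  pool sizes:", paste(vapply(x$loops, function(l) length(l$pool),
                                    integer(1)), collapse = " "), "\n")
  cat("  median MSEP by loop:", paste(round(med), collapse = " "), "\n")
  cat("  best regime: {", paste(x$best$days, collapse = ", "), "} MSEP",
      round(x$best$msep, 1), "(loop", x$best$loop, ")\n")
  invisible(x)
}

#' Pool-size recurrence of the elimination loop
#'
#' Sizes of the day pool across loops when `floor(3n/4)` days are kept at
#' each elimination: from 280 days the sequence is 280, 210, 157, 117, 87,
#' 65, 48, 36, 27, 20.
#'
#' @param start initial pool size.
#' @param loops number of loops.
#' @return integer vector of pool sizes at each loop.
#' @export
pool_size_sequence <- function(start = 280, loops = 10) {
  out <- integer(loops)
  n <- as.integer(start)
  for (l in seq_len(loops)) {
    out[l] <- n
    n <- floor(3 * n / 4)
  }
  out
}

#' Number of possible sampling regimes
#'
#' How many regimes of `m` distinct test days can be formed from a pool of
#' `n` days, counted either as ordered selections `n!/(n-m)!` or as
#' unordered combinations `choose(n, m)`. From 280 days with m = 5 the
#' ordered count exceeds 1.6e12.
#'
#' @param n pool size.
#' @param m regime size.
#' @param ordered count ordered selections (default) or combinations.
#' @return a (possibly very large) numeric count.
#' @export
tdsr_combination_count <- function(n, m, ordered = TRUE) {
  if (ordered) prod(n - seq_len(m) + 1) else choose(n, m)
}
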