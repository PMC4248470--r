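#' Filter sampling regimes by EBV ranking agreement
#'
#' Keeps the regimes whose Top-k overlap with the true EBV ranking strictly
#' exceeds the threshold (default: over 80 of the top 100), the
#' qualification rule for recommending sampling windows.
#'
#' @param tdsrs list of regimes (integer day vectors).
#' @param overlaps integer Top-k overlap per regime (from
#'   [top_k_overlap()] against the true EBVs).
#' @param threshold qualification threshold (strict `>`).
#' @return list: `tdsrs` (qualifying regimes), `overlaps`, `fraction`
#'   (qualifying fraction of all tested regimes).
#' @export
filter_qualifying <- function(tdsrs, overlaps, threshold = 80) {
  if (length(tdsrs) != length(overlaps)) {
    stop("'tdsrs' and 'overlaps' lengths differ")
  }
  keep <- !is.na(overlaps) & overlaps > threshold
  list(tdsrs = tdsrs[keep], overlaps = overlaps[keep],
       fraction = mean(keep, na.rm = FALSE))
}

#' Order-statistic distributions of qualifying test days
#'
#' Across the qualifying regimes (each sorted, all of size m), the j-th
#' smallest day forms the position-j distribution. For each position the
#' summary reports the median and the central quarter of the distribution
#' (the 37.5th to 62.5th percentile band, the "middle 25%" convention).
#'
#' @param tdsrs list of qualifying regimes, each a sorted integer vector of
#'   common length m.
#' @param m regime size (checked against the regimes).
#' @return list of class `window_summary`: `positions` (data.frame
#'   `position`, `n`, `p37.5`, `median`, `p62.5`), `samples` (n x m matrix
#'   of days, column j = position j).
#' @export
position_distributions <- function(tdsrs, m) {
  if (length(tdsrs) == 0L) stop("no qualifying regimes")
  if (any(lengths(tdsrs) != m)) stop("regimes of mixed size")
  Q <- t(vapply(tdsrs, function(d) sort(as.numeric(d)), numeric(m)))
  pos <- lapply(seq_len(m), function(j) {
    q <- stats::quantile(Q[, j], c(0.375, 0.5, 0.625), names = FALSE)
    data.frame(position = j, n = nrow(Q),
               p37.5 = q[1], median = q[2], p62.5 = q[3])
  })
  structure(list(positions = do.call(rbind, pos), samples = Q),
            class = "window_summary")
}

#' @export
print.window_summary <- function(x, ...) {
  cat("Recommended sampling windows over", x$positions$n[1],
      "qualifying regimes\n")
  for (i in seq_len(nrow(x$positions))) {
    p <- x$positions[i, ]
    cat(sprintf("  TD %d: median day %.0f (middle 25%%: %.0f-%.0f)\n",
                p$position, p$median, p$p37.5, p$p62.5))
  }
  invisible(x)
}

#' Kolmogorov-Smirnov test of position distributions against uniform
#' order statistics
#'
#' Tests, for each test-day position j, whether the empirical distribution
#' of the j-th sampling day across qualifying regimes is consistent with
#' the j-th of m order statistics from a uniform distribution on (0, L) —
#' exactly the `L * Beta(j, m + 1 - j)` law. Rejection means the
#' recommended windows are genuinely strategic rather than uniform-random.
#' Days are integers, so the reference law is continuous only
#' approximately; ties make the p-values approximate.
#'
#' @param ws a [position_distributions()] result (or an n x m matrix of
#'   sorted regime days).
#' @param L lactation length.
#' @return data.frame: `position`, `n`, `ks_stat`, `p_value`.
#' @export
ks_uniformity_test <- function(ws, L = 280) {
  Q <- if (inherits(ws, "window_summary")) ws$samples else as.matrix(ws)
  if (nrow(Q) < 10) stop("need at least 10 qualifying regimes")
  m <- ncol(Q)
  rows <- lapply(seq_len(m), function(j) {
    kt <- suppressWarnings(
      stats::ks.test(Q[, j], function(q) stats::pbeta(q / L, j, m + 1 - j)))
    data.frame(position = j, n = nrow(Q),
               ks_stat = unname(kt$statistic), p_value = kt$p.value)
  })
  do.call(rbind, rows)
}
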