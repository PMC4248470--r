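# Natural-scale Wood-curve fitting machinery.
#
# The workhorse is a two-stage empirical-Bayes fit on the natural scale of
# the observation model y_t = exp(k + b log t - c t) + eps:
#   stage 1 - per-cow maximum likelihood by damped Gauss-Newton, started at
#             the log-linear OLS solution;
#   stage 2 - per-cow posterior mode under a working normal prior on the
#             triples whose mean, covariance and residual variance are
#             estimated from stage 1 (sampling covariance subtracted by
#             method of moments).
# Stage 2 reproduces the shrinkage of a full nonlinear mixed model at a
# tiny fraction of its cost, which is what makes scoring thousands of
# sampling regimes feasible. All per-cow 3x3 solves are vectorised across
# cows via closed-form (adjugate) inverses.

# Solve n independent 3x3 symmetric systems G x = r, entries as n-vectors.
solve3_sym <- function(g11, g12, g13, g22, g23, g33, r1, r2, r3) {
  i11 <- g22 * g33 - g23^2
  i12 <- -(g12 * g33 - g13 * g23)
  i13 <- g12 * g23 - g13 * g22
  i22 <- g11 * g33 - g13^2
  i23 <- -(g11 * g23 - g12 * g13)
  i33 <- g11 * g22 - g12^2
  det <- g11 * i11 + g12 * i12 + g13 * i13
  cbind((i11 * r1 + i12 * r2 + i13 * r3) / det,
        (i12 * r1 + i22 * r2 + i23 * r3) / det,
        (i13 * r1 + i23 * r2 + i33 * r3) / det)
}

# One damped Gauss-Newton pass for all cows sharing the design (days).
# B: n x 3 start values; Y: n x m yields; prior: NULL (maximum likelihood,
# with a tiny Levenberg ridge) or list(P = 3x3 precision, mu, s2).
gn_pass <- function(B, Y, days, prior = NULL, iters = 12, damp = 0.8) {
  n <- nrow(Y)
  M <- cbind(1, log(days), -days)
  MM <- list(M[, 1]^2, M[, 1] * M[, 2], M[, 1] * M[, 3],
             M[, 2]^2, M[, 2] * M[, 3], M[, 3]^2)
  s2 <- if (is.null(prior)) 1 else prior$s2
  for (it in seq_len(iters)) {
    eta <- B %*% t(M)
    W <- exp(pmin(eta, 50))
    R <- Y - W
    W2 <- W^2
    g <- lapply(MM, function(mm) rowSums(W2 * rep(mm, each = n)) / s2)
    r1 <- rowSums(W * R * rep(M[, 1], each = n)) / s2
    r2 <- rowSums(W * R * rep(M[, 2], each = n)) / s2
    r3 <- rowSums(W * R * rep(M[, 3], each = n)) / s2
    if (!is.null(prior)) {
      P <- prior$P
      D <- sweep(B, 2, prior$mu)
      r1 <- r1 - (D[, 1] * P[1, 1] + D[, 2] * P[1, 2] + D[, 3] * P[1, 3])
      r2 <- r2 - (D[, 1] * P[2, 1] + D[, 2] * P[2, 2] + D[, 3] * P[2, 3])
      r3 <- r3 - (D[, 1] * P[3, 1] + D[, 2] * P[3, 2] + D[, 3] * P[3, 3])
      g[[1]] <- g[[1]] + P[1, 1]; g[[2]] <- g[[2]] + P[1, 2]
      g[[3]] <- g[[3]] + P[1, 3]; g[[4]] <- g[[4]] + P[2, 2]
      g[[5]] <- g[[5]] + P[2, 3]; g[[6]] <- g[[6]] + P[3, 3]
    } else {
      ridge <- 1e-8
      g[[1]] <- g[[1]] + ridge; g[[4]] <- g[[4]] + ridge
      g[[6]] <- g[[6]] + ridge
    }
    step <- solve3_sym(g[[1]], g[[2]], g[[3]], g[[4]], g[[5]], g[[6]],
                       r1, r2, r3)
    step[!is.finite(step)] <- 0
    B <- B + damp * step
  }
  B
}

# Log-linear OLS for all cows sharing a design; exact with 3 noiseless
# records, the starting point for the natural-scale passes.
loglin_ols <- function(Y, days) {
  M <- cbind(1, log(days), -days)
  B <- log(Y) %*% M %*% solve(crossprod(M))
  colnames(B) <- c("k", "b", "c")
  B
}

# Empirical-Bayes natural-scale fit for a balanced block of cows
# (all sharing `days`). Returns the n x 3 parameter matrix.
eb_fit_block <- function(Y, days, iters = 12, damp = 0.8) {
  n <- nrow(Y); m <- length(days)
  B1 <- gn_pass(loglin_ols(Y, days), Y, days, iters = iters, damp = damp)
  if (n < 3 || m <= 3) return(B1)   # no df to estimate a prior from
  M <- cbind(1, log(days), -days)
  W <- exp(pmin(B1 %*% t(M), 50))
  R <- Y - W
  s2 <- sum(R^2) / (n * (m - 3))
  if (!is.finite(s2) || s2 < 1e-10) return(B1)   # (near-)noiseless data
  # average sampling information of the per-cow ML estimates
  W2 <- W^2
  MM <- list(M[, 1]^2, M[, 1] * M[, 2], M[, 1] * M[, 3],
             M[, 2]^2, M[, 2] * M[, 3], M[, 3]^2)
  gbar <- vapply(MM, function(mm) mean(rowSums(W2 * rep(mm, each = n))),
                 numeric(1))
  Gbar <- matrix(gbar[c(1, 2, 3, 2, 4, 5, 3, 5, 6)], 3, 3) / s2
  Samp <- tryCatch(solve(Gbar), error = function(e) NULL)
  if (is.null(Samp)) return(B1)
  Sigma <- stats::cov(B1) - Samp
  ee <- eigen((Sigma + t(Sigma)) / 2, symmetric = TRUE)
  Sigma <- ee$vectors %*% (pmax(ee$values, 1e-10) * t(ee$vectors))
  P <- tryCatch(solve(Sigma), error = function(e) NULL)
  if (is.null(P)) return(B1)
  B2 <- gn_pass(B1, Y, days, prior = list(P = P, mu = colMeans(B1), s2 = s2),
                iters = iters, damp = damp)
  colnames(B2) <- c("k", "b", "c")
  B2
}

# Records data.frame -> list of balanced blocks (Y matrix + days), grouped
# by identical day sets so each block can be fitted vectorised.
records_to_blocks <- function(records) {
  by_cow <- split(records[, c("dim", "yield")], records$cow)
  keys <- vapply(by_cow, function(r) paste(sort(r$dim), collapse = ","),
                 character(1))
  lapply(split(names(by_cow), keys), function(cows) {
    days <- sort(by_cow[[cows[1]]]$dim)
    Y <- t(vapply(cows, function(cw) {
      r <- by_cow[[cw]]
      r$yield[order(r$dim)]
    }, numeric(length(days))))
    rownames(Y) <- cows
    list(Y = Y, days = days)
  })
}

# nlme natural-scale nonlinear mixed fit (the reference estimator).
fit_nlme <- function(records, start) {
  df <- data.frame(y = records$yield, t = records$dim,
                   cow = factor(records$cow))
  fit <- tryCatch(
    suppressWarnings(
      nlme::nlme(y ~ exp(k + b * log(t) - c * t), data = df,
                 fixed = k + b + c ~ 1, random = k + b + c ~ 1 | cow,
                 start = start,
                 control = nlme::nlmeControl(maxIter = 100, msMaxIter = 100,
                                             returnObject = TRUE))),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  cf <- stats::coef(fit)
  B <- as.matrix(cf[, c("k", "b", "c")])
  rownames(B) <- rownames(cf)
  B
}
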