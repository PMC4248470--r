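#' Animal-model BLUP breeding values
#'
#' Solves Henderson's mixed-model equations for the single-trait animal
#' model `y = 1*mu + Z a + e`, `a ~ N(0, A sigma_A^2)`,
#' `e ~ N(0, I sigma_e^2)`:
#' `[X'X, X'Z; Z'X, Z'Z + A^{-1} lambda] [mu; a] = [X'y; Z'y]` with
#' `lambda = sigma_e^2 / sigma_A^2 = (1 - h2) / h2`. A single overall mean
#' is the only fixed effect. The relationship-matrix inverse is obtained by
#' a dense solve (populations here are hundreds of animals). EBVs are
#' returned for every pedigree animal; unphenotyped parents receive
#' progeny/parent-average-consistent predictions.
#'
#' @param yields named numeric vector of phenotypes (names = animal ids) or
#'   data.frame with columns `animal`/`cow` and `yield`/`estimate`.
#' @param ped a [pedigree()].
#' @param h2 heritability in (0, 1); alternatively give `sigma_a2` and
#'   `sigma_e2` directly.
#' @param sigma_a2,sigma_e2 additive and residual variances (override
#'   `h2`).
#' @return data.frame of class `ebv_set` with columns `animal`, `ebv`;
#'   attributes `mu`, `sigma_a2`, `sigma_e2`, `h2`.
#' @export
blup_ebv <- function(yields, ped, h2 = NULL, sigma_a2 = NULL, sigma_e2 = NULL) {
  y <- as_named_yields(yields)
  vr <- resolve_varratio(h2, sigma_a2, sigma_e2)
  solver <- blup_solver(ped, names(y), h2 = vr$h2)
  ebv <- solver(y)
  out <- data.frame(animal = names(ebv), ebv = as.numeric(ebv),
                    stringsAsFactors = FALSE)
  attr(out, "mu") <- attr(ebv, "mu")
  attr(out, "h2") <- vr$h2
  attr(out, "sigma_a2") <- vr$sigma_a2
  attr(out, "sigma_e2") <- vr$sigma_e2
  class(out) <- c("ebv_set", "data.frame")
  out
}

as_named_yields <- function(yields) {
  if (is.data.frame(yields)) {
    id_col <- intersect(c("animal", "cow"), names(yields))[1]
    val_col <- intersect(c("yield", "estimate", "true_yield"), names(yields))[1]
    if (is.na(id_col) || is.na(val_col)) {
      stop("yield data.frame needs an id column (animal/cow) and a value ",
           "column (yield/estimate)")
    }
    stats::setNames(yields[[val_col]], yields[[id_col]])
  } else {
    if (is.null(names(yields))) stop("yields must be named by animal id")
    yields
  }
}

resolve_varratio <- function(h2, sigma_a2, sigma_e2) {
  if (!is.null(sigma_a2) && !is.null(sigma_e2)) {
    h2 <- sigma_a2 / (sigma_a2 + sigma_e2)
  } else if (!is.null(h2)) {
    if (h2 <= 0 || h2 >= 1) stop("'h2' must be in (0, 1)")
    sigma_a2 <- h2; sigma_e2 <- 1 - h2   # ratio is all the MME need
  } else stop("give either 'h2' or both 'sigma_a2' and 'sigma_e2'")
  list(h2 = h2, sigma_a2 = sigma_a2, sigma_e2 = sigma_e2)
}

#' Pre-factorised BLUP solver for repeated evaluations
#'
#' The MME coefficient matrix depends only on the pedigree, the phenotyped
#' animal set and the variance ratio — not on the phenotypes. This
#' factorises it once (Cholesky) and returns a function mapping a phenotype
#' vector to the EBV vector, so scoring thousands of sampling regimes costs
#' only triangular solves.
#'
#' @param ped a [pedigree()].
#' @param pheno_ids ids of the phenotyped animals (the solver's input must
#'   be named with exactly these).
#' @param h2 heritability in (0, 1).
#' @return function(y) -> named EBV vector over all pedigree animals (with
#'   attribute `mu`).
#' @export
blup_solver <- function(ped, pheno_ids, h2) {
  if (h2 <= 0 || h2 >= 1) stop("'h2' must be in (0, 1)")
  A <- build_a_matrix(ped)
  ids <- ped$animal
  if (!all(pheno_ids %in% ids)) stop("unknown animals in phenotype set")
  lambda <- (1 - h2) / h2
  nA <- length(ids)
  nR <- length(pheno_ids)
  Z <- matrix(0, nR, nA, dimnames = list(pheno_ids, ids))
  Z[cbind(seq_len(nR), match(pheno_ids, ids))] <- 1
  Ainv <- solve(A)
  X <- matrix(1, nR, 1)
  LHS <- rbind(cbind(crossprod(X), crossprod(X, Z)),
               cbind(crossprod(Z, X), crossprod(Z) + lambda * Ainv))
  R <- chol(LHS)
  function(y) {
    if (is.null(names(y))) stop("phenotypes must be named by animal id")
    y <- y[pheno_ids]
    if (anyNA(y)) stop("phenotypes missing for some animals in the solver set")
    rhs <- c(sum(y), as.numeric(crossprod(Z, y)))
    sol <- backsolve(R, backsolve(R, rhs, transpose = TRUE))
    structure(stats::setNames(sol[-1], ids), mu = sol[1])
  }
}

#' Animal-model REML heritability
#'
#' Restricted-maximum-likelihood estimation of heritability under the
#' single-trait animal model with one overall mean, using the
#' eigendecomposition of the observed-animal submatrix of A: rotating by
#' the eigenvectors diagonalises the covariance
#' `V = sigma_p^2 (h2 D + (1 - h2) I)`, so the REML log-likelihood profile
#' over h2 is a cheap one-dimensional optimisation.
#'
#' @param yields named numeric phenotypes (or data.frame, see
#'   [blup_ebv()]).
#' @param ped a [pedigree()].
#' @param interval search interval for h2.
#' @return list: `h2`, `sigma_a2`, `sigma_e2`, `mu`, `logLik` (restricted,
#'   up to a constant).
#' @export
reml_h2 <- function(yields, ped, interval = c(1e-4, 1 - 1e-4)) {
  y <- as_named_yields(yields)
  A <- build_a_matrix(ped)
  ids <- names(y)
  if (!all(ids %in% rownames(A))) stop("unknown animals in phenotype set")
  Ao <- A[ids, ids]
  n <- length(y)
  ee <- eigen(Ao, symmetric = TRUE)
  d <- pmax(ee$values, 1e-12)
  yt <- as.numeric(crossprod(ee$vectors, y))
  xt <- as.numeric(crossprod(ee$vectors, rep(1, n)))
  neg_rll <- function(h2) {
    v <- h2 * d + (1 - h2)
    w <- 1 / v
    sxx <- sum(w * xt^2)
    mu <- sum(w * xt * yt) / sxx
    r <- yt - xt * mu
    s2 <- sum(w * r^2) / (n - 1)
    0.5 * ((n - 1) * log(s2) + sum(log(v)) + log(sxx))
  }
  opt <- stats::optimize(neg_rll, interval)
  h2 <- opt$minimum
  v <- h2 * d + (1 - h2); w <- 1 / v
  sxx <- sum(w * xt^2)
  mu <- sum(w * xt * yt) / sxx
  s2 <- sum(w * (yt - xt * mu)^2) / (n - 1)
  list(h2 = h2, sigma_a2 = h2 * s2, sigma_e2 = (1 - h2) * s2, mu = mu,
       logLik = -opt$objective)
}

#' Top-k ranking overlap between two EBV sets
#'
#' Number of animals appearing in the top k of both rankings. Ties in EBV
#' are broken deterministically by animal id.
#'
#' @param ebv_a,ebv_b named EBV vectors or `ebv_set` data.frames sharing at
#'   least `k` animals.
#' @param k size of the selected group (default 100).
#' @return integer overlap count in `[0, k]`.
#' @export
top_k_overlap <- function(ebv_a, ebv_b, k = 100) {
  a <- as_named_ebv(ebv_a); b <- as_named_ebv(ebv_b)
  ids <- intersect(names(a), names(b))
  if (length(ids) < k) stop("fewer than k animals in common")
  top <- function(x) ids[order(-x[ids], ids)][seq_len(k)]
  length(intersect(top(a), top(b)))
}

as_named_ebv <- function(x) {
  if (inherits(x, "ebv_set") || is.data.frame(x)) {
    stats::setNames(x$ebv, x$animal)
  } else x
}

#' Pearson correlation between two EBV sets
#'
#' @param ebv_a,ebv_b named EBV vectors or `ebv_set` data.frames with at
#'   least 3 animals in common.
#' @return correlation in `[-1, 1]`.
#' @export
ebv_correlation <- function(ebv_a, ebv_b) {
  a <- as_named_ebv(ebv_a); b <- as_named_ebv(ebv_b)
  ids <- intersect(names(a), names(b))
  if (length(ids) < 3) stop("need at least 3 animals in common")
  if (stats::sd(a[ids]) == 0 || stats::sd(b[ids]) == 0) {
    stop("zero-variance EBV set")
  }
  stats::cor(a[ids], b[ids])
}
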