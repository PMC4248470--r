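#' Scenario fixed effects for the simulated herd
#'
#' Fixed-effect intercepts of the Wood parameters (k, b, c) for the two
#' simulated curve shapes, plus optional additive adjustments for
#' month-of-calving, year and age (each a (k, b, c) offset triple, default
#' zero). The presets are chosen so that the mean APHP curve peaks at 34 DIM
#' with a persistent tail and the mean HPLP curve peaks at 35 DIM with a
#' higher peak and a visibly faster decline, at Sahiwal-plausible daily
#' yields (peak roughly 6.5-7.5 kg/day):
#'
#' * `APHP` (average peak, high persistency): k0 = 1.442, b0 = 0.170,
#'   c0 = 0.005 (peak day 34, peak ~6.5 kg/d).
#' * `HPLP` (high peak, low persistency): k0 = 1.121, b0 = 0.350,
#'   c0 = 0.010 (peak day 35, peak ~7.5 kg/d).
#'
#' @param scenario `"APHP"` or `"HPLP"`.
#' @param moc,year,age optional numeric length-3 adjustment triples
#'   `(k, b, c)` added to the intercepts.
#' @return list of class `scenario_effects` with `k0`, `b0`, `c0`,
#'   adjustment triples and the scenario `label`.
#' @export
scenario_effects <- function(scenario = c("APHP", "HPLP"),
                             moc = c(0, 0, 0), year = c(0, 0, 0),
                             age = c(0, 0, 0)) {
  scenario <- match.arg(scenario)
  base <- switch(scenario,
                 APHP = c(k0 = 1.442, b0 = 0.170, c0 = 0.005),
                 HPLP = c(k0 = 1.121, b0 = 0.350, c0 = 0.010))
  out <- list(k0 = unname(base["k0"]), b0 = unname(base["b0"]),
              c0 = unname(base["c0"]),
              moc = moc, year = year, age = age, label = scenario)
  m <- scenario_mean_triple(out)
  if (m["b"] <= 0 || m["c"] <= 0) {
    stop("scenario mean curve must have b > 0 and c > 0")
  }
  class(out) <- "scenario_effects"
  out
}

#' Mean parameter triple of a scenario
#' @param scn a [scenario_effects()].
#' @return named numeric `(k, b, c)`: intercepts plus all adjustments.
#' @export
scenario_mean_triple <- function(scn) {
  adj <- scn$moc + scn$year + scn$age
  c(k = scn$k0 + adj[1], b = scn$b0 + adj[2], c = scn$c0 + adj[3])
}

#' Variance components for the curve-parameter sub-models
#'
#' Container for the 3x3 genetic covariance matrix G of the polygenic
#' random effects (K.G, B.G, C.G), the 3x3 environmental covariance E of
#' the cow-specific environmental effects (K.E, B.E, C.E), and the residual
#' variance of daily yield, `sigma_eps2` (kg^2). G and E must be symmetric
#' positive semidefinite. By default the environmental covariance is
#' diagonal (non-zero covariances are used only in G).
#'
#' @param G,E symmetric PSD 3x3 matrices (rows/cols ordered k, b, c).
#' @param sigma_eps2 non-negative residual variance of daily yield.
#' @return list of class `variance_components`.
#' @export
variance_components <- function(G, E, sigma_eps2) {
  G <- as.matrix(G); E <- as.matrix(E)
  check_psd3 <- function(M, nm) {
    if (!all(dim(M) == c(3, 3))) stop("'", nm, "' must be 3x3")
    if (max(abs(M - t(M))) > 1e-8) stop("'", nm, "' must be symmetric")
    if (min(eigen(M, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
      stop("'", nm, "' must be positive semidefinite")
    }
  }
  check_psd3(G, "G"); check_psd3(E, "E")
  if (sigma_eps2 < 0) stop("'sigma_eps2' must be non-negative")
  dimnames(G) <- dimnames(E) <- list(c("k", "b", "c"), c("k", "b", "c"))
  structure(list(G = G, E = E, sigma_eps2 = sigma_eps2),
            class = "variance_components")
}

cor_to_cov <- function(sds, R) {
  diag(sds) %*% R %*% diag(sds)
}

# Base (pre-calibration) genetic covariance: modest genetic variation in
# curve shape with the sign pattern typical of Wood fits (higher intercept
# with flatter rise; rise and decay positively coupled).
base_G <- function() {
  sds <- c(0.06, 0.022, 0.00055)
  R <- matrix(c(1, -0.4, -0.3,
                -0.4, 1, 0.7,
                -0.3, 0.7, 1), 3, 3)
  cor_to_cov(sds, R)
}

base_E <- function() {
  diag(c(0.11, 0.040, 0.0010)^2)
}

#' Default calibrated variance components
#'
#' The variance components shipped with the package. The environmental
#' covariance is diagonal (sd of K.E, B.E, C.E = 0.11, 0.040, 0.0010), the
#' daily residual variance is 1.44 kg^2 (sd 1.2 kg/day), and the genetic
#' covariance is the base matrix (sd 0.06, 0.022, 0.00055 with correlations
#' r_kb = -0.4, r_kc = -0.3, r_bc = 0.7) scaled by the factor found by
#' [calibrate_varcomps()] so that the realized heritability of cumulative
#' 280-day yield under the APHP scenario is 0.2.
#'
#' @return a [variance_components()] object.
#' @export
default_varcomps <- function() {
  variance_components(G = .default_G_scale * base_G(),
                      E = base_E(),
                      sigma_eps2 = 1.44)
}

# Genetic scale frozen from calibrate_varcomps(target_h2 = 0.2, n = 50000,
# seed = 20140078) under the APHP scenario; see the methods vignette.
.default_G_scale <- 2.6937

#' Symmetric PSD matrix square root
#' @keywords internal
mat_sqrt <- function(M) {
  e <- eigen(M, symmetric = TRUE)
  if (min(e$values) < -1e-8) stop("matrix is not positive semidefinite")
  v <- pmax(e$values, 0)
  e$vectors %*% (sqrt(v) * t(e$vectors))
}

#' Derive named substream seeds from one master seed
#'
#' All randomness in a pipeline run flows from a single master seed through
#' named substreams, so that any stage can be reproduced in isolation. The
#' mapping from `(seed, names)` to substream seeds is deterministic and part
#' of the public contract.
#'
#' @param seed master integer seed.
#' @param names character vector of substream names.
#' @return named integer vector of seeds (each below 2^31).
#' @export
derive_seeds <- function(seed, names) {
  set.seed(seed)
  stats::setNames(sample.int(.Machine$integer.max - 1L, length(names)), names)
}

#' Sample pedigree-correlated genetic and environmental effect triples
#'
#' Draws the stacked genetic vector of (K.G, B.G, C.G) from
#' `N(0, G (x) A)` (Kronecker structure: covariance G across parameters,
#' relationship matrix A across animals) and the environmental triples
#' i.i.d. from `N(0, E)`. With G = 0 and E = 0 all triples are exactly zero.
#'
#' @param vc a [variance_components()].
#' @param A numerator relationship matrix with animal-id dimnames.
#' @param seed optional integer seed.
#' @return list with matrices `genetic` and `environment` (n x 3, columns
#'   k, b, c, rownames the animal ids).
#' @export
sample_random_effects <- function(vc, A, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(A)
  La <- t(chol_psd(A))            # n x n lower factor, A = La La'
  Lg <- mat_sqrt(vc$G)            # 3 x 3 symmetric root
  Le <- mat_sqrt(vc$E)
  Zg <- matrix(stats::rnorm(n * 3), n, 3)
  Ze <- matrix(stats::rnorm(n * 3), n, 3)
  # matrix-normal draw: row covariance A, column covariance G
  gen <- La %*% Zg %*% t(Lg)
  env <- Ze %*% t(Le)
  dimnames(gen) <- dimnames(env) <- list(rownames(A), c("k", "b", "c"))
  list(genetic = gen, environment = env)
}

# Cholesky factor tolerant of PSD (rank-deficient) matrices.
chol_psd <- function(A) {
  ch <- tryCatch(chol(A), error = function(e) NULL)
  if (!is.null(ch)) return(ch)
  e <- eigen(A, symmetric = TRUE)
  if (min(e$values) < -1e-8) stop("relationship matrix is not PSD")
  v <- pmax(e$values, 0)
  t(e$vectors %*% (sqrt(v) * t(e$vectors)))
}

#' Simulate a lactating population
#'
#' For every recorded cow, the Wood parameter triple is the scenario fixed
#' triple plus a pedigree-correlated genetic triple plus an independent
#' environmental triple. Daily yield at day t is the curve value plus an
#' independent residual `N(0, sigma_eps2)`; negative draws are floored at
#' 0.01 kg (counted for audit). The true 280-day yield is the sum of the
#' stored (noisy) daily yields, a noise-free curve total is kept alongside.
#'
#' @param scenario a [scenario_effects()].
#' @param vc a [variance_components()].
#' @param ped a [pedigree()]; recorded cows default to all non-founders (in
#'   a founders-only pedigree, all animals).
#' @param L lactation length in days (default 280).
#' @param seed optional integer seed.
#' @param cow_ids optional character vector naming the recorded cows.
#' @return list of class `td_population`: `ped`, `A`, `scenario`, `vc`,
#'   `cows` (ids), `params` (n x 3), `genetic`/`environment` (all-animal
#'   matrices), `yields` (n x L daily matrix), `true_yield` (incl.
#'   residuals), `curve_yield` (noise-free), `n_floored`, `L`, `seed`.
#' @export
simulate_population <- function(scenario, vc, ped, L = 280, seed = NULL,
                                cow_ids = NULL) {
  if (L < 1) stop("'L' must be >= 1")
  A <- build_a_matrix(ped)
  if (is.null(cow_ids)) {
    cow_ids <- ped$animal[!is_founder(ped)]
    if (length(cow_ids) == 0L) cow_ids <- ped$animal
  }
  if (!all(cow_ids %in% ped$animal)) stop("unknown cow ids")
  seeds <- if (is.null(seed)) NULL else derive_seeds(seed, c("effects", "residuals"))
  eff <- sample_random_effects(vc, A, seed = if (is.null(seeds)) NULL else seeds[["effects"]])
  mean_triple <- scenario_mean_triple(scenario)
  n <- length(cow_ids)
  params <- sweep(eff$genetic[cow_ids, , drop = FALSE] +
                    eff$environment[cow_ids, , drop = FALSE], 2,
                  mean_triple, "+")
  colnames(params) <- c("k", "b", "c")
  curve <- wood_daily_matrix(params, L)
  if (!is.null(seeds)) set.seed(seeds[["residuals"]])
  noise <- matrix(stats::rnorm(n * L, 0, sqrt(vc$sigma_eps2)), n, L)
  yields <- curve + noise
  n_floored <- sum(yields < 0.01)
  yields[yields < 0.01] <- 0.01
  dimnames(yields) <- list(cow_ids, NULL)
  structure(list(ped = ped, A = A, scenario = scenario, vc = vc,
                 cows = cow_ids, params = params,
                 genetic = eff$genetic, environment = eff$environment,
                 yields = yields,
                 true_yield = stats::setNames(rowSums(yields), cow_ids),
                 curve_yield = stats::setNames(rowSums(curve), cow_ids),
                 n_floored = n_floored, L = L, seed = seed),
            class = "td_population")
}

#' @export
print.td_population <- function(x, ...) {
  cat("Simulated lactation population (", x$scenario$label, ")\n", sep = "")
  cat("  cows:", length(x$cows), " lactation length:", x$L, "days\n")
  cat("  mean true yield:", round(mean(x$true_yield), 1), "kg;",
      "phenotypic SD:", round(stats::sd(x$true_yield), 1), "kg\n")
  invisible(x)
}

#' Monte-Carlo realized heritability of cumulative yield
#'
#' Heritability of total L-day yield implied by a set of variance
#' components, estimated by simulation with unrelated animals: the variance
#' of genetic-only curve totals over the total variance of noisy yields
#' (curve totals with genetic + environmental triples, plus the residual
#' sum with variance `L * sigma_eps2`).
#'
#' @param vc a [variance_components()].
#' @param scenario a [scenario_effects()].
#' @param n Monte-Carlo population size.
#' @param L lactation length.
#' @param seed optional integer seed.
#' @return realized heritability (scalar in (0, 1)).
#' @export
realized_h2_mc <- function(vc, scenario, n = 20000, L = 280, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  Zg <- matrix(stats::rnorm(n * 3), n, 3)
  Ze <- matrix(stats::rnorm(n * 3), n, 3)
  eps <- stats::rnorm(n, 0, sqrt(L * vc$sigma_eps2))
  h2_from_scale(1, Zg, Ze, eps, vc$G, vc$E, scenario, L)
}

# realized h2 with genetic covariance s * G, reusing common random numbers
h2_from_scale <- function(s, Zg, Ze, eps, G, E, scenario, L) {
  m <- scenario_mean_triple(scenario)
  g <- Zg %*% t(mat_sqrt(s * G))
  e <- Ze %*% t(mat_sqrt(E))
  Yg <- wood_total(m["k"] + g[, 1], m["b"] + g[, 2], m["c"] + g[, 3], L)
  p <- sweep(g + e, 2, m, "+")
  Yt <- wood_total(p[, 1], p[, 2], p[, 3], L) + eps
  stats::var(Yg) / stats::var(Yt)
}

#' Calibrate genetic variance to a target heritability
#'
#' Scales the genetic covariance G relative to a fixed environmental
#' covariance so that the Monte-Carlo realized heritability of cumulative
#' L-day yield (see [realized_h2_mc()]) hits `target_h2`. The search is a
#' root find over the log scale factor using common random numbers, so the
#' objective is smooth and deterministic given the seed.
#'
#' @param scenario a [scenario_effects()].
#' @param target_h2 target heritability in (0, 1).
#' @param base_vc variance components providing the unscaled G, E and
#'   residual variance (default: the package base values).
#' @param n Monte-Carlo population size used during calibration.
#' @param L lactation length.
#' @param seed integer seed for the common random numbers.
#' @param tol acceptable |realized - target| (default 0.02).
#' @return a [variance_components()] with scaled G; attributes `scale` (the
#'   multiplier applied to G) and `realized_h2`.
#' @export
calibrate_varcomps <- function(scenario = scenario_effects("APHP"),
                               target_h2 = 0.2,
                               base_vc = variance_components(base_G(), base_E(), 1.44),
                               n = 10000, L = 280, seed = 1, tol = 0.02) {
  if (target_h2 <= 0 || target_h2 >= 1) stop("'target_h2' must be in (0, 1)")
  set.seed(seed)
  Zg <- matrix(stats::rnorm(n * 3), n, 3)
  Ze <- matrix(stats::rnorm(n * 3), n, 3)
  eps <- stats::rnorm(n, 0, sqrt(L * base_vc$sigma_eps2))
  f <- function(ls) {
    h2_from_scale(exp(ls), Zg, Ze, eps, base_vc$G, base_vc$E, scenario, L) -
      target_h2
  }
  lo <- log(1e-3); hi <- log(1e3)
  if (f(lo) > 0 || f(hi) < 0) {
    stop("calibration failed: target heritability not bracketed by scale ",
         "search in [0.001, 1000]; realized h2 at bounds: ",
         signif(f(lo) + target_h2, 3), ", ", signif(f(hi) + target_h2, 3))
  }
  root <- stats::uniroot(f, c(lo, hi), tol = 1e-6)
  s <- exp(root$root)
  realized <- f(root$root) + target_h2
  if (abs(realized - target_h2) > tol) {
    stop("calibration failed to reach target within tolerance")
  }
  out <- variance_components(s * base_vc$G, base_vc$E, base_vc$sigma_eps2)
  attr(out, "scale") <- s
  attr(out, "realized_h2") <- realized
  out
}
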