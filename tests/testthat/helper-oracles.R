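# Independent oracles used across the suite. These deliberately take
# different algorithmic routes from the package implementations.

# --- Wright path-counting relationship oracle -------------------------------
# a_ij = sum over common ancestors A and pairs of ancestor paths (i..A, j..A)
# sharing no animal but A, of (1/2)^(len_i + len_j) * (1 + F_A).
# Exponential, fine for pedigrees up to ~60 animals.
oracle_a_matrix <- function(ped) {
  n <- nrow(ped)
  idx <- setNames(seq_len(n), ped$animal)
  parents <- lapply(seq_len(n), function(j) {
    p <- c(ped$sire[j], ped$dam[j])
    unname(idx[p[!is.na(p)]])
  })
  # all ancestor paths from i, as integer vectors i..ancestor
  paths_from <- function(i) {
    res <- list(i)
    for (p in parents[[i]]) {
      for (pp in paths_from(p)) res <- c(res, list(c(i, pp)))
    }
    res
  }
  path_cache <- lapply(seq_len(n), paths_from)
  Fcoef <- rep(NA_real_, n)
  a_pair <- function(i, j) {
    total <- 0
    for (P in path_cache[[i]]) {
      for (Q in path_cache[[j]]) {
        anc <- P[length(P)]
        if (anc != Q[length(Q)]) next
        # paths must share only the common ancestor
        if (length(intersect(P[-length(P)], Q[-length(Q)])) > 0) next
        total <- total + 0.5^(length(P) - 1 + length(Q) - 1) * (1 + inbreeding(anc))
      }
    }
    total
  }
  inbreeding <- function(i) {
    if (!is.na(Fcoef[i])) return(Fcoef[i])
    ps <- parents[[i]]
    f <- if (length(ps) == 2) 0.5 * a_pair(ps[1], ps[2]) else 0
    Fcoef[i] <<- f
    f
  }
  A <- matrix(0, n, n, dimnames = list(ped$animal, ped$animal))
  for (i in seq_len(n)) {
    for (j in i:n) {
      A[i, j] <- A[j, i] <- if (i == j) 1 + inbreeding(i) else a_pair(i, j)
    }
  }
  A
}

# random multi-generation pedigree: later animals draw parents (possibly
# unknown) among earlier animals
random_pedigree <- function(n, p_known = 0.7, n_founders = max(3, n %/% 5),
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ids <- paste0("A", seq_len(n))
  sire <- dam <- rep(NA_character_, n)
  for (j in seq_len(n)) {
    if (j <= n_founders) next
    pool <- ids[seq_len(j - 1)]
    pick <- sample(pool, 2)
    if (runif(1) < p_known) sire[j] <- pick[1]
    if (runif(1) < p_known) dam[j] <- pick[2]
  }
  pedigree(ids, sire, dam)
}

# --- TIM oracle: explicit interval-by-interval accumulation -----------------
oracle_tim <- function(dim, yield, L) {
  o <- order(dim)
  d <- dim[o]; y <- yield[o]
  total <- d[1] * y[1]
  i <- 1
  while (i < length(d)) {
    total <- total + (d[i + 1] - d[i]) * mean(c(y[i], y[i + 1]))
    i <- i + 1
  }
  total + (L - d[length(d)]) * y[length(d)]
}

# --- GLS oracle for animal-model BLUP ---------------------------------------
# a_hat = sigma_a2 * A Z' V^-1 (y - X mu_hat), V = Z A Z' sigma_a2 + I
# sigma_e2, mu_hat by GLS. An independent route to the same predictor as
# Henderson's equations.
oracle_blup <- function(y, ped, h2) {
  A <- build_a_matrix(ped)
  ids <- colnames(A)
  obs <- names(y)
  Z <- matrix(0, length(obs), length(ids), dimnames = list(obs, ids))
  Z[cbind(seq_along(obs), match(obs, ids))] <- 1
  sa <- h2; se <- 1 - h2
  V <- Z %*% A %*% t(Z) * sa + diag(se, length(obs))
  Vi <- solve(V)
  X <- matrix(1, length(obs), 1)
  mu <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)[1, 1]
  a_hat <- sa * A %*% t(Z) %*% Vi %*% (y - mu)
  setNames(as.numeric(a_hat), ids)
}

# --- dense REML log-likelihood oracle ---------------------------------------
# Restricted log-likelihood of the animal model computed from the generic
# matrix formula, up to an additive constant.
oracle_rll <- function(h2, y, A_obs) {
  n <- length(y)
  V <- h2 * A_obs + (1 - h2) * diag(n)
  Vi <- solve(V)
  X <- matrix(1, n, 1)
  XVX <- t(X) %*% Vi %*% X
  mu <- solve(XVX, t(X) %*% Vi %*% y)[1, 1]
  r <- y - mu
  q <- as.numeric(t(r) %*% Vi %*% r)
  s2 <- q / (n - 1)
  -0.5 * ((n - 1) * log(s2) + determinant(V)$modulus + log(det(XVX)))
}

# --- small populations for fast tests ---------------------------------------
small_population <- function(n_sires = 20, n_dams = 120, scenario = "APHP",
                             seed = 1, L = 280) {
  ped <- synthetic_pedigree(n_sires, n_dams, seed = seed)
  simulate_population(scenario_effects(scenario), default_varcomps(), ped,
                      L = L, seed = seed + 1000)
}
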