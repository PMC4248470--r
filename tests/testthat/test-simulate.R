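test_that("zero variance components give exactly zero random effects", {
  vc <- variance_components(matrix(0, 3, 3), matrix(0, 3, 3), 0)
  A <- build_a_matrix(synthetic_pedigree(3, 9, seed = 1))
  eff <- sample_random_effects(vc, A, seed = 2)
  expect_true(all(eff$genetic == 0))
  expect_true(all(eff$environment == 0))
})

test_that("with identity A the sampled triple covariance recovers G + E", {
  vc <- default_varcomps()
  n <- 2000
  ped <- pedigree(paste0("F", 1:n), rep(NA, n), rep(NA, n))
  A <- diag(n) |> `dimnames<-`(list(ped$animal, ped$animal))
  eff <- sample_random_effects(vc, A, seed = 5)
  S <- cov(eff$genetic + eff$environment)
  Tgt <- vc$G + vc$E
  # Monte-Carlo tolerance ~ 3 standard errors of a covariance estimate
  for (i in 1:3) for (j in 1:3) {
    se <- sqrt((Tgt[i, i] * Tgt[j, j] + Tgt[i, j]^2) / n)
    expect_lt(abs(S[i, j] - Tgt[i, j]), 3.5 * se)
  }
})

test_that("half-sib genetic covariance is G/4", {
  vc <- default_varcomps()
  ped <- synthetic_pedigree(1, 2, seed = 1)   # two half sibs, one sire
  A <- build_a_matrix(ped)
  nrep <- 4000
  set.seed(9)
  prods <- matrix(0, nrep, 3)
  for (r in seq_len(nrep)) {
    g <- sample_random_effects(vc, A)$genetic
    prods[r, ] <- g["C1", ] * g["C2", ]
  }
  est <- colMeans(prods)   # E[g1 g2] = 0.25 * diag(G) per component
  tgt <- 0.25 * diag(vc$G)
  se <- apply(prods, 2, sd) / sqrt(nrep)
  expect_true(all(abs(est - tgt) < 3.5 * se))
})

test_that("non-PSD covariance is rejected", {
  M <- matrix(c(1, 2, 0, 2, 1, 0, 0, 0, 1), 3, 3)
  expect_error(variance_components(M, diag(3), 1), "positive semidefinite")
})

test_that("noise-free flat population yields exactly L per cow", {
  vc <- variance_components(matrix(0, 3, 3), matrix(0, 3, 3), 0)
  scn <- scenario_effects("APHP")
  scn$k0 <- 0; scn$b0 <- 1e-9; scn$c0 <- 1e-9  # essentially flat, valid
  pop <- simulate_population(scn, vc, synthetic_pedigree(2, 6, seed = 1),
                             L = 280, seed = 3)
  expect_equal(unname(pop$true_yield), rep(280, 6), tolerance = 1e-5)
})

test_that("paper-scale run returns one lactation per cow", {
  pop <- small_population(82, 464, seed = 11)
  expect_length(pop$true_yield, 464)
  expect_equal(dim(pop$yields), c(464, 280))
})

test_that("equal seeds give bit-identical populations", {
  p1 <- small_population(5, 30, seed = 7)
  p2 <- small_population(5, 30, seed = 7)
  expect_identical(p1$yields, p2$yields)
  expect_identical(p1$params, p2$params)
})

test_that("true yield equals the sum of stored daily yields", {
  pop <- small_population(5, 40, seed = 2)
  expect_equal(pop$true_yield, rowSums(pop$yields), tolerance = 1e-9)
  # params decompose as fixed + genetic + environment
  m <- scenario_mean_triple(pop$scenario)
  recon <- sweep(pop$genetic[pop$cows, ] + pop$environment[pop$cows, ], 2,
                 m, "+")
  expect_equal(unname(pop$params), unname(recon), tolerance = 1e-12)
})

test_that("daily yields are floored at 0.01 kg", {
  pop <- small_population(10, 80, seed = 5)
  expect_gte(min(pop$yields), 0.01)
  expect_true(pop$n_floored >= 0)
})

test_that("calibration hits the target heritability and scales monotonely", {
  scn <- scenario_effects("APHP")
  vc <- calibrate_varcomps(scn, 0.2, n = 4000, seed = 10)
  expect_lt(abs(attr(vc, "realized_h2") - 0.2), 0.02)
  # doubling G strictly increases realized h2
  vc2 <- variance_components(2 * vc$G, vc$E, vc$sigma_eps2)
  h_lo <- realized_h2_mc(vc, scn, n = 8000, seed = 11)
  h_hi <- realized_h2_mc(vc2, scn, n = 8000, seed = 11)
  expect_gt(h_hi, h_lo)
  # tiny target drives G toward zero
  vc0 <- calibrate_varcomps(scn, 0.01, n = 2000, seed = 12)
  expect_lt(max(abs(vc0$G)), max(abs(vc$G)) / 5)
})

test_that("test-day subsetting reuses the stored noise realisation", {
  pop <- small_population(4, 20, seed = 6)
  rec <- subset_testdays(pop, standard_schedule("monthly"))
  expect_equal(nrow(rec), 20 * 10)        # 10 monthly records per cow
  one <- rec[rec$cow == pop$cows[1], ]
  expect_equal(one$yield, unname(pop$yields[pop$cows[1], one$dim]))
  # full daily schedule gives L records per cow
  rec_all <- subset_testdays(pop, td_schedule(1:280))
  expect_equal(nrow(rec_all), 20 * 280)
  # weekly convention: 40 records
  expect_length(standard_schedule("weekly"), 40)
  expect_length(standard_schedule("quarterly"), 4)
  expect_error(subset_testdays(pop, c(0, 10)), "out of range")
})

test_that("substream seeds are deterministic and named", {
  s1 <- derive_seeds(99, c("pedigree", "genetics"))
  s2 <- derive_seeds(99, c("pedigree", "genetics"))
  expect_identical(s1, s2)
  expect_named(s1, c("pedigree", "genetics"))
})
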