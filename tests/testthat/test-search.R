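test_that("batch drawing guarantees per-day coverage", {
  pool <- c(10, 50, 120, 200)
  batch <- draw_tdsr_batch(pool, 4, min_coverage = 25, seed = 1)
  expect_length(batch, 25)                       # only one subset exists
  expect_true(all(vapply(batch, identical, logical(1),
                         sort(as.integer(pool)))))

  batch2 <- draw_tdsr_batch(1:280, 5, min_coverage = 25, seed = 2)
  counts <- table(unlist(batch2))
  expect_length(counts, 280)
  expect_gte(min(counts), 25)

  # pigeonhole: 12 days, m = 4, coverage 1 needs at least ceiling(12/4)
  batch3 <- draw_tdsr_batch(1:12, 4, min_coverage = 1, seed = 3)
  expect_gte(length(batch3), 3)
  expect_error(draw_tdsr_batch(1:3, 4), "smaller")
})

test_that("batch drawing is reproducible under a seed", {
  expect_identical(draw_tdsr_batch(1:100, 5, 5, seed = 9),
                   draw_tdsr_batch(1:100, 5, 5, seed = 9))
})

test_that("regime evaluation is deterministic and consistent with
           score_estimates", {
  pop <- small_population(6, 50, seed = 14)
  tdsr <- c(20, 70, 150, 240)
  e1 <- evaluate_tdsr(tdsr, pop)
  e2 <- evaluate_tdsr(tdsr, pop)
  expect_identical(e1$msep, e2$msep)
  rp <- score_estimates(e1$estimates, pop$true_yield)
  expect_equal(e1$msep, rp$msep, tolerance = 1e-12)
  expect_error(evaluate_tdsr(c(0, 10, 50, 100), pop), "outside")
})

test_that("a noise-free population is recovered near-exactly from any
           spread regime", {
  vc0 <- variance_components(matrix(0, 3, 3), default_varcomps()$E, 0)
  pop <- simulate_population(scenario_effects("APHP"), vc0,
                             synthetic_pedigree(3, 15, seed = 2), seed = 3)
  ev <- evaluate_tdsr(c(15, 60, 150, 240), pop, mode = "percow")
  expect_lt(ev$msep, 1e-6)
})

test_that("pruning keeps floor(3n/4) days with the documented tie-break", {
  # equal MSEP everywhere: removal is purely by later-DIM-first
  pool <- 1:280
  tdsrs <- lapply(seq(1, 277), function(i) i:(i + 3))
  mseps <- rep(1, length(tdsrs))
  res <- rank_and_prune(pool, tdsrs, mseps)
  expect_length(res$pool, 210)
  expect_equal(res$pool, 1:210)          # later days removed first on ties
  expect_equal(res$removed, 211:280)

  # day means: a day in uniformly worse regimes is removed first
  pool2 <- c(1, 2, 3, 4)
  tdsrs2 <- list(c(1, 2), c(3, 4), c(1, 3))
  res2 <- rank_and_prune(pool2, tdsrs2, c(10, 1000, 10))
  expect_true(4 %in% res2$removed)
})

test_that("pool sizes follow the floor(3n/4) recurrence", {
  expect_equal(pool_size_sequence(280, 10),
               c(280, 210, 157, 117, 87, 65, 48, 36, 27, 20))
  # property: recurrence holds for any start
  for (start in c(13, 97, 301)) {
    s <- pool_size_sequence(start, 6)
    expect_equal(s[-1], floor(3 * s[-6] / 4))
  }
})

test_that("regime counting matches ordered and unordered conventions", {
  expect_equal(tdsr_combination_count(280, 5, ordered = TRUE),
               280 * 279 * 278 * 277 * 276)
  expect_equal(tdsr_combination_count(280, 5, ordered = FALSE),
               choose(280, 5))
})

test_that("a small seeded search runs the loop contract", {
  pop <- small_population(10, 80, seed = 15)
  sr <- run_search(pop, m = 4, loops = 3, min_coverage = 3, seed = 20)
  expect_length(sr$loops, 3)
  sizes <- vapply(sr$loops, function(l) length(l$pool), integer(1))
  expect_equal(sizes, pool_size_sequence(280, 3))
  expect_true(all(sr$best$days %in% sr$loops[[sr$best$loop]]$pool))
  expect_equal(sr$best$msep, min(sr$trace$msep, na.rm = TRUE))
  # per-day means aggregate only pool days
  pd <- sr$loops[[2]]$per_day_mean_msep
  expect_true(all(as.integer(names(pd)) %in% sr$loops[[2]]$pool))
  # bit-reproducible under the same seed
  sr2 <- run_search(pop, m = 4, loops = 3, min_coverage = 3, seed = 20)
  expect_identical(sr$trace, sr2$trace)
})

test_that("single-loop search leaves the pool untouched", {
  pop <- small_population(5, 40, seed = 16)
  sr <- run_search(pop, m = 4, loops = 1, min_coverage = 2, seed = 21)
  expect_equal(sr$loops[[1]]$pool, 1:280)
})
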