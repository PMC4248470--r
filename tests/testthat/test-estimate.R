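test_that("TIM reproduces hand-computed totals", {
  expect_equal(tim_yield(c(10, 100, 190, 280), rep(5, 4), L = 280), 1400)
  expect_equal(tim_yield(140, 4, L = 280), 1120)   # single record
  expect_error(tim_yield(integer(0), numeric(0)), "at least one")
  expect_error(tim_yield(c(10, 10), c(1, 2)), "distinct")
})

test_that("TIM equals the interval-accumulation oracle on random data", {
  set.seed(4)
  for (i in 1:20) {
    m <- sample(2:12, 1)
    d <- sort(sample(280, m))
    y <- runif(m, 1, 9)
    expect_equal(tim_yield(d, y, 280), oracle_tim(d, y, 280),
                 tolerance = 1e-12)
  }
})

test_that("TIM on the full daily schedule leaves only the trapezoid end
           correction (y1 - yL)/2", {
  pop <- small_population(3, 12, seed = 8)
  rec <- subset_testdays(pop, td_schedule(1:280))
  est <- tim_yields(rec, L = 280)
  y1 <- pop$yields[est$cow, 1]
  yL <- pop$yields[est$cow, 280]
  expect_equal(est$estimate,
               unname(pop$true_yield[est$cow] + (y1 - yL) / 2),
               tolerance = 1e-9)
})

test_that("per-cow fit recovers parameters exactly from noiseless records", {
  k <- 1.3; b <- 0.2; c <- 0.006
  days <- c(15, 60, 150, 240)
  cows <- paste0("C", 1:4)
  rec <- data.frame(cow = rep(cows, each = 4), dim = rep(days, 4),
                    yield = rep(wood_daily(days, k, b, c), 4))
  fit <- fit_wood(rec, mode = "percow")
  expect_equal(fit$params$k, rep(k, 4), tolerance = 1e-8)
  expect_equal(fit$params$b, rep(b, 4), tolerance = 1e-8)
  expect_equal(fit$params$c, rep(c, 4), tolerance = 1e-8)
  # composition: wood_yields reproduces the generating total
  wy <- wood_yields(fit, L = 280)
  expect_equal(wy$estimate, rep(wood_total(k, b, c, 280), 4),
               tolerance = 1e-6)
})

test_that("cows with too few usable records are flagged unfit", {
  rec <- data.frame(cow = c(rep("A", 4), rep("B", 2)),
                    dim = c(10, 60, 120, 200, 30, 90),
                    yield = c(wood_daily(c(10, 60, 120, 200), 1.4, .2, .005),
                              5, 4))
  fit <- fit_wood(rec, mode = "percow")
  expect_equal(fit$unfit, "B")
  expect_equal(fit$params$cow, "A")
  rec2 <- data.frame(cow = "A", dim = c(10, 10, 60, 120),
                     yield = c(5, 5, 4, 3))
  expect_error(fit_wood(rec2, mode = "percow"), "few|singular|duplicate")
})

test_that("hierarchical fit recovers population means within Monte-Carlo
           error and shrinks the triples", {
  pop <- small_population(20, 200, seed = 13)
  rec <- subset_testdays(pop, standard_schedule("monthly"))
  fit <- fit_wood(rec, mode = "hierarchical")
  truth <- colMeans(pop$params)
  fitted_mean <- colMeans(as.matrix(fit$params[, c("k", "b", "c")]))
  se <- apply(pop$params, 2, sd) / sqrt(nrow(pop$params))
  # fitted means should land near the simulated means (few SE of spread)
  expect_true(all(abs(fitted_mean - truth) < 4 * se + 0.05))
  # shrinkage: hierarchical triples vary less than per-cow OLS triples
  ols <- fit_wood(rec, mode = "percow")
  v_h <- apply(as.matrix(fit$params[, c("k", "b", "c")]), 2, var)
  v_o <- apply(as.matrix(ols$params[, c("k", "b", "c")]), 2, var)
  expect_true(all(v_h <= v_o))
})

test_that("hierarchical and nlme fits agree closely on a small population", {
  skip_if_not_installed("nlme")
  pop <- small_population(8, 60, seed = 21)
  rec <- subset_testdays(pop, standard_schedule("quarterly"))
  eb <- fit_wood(rec, mode = "hierarchical")
  nl <- fit_wood(rec, mode = "nlme")
  if (nl$mode == "nlme") {
    e1 <- wood_yields(eb)$estimate
    e2 <- wood_yields(nl)$estimate
    # same shrinkage family: totals correlate strongly
    expect_gt(cor(e1, e2), 0.9)
  }
  succeed()
})

test_that("wood_yields totals match the summation oracle", {
  params <- data.frame(cow = c("A", "B"), k = c(0, 1.2), b = c(0, 0.25),
                       c = c(0, 0.008))
  wy <- wood_yields(params, L = 280)
  expect_equal(wy$estimate[1], 280)
  direct <- sum(exp(1.2 + 0.25 * log(1:280) - 0.008 * (1:280)))
  expect_equal(wy$estimate[2], direct, tolerance = 1e-9)
})

test_that("score_estimates computes MSEP, bias and sigma_delta", {
  truths <- c(A = 100, B = 200)
  expect_equal(score_estimates(c(A = 100, B = 200), truths)$msep, 0)
  r <- score_estimates(c(A = 90, B = 210), truths)
  expect_equal(r$msep, 100)
  expect_equal(r$bias, 0)
  # decomposition msep = bias^2 + (n-1)/n * sigma_delta^2
  set.seed(5)
  for (i in 1:10) {
    n <- sample(5:50, 1)
    est <- setNames(rnorm(n, 1000, 50), paste0("C", 1:n))
    tru <- setNames(rnorm(n, 1000, 50), paste0("C", 1:n))
    rp <- score_estimates(est, tru)
    expect_equal(rp$msep, rp$bias^2 + (n - 1) / n * rp$sigma_delta^2,
                 tolerance = 1e-9)
  }
  expect_error(score_estimates(c(X = 1, Y = 2), truths), "unknown")
})
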