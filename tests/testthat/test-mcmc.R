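# cheap analytic targets wrapped as minimal "problems" where needed

gaussian2d_lp <- function(theta) -0.5 * sum(theta^2)

run_gaussian_chain <- function(n_steps = 1500L, burn_in = 500L, seed = 2L,
                               d = 2L) {
  cfg <- mcmc_config(n_walkers = 32L, n_steps = n_steps, burn_in = burn_in,
                     seed = seed)
  init <- cvscalib:::with_seed(seed + 1000L, {
    matrix(stats::rnorm(32 * d, 0, 0.1), ncol = d,
           dimnames = list(NULL, paste0("x", seq_len(d))))
  })
  run_ensemble(gaussian2d_lp, init, cfg)
}

test_that("log-posterior applies the box prior and the -cost/2 likelihood", {
  ptab <- tibble::tibble(name = c("a", "b"), units = "1", value = c(1, 1),
                         min = c(0, 0), max = c(2, 2), status = "free")
  ms <- measurement_set(data.frame(name = "y", value = 3, sigma = 0.5))
  prob <- calibration_problem(
    function(theta) c(y = theta[["a"]] + theta[["b"]]), ptab, ms)
  expect_identical(log_posterior(c(a = -0.1, b = 1), prob), -Inf)
  expect_identical(log_posterior(c(a = 1, b = 3), prob), -Inf)
  # perfect fit gives zero
  expect_equal(log_posterior(c(a = 1.5, b = 1.5), prob), 0)
  # differences of in-box log-posteriors equal -0.5 * cost differences
  t1 <- c(a = 1, b = 1); t2 <- c(a = 0.5, b = 1.2)
  expect_equal(log_posterior(t1, prob) - log_posterior(t2, prob),
               -0.5 * (prob$cost(t1) - prob$cost(t2)))
  # solver failure maps to -Inf
  prob_fail <- calibration_problem(function(theta) NULL, ptab, ms)
  expect_identical(log_posterior(c(a = 1, b = 1), prob_fail), -Inf)
})

test_that("walker initialization concentrates around the optimum", {
  theta_star <- c(p1 = 2, p2 = 0.5)
  lp <- function(theta) 0
  cfg <- mcmc_config(n_walkers = 10000L, n_steps = 10, burn_in = 1,
                     seed = 1)
  set.seed(31)
  init <- init_walkers(theta_star, lp, lower = c(0, 0), upper = c(10, 10),
                       config = cfg)
  expect_true(all(init[, 1] > 0 & init[, 1] < 10))
  # CLT check on the mean: within 3 standard errors of theta_star
  for (j in 1:2) {
    se <- 0.01 * theta_star[j] / sqrt(nrow(init))
    expect_lt(abs(mean(init[, j]) - theta_star[j]), 3 * se)
    # per-coordinate SD matches 0.01 * theta within 10%
    expect_equal(stats::sd(init[, j]), unname(0.01 * theta_star[j]),
                 tolerance = 0.1)
  }
  # impossible initialization errors out
  expect_error(
    init_walkers(theta_star, function(theta) -Inf, c(0, 0), c(10, 10),
                 mcmc_config(n_walkers = 4), max_tries = 5),
    "could not initialize")
})

test_that("the stretch move samples a 2-D Gaussian correctly", {
  ch <- run_gaussian_chain()
  ps <- posterior_samples(ch)
  # posterior mean within +/- 0.05 and marginal SDs within 5% of 1
  expect_lt(abs(mean(ps$x1)), 0.05)
  expect_lt(abs(mean(ps$x2)), 0.05)
  expect_equal(stats::sd(ps$x1), 1, tolerance = 0.05)
  expect_equal(stats::sd(ps$x2), 1, tolerance = 0.05)
  expect_true(all(is.finite(ps$log_post)))
  expect_equal(nrow(ps), 32 * (1500 - 500))
})

test_that("1-D Normal target matches the analytic CDF (KS check)", {
  cfg <- mcmc_config(n_walkers = 32L, n_steps = 1500L, burn_in = 500L,
                     seed = 8)
  init <- matrix(stats::rnorm(32, 0, 0.1), ncol = 1,
                 dimnames = list(NULL, "x"))
  ch <- run_ensemble(function(theta) -0.5 * theta[[1]]^2, init, cfg)
  x <- posterior_samples(ch)$x
  x <- x[seq(1, length(x), length.out = 3e4)]
  ks <- max(abs(stats::ecdf(x)(x) - stats::pnorm(x)))
  expect_lt(ks, 0.02)
})

test_that("uniform box target stays in support with sane acceptance", {
  cfg <- mcmc_config(n_walkers = 16L, n_steps = 800L, burn_in = 200L,
                     seed = 3)
  lpu <- function(theta) {
    if (any(theta < 0 | theta > 1)) -Inf else 0
  }
  init <- matrix(stats::runif(16 * 2, 0.4, 0.6), ncol = 2,
                 dimnames = list(NULL, c("u1", "u2")))
  ch <- run_ensemble(lpu, init, cfg)
  ps <- posterior_samples(ch)
  expect_true(all(ps$u1 >= 0 & ps$u1 <= 1))
  expect_true(all(ps$u2 >= 0 & ps$u2 <= 1))
  expect_true(all(ch$acceptance > 0.1 & ch$acceptance < 0.95))
})

test_that("chains are bit-identical under a fixed seed", {
  c1 <- run_gaussian_chain(n_steps = 300L, burn_in = 100L, seed = 77)
  c2 <- run_gaussian_chain(n_steps = 300L, burn_in = 100L, seed = 77)
  expect_identical(c1$samples, c2$samples)
  expect_identical(c1$log_post, c2$log_post)
  c3 <- run_gaussian_chain(n_steps = 300L, burn_in = 100L, seed = 78)
  expect_false(identical(c1$samples, c3$samples))
})

test_that("Geweke is calibrated under the null and detects drift", {
  # null: iid Normal chains should essentially never flag |Z| >= 3
  set.seed(99)
  zs <- replicate(200, {
    g <- geweke(stats::rnorm(1e4))
    abs(g$z)
  })
  expect_gte(mean(zs < 3), 0.99)
  # power: a linear trend spanning 5 SDs is detected
  set.seed(100)
  drift <- stats::rnorm(1e4) + seq(0, 5, length.out = 1e4)
  expect_lt(geweke(drift)$p_value, 0.05)
  # a series equal to its own reverse has identical first-k / last-k
  # segment means for equal fractions, giving Z of exactly zero
  set.seed(101)
  half <- stats::rnorm(5e3)
  sym <- c(half, rev(half))
  expect_lt(abs(geweke(sym, first = 0.25, last = 0.25)$z), 1e-8)
  # degenerate chains error
  expect_error(geweke(rep(1, 1000)), "zero-variance")
  expect_error(geweke(stats::rnorm(50)), "too short")
})

test_that("Geweke on a chain_set reports one p-value per parameter", {
  ch <- run_gaussian_chain(n_steps = 800L, burn_in = 300L, seed = 21)
  gw <- geweke(ch)
  expect_equal(gw$parameter, c("x1", "x2"))
  expect_true(all(gw$p_value >= 0 & gw$p_value <= 1))
  expect_identical(attr(gw, "pass"), all(gw$p_value > 0.05))
})

test_that("chain summaries and persistence round-trip", {
  ch <- run_gaussian_chain(n_steps = 300L, burn_in = 100L, seed = 5)
  td <- tidy(ch)
  expect_equal(td$parameter, c("x1", "x2"))
  expect_true(all(td$conf_low <= td$median & td$median <= td$conf_high))
  gl <- glance(ch)
  expect_equal(gl$retained_samples, 32 * 200)

  prefix <- file.path(withr::local_tempdir(), "chains")
  write_chains(ch, prefix)
  back <- read_chains(prefix)
  expect_equal(back$samples, ch$samples, tolerance = 0)
  expect_equal(back$log_post, ch$log_post, tolerance = 0)
  expect_identical(back$parameters, ch$parameters)
  expect_identical(back$burn_in, ch$burn_in)
})
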