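# toy forward models used throughout: cheap, analytic, named in/out.
# forward functions receive a named subset of the parameters and must
# complete it from the defaults (the calibration_problem contract)
with_defaults <- function(defaults, impl) {
  function(theta) {
    full <- defaults
    full[names(theta)] <- theta
    impl(full)
  }
}

linear_fn <- function(A, names_out, defaults = NULL) {
  if (is.null(defaults)) {
    defaults <- stats::setNames(rep(1, ncol(A)), colnames(A))
  }
  with_defaults(defaults, function(full) {
    stats::setNames(as.numeric(A %*% full[colnames(A)]), names_out)
  })
}

test_that("sensitivity matrix is exact on linear models and scales with sigma", {
  A <- matrix(c(2, -1, 0.5, 3), nrow = 2,
              dimnames = list(NULL, c("p1", "p2")))
  fn <- linear_fn(A, c("y1", "y2"))
  theta <- c(p1 = 1.5, p2 = 0.8)
  sigma <- c(y1 = 0.5, y2 = 2)
  S <- sensitivity_matrix(fn, theta, sigma)
  # forward differences are exact on linear f: S_kl = A_kl * theta_l / sigma_k
  expected <- A * outer(1 / sigma, theta)
  expect_equal(unname(S), unname(expected), tolerance = 1e-9)
  # doubling sigma_k halves row k only
  S2 <- sensitivity_matrix(fn, theta, c(y1 = 1.0, y2 = 2))
  expect_equal(S2["y1", ], S["y1", ] / 2, tolerance = 1e-9)
  expect_equal(S2["y2", ], S["y2", ], tolerance = 1e-9)
})

test_that("finite differences agree with the analytic derivative on a quadratic", {
  fn <- function(theta) c(y = theta[["p"]]^2)
  theta <- c(p = 3)
  S <- sensitivity_matrix(fn, theta, c(y = 1), rel_step = 1e-4)
  analytic <- 2 * 3 * 3 / 1
  # forward differences carry an O(h) truncation error
  expect_equal(S[1, 1], analytic, tolerance = 1e-3)
  expect_error(sensitivity_matrix(fn, c(p = 0), c(y = 1)), "zero-valued")
})

test_that("sensitivity computation retries with halved steps on failure", {
  # model fails for p > 2.0015: the default step at p = 2 (h = 2e-3)
  # crosses the failure boundary, the halved step does not
  fn <- function(theta) {
    if (theta[["p"]] > 2.0015) return(NULL)
    c(y = 2 * theta[["p"]])
  }
  S <- sensitivity_matrix(fn, c(p = 2), c(y = 1), rel_step = 1e-3)
  expect_equal(S[1, 1], 4, tolerance = 1e-6)
  fn_always <- function(theta) if (theta[["p"]] != 1) NULL else c(y = 1)
  expect_error(sensitivity_matrix(fn_always, c(p = 1), c(y = 1)),
               "perturbations")
})

test_that("parameter importance is the column root-mean-square", {
  S <- cbind(a = rep(0, 4), b = rep(3, 4), c = c(1, -2, 0.5, 4))
  delta <- parameter_importance(S)
  expect_equal(delta[["a"]], 0)
  expect_equal(delta[["b"]], 3)
  # brute-force oracle on a random matrix
  set.seed(11)
  R <- matrix(stats::rnorm(12), nrow = 4)
  expect_equal(unname(parameter_importance(R)),
               apply(R, 2, function(col) sqrt(mean(col^2))))
  # reordering measurements leaves delta unchanged; scaling all sigma by c
  # scales delta by 1/c (sigma enters S linearly)
  expect_equal(parameter_importance(R[c(3, 1, 4, 2), ]),
               parameter_importance(R))
})

test_that("collinearity matches the closed form 1/sqrt(1 - |cos|)", {
  # eigen-decomposition path vs closed form on random matrices
  set.seed(23)
  for (rep in 1:20) {
    S <- matrix(stats::rnorm(5 * 3), nrow = 5)
    colnames(S) <- c("a", "b", "c")
    for (pair in list(c(1, 2), c(1, 3), c(2, 3))) {
      u <- S[, pair[1]] / sqrt(sum(S[, pair[1]]^2))
      w <- S[, pair[2]] / sqrt(sum(S[, pair[2]]^2))
      closed <- 1 / sqrt(1 - abs(sum(u * w)))
      expect_equal(collinearity(S, pair[1], pair[2]), closed,
                   tolerance = 1e-10)
    }
    G <- collinearity_matrix(S)
    expect_equal(G, t(G))
    expect_true(all(G[upper.tri(G)] >= 1))
  }
  # orthogonal columns: gamma = 1
  S_orth <- cbind(c(1, 0, 0), c(0, 1, 0))
  expect_equal(collinearity(S_orth, 1, 2), 1)
  # proportional columns: gamma hits the cap sentinel
  S_prop <- cbind(c(1, 2, 3), c(2, 4, 6))
  expect_gt(collinearity(S_prop, 1, 2), 1e6)
  # |cos| = 0.99 corresponds to gamma = 10, the default threshold
  th <- acos(0.99)
  S_99 <- cbind(c(1, 0), c(cos(th), sin(th)))
  expect_equal(collinearity(S_99, 1, 2), 10, tolerance = 1e-10)
  expect_equal(reduction_config()$t_c, 10)
})

test_that("zero-importance columns yield NA collinearity", {
  S <- cbind(a = c(1, 2), b = c(0, 0))
  expect_true(is.na(collinearity(S, "a", "b")))
})

test_that("reduction fixes exactly one member of a fully collinear pair", {
  # f(theta) = theta1 * theta2: one output, perfectly compensating pair
  ptab <- tibble::tibble(name = c("t1", "t2"), units = "1",
                         value = c(1, 2), min = c(0.1, 0.1),
                         max = c(5, 5), status = "free")
  ms <- measurement_set(data.frame(name = "y", value = 2, sigma = 0.1))
  prob <- calibration_problem(
    with_defaults(c(t1 = 1, t2 = 2),
                  function(full) c(y = full[["t1"]] * full[["t2"]])),
    ptab, ms)
  red <- reduce_parameters(prob, reduction_config(),
                           ga_config(pop_size = 20, generations = 20,
                                     seed = 1))
  expect_length(red$fixed, 1)
  expect_length(red$free, 1)
  expect_match(red$iterations[[1]]$reason, "collinear-with:")
  expect_true(red$converged)
  # fixed at its nominal value
  expect_equal(unname(red$fixed_values),
               ptab$value[match(red$fixed, ptab$name)])
})

test_that("reduction fixes parameters absent from the outputs by importance", {
  ptab <- tibble::tibble(name = c("t1", "t2", "t3"), units = "1",
                         value = c(1, 2, 1), min = 0.1, max = 5,
                         status = "free")
  ms <- measurement_set(data.frame(name = c("y1", "y2"), value = c(1, 2),
                                   sigma = c(0.1, 0.1)))
  prob <- calibration_problem(
    with_defaults(c(t1 = 1, t2 = 2, t3 = 1),
                  function(full) c(y1 = full[["t1"]], y2 = full[["t2"]])),
    ptab, ms)
  red <- reduce_parameters(prob, reduction_config(),
                           ga_config(pop_size = 20, generations = 20,
                                     seed = 1))
  expect_true("t3" %in% red$fixed)
  it_t3 <- Filter(function(it) identical(it$fixed, "t3"), red$iterations)
  expect_equal(it_t3[[1]]$reason, "low-importance")
  expect_setequal(red$free, c("t1", "t2"))
})

test_that("pipeline-fixed parameters match the rank deficiency of an exact Jacobian", {
  # linear-Gaussian toy: y = A theta with a rank-2 A in 3 parameters;
  # the SVD null direction involves p2 and p3 equally, so the reduction
  # must fix exactly one of them and keep p1
  A <- cbind(c(1, 0, 1), c(0, 1, 1), c(0, 1, 1))
  colnames(A) <- c("p1", "p2", "p3")
  sv <- svd(A)
  expect_lt(sv$d[3] / sv$d[1], 1e-12)  # oracle: rank deficiency exists
  null_dir <- abs(sv$v[, 3]) > 1e-8
  expect_equal(colnames(A)[null_dir], c("p2", "p3"))

  ptab <- tibble::tibble(name = colnames(A), units = "1",
                         value = c(1, 1.5, 0.5), min = 0.1, max = 5,
                         status = "free")
  truth <- c(p1 = 1, p2 = 1.5, p3 = 0.5)
  y <- as.numeric(A %*% truth)
  ms <- measurement_set(data.frame(name = paste0("y", 1:3), value = y,
                                   sigma = 0.05))
  prob <- calibration_problem(
    linear_fn(A, paste0("y", 1:3),
              defaults = stats::setNames(ptab$value, ptab$name)),
    ptab, ms)
  red <- reduce_parameters(prob, reduction_config(),
                           ga_config(pop_size = 30, generations = 40,
                                     seed = 2))
  expect_length(red$fixed, 1)
  expect_true(red$fixed %in% c("p2", "p3"))
  expect_true("p1" %in% red$free)
})

test_that("prediction-safety check retains parameters the prediction needs", {
  # p2 and p3 are collinear for the measured output but p3 alone drives
  # the core prediction: fixing p3 would fictitiously shrink the
  # prediction uncertainty, so p2 must be the one fixed
  fn <- with_defaults(c(p2 = 1, p3 = 1),
                      function(full) c(y = full[["p2"]] * full[["p3"]],
                                       pred = full[["p3"]]))
  ptab <- tibble::tibble(name = c("p2", "p3"), units = "1",
                         value = c(1, 1), min = 0.1, max = 5,
                         status = "free")
  ms <- measurement_set(data.frame(name = "y", value = 1, sigma = 0.1))
  prob <- calibration_problem(fn, ptab, ms, predictions = "pred")
  red <- reduce_parameters(prob, reduction_config(),
                           ga_config(pop_size = 20, generations = 15,
                                     seed = 3))
  expect_identical(red$fixed, "p2")
  expect_identical(red$free, "p3")
})

test_that("reduction terminates and reports tidy/glance summaries", {
  ptab <- tibble::tibble(name = c("t1", "t2"), units = "1",
                         value = c(1, 2), min = 0.1, max = 5,
                         status = "free")
  ms <- measurement_set(data.frame(name = "y", value = 2, sigma = 0.1))
  prob <- calibration_problem(
    with_defaults(c(t1 = 1, t2 = 2),
                  function(full) c(y = full[["t1"]] * full[["t2"]])),
    ptab, ms)
  red <- reduce_parameters(prob, reduction_config(),
                           ga_config(pop_size = 16, generations = 10,
                                     seed = 1))
  expect_lte(length(red$iterations), 2)  # <= n_theta - 1 fixations, + final
  td <- tidy(red)
  expect_true(all(c("iteration", "parameter", "delta", "max_gamma",
                    "fixed") %in% names(td)))
  gl <- glance(red)
  expect_equal(gl$n_free + gl$n_fixed, 2)
  path <- withr::local_tempfile(fileext = ".json")
  write_reduction_json(red, path)
  blob <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(blob$free, red$free)
})
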