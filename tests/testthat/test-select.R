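test_that("a single strong regulator is recovered with its coefficient", {
  # x_t = 50 + 2000 * f_3 - u/0.5, low noise
  prob <- random_problem(m = 120, p = 8, k = 0, sigma = 1, seed = 3)
  beta3 <- 2000
  x_t <- 50 + beta3 * prob$design[, 3] - prob$response / 0.5 +
    rnorm(120, 0, 1)
  prob$design[, 9] <- -x_t
  sel <- select_model(prob)
  expect_identical(sel$regressors, "r3")
  expect_equal(unname(sel$weights["r3"]), beta3, tolerance = 0.01)
  expect_equal(sel$lambda, 0.5, tolerance = 0.01)
})

test_that("pure-noise responses select the empty model almost always", {
  empty <- 0
  for (s in 1:200) {
    set.seed(s)
    m <- 5000
    H <- matrix(runif(m * 5), m, 5)
    u <- rnorm(m)
    x_t <- runif(m, 100, 1000)            # level unrelated to candidates
    prob <- structure(list(
      target = "t", target_index = 6L, response = u,
      design = cbind(H, -x_t), regressor_genes = paste0("r", 1:5),
      K = stats::setNames(rep(0.5, 5), paste0("r", 1:5)),
      row_meta = data.frame(kind = rep("time_series", m)),
      basis = basis_config()), class = "regression_problem")
    colnames(prob$design) <- c(paste0("r", 1:5), ".degradation")
    if (length(select_model(prob)$regressors) == 0) empty <- empty + 1
  }
  expect_gte(empty / 200, 0.95)
})

test_that("selected coefficients equal the least-squares refit on those columns", {
  for (s in 1:10) {
    prob <- random_problem(m = 60, p = 7, k = 2, sigma = 20, seed = 100 + s)
    sel <- select_model(prob)
    if (!length(sel$regressors)) next
    H <- prob$design[, match(sel$regressors, prob$regressor_genes), drop = FALSE]
    x_t <- -prob$design[, 8]
    refit <- stats::lm(x_t ~ H + prob$response)
    expect_equal(unname(sel$weights), unname(coef(refit)[2:(1 + ncol(H))]),
                 tolerance = 1e-8)
    expect_equal(sel$rss, sum(residuals(refit)^2), tolerance = 1e-8)
  }
})

test_that("the cost trace is non-increasing and ends at the returned model", {
  for (s in 1:20) {
    prob <- random_problem(m = 50, p = 6, k = 2, sigma = 30, seed = 300 + s)
    sel <- select_model(prob)
    expect_true(all(diff(sel$cost_trace) <= 1e-10))
    expect_equal(sel$cost, min(sel$cost_trace), tolerance = 1e-8)
  }
})

test_that("selection is deterministic", {
  prob <- random_problem(m = 60, p = 8, k = 3, sigma = 25, seed = 77)
  s1 <- select_model(prob)
  s2 <- select_model(prob)
  expect_identical(s1[c("regressors", "weights", "lambda", "cost")],
                   s2[c("regressors", "weights", "lambda", "cost")])
})

test_that("an all-zero expression matrix yields the empty model", {
  m <- matrix(0, 3, 6, dimnames = list(c("a", "b", "c"), paste0("s", 1:6)))
  meta <- data.frame(sample_id = paste0("s", 1:6), kind = "steady_state",
                     replicate = NA_integer_, time_h = NA_real_,
                     perturbed_gene = rep(c("a", "b", "c"), 2),
                     knockdown_fraction = 0.5)
  ds <- expression_dataset(m, meta)
  prob <- build_ss_problem(ds, "a", basis_config(rule = "fixed", K_fixed = 1))
  expect_length(select_model(prob)$regressors, 0)
})

test_that("rank-deficient designs are handled by dropping dependent columns", {
  prob <- random_problem(m = 40, p = 5, k = 1, sigma = 5, seed = 55)
  prob$design[, 2] <- prob$design[, 1]       # duplicate column
  sel <- select_model(prob)
  expect_false(all(c("r1", "r2") %in% sel$regressors))
  expect_true(all(is.finite(sel$weights)))
})
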