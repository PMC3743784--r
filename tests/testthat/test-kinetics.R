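test_that("parameter sampling is deterministic and respects its ranges", {
  net <- generate_scale_free(20, k_av = 3, seed = 1)
  m1 <- sample_parameters(net, seed = 5)
  m2 <- sample_parameters(net, seed = 5)
  expect_identical(m1[c("V", "lambda", "b", "theta", "phi")],
                   m2[c("V", "lambda", "b", "theta", "phi")])
  lams <- unlist(lapply(1:50, function(s) {
    sample_parameters(net, seed = s)$lambda
  }))
  expect_true(all(lams >= 0.1 & lams <= 1))
  Vs <- unlist(lapply(1:50, function(s) sample_parameters(net, seed = s)$V))
  expect_true(all(Vs >= 100 & Vs <= 1000))
})

test_that("regulation rate has the saturating form and monotonicity", {
  net <- gene_network(3, data.frame(parent = c(1, 2), child = c(3, 3),
                                    sign = c(1L, -1L)))
  model <- sample_parameters(net, seed = 2, calibrate = FALSE)
  # gene with no regulators: g = b
  expect_equal(regulation_rate(1, c(500, 500, 500), model), model$b[1])
  # saturation limit: lone activator at very high expression -> b + 1
  net2 <- gene_network(2, data.frame(parent = 1, child = 2, sign = 1L))
  model2 <- sample_parameters(net2, seed = 3, calibrate = FALSE)
  expect_equal(regulation_rate(2, c(1e12, 0), model2), model2$b[2] + 1,
               tolerance = 1e-6)
  # raising an inhibitor never increases g (1000 random states)
  set.seed(11)
  for (i in 1:1000) {
    x <- runif(3, 0, 3000)
    g0 <- regulation_rate(3, x, model)
    x2 <- x
    x2[2] <- x[2] + runif(1, 1, 2000)
    expect_lte(regulation_rate(3, x2, model), g0 + 1e-12)
  }
})

test_that("reference state solves the ODE and is reproducible", {
  fx <- saturating_fixture()
  x <- fx$model$x_ref
  dx <- mikana:::model_derivs(as.numeric(x), fx$model)
  expect_lt(max(abs(dx)) / max(x), 1e-6)
  expect_identical(x, find_reference_state(fx$model, seed = 9))
  expect_false(identical(as.numeric(x),
                         as.numeric(find_reference_state(fx$model, seed = 10))))
})

test_that("an isolated gene settles at V*b/lambda", {
  net <- gene_network(1)
  model <- sample_parameters(net, seed = 4)
  x <- find_reference_state(model, seed = 1)
  expect_equal(as.numeric(x), model$V[1] * model$b[1] / model$lambda[1],
               tolerance = 1e-6)
})

test_that("sampled models are overwhelmingly stable on 20-gene networks", {
  ok <- 0
  for (s in 1:50) {
    net <- generate_scale_free(20, k_av = 3, seed = s)
    model <- sample_parameters(net, seed = 100 + s)
    x <- tryCatch(find_reference_state(model, seed = 200 + s),
                  mikana_stability_error = function(e) NULL)
    if (!is.null(x) && all(is.finite(x)) && all(x >= 0)) ok <- ok + 1
  }
  expect_gte(ok / 50, 0.9)
})

test_that("knockdown clamps the target and relaxes the rest", {
  fx <- saturating_fixture()
  xr <- fx$model$x_ref
  # delta = 0: nothing changes
  x0 <- simulate_knockdown(fx$model, 1, 0)
  expect_equal(as.numeric(x0), as.numeric(xr), tolerance = 1e-5)
  # delta = 1: the clamped entry is exactly zero
  x1 <- simulate_knockdown(fx$model, 3, 1)
  expect_identical(unname(x1[3]), 0)
  # partial knockdown holds the clamp exactly
  x5 <- simulate_knockdown(fx$model, 5, 0.4)
  expect_equal(unname(x5[5]), unname(0.6 * xr[5]))
  expect_error(simulate_knockdown(fx$model, 1, 1.5), "delta")
})

test_that("knockdowns only propagate along directed paths", {
  # two disconnected blocks: 1->2->3 and 4->5
  net <- gene_network(5, data.frame(parent = c(1, 2, 4), child = c(2, 3, 5),
                                    sign = 1L))
  model <- sample_parameters(net, seed = 21)
  model$x_ref <- find_reference_state(model, seed = 22)
  kd <- simulate_knockdown(model, 1, 0.9)
  unreachable <- setdiff(1:5, c(1, reachable_from(net, 1)))
  expect_equal(sort(unreachable), c(4, 5))
  rel <- abs(kd - model$x_ref) / model$x_ref
  expect_true(all(rel[unreachable] < 1e-6))
})

test_that("steady-state datasets record one perturbation per sample", {
  fx <- saturating_fixture()
  ds <- simulate_steady_state_dataset(fx$model, seed = 31)
  expect_equal(ncol(ds$matrix), 12)
  expect_setequal(ds$sample_meta$perturbed_gene, fx$net$genes)
  expect_true(all(table(ds$sample_meta$perturbed_gene) == 1))
  expect_true(all(ds$sample_meta$knockdown_fraction >= 0 &
                    ds$sample_meta$knockdown_fraction <= 1))
  empty <- simulate_steady_state_dataset(fx$model, targets = integer(0))
  expect_equal(ncol(empty$matrix), 0)
  # repeated targets act as independent experiments
  rep2 <- simulate_steady_state_dataset(fx$model, targets = c(1, 1), seed = 5)
  expect_equal(ncol(rep2$matrix), 2)
  expect_false(identical(rep2$matrix[, 1], rep2$matrix[, 2]))
  expect_identical(ds$matrix,
                   simulate_steady_state_dataset(fx$model, seed = 31)$matrix)
})

test_that("time series relax from perturbed initial conditions to steady state", {
  fx <- saturating_fixture()
  ts <- simulate_timeseries(fx$model, n_timepoints = 10, n_replicates = 3,
                            seed = 41)
  expect_equal(ncol(ts$matrix), 30)
  for (r in 1:3) {
    tt <- ts$sample_meta$time_h[ts$sample_meta$replicate == r]
    expect_length(tt, 10)
    expect_true(all(diff(tt) > 0))
  }
  # rho = 0 keeps the system at the reference state
  flat <- simulate_timeseries(fx$model, 5, 1, rho = matrix(0, 12, 1))
  expect_lt(max(abs(flat$matrix - as.numeric(fx$model$x_ref))), 1e-3)
  # long default horizon: the final interval changes little (near new steady state)
  m <- ts$matrix[, ts$sample_meta$replicate == 1]
  rel_change <- abs(m[, 10] - m[, 9]) / pmax(abs(m[, 9]), 1)
  expect_lt(max(rel_change), 0.05)
  expect_error(simulate_timeseries(fx$model, 1, 3), "time points")
})

test_that("the euler method generates the exact discrete-time model", {
  fx <- oracle_fixture()
  m <- fx$ts$matrix[, fx$ts$sample_meta$replicate == 2]
  tt <- fx$ts$sample_meta$time_h[fx$ts$sample_meta$replicate == 2]
  for (k in c(1, 7, 19)) {
    dt <- tt[k + 1] - tt[k]
    step <- m[, k] + dt * mikana:::model_derivs(m[, k], fx$model)
    expect_equal(unname(m[, k + 1]), unname(step), tolerance = 1e-12)
  }
})

test_that("hill-sum models validate their inputs", {
  net <- gene_network(3, data.frame(parent = 1, child = 2, sign = 1L))
  expect_error(hill_kinetic_model(net, lambda = 0.5, K = 500), "weight")
  net$edges$weight <- 800
  expect_error(hill_kinetic_model(net, lambda = 0.5, K = -1), "positive")
  model <- hill_kinetic_model(net, lambda = 0.5, K = 500)
  expect_s3_class(model, "kinetic_model")
  expect_error(simulate_knockdown(model, 1, 0.5), "reference state")
})
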