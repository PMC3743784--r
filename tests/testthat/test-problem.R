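test_that("hill basis matches its closed forms", {
  expect_identical(hill_basis(0, K = 500, n = 2), 0)
  for (n in c(1, 2, 4.5)) expect_equal(hill_basis(500, K = 500, n = n), 0.5)
  expect_equal(hill_basis(1000, K = 500, n = 2), 0.8)
  expect_error(hill_basis(10, K = 0), "K must")
  expect_error(basis_config(rule = "fixed"), "K_fixed")
  expect_error(basis_config(n = -1), "exponent")
})

test_that("steady-state problems drop the sample perturbing the target", {
  fx <- oracle_fixture()          # 3 knockdown sweeps over 10 genes
  prob <- build_ss_problem(fx$ss, "g001", fx$basis)
  expect_equal(length(prob$response), 30 - 3)
  expect_true(all(prob$response == 0))
  # a target never perturbed keeps every row
  ss_partial <- subset_samples(fx$ss, fx$ss$sample_meta$perturbed_gene != "g002")
  prob2 <- build_ss_problem(ss_partial, "g002", fx$basis)
  expect_equal(length(prob2$response), ncol(ss_partial$matrix))
  # no Hill column for the target; degradation column is last and equals -x
  expect_false("g001" %in% prob$regressor_genes)
  expect_equal(colnames(prob$design)[10], ".degradation")
  kept <- fx$ss$sample_meta$perturbed_gene != "g001"
  expect_equal(unname(prob$design[, 10]), unname(-fx$ss$matrix["g001", kept]))
  # all samples perturbing the target -> no usable rows
  only_t <- subset_samples(fx$ss, fx$ss$sample_meta$perturbed_gene == "g001")
  expect_error(build_ss_problem(only_t, "g001", fx$basis), "no usable rows")
})

test_that("time-series problems difference within replicates only", {
  fx <- oracle_fixture()          # 3 replicates x 20 points
  prob <- build_ts_problem(fx$ts, "g003", fx$basis)
  expect_equal(length(prob$response), 3 * 19)
  expect_true(all(prob$row_meta$kind == "time_series"))
  # a linear trajectory has exact forward-difference derivative everywhere
  tt <- c(0, 0.7, 1.1, 3, 4.2)
  m <- rbind(a = 5 * tt + 100, b = runif(5, 100, 1000))
  colnames(m) <- paste0("s", 1:5)
  ds <- expression_dataset(m, data.frame(
    sample_id = paste0("s", 1:5), kind = "time_series", replicate = 1L,
    time_h = tt, perturbed_gene = NA_character_, knockdown_fraction = NA_real_))
  p <- build_ts_problem(ds, "a")
  expect_equal(unname(p$response), rep(5, 4))
  # constant trajectory -> zero response
  m2 <- rbind(a = rep(7, 5), b = rep(3, 5))
  colnames(m2) <- paste0("s", 1:5)
  ds2 <- expression_dataset(m2, ds$sample_meta)
  expect_true(all(build_ts_problem(ds2, "a")$response == 0))
  # single-point replicate is rejected
  ds1 <- subset_samples(ds, 1)
  expect_error(build_ts_problem(ds1, "a"), "fewer than 2")
})

test_that("combined problems reduce to their single-type counterparts", {
  fx <- oracle_fixture()
  for (g in c("g001", "g007")) {
    ss_only <- build_combined_problem(fx$ss, NULL, g, fx$basis)
    ref_ss <- build_ss_problem(fx$ss, g, fx$basis)
    expect_equal(ss_only$design, ref_ss$design)
    expect_equal(ss_only$response, ref_ss$response)
    ts_only <- build_combined_problem(NULL, fx$ts, g, fx$basis)
    ref_ts <- build_ts_problem(fx$ts, g, fx$basis)
    expect_equal(ts_only$design, ref_ts$design)
    expect_equal(ts_only$response, ref_ts$response)
  }
  expect_error(build_combined_problem(NULL, NULL, "g001", fx$basis), "empty")
})

test_that("combined problems stack time-series rows above steady-state rows", {
  # 25 genes: one 10-point temporal experiment plus 20 knockdowns that never
  # target gene 21 -> 9 + 20 rows for that gene
  net <- generate_scale_free(25, k_av = 2, seed = 3)
  model <- sample_parameters(net, seed = 4)
  model$x_ref <- find_reference_state(model, seed = 5)
  ss <- simulate_steady_state_dataset(model, targets = 1:20, seed = 6)
  ts <- simulate_timeseries(model, 10, 1, seed = 7)
  prob <- build_combined_problem(ss, ts, 21)
  expect_equal(length(prob$response), 9 + 20)
  expect_equal(prob$row_meta$kind, rep(c("time_series", "steady_state"),
                                       c(9, 20)))
  # provenance names every row's source sample
  expect_true(all(prob$row_meta$sample_id %in%
                    c(ss$sample_meta$sample_id, ts$sample_meta$sample_id)))
})

test_that("median rule centres each regressor's half-saturation in its data", {
  fx <- saturating_fixture()
  ss <- simulate_steady_state_dataset(fx$model, seed = 51)
  prob <- build_ss_problem(ss, 1, basis_config())
  for (g in prob$regressor_genes[1:3]) {
    kept <- ss$sample_meta$perturbed_gene != fx$net$genes[1]
    expect_equal(unname(prob$K[g]),
                 max(median(pmax(ss$matrix[g, kept], 0)), 1e-6))
  }
  fixed <- build_ss_problem(ss, 1, basis_config(rule = "fixed", K_fixed = 123))
  expect_true(all(fixed$K == 123))
})
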