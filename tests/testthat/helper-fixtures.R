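# Shared fixtures, all generated in code.

# Well-specified oracle instance: 10-gene activating ring + 5 chords with
# known Hill-sum kinetics; steady-state data from 3 knockdown sweeps and
# time-series data from the discrete-time (Euler) variant of the model, so
# the inference model is exactly correct for both data types.
oracle_fixture_cache <- new.env(parent = emptyenv())
oracle_fixture <- function() {
  if (is.null(oracle_fixture_cache$fx)) {
    model <- hill_ring_network(10, n_extra = 5, seed = 42)
    model$x_ref <- find_reference_state(model, seed = 1)
    ss <- simulate_steady_state_dataset(model, targets = rep(1:10, 3), seed = 2)
    ts <- simulate_timeseries(model, n_timepoints = 20, n_replicates = 3,
                              seed = 3, method = "euler", horizon = 19 * 0.25)
    oracle_fixture_cache$fx <- list(
      model = model, ss = ss, ts = ts,
      basis = basis_config(n = model$n, rule = "fixed", K_fixed = model$K))
  }
  oracle_fixture_cache$fx
}

# A small saturating-kinetics instance for integration-style tests.
saturating_fixture <- function(n_genes = 12, seed = 7) {
  net <- generate_scale_free(n_genes, k_av = 3, seed = seed)
  model <- sample_parameters(net, seed = seed + 1)
  model$x_ref <- find_reference_state(model, seed = seed + 2)
  list(net = net, model = model)
}

# Random regression problem in the package's own container, for selection
# tests: p Hill-like candidate columns, a degradation column, and a response
# generated from a sparse truth (k active terms) plus Gaussian noise.
random_problem <- function(m, p, k, sigma, seed,
                           beta_scale = 800, lambda = 0.5, basal = 50) {
  set.seed(seed)
  H <- matrix(runif(m * p), m, p)
  x_t <- numeric(m)
  active <- if (k > 0) sample(p, k) else integer(0)
  beta <- numeric(p)
  beta[active] <- rnorm(k, 0, beta_scale)
  u <- rnorm(m, 0, 50)                     # derivative response rows
  x_t <- basal + drop(H %*% beta) - u / lambda + rnorm(m, 0, sigma)
  design <- cbind(H, -x_t)
  colnames(design) <- c(paste0("r", seq_len(p)), ".degradation")
  structure(list(
    target = "target", target_index = p + 1L, response = u,
    design = design, regressor_genes = paste0("r", seq_len(p)),
    K = stats::setNames(rep(0.5, p), paste0("r", seq_len(p))),
    row_meta = data.frame(kind = rep("time_series", m),
                          sample_id = sprintf("s%d", seq_len(m)),
                          pair_to = NA_character_),
    basis = basis_config()), class = "regression_problem")
}

# Uniform-random directed graph with a fixed number of edges (test oracle
# for the degree-distribution comparison; not part of the package).
erdos_renyi_digraph <- function(n, m_edges, seed) {
  set.seed(seed)
  off_diag <- setdiff(seq_len(n * n), seq(1, n * n, by = n + 1))
  pick <- sample(off_diag, m_edges)
  parent <- ((pick - 1) %% n) + 1
  child <- ((pick - 1) %/% n) + 1
  gene_network(n, data.frame(parent = parent, child = child, sign = 1L))
}

# Random signed network over a fixed universe (for evaluation tests).
random_network <- function(n, m_edges, seed) {
  set.seed(seed)
  pairs <- expand.grid(parent = seq_len(n), child = seq_len(n))
  pairs <- pairs[pairs$parent != pairs$child, ]
  pick <- pairs[sample(nrow(pairs), m_edges), ]
  gene_network(n, data.frame(parent = pick$parent, child = pick$child,
                             sign = sample(c(-1L, 1L), m_edges, TRUE),
                             weight = rnorm(m_edges)))
}
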