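#' Simulation study designs
#'
#' Bundles the configuration of the three simulation studies: the noise
#' sweep (inference performance of the three modes across measurement-noise
#' levels), the matched sample-budget comparison (multiple time-series
#' replicates vs a single time series plus knockdowns, at equal total sample
#' count), and the edge-directionality study. `scale = "paper"` uses
#' 100-gene networks and 50 simulations per condition; `scale = "desk"` uses
#' 30 genes and 10 simulations, preserving the qualitative comparisons at a
#' fraction of the cost.
#'
#' @param kind One of `"noise_sweep"`, `"budget_comparison"`,
#'   `"directionality"`.
#' @param scale `"paper"` or `"desk"`.
#' @param n_genes,n_simulations Override the scale preset.
#' @param noise_levels Noise levels for the sweep (fractions of signal).
#' @param timepoint_counts Time points per replicate for each matched budget
#'   (budget = 3x this count).
#' @param n_timepoints,n_replicates Time-series shape for the noise sweep
#'   and directionality study.
#' @param generator `"saturating"` simulates the saturating-kinetics model;
#'   `"hill_sum"` simulates the inference model itself (well-specified
#'   regime, see [hill_ring_network()]).
#' @param base_seed Integer; every per-simulation seed derives from it.
#' @param k_av,p_pos Ground-truth topology parameters.
#' @return An object of class `experiment_design`.
#' @export
experiment_design <- function(kind = c("noise_sweep", "budget_comparison",
                                       "directionality"),
                              scale = c("desk", "paper"),
                              n_genes = NULL, n_simulations = NULL,
                              noise_levels = NULL,
                              timepoint_counts = c(5, 10, 20, 40),
                              n_timepoints = 10, n_replicates = NULL,
                              generator = c("saturating", "hill_sum"),
                              base_seed = 1L, k_av = 3, p_pos = 0.5) {
  kind <- match.arg(kind)
  scale <- match.arg(scale)
  generator <- match.arg(generator)
  n_genes <- n_genes %||% if (scale == "paper") 100L else 30L
  n_simulations <- n_simulations %||% if (scale == "paper") 50L else 10L
  noise_levels <- noise_levels %||% switch(kind,
    noise_sweep = c(0.01, 0.03, 0.05, 0.08, 0.10, 0.13, 0.15, 0.18, 0.20),
    0.10)
  n_replicates <- n_replicates %||% if (kind == "directionality") 10L else 3L
  if (any(noise_levels < 0 | noise_levels > 1)) {
    stop_mikana("noise levels must lie in [0, 1]")
  }
  if (!length(noise_levels) || !length(timepoint_counts)) {
    stop_mikana("design lists must be non-empty")
  }
  structure(list(kind = kind, scale = scale, n_genes = as.integer(n_genes),
                 n_simulations = as.integer(n_simulations),
                 noise_levels = noise_levels,
                 timepoint_counts = as.integer(timepoint_counts),
                 n_timepoints = as.integer(n_timepoints),
                 n_replicates = as.integer(n_replicates),
                 generator = generator, base_seed = as.integer(base_seed),
                 k_av = k_av, p_pos = p_pos),
            class = "experiment_design")
}

#' @export
print.experiment_design <- function(x, ...) {
  cat(sprintf("experiment_design '%s' (%s scale): %d genes, %d simulations, seed %d\n",
              x$kind, x$scale, x$n_genes, x$n_simulations, x$base_seed))
  invisible(x)
}

#' Ring-backbone network with known Hill-sum kinetics
#'
#' Builds the ground truth for the well-specified regime: an activating ring
#' through all genes (so every gene has a regulator sustaining its
#' expression) plus `n_extra` activating chords, with edge weights and
#' degradation rates drawn so that the Hill-sum model has a stable, strictly
#' positive steady state. Used to generate data for which the inference
#' model is exactly correct, where structure and coefficients should be
#' recovered exactly from noiseless data.
#'
#' @param n_genes Number of genes (>= 3).
#' @param n_extra Number of additional chord edges.
#' @param seed Integer seed.
#' @param K Hill half-saturation constant of the model.
#' @param n Hill exponent.
#' @return A `kinetic_model` of form `"hill_sum"` whose `network` carries
#'   the true weights.
#' @export
hill_ring_network <- function(n_genes, n_extra = round(n_genes / 2),
                              seed = NULL, K = 500, n = 2) {
  if (n_genes < 3) stop_mikana("need at least 3 genes")
  with_seed(seed, {
    parent <- seq_len(n_genes)
    child <- c(seq_len(n_genes)[-1], 1L)
    seen <- paste(parent, child)
    added <- 0L
    while (added < n_extra) {
      a <- sample.int(n_genes, 1L)
      b <- sample.int(n_genes, 1L)
      if (a == b || paste(a, b) %in% seen) next
      parent <- c(parent, a)
      child <- c(child, b)
      seen <- c(seen, paste(a, b))
      added <- added + 1L
    }
    lambda <- stats::runif(n_genes, 0.3, 1)
    # per-edge weight large enough that the ring sustains expression well
    # above the Hill half-saturation point
    weight <- stats::runif(length(parent), 1.6, 3.2) * K * lambda[child]
    net <- gene_network(n_genes,
                        data.frame(parent = parent, child = child,
                                   sign = 1L, weight = weight))
    hill_kinetic_model(net, lambda = lambda, K = K, n = n)
  })
}

# Ground truth + kinetics + reference state for one simulation index.
# Stability failures retry with a fresh derived seed (up to 5 attempts).
simulation_instance <- function(design, sim) {
  for (attempt in 1:5) {
    res <- tryCatch({
      if (design$generator == "saturating") {
        net <- generate_scale_free(design$n_genes, k_av = design$k_av,
                                   p_pos = design$p_pos,
                                   seed = derive_seed(design$base_seed, sim, 1, attempt))
        model <- sample_parameters(net, seed = derive_seed(design$base_seed, sim, 2, attempt))
      } else {
        model <- hill_ring_network(design$n_genes,
                                   n_extra = max(0L, round(design$k_av * design$n_genes / 2) - design$n_genes),
                                   seed = derive_seed(design$base_seed, sim, 1, attempt))
        net <- model$network
      }
      model$x_ref <- find_reference_state(
        model, seed = derive_seed(design$base_seed, sim, 3, attempt))
      list(net = net, model = model, attempt = attempt)
    }, mikana_stability_error = function(e) NULL)
    if (!is.null(res)) return(res)
  }
  stop_mikana("no stable model found for simulation %d after 5 attempts", sim,
              class = "mikana_stability_error")
}

# Basis matching the generator: fixed-K for the well-specified regime,
# data-median Hill otherwise.
design_basis <- function(design, model) {
  if (design$generator == "hill_sum") {
    basis_config(n = model$n, rule = "fixed", K_fixed = model$K)
  } else {
    basis_config()
  }
}

design_ts_method <- function(design) {
  if (design$generator == "hill_sum") "euler" else "lsoda"
}

score_row <- function(fit, truth, ...) {
  s <- score_edges(fit$network, truth)
  data.frame(..., sn = s$sensitivity, fdr = s$fdr,
             tp = s$tp, fp = s$fp, fn = s$fn)
}

summarise_scores <- function(detail, by) {
  agg <- stats::aggregate(detail[c("sn", "fdr")], detail[by], function(v) {
    c(mean = mean(v, na.rm = TRUE), sd = stats::sd(v))
  })
  out <- agg[by]
  out$mean_sn <- agg$sn[, "mean"]
  out$sd_sn <- agg$sn[, "sd"]
  out$mean_fdr <- agg$fdr[, "mean"]
  out$sd_fdr <- agg$fdr[, "sd"]
  out
}

new_experiment_result <- function(design, detail, summary, failures) {
  structure(list(design = design, detail = detail, summary = summary,
                 failures = failures), class = "mikana_experiment")
}

#' @export
print.mikana_experiment <- function(x, ...) {
  cat(sprintf("%s (%s scale, %d simulations, %d failed)\n\n",
              x$design$kind, x$design$scale, x$design$n_simulations,
              nrow(x$failures)))
  print(x$summary, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Run the noise-sweep study
#'
#' For each simulation, one ground-truth network and kinetic model are drawn
#' and both data types generated (a knockdown per gene, plus time series).
#' At each noise level, all three inference modes are run and scored against
#' the truth. Simulations whose kinetics never stabilise are logged in the
#' result's `failures` table and excluded from the summary, never silently
#' dropped.
#'
#' @param design An [experiment_design()] of kind `"noise_sweep"`.
#' @return A `mikana_experiment` with per-run `detail` rows and a `summary`
#'   of mean/sd sensitivity and FDR per noise level and mode (one row per
#'   noise level x mode).
#' @export
run_noise_sweep <- function(design) {
  if (design$kind != "noise_sweep") stop_mikana("design kind must be noise_sweep")
  detail <- list()
  failures <- data.frame(sim = integer(), error = character())
  for (sim in seq_len(design$n_simulations)) {
    inst <- tryCatch(simulation_instance(design, sim),
                     mikana_stability_error = function(e) e)
    if (inherits(inst, "error")) {
      failures <- rbind(failures,
                        data.frame(sim = sim, error = conditionMessage(inst)))
      next
    }
    basis <- design_basis(design, inst$model)
    ss0 <- simulate_steady_state_dataset(
      inst$model, seed = derive_seed(design$base_seed, sim, 4))
    ts0 <- simulate_timeseries(
      inst$model, design$n_timepoints, design$n_replicates,
      seed = derive_seed(design$base_seed, sim, 5),
      method = design_ts_method(design))
    for (li in seq_along(design$noise_levels)) {
      lvl <- design$noise_levels[li]
      ssn <- add_noise(ss0, lvl, seed = derive_seed(design$base_seed, sim, 6, li))
      tsn <- add_noise(ts0, lvl, seed = derive_seed(design$base_seed, sim, 7, li))
      for (mode in c("ss", "ts", "combined")) {
        fit <- mikana(ss = if (mode != "ts") ssn else NULL,
                      ts = if (mode != "ss") tsn else NULL,
                      mode = mode, basis = basis)
        detail[[length(detail) + 1]] <-
          score_row(fit, inst$net, sim = sim, noise = lvl, mode = mode,
                    seed = design$base_seed)
      }
    }
  }
  detail <- do.call(rbind, detail)
  new_experiment_result(design, detail,
                        summarise_scores(detail, c("noise", "mode")),
                        failures)
}

#' Run the matched sample-budget comparison
#'
#' Compares two ways of spending the same number of samples: the time-series
#' arm uses `T` time points in 3 replicates (budget `3T`); the combined arm
#' uses a single `T`-point time series plus `2T` steady-state knockdown
#' samples. Both arms of a budget share the same ground-truth network and
#' kinetics. Data carry the design's noise level (default 10%).
#'
#' @param design An [experiment_design()] of kind `"budget_comparison"`;
#'   `timepoint_counts` gives `T` for each budget.
#' @return A `mikana_experiment`; the summary has one row per budget x arm.
#' @export
run_budget_comparison <- function(design) {
  if (design$kind != "budget_comparison") {
    stop_mikana("design kind must be budget_comparison")
  }
  lvl <- design$noise_levels[1]
  detail <- list()
  failures <- data.frame(sim = integer(), error = character())
  for (sim in seq_len(design$n_simulations)) {
    inst <- tryCatch(simulation_instance(design, sim),
                     mikana_stability_error = function(e) e)
    if (inherits(inst, "error")) {
      failures <- rbind(failures,
                        data.frame(sim = sim, error = conditionMessage(inst)))
      next
    }
    basis <- design_basis(design, inst$model)
    genes <- inst$net$genes
    for (bi in seq_along(design$timepoint_counts)) {
      tp <- design$timepoint_counts[bi]
      budget <- 3L * tp
      ts3 <- simulate_timeseries(inst$model, tp, 3L,
                                 seed = derive_seed(design$base_seed, sim, 10, bi),
                                 method = design_ts_method(design))
      ts1 <- simulate_timeseries(inst$model, tp, 1L,
                                 seed = derive_seed(design$base_seed, sim, 11, bi),
                                 method = design_ts_method(design))
      targets <- rep(seq_along(genes), length.out = 2L * tp)
      ss <- simulate_steady_state_dataset(
        inst$model, targets, seed = derive_seed(design$base_seed, sim, 12, bi))
      stopifnot(ncol(ts3$matrix) == ncol(ts1$matrix) + ncol(ss$matrix))
      ts3n <- add_noise(ts3, lvl, derive_seed(design$base_seed, sim, 13, bi))
      ts1n <- add_noise(ts1, lvl, derive_seed(design$base_seed, sim, 14, bi))
      ssn <- add_noise(ss, lvl, derive_seed(design$base_seed, sim, 15, bi))
      fit_ts <- mikana(ts = ts3n, mode = "ts", basis = basis)
      fit_c <- mikana(ss = ssn, ts = ts1n, mode = "combined", basis = basis)
      detail[[length(detail) + 1]] <-
        score_row(fit_ts, inst$net, sim = sim, budget = budget, arm = "ts")
      detail[[length(detail) + 1]] <-
        score_row(fit_c, inst$net, sim = sim, budget = budget, arm = "combined")
    }
  }
  detail <- do.call(rbind, detail)
  new_experiment_result(design, detail,
                        summarise_scores(detail, c("budget", "arm")),
                        failures)
}

#' Run the edge-directionality study
#'
#' Per simulation, all three modes are fitted and the proportion of
#' ground-truth edges recovered with correct (forward) and with flipped
#' (reversed) orientation is computed for each.
#'
#' @param design An [experiment_design()] of kind `"directionality"`.
#' @return A `mikana_experiment`; the summary reports mean forward and
#'   reversed proportions per mode.
#' @export
run_directionality_study <- function(design) {
  if (design$kind != "directionality") {
    stop_mikana("design kind must be directionality")
  }
  lvl <- design$noise_levels[1]
  detail <- list()
  failures <- data.frame(sim = integer(), error = character())
  for (sim in seq_len(design$n_simulations)) {
    inst <- tryCatch(simulation_instance(design, sim),
                     mikana_stability_error = function(e) e)
    if (inherits(inst, "error")) {
      failures <- rbind(failures,
                        data.frame(sim = sim, error = conditionMessage(inst)))
      next
    }
    basis <- design_basis(design, inst$model)
    ss0 <- simulate_steady_state_dataset(
      inst$model, seed = derive_seed(design$base_seed, sim, 4))
    ts0 <- simulate_timeseries(
      inst$model, design$n_timepoints, design$n_replicates,
      seed = derive_seed(design$base_seed, sim, 5),
      method = design_ts_method(design))
    ssn <- add_noise(ss0, lvl, derive_seed(design$base_seed, sim, 6))
    tsn <- add_noise(ts0, lvl, derive_seed(design$base_seed, sim, 7))
    for (mode in c("ss", "ts", "combined")) {
      fit <- mikana(ss = if (mode != "ts") ssn else NULL,
                    ts = if (mode != "ss") tsn else NULL,
                    mode = mode, basis = basis)
      pr <- directionality_proportions(fit$network, inst$net)
      detail[[length(detail) + 1]] <-
        data.frame(sim = sim, mode = mode,
                   forward = pr[["forward"]], reversed = pr[["reversed"]])
    }
  }
  detail <- do.call(rbind, detail)
  agg <- stats::aggregate(detail[c("forward", "reversed")],
                          detail["mode"], mean, na.rm = TRUE)
  names(agg) <- c("mode", "mean_forward", "mean_reversed")
  new_experiment_result(design, detail, agg, failures)
}
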