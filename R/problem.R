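#' Per-gene regression problems
#'
#' Each target gene is fitted separately. A `regression_problem` holds the
#' response vector and the candidate-regressor design matrix: one Hill column
#' per candidate regulator (never the target itself) plus one structural
#' degradation column equal to minus the target's expression. Steady-state
#' rows have response 0 (the derivative vanishes at steady state); time
#' series rows have the forward finite difference of the target as response,
#' with regressors evaluated at the left time point. The two kinds share one
#' column structure, so they stack directly in the combined problem.
#'
#' @name regression_problem
NULL

new_regression_problem <- function(target, target_index, response, design,
                                   regressor_genes, K, row_meta, basis) {
  structure(list(target = target, target_index = target_index,
                 response = response, design = design,
                 regressor_genes = regressor_genes, K = K,
                 row_meta = row_meta, basis = basis),
            class = "regression_problem")
}

#' @export
print.regression_problem <- function(x, ...) {
  cat(sprintf(
    "regression_problem for %s: %d rows (%d steady-state, %d time-series), %d candidate regulators\n",
    x$target, length(x$response), sum(x$row_meta$kind == "steady_state"),
    sum(x$row_meta$kind == "time_series"), length(x$regressor_genes)))
  invisible(x)
}

# Collect evaluation-point states and responses for one target gene.
# Returns states (rows x genes), response y, and row provenance.
gather_rows <- function(ss, ts, target_gene) {
  states <- list(); y <- list(); meta <- list()
  if (!is.null(ts) && ncol(ts$matrix)) {
    tm <- ts$sample_meta
    if (any(tm$kind != "time_series")) {
      stop_mikana("time-series input contains non-time-series samples")
    }
    for (rep in unique(tm$replicate)) {
      cols <- which(tm$replicate == rep)
      if (length(cols) < 2) {
        stop_mikana("replicate %s has fewer than 2 time points", rep)
      }
      tt <- tm$time_h[cols]
      xmat <- ts$matrix[, cols, drop = FALSE]
      k <- seq_len(length(cols) - 1)
      dt <- tt[k + 1] - tt[k]
      states[[length(states) + 1]] <- t(xmat[, k, drop = FALSE])
      y[[length(y) + 1]] <- (xmat[target_gene, k + 1] - xmat[target_gene, k]) / dt
      meta[[length(meta) + 1]] <- data.frame(
        kind = "time_series",
        sample_id = tm$sample_id[cols][k],
        pair_to = tm$sample_id[cols][k + 1])
    }
  }
  if (!is.null(ss) && ncol(ss$matrix)) {
    sm <- ss$sample_meta
    if (any(sm$kind != "steady_state")) {
      stop_mikana("steady-state input contains non-steady-state samples")
    }
    keep <- which(sm$perturbed_gene != target_gene)
    if (length(keep)) {
      states[[length(states) + 1]] <- t(ss$matrix[, keep, drop = FALSE])
      y[[length(y) + 1]] <- rep(0, length(keep))
      meta[[length(meta) + 1]] <- data.frame(
        kind = "steady_state",
        sample_id = sm$sample_id[keep],
        pair_to = NA_character_)
    }
  }
  if (!length(states)) {
    stop_mikana("no usable rows for target %s", target_gene,
                class = "mikana_insufficient_data")
  }
  list(states = do.call(rbind, states), y = unlist(y, use.names = FALSE),
       meta = do.call(rbind, meta))
}

# Turn gathered rows into a regression problem: Hill columns for every gene
# but the target (inputs floored at zero), degradation column -x_target.
assemble_problem <- function(rows, genes, target_gene, basis) {
  target_index <- match(target_gene, genes)
  regressors <- setdiff(genes, target_gene)
  xp <- pmax(rows$states, 0)            # Hill inputs only
  K <- if (basis$rule == "fixed") {
    stats::setNames(rep(basis$K_fixed, length(regressors)), regressors)
  } else {
    stats::setNames(
      pmax(apply(xp[, match(regressors, genes), drop = FALSE], 2,
                 stats::median), basis$K_floor),
      regressors)
  }
  design <- matrix(0, nrow(rows$states), length(regressors) + 1,
                   dimnames = list(NULL, c(regressors, ".degradation")))
  for (j in seq_along(regressors)) {
    design[, j] <- hill_basis(xp[, match(regressors[j], genes)], K[j], basis$n)
  }
  design[, length(regressors) + 1] <- -rows$states[, target_index]
  new_regression_problem(target_gene, target_index, rows$y, design,
                         regressors, K, rows$meta, basis)
}

#' Build the steady-state regression problem for one gene
#'
#' One row per knockdown sample, except that every sample perturbing the
#' target gene itself is removed (the strength of that perturbation is
#' unknown, so its row would be mis-specified). The response is identically
#' zero: at steady state, transcription balances degradation.
#'
#' @param data An `expression_dataset` containing only steady-state samples.
#' @param target Gene index or identifier.
#' @param basis A [basis_config()].
#' @return A `regression_problem`.
#' @export
build_ss_problem <- function(data, target, basis = basis_config()) {
  genes <- rownames(data$matrix)
  target_gene <- genes[resolve_gene_id(target, genes)]
  rows <- gather_rows(ss = data, ts = NULL, target_gene = target_gene)
  assemble_problem(rows, genes, target_gene, basis)
}

#' Build the time-series regression problem for one gene
#'
#' One row per consecutive time pair within each replicate (never across
#' replicate boundaries). The response is the forward difference
#' `(x(t_{k+1}) - x(t_k)) / (t_{k+1} - t_k)` of the target; regressors are
#' evaluated at the left time point. No smoothing is applied.
#'
#' @inheritParams build_ss_problem
#' @param data An `expression_dataset` containing only time-series samples,
#'   every replicate with at least two time points.
#' @return A `regression_problem`.
#' @export
build_ts_problem <- function(data, target, basis = basis_config()) {
  genes <- rownames(data$matrix)
  target_gene <- genes[resolve_gene_id(target, genes)]
  rows <- gather_rows(ss = NULL, ts = data, target_gene = target_gene)
  assemble_problem(rows, genes, target_gene, basis)
}

#' Build the combined steady-state + time-series problem for one gene
#'
#' The steady-state and time-series formulations share the same right-hand
#' side, so their rows stack into a single regression: time-series rows
#' first, then the retained steady-state rows, with one shared column
#' structure and no row weighting. Half-saturation constants under the
#' median rule are computed over all rows entering the combined problem.
#'
#' @param ss Steady-state `expression_dataset` (may be `NULL`).
#' @param ts Time-series `expression_dataset` (may be `NULL`).
#' @param ss_weight Scalar weight applied to the steady-state rows of the
#'   stack (default 1: unweighted, the two blocks are combined as they are).
#' @inheritParams build_ss_problem
#' @return A `regression_problem`.
#' @export
build_combined_problem <- function(ss, ts, target, basis = basis_config(),
                                   ss_weight = 1) {
  if ((is.null(ss) || !ncol(ss$matrix)) && (is.null(ts) || !ncol(ts$matrix))) {
    stop_mikana("both inputs are empty", class = "mikana_insufficient_data")
  }
  genes <- if (!is.null(ts) && ncol(ts$matrix)) rownames(ts$matrix)
           else rownames(ss$matrix)
  if (!is.null(ss) && !is.null(ts) && ncol(ss$matrix) && ncol(ts$matrix) &&
      !identical(rownames(ss$matrix), rownames(ts$matrix))) {
    stop_mikana("steady-state and time-series datasets cover different genes")
  }
  target_gene <- genes[resolve_gene_id(target, genes)]
  use_ss <- if (!is.null(ss) && ncol(ss$matrix)) ss else NULL
  use_ts <- if (!is.null(ts) && ncol(ts$matrix)) ts else NULL
  rows <- gather_rows(ss = use_ss, ts = use_ts, target_gene = target_gene)
  problem <- assemble_problem(rows, genes, target_gene, basis)
  if (ss_weight != 1) {
    if (ss_weight <= 0) stop_mikana("ss_weight must be positive")
    is_ss <- problem$row_meta$kind == "steady_state"
    problem$design[is_ss, ] <- problem$design[is_ss, ] * ss_weight
    problem$response[is_ss] <- problem$response[is_ss] * ss_weight
  }
  problem
}

resolve_gene_id <- function(gene, genes) {
  if (is.character(gene)) {
    i <- match(gene, genes)
    if (is.na(i)) stop_mikana("unknown gene '%s'", gene)
    i
  } else {
    i <- as.integer(gene)
    if (is.na(i) || i < 1 || i > length(genes)) {
      stop_mikana("gene index out of range")
    }
    i
  }
}
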