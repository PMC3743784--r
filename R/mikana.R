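#' Infer a gene regulatory network by ODE regression
#'
#' Fits, gene by gene, the model
#' `dx_i/dt = sum_j w_ij f(x_j) - lambda_i x_i`
#' with `f` the Hill basis, choosing each gene's regulators by iterative
#' forward-backward subset selection ([select_model()]). Three modes match
#' three experiment designs: `"ss"` regresses on steady-state knockdown
#' samples (ssMIKANA), `"ts"` on finite differences of time-series samples
#' (tsMIKANA), and `"combined"` stacks both row types into one regression
#' (cMIKANA), which is possible because the two formulations share the same
#' right-hand side. A directed edge j -> i is reported for every selected
#' Hill term, signed by its coefficient.
#'
#' @param ss Steady-state `expression_dataset`, or `NULL`.
#' @param ts Time-series `expression_dataset`, or `NULL`.
#' @param mode `"ss"`, `"ts"` or `"combined"`.
#' @param basis A [basis_config()].
#' @param cost A [cost_config()].
#' @param intercept Include a structural basal-transcription intercept in
#'   every per-gene regression (default `TRUE`); like the degradation term
#'   it is always present, unpenalised, and never reported as an edge.
#' @param ss_weight Scalar weight on steady-state rows in the combined
#'   stack (default 1, i.e. the two data types are combined without
#'   weighting).
#' @return An object of class `mikana`: a list with `network` (the inferred
#'   `gene_network`, edge weights = regression coefficients), `fits` (one
#'   [select_model()] result per gene), `mode`, `genes`, `basis`, `cost`.
#' @examples
#' net <- generate_scale_free(10, seed = 1)
#' mod <- sample_parameters(net, seed = 2)
#' mod$x_ref <- find_reference_state(mod, seed = 3)
#' ss <- simulate_steady_state_dataset(mod, seed = 4)
#' fit <- mikana(ss = ss, mode = "ss")
#' fit
#' @export
mikana <- function(ss = NULL, ts = NULL, mode = c("combined", "ss", "ts"),
                   basis = basis_config(), cost = cost_config(),
                   intercept = TRUE, ss_weight = 1) {
  mode <- match.arg(mode)
  if (mode == "ss" && (is.null(ss) || !ncol(ss$matrix))) {
    stop_mikana("mode 'ss' needs a steady-state dataset")
  }
  if (mode == "ts" && (is.null(ts) || !ncol(ts$matrix))) {
    stop_mikana("mode 'ts' needs a time-series dataset")
  }
  if (mode == "combined" && (is.null(ss) || !ncol(ss$matrix)) &&
      (is.null(ts) || !ncol(ts$matrix))) {
    stop_mikana("mode 'combined' needs at least one dataset")
  }
  if (!is.null(ss) && !is.null(ts) && ncol(ss$matrix) && ncol(ts$matrix) &&
      !identical(rownames(ss$matrix), rownames(ts$matrix))) {
    offenders <- union(setdiff(rownames(ss$matrix), rownames(ts$matrix)),
                       setdiff(rownames(ts$matrix), rownames(ss$matrix)))
    stop_mikana("gene universes disagree%s",
                if (length(offenders)) paste0(": ", paste(offenders, collapse = ", "))
                else " (same genes, different order)")
  }
  genes <- if (!is.null(ss) && ncol(ss$matrix)) rownames(ss$matrix)
           else rownames(ts$matrix)
  fits <- vector("list", length(genes))
  names(fits) <- genes
  for (g in genes) {
    problem <- switch(mode,
      ss = build_ss_problem(ss, g, basis),
      ts = build_ts_problem(ts, g, basis),
      combined = build_combined_problem(ss, ts, g, basis,
                                        ss_weight = ss_weight))
    fits[[g]] <- select_model(problem, cost, intercept = intercept)
  }
  edges <- do.call(rbind, lapply(genes, function(g) {
    f <- fits[[g]]
    if (!length(f$regressors)) return(NULL)
    data.frame(parent = match(f$regressors, genes),
               child = match(g, genes),
               sign = ifelse(f$weights > 0, 1L, -1L),
               weight = unname(f$weights))
  }))
  if (is.null(edges)) {
    edges <- data.frame(parent = integer(), child = integer(),
                        sign = integer(), weight = numeric())
  }
  structure(list(network = gene_network(genes, edges),
                 fits = fits, mode = mode, genes = genes,
                 basis = basis, cost = cost, call = match.call()),
            class = "mikana")
}

#' @export
print.mikana <- function(x, ...) {
  cat(sprintf("mikana fit (mode '%s'): %d genes, %d inferred edges\n",
              x$mode, length(x$genes), nrow(x$network$edges)))
  invisible(x)
}

#' @export
summary.mikana <- function(object, ...) {
  tab <- do.call(rbind, lapply(object$genes, function(g) {
    f <- object$fits[[g]]
    data.frame(gene = g, n_regulators = length(f$regressors),
               lambda = f$lambda, rss = f$rss, n_obs = f$n_obs,
               cost = f$cost)
  }))
  structure(list(mode = object$mode, table = tab,
                 n_edges = nrow(object$network$edges)), class = "summary.mikana")
}

#' @export
print.summary.mikana <- function(x, ...) {
  cat(sprintf("mikana fit (mode '%s'), %d edges\n\n", x$mode, x$n_edges))
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Coefficients of a mikana fit
#'
#' @param object A `mikana` fit.
#' @param ... Unused.
#' @return A data frame with one row per inferred interaction (`parent`,
#'   `child`, `weight`, `sign`) plus an attribute `lambda`: the per-gene
#'   degradation coefficients.
#' @export
coef.mikana <- function(object, ...) {
  e <- object$network$edges
  out <- data.frame(parent = object$genes[e$parent],
                    child = object$genes[e$child],
                    weight = e$weight, sign = e$sign)
  attr(out, "lambda") <- vapply(object$fits, function(f) f$lambda, numeric(1))
  out
}

#' @export
residuals.mikana <- function(object, ...) {
  lapply(object$fits, function(f) f$residuals)
}

#' @export
fitted.mikana <- function(object, ...) {
  lapply(object$fits, function(f) f$fitted)
}

#' Predicted expression rates of change
#'
#' Evaluates the fitted right-hand side `sum_j w_ij f(x_j) - lambda_i x_i`
#' at given expression states, using each target gene's fitted regulators,
#' coefficients and half-saturation constants.
#'
#' @param object A `mikana` fit.
#' @param newdata Numeric expression vector (named by gene) or genes x
#'   states matrix.
#' @param ... Unused.
#' @return A genes x states matrix of predicted dx/dt values (a vector for a
#'   single state).
#' @export
predict.mikana <- function(object, newdata, ...) {
  x <- if (is.matrix(newdata)) newdata else
    matrix(newdata, ncol = 1, dimnames = list(names(newdata), NULL))
  if (!all(object$genes %in% rownames(x))) {
    stop_mikana("newdata must cover every fitted gene")
  }
  x <- x[object$genes, , drop = FALSE]
  out <- matrix(0, length(object$genes), ncol(x),
                dimnames = list(object$genes, colnames(x)))
  xp <- pmax(x, 0)
  for (g in object$genes) {
    f <- object$fits[[g]]
    level <- f$basal - x[g, ]           # basal + sum beta f(x) - x_target
    for (r in f$regressors) {
      level <- level + f$weights[r] * hill_basis(xp[r, ], f$K[r], object$basis$n)
    }
    # dx/dt = lambda * (basal + sum beta f - x); lambda = 1 when unidentified
    lam <- if (is.na(f$lambda)) 1 else f$lambda
    out[g, ] <- lam * level
  }
  if (ncol(out) == 1) drop(out) else out
}

#' Plot a mikana fit
#'
#' `type = "cost"` overlays the per-gene selection cost traces (cost after
#' each accepted selection step); `type = "degree"` shows the out-degree
#' distribution of the inferred network.
#'
#' @param x A `mikana` fit.
#' @param type `"cost"` or `"degree"`.
#' @param ... Passed to the underlying plotting function.
#' @return Invisibly, `x`.
#' @export
plot.mikana <- function(x, type = c("cost", "degree"), ...) {
  type <- match.arg(type)
  if (type == "cost") {
    traces <- lapply(x$fits, function(f) f$cost_trace)
    len <- max(vapply(traces, length, integer(1)))
    mat <- vapply(traces, function(tr) c(tr, rep(NA, len - length(tr))),
                  numeric(len))
    graphics::matplot(seq_len(len) - 1, mat, type = "l", lty = 1,
                      xlab = "selection step", ylab = "cost", ...)
  } else {
    dd <- degree_counts(x$network, "out")
    graphics::hist(dd, breaks = seq(-0.5, max(dd) + 0.5, 1),
                   xlab = "out-degree", main = "inferred out-degree", ...)
  }
  invisible(x)
}
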