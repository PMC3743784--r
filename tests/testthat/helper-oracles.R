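# Independent oracles. These re-derive expected values by brute force or
# closed form, never through the code paths they check.

# Exhaustive best-subset search over all 2^p candidate subsets, fitting each
# model with stats::lm (level-normalised form: expression level on selected
# Hill columns, the derivative response as structural regressor, and an
# intercept) and scoring it with the same published cost function.
exhaustive_best_subset <- function(problem, cost = cost_config()) {
  p <- length(problem$regressor_genes)
  H <- problem$design[, seq_len(p), drop = FALSE]
  x_t <- -problem$design[, p + 1]
  u <- problem$response
  m <- length(x_t)
  has_deriv <- any(u != 0)
  floorv <- m * cost$rss_floor_rel^2 * mean(x_t^2)
  best_cost <- Inf
  best_set <- integer(0)
  for (mask in seq_len(2^p) - 1L) {
    sel <- which(bitwAnd(mask, bitwShiftL(1L, 0:(p - 1))) > 0)
    X <- H[, sel, drop = FALSE]
    if (has_deriv) X <- cbind(X, u)
    fit <- if (ncol(X)) stats::lm(x_t ~ X) else stats::lm(x_t ~ 1)
    rss <- sum(stats::residuals(fit)^2)
    cc <- selection_cost(rss, m, length(sel), n_candidates = p,
                         rss_floor = floorv, penalty = cost$penalty,
                         gamma = cost$gamma)
    if (cc < best_cost) {
      best_cost <- cc
      best_set <- sel
    }
  }
  list(cost = best_cost, set = best_set)
}

# Directed reachability on a gene_network (for the knockdown-propagation
# check), by simple breadth-first expansion.
reachable_from <- function(net, start) {
  e <- net$edges
  seen <- start
  frontier <- start
  while (length(frontier)) {
    nxt <- unique(e$child[e$parent %in% frontier])
    frontier <- setdiff(nxt, seen)
    seen <- c(seen, frontier)
  }
  setdiff(seen, start)
}
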