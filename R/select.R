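#' Selection cost: description length of a candidate model
#'
#' The compromise between goodness-of-fit and complexity used by the
#' iterative selection loop:
#' `C(S) = (m/2) * log(RSS(S)/m) + (|S|/2) * log(m) + gamma * log(choose(p, |S|))`,
#' where `m` is the number of rows, `|S|` the number of selected Hill terms
#' (structural terms are never counted) and `p` the number of candidates.
#' The first two terms are the classical description-length/BIC compromise;
#' the last is the code length of naming which subset was selected, which
#' keeps false selections controlled when the candidate count is of the
#' order of the row count. `RSS` is floored at `rss_floor` so that
#' numerically exact fits do not drive the log term to minus infinity and
#' admit spurious terms.
#'
#' @param rss Residual sum of squares of the candidate model.
#' @param n_obs Number of rows m.
#' @param n_terms Number of selected Hill terms.
#' @param n_candidates Number of candidate Hill terms p (only used when
#'   `gamma > 0`).
#' @param rss_floor Lower bound applied to `rss` (default 0).
#' @param penalty Multiplier on the `(|S|/2) log(m)` term (default 1).
#' @param gamma Weight of the subset-naming term (default 0).
#' @return The scalar cost.
#' @export
selection_cost <- function(rss, n_obs, n_terms, n_candidates = n_terms,
                           rss_floor = 0, penalty = 1, gamma = 0) {
  rss <- max(rss, rss_floor)
  (n_obs / 2) * log(rss / n_obs) + penalty * (n_terms / 2) * log(n_obs) +
    gamma * lchoose(n_candidates, n_terms)
}

#' Selection cost configuration
#'
#' @param penalty Multiplier on the `(|S|/2) log(m)` complexity term of
#'   [selection_cost()].
#' @param gamma Weight of the subset-naming code-length term
#'   `log(choose(p, |S|))`.
#' @param rss_floor_rel Relative RSS floor: the floor is
#'   `m * (rss_floor_rel)^2 * mean(y^2)` for a problem with effective
#'   response `y`, guarding the log against numerically exact fits.
#' @return An object of class `cost_config`.
#' @export
cost_config <- function(penalty = 1, gamma = 0, rss_floor_rel = 1e-8) {
  structure(list(penalty = penalty, gamma = gamma,
                 rss_floor_rel = rss_floor_rel),
            class = "cost_config")
}

# Least-squares fit of the level-normalised model for one candidate subset:
#   x_target = basal + sum_j beta_j f(x_j) + alpha * u
# where u is the derivative response (zero on steady-state rows), so
# beta = w/lambda and alpha = -1/lambda. The derivative column is structural
# and present whenever the problem has time-series rows; the intercept
# (basal transcription over lambda) is structural when requested. Rank
# deficiency is resolved by lm.fit's pivoting: aliased (later, dependent)
# columns get NA coefficients and are treated as dropped.
fit_subset <- function(H, x_t, u, sel, has_deriv, intercept = TRUE) {
  m <- length(x_t)
  X <- H[, sel, drop = FALSE]
  if (has_deriv) X <- cbind(X, u)
  if (intercept) X <- cbind(X, 1)
  if (ncol(X) == 0) {
    return(list(coef = numeric(0), alpha = NA_real_, basal = 0,
                rss = sum(x_t^2), fitted = rep(0, m)))
  }
  fit <- stats::lm.fit(X, x_t)
  co <- fit$coefficients
  co[is.na(co)] <- 0
  fitted <- drop(X %*% co)
  basal <- if (intercept) co[length(co)] else 0
  if (intercept) co <- co[-length(co)]
  alpha <- if (has_deriv) unname(co[length(co)]) else NA_real_
  beta <- if (has_deriv) co[-length(co)] else co
  list(coef = beta, alpha = alpha, basal = unname(basal),
       rss = sum((x_t - fitted)^2), fitted = fitted)
}

#' Iterative forward-backward subset selection for one gene
#'
#' Selects which candidate regulators enter the model for one target gene.
#' The search explores a forward path — repeatedly adding the candidate
#' with the largest marginal improvement in residual sum of squares, up to
#' the size the data can support (at least three rows per fitted term, so
#' near-interpolating fits are never candidates) — and a backward path
#' pruning the term whose removal does least damage, evaluating the
#' selection cost of every model visited. The best model encountered is
#' then polished by a cost-greedy local search over single additions,
#' removals and one-for-one replacements until no such step lowers the
#' cost. Ties are broken towards the lowest column index; the returned
#' subset attains the minimum cost encountered. Coefficients are the
#' ordinary least-squares solution on exactly the selected columns.
#'
#' Fitting uses the level-normalised form of the regression: the equation
#' `u = sum_j w_j f(x_j) - lambda x_target` (with `u` the finite-difference
#' derivative on time-series rows and 0 on steady-state rows) is solved as
#' `x_target = basal + sum_j beta_j f(x_j) + alpha u` with `beta = w/lambda`
#' and `alpha = -1/lambda`. The two forms are algebraically identical, but
#' regressing on the expression level keeps steady-state rows informative
#' even when the degradation rate is weakly determined, and puts
#' steady-state and time-series rows on a common response scale in the
#' combined stack. The derivative term and (by default) an intercept
#' capturing basal transcription are structural: always in the model, never
#' penalised or removable. For a pure steady-state problem the derivative
#' column vanishes and the scale of `(w, lambda)` is not identifiable;
#' coefficients are then reported in the `w/lambda` parametrisation with
#' `lambda = NA`.
#'
#' @param problem A `regression_problem`.
#' @param cost A [cost_config()].
#' @param intercept Include the structural basal-transcription intercept
#'   (default `TRUE`).
#' @return A list of class `mikana_selection` with elements `regressors`
#'   (selected gene ids), `weights` (their coefficients `beta = w/lambda`,
#'   the reported interaction strengths), `lambda` (degradation rate
#'   `-1/alpha`; `NA` when not identified), `alpha`, `basal`,
#'   `lambda_fitted` (logical: problem had time-series rows), `rss`, `cost`
#'   (cost of the returned model), `cost_trace` (cost at each accepted
#'   improvement, starting from the empty model), `fitted`, `residuals`
#'   (on the expression-level scale) and `K` (per-regressor
#'   half-saturation constants used).
#' @export
select_model <- function(problem, cost = cost_config(), intercept = TRUE) {
  y <- problem$response
  m <- length(y)
  if (m < 2) stop_mikana("need at least 2 rows to select a model")
  p <- length(problem$regressor_genes)
  H <- problem$design[, seq_len(p), drop = FALSE]
  x_t <- -problem$design[, p + 1]       # degradation column is -x_target
  u <- y
  has_deriv <- any(u != 0)
  rss_floor <- m * cost$rss_floor_rel^2 * mean(x_t^2)
  cost_of <- function(rss, k) {
    selection_cost(rss, m, k, n_candidates = p, rss_floor = rss_floor,
                   penalty = cost$penalty, gamma = cost$gamma)
  }

  rss_of <- function(sel) {
    fit_subset(H, x_t, u, sel, has_deriv, intercept)$rss
  }
  empty_cost <- cost_of(rss_of(integer(0)), 0)
  best <- list(sel = integer(0), cost = empty_cost)
  trace <- empty_cost
  note <- function(sel, cc) {
    if (cc < best$cost - 1e-10) {
      best <<- list(sel = sel, cost = cc)
      trace <<- c(trace, cc)
    }
  }
  # df guard: at least ~3 rows per fitted term, so near-interpolating
  # models (whose RSS term degenerates) are never candidates
  size_cap <- min(p, max(0L, m - 2L), max(1L, m %/% 3L))

  # forward sweep: largest marginal RSS improvement first (ties: low index)
  sel <- integer(0)
  while (length(sel) < size_cap) {
    cand <- setdiff(seq_len(p), sel)
    rss <- vapply(cand, function(j) rss_of(sort(c(sel, j))), numeric(1))
    j <- cand[which.min(rss)]
    sel <- sort(c(sel, j))
    note(sel, cost_of(min(rss), length(sel)))
  }
  # backward sweep from the largest model: least-damage removal first
  while (length(sel) > 0) {
    rss <- vapply(sel, function(j) rss_of(setdiff(sel, j)), numeric(1))
    j <- sel[which.min(rss)]
    sel <- setdiff(sel, j)
    note(sel, cost_of(min(rss), length(sel)))
  }

  # cost-greedy polish from the incumbent: single additions/removals, then
  # one-for-one replacements when no single step improves
  try_sets <- function(cands, limit) {
    move <- NULL
    move_cost <- limit
    for (cand in cands) {
      cc <- cost_of(rss_of(cand), length(cand))
      if (cc < move_cost) {
        move_cost <- cc
        move <- cand
      }
    }
    list(set = move, cost = move_cost)
  }
  sel <- best$sel
  cur_cost <- best$cost
  for (iter in seq_len(10L * p + 20L)) {
    singles <- lapply(seq_len(p), function(j) {
      if (j %in% sel) setdiff(sel, j) else sort(c(sel, j))
    })
    singles <- Filter(function(s) length(s) <= size_cap, singles)
    step <- try_sets(singles, cur_cost - 1e-10)
    if (is.null(step$set) && length(sel)) {
      swaps <- list()
      for (j in sel) for (l in setdiff(seq_len(p), sel)) {
        swaps[[length(swaps) + 1]] <- sort(c(setdiff(sel, j), l))
      }
      step <- try_sets(swaps, cur_cost - 1e-10)
    }
    if (is.null(step$set)) break
    sel <- step$set
    cur_cost <- step$cost
    note(sel, cur_cost)
  }

  final <- fit_subset(H, x_t, u, best$sel, has_deriv, intercept)
  keep <- final$coef != 0
  regs <- problem$regressor_genes[best$sel][keep]
  w <- final$coef[keep]
  names(w) <- regs
  lambda <- if (has_deriv && is.finite(final$alpha) && final$alpha != 0) {
    -1 / final$alpha
  } else {
    NA_real_
  }
  structure(list(
    target = problem$target,
    regressors = regs,
    weights = w,
    lambda = lambda,
    alpha = final$alpha,
    lambda_fitted = has_deriv,
    basal = final$basal,
    intercept = intercept,
    rss = final$rss,
    cost = cost_of(final$rss, length(best$sel)),
    cost_trace = trace,
    fitted = final$fitted,
    residuals = x_t - final$fitted,
    n_obs = m,
    K = problem$K[regs]
  ), class = "mikana_selection")
}

#' @export
print.mikana_selection <- function(x, ...) {
  cat(sprintf("selected model for %s: %d regulator(s) [%s], lambda = %s\n",
              x$target, length(x$regressors),
              paste(x$regressors, collapse = ", "),
              if (is.na(x$lambda)) "not identified" else sprintf("%.4g", x$lambda)))
  invisible(x)
}
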