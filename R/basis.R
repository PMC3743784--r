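#' Hill basis function
#'
#' The saturating basis used for every candidate regulator:
#' `f(x) = x^n / (K^n + x^n)`, which rises from 0 at `x = 0` through 1/2 at
#' `x = K` towards 1 as `x` grows. Only the independent effect of each
#' regulator is modelled (no product terms).
#'
#' @param x Non-negative expression value(s); negative measurements must be
#'   floored upstream.
#' @param K Half-saturation constant (> 0).
#' @param n Hill exponent (> 0).
#' @return Values in \[0, 1).
#' @examples
#' hill_basis(c(0, 500, 1000), K = 500, n = 2)  # 0, 0.5, 0.8
#' @export
hill_basis <- function(x, K, n = 2) {
  if (any(K <= 0)) stop_mikana("Hill K must be strictly positive")
  if (any(n <= 0)) stop_mikana("Hill exponent must be strictly positive")
  xn <- x^n
  xn / (K^n + xn)
}

#' Hill basis configuration
#'
#' Controls the basis used when assembling regression problems. With the
#' `"median"` rule each regulator gene gets its own half-saturation constant:
#' the median of that gene's expression over the rows entering the problem,
#' floored at `K_floor`, which centres the basis in its operating range
#' without tuning. The `"fixed"` rule uses one constant `K_fixed` for every
#' regulator (used e.g. when fitting data generated from a Hill-sum model
#' with known K).
#'
#' @param n Hill exponent (default 2).
#' @param rule Half-saturation rule, `"median"` or `"fixed"`.
#' @param K_fixed Constant K under the fixed rule.
#' @param K_floor Lower bound for data-derived K values.
#' @return An object of class `basis_config`.
#' @export
basis_config <- function(n = 2, rule = c("median", "fixed"), K_fixed = NULL,
                         K_floor = 1e-6) {
  rule <- match.arg(rule)
  if (n <= 0) stop_mikana("Hill exponent must be positive")
  if (rule == "fixed") {
    if (is.null(K_fixed) || K_fixed <= 0) {
      stop_mikana("the fixed rule needs K_fixed > 0")
    }
  }
  structure(list(n = n, rule = rule, K_fixed = K_fixed, K_floor = K_floor),
            class = "basis_config")
}
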