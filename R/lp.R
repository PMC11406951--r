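# Bounded-variable linear programming front end. The kernel is a dense
# two-phase primal simplex implemented in C++ (src/simplex.cpp): explicit
# basis inverse with eta updates, Dantzig pricing with a switch to Bland's
# rule after a run of degenerate steps (anti-cycling), artificial variables
# with bounds [0, big] in phase 1 clamped to [0, 0] in phase 2.

#' Solve a bounded-variable linear program
#'
#' Solves `max (or min) c'x` subject to `A x = b` and finite bounds
#' `l <= x <= u`. This is the kernel under flux balance and flux variability
#' analysis; flux problems always have `b = 0` and bounds containing zero,
#' but the solver handles general right-hand sides (used by objective-fixed
#' FVA).
#'
#' @param A constraint matrix (m x n), dense numeric.
#' @param obj objective coefficients (length n).
#' @param lower,upper finite variable bounds (length n), `lower <= upper`.
#' @param b right-hand side (length m), default zeros.
#' @param maximize maximize (default) or minimize.
#' @param tol feasibility/optimality tolerance (default 1e-9).
#' @return list with `status` ("optimal", "infeasible", "unbounded",
#'   "iteration_limit"), `objective`, and `x` (length n) when optimal.
#' @export
lp_solve_bounded <- function(A, obj, lower, upper, b = NULL,
                             maximize = TRUE, tol = 1e-9) {
  A <- as.matrix(A)
  storage.mode(A) <- "double"
  m <- nrow(A); n <- ncol(A)
  if (is.null(b)) b <- rep(0, m)
  cg_assert(length(obj) == n && length(lower) == n && length(upper) == n &&
            length(b) == m, "dimension mismatch")
  cg_assert(all(is.finite(lower)) && all(is.finite(upper)),
            "bounds must be finite")
  cg_assert(all(lower <= upper + tol), "lower bound exceeds upper bound")

  if (m == 0) {
    cs <- if (maximize) as.numeric(obj) else -as.numeric(obj)
    x <- ifelse(cs > 0, upper, lower)
    return(list(status = "optimal", objective = sum(as.numeric(obj) * x),
                x = x))
  }
  res <- simplex_bounded_cpp(A, as.numeric(obj), as.numeric(lower),
                             as.numeric(upper), as.numeric(b),
                             isTRUE(maximize), tol)
  status <- c("optimal", "infeasible", "unbounded",
              "iteration_limit")[res$status + 1]
  if (status != "optimal") return(list(status = status))
  list(status = "optimal", objective = res$objective, x = res$x)
}
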