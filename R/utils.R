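#' @keywords internal
#' @useDynLib commgem, .registration = TRUE
#' @importFrom Rcpp sourceCpp
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Signal a classed commgem error
#'
#' All user-facing errors in the package carry a subclass so callers and tests
#' can distinguish precondition violations from generation failures, solver
#' statuses, etc.
#'
#' @param msg message string.
#' @param class error subclass (prefixed internally with "commgem_").
#' @param ... fields attached to the condition.
#' @keywords internal
cg_stop <- function(msg, class = "error", ...) {
  cond <- structure(
    class = c(paste0("commgem_", class), "commgem_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  )
  stop(cond)
}

cg_assert <- function(ok, msg, class = "precondition") {
  if (!isTRUE(ok)) cg_stop(msg, class = class)
  invisible(TRUE)
}

#' Derive a child seed from a run seed and a stage label
#'
#' One global integer seed drives a pipeline run; every stage derives its own
#' seed deterministically from `(seed, label)` so stages can be re-run in
#' isolation and adding a stage never perturbs the streams of the others.
#' The derivation hashes the label bytes (djb2, modulo 2^31 - 1) and folds in
#' the run seed; the result always fits a 32-bit signed integer.
#'
#' @param seed integer run seed.
#' @param label character stage label.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(1, "netgen")
derive_seed <- function(seed, label) {
  cg_assert(is.numeric(seed) && length(seed) == 1 && is.finite(seed),
            "seed must be a single finite number")
  cg_assert(is.character(label) && length(label) == 1,
            "label must be a single string")
  m <- 2147483647 # 2^31 - 1
  h <- 5381
  for (b in utf8ToInt(label)) h <- (h * 33 + b) %% m
  as.integer((h * 31 + (abs(as.numeric(seed)) %% m) * 7919) %% m)
}

# Evaluate expr under a given RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# round() half-away-from-zero, as tables in the field print percentages.
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
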