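# Independent oracles used by the dual-route checks.
#
# The LP oracles run scipy.optimize.linprog (HiGHS) through the system
# `python`, batched into a single process call per test; the implementation
# under test never touches scipy. The combinatorial oracles below enumerate
# directly in R with choose()/combn().

scipy_available <- local({
  ok <- NULL
  function() {
    if (is.null(ok)) {
      ok <<- nzchar(Sys.which("python")) &&
        suppressWarnings(system2("python", c("-c", shQuote("import scipy")),
                                 stdout = FALSE, stderr = FALSE)) == 0
    }
    ok
  }
})

# cases: list of list(A = matrix, obj, lower, upper, b, maximize)
# returns data.frame(status, objective)
scipy_lp_batch <- function(cases) {
  fin <- tempfile(fileext = ".json")
  fout <- tempfile(fileext = ".json")
  jsonlite::write_json(lapply(cases, function(cs) list(
    A = cs$A, obj = cs$obj, lower = cs$lower, upper = cs$upper,
    b = cs$b %||% rep(0, nrow(cs$A)),
    maximize = isTRUE(cs$maximize %||% TRUE)
  )), fin, digits = NA, matrix = "rowmajor", auto_unbox = FALSE)
  status <- system2("python", c(test_path("oracle_lp.py"), fin, fout),
                    stdout = "", stderr = "")
  stopifnot(status == 0)
  res <- jsonlite::read_json(fout, simplifyVector = TRUE)
  data.frame(status = res$status, objective = res$objective)
}

# per-reaction two-LP brute-force FVA via scipy; returns list with min, max
# matrices (rows = cases); blocked determined in the caller
scipy_fva_batch <- function(cases) {
  fin <- tempfile(fileext = ".json")
  fout <- tempfile(fileext = ".json")
  jsonlite::write_json(lapply(cases, function(cs) list(
    A = cs$A, lower = cs$lower, upper = cs$upper,
    b = cs$b %||% rep(0, nrow(cs$A))
  )), fin, digits = NA, matrix = "rowmajor", auto_unbox = FALSE)
  status <- system2("python", c(test_path("oracle_fva.py"), fin, fout),
                    stdout = "", stderr = "")
  stopifnot(status == 0)
  jsonlite::read_json(fout, simplifyVector = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# exact hypergeometric upper tail P(X >= k) by direct enumeration of the
# two-group urn with choose(); independent of phyper
enum_hyper_tail <- function(k, K, N, n) {
  kk <- max(k, max(0, n - (N - K))):min(K, n)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# exhaustive minimal gapfill cardinality: smallest subset of `candidates`
# whose addition makes the model grow on the medium
powerset_min_gapfill <- function(model, universal, candidates, medium) {
  grows <- function(ids) {
    m <- add_reactions_to_model(model, universal, ids)
    r <- fba(flux_problem(m, medium = medium))
    r$status == "optimal" && r$objective > 1e-9
  }
  if (grows(character(0))) return(0L)
  for (k in seq_along(candidates)) {
    for (sub in utils::combn(candidates, k, simplify = FALSE)) {
      if (grows(sub)) return(k)
    }
  }
  NA_integer_
}
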