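# Constraint-based flux analysis: problem assembly from models, flux balance
# analysis (FBA), flux variability analysis (FVA) with blocked-reaction
# classification, and parsimonious gapfilling against the universal catalog.

#' Default growth medium: all catalog seed compounds open for uptake
#' @param universal a `universal_network`.
#' @param uptake uptake limit per compound (flux units).
#' @return named numeric vector, compound id -> uptake limit.
#' @export
default_medium <- function(universal, uptake = 10) {
  stats::setNames(rep(uptake, length(universal$seeds)), universal$seeds)
}

#' Assemble a flux problem from a model
#'
#' Builds the stoichiometric matrix over compound instances (rows) and
#' reactions (columns), with exchange reactions added on every extracellular
#' compound instance: secretion open (0..1000), uptake opened to the medium
#' limit for medium compounds. Medium compounds the model does not carry get
#' an extracellular species and exchange anyway, so availability is uniform
#' (the compound simply stays inert until a transporter exists). The shared
#' compartment is "e" for an organism model and "e0" for a community model.
#'
#' @param model an `organism_model` or `community_model`.
#' @param medium named numeric vector (compound -> uptake limit), a character
#'   vector (limit 10), or NULL for a closed medium.
#' @param objective reaction id(s) with optional weights (named numeric);
#'   default: the model's biomass reaction(s).
#' @return an object of class `flux_problem`: `S`, `lower`, `upper`,
#'   `objective` (full-length coefficient vector), `reaction_ids`.
#' @export
flux_problem <- function(model, medium = NULL, objective = NULL) {
  if (is.character(medium)) medium <- stats::setNames(rep(10, length(medium)), medium)
  ext_comp <- if (inherits(model, "community_model")) "e0" else "e"
  reactions <- model$reactions

  if (inherits(model, "organism_model")) {
    inst <- model$compounds
    ext <- sort(unique(c(inst$compound[inst$compartment == ext_comp],
                         names(medium))))
    for (cid in ext) {
      rid <- paste0("EX_", cid)
      reactions[[rid]] <- list(
        id = rid, lower = 0, upper = 1000, reversible = FALSE,
        transport = FALSE,
        stoich = data.frame(compound = cid, compartment = ext_comp,
                            coeff = -1, stringsAsFactors = FALSE))
    }
    if (is.null(objective)) objective <- model$biomass_reaction
  } else if (inherits(model, "community_model")) {
    miss <- setdiff(names(medium), unique(
      model$compounds$compound[model$compounds$compartment == ext_comp]))
    for (cid in miss) {
      rid <- paste0("EX_", cid)
      if (!rid %in% names(reactions)) {
        reactions[[rid]] <- list(
          id = rid, lower = 0, upper = 1000, reversible = FALSE,
          transport = FALSE,
          stoich = data.frame(compound = cid, compartment = ext_comp,
                              coeff = -1, stringsAsFactors = FALSE))
      }
    }
    if (is.null(objective)) {
      objective <- names(reactions)[vapply(reactions, function(r)
        grepl(":bio1$", r$id), logical(1))]
    }
  } else {
    cg_stop("model must be an organism_model or community_model")
  }

  rids <- names(reactions)
  species <- unique(do.call(rbind, lapply(reactions, function(r)
    r$stoich[, c("compound", "compartment")])))
  skey <- paste(species$compound, species$compartment, sep = "@")
  S <- matrix(0, nrow = length(skey), ncol = length(rids),
              dimnames = list(skey, rids))
  for (j in seq_along(rids)) {
    st <- reactions[[j]]$stoich
    k <- paste(st$compound, st$compartment, sep = "@")
    S[k, j] <- S[k, j] + st$coeff
  }
  lower <- vapply(reactions, `[[`, numeric(1), "lower")
  upper <- vapply(reactions, `[[`, numeric(1), "upper")
  # open uptake for medium compounds
  for (cid in names(medium)) {
    rid <- paste0("EX_", cid)
    if (rid %in% rids) lower[rid] <- -abs(medium[[cid]])
  }
  if (is.null(names(objective))) {
    objective <- stats::setNames(rep(1, length(objective)), objective)
  }
  cg_assert(all(names(objective) %in% rids), "objective reaction not in model")
  cvec <- stats::setNames(rep(0, length(rids)), rids)
  cvec[names(objective)] <- objective

  structure(list(S = S, lower = lower, upper = upper, objective = cvec,
                 reaction_ids = rids, tol = 1e-9),
            class = "flux_problem")
}

#' Flux balance analysis
#'
#' Maximizes the objective flux subject to steady state (`S v = 0`) and flux
#' bounds. Returns an explicit status; the steady-state residual of an
#' optimal solution is checked to 1e-6 flux units.
#'
#' @param problem a `flux_problem`.
#' @return list with `status` ("optimal" / "infeasible" / "unbounded"),
#'   `objective`, and named `fluxes`.
#' @export
fba <- function(problem) {
  cg_assert(inherits(problem, "flux_problem"), "flux_problem required")
  res <- lp_solve_bounded(problem$S, problem$objective, problem$lower,
                          problem$upper, maximize = TRUE, tol = problem$tol)
  if (res$status != "optimal") {
    return(list(status = res$status, objective = NA_real_, fluxes = NULL))
  }
  v <- stats::setNames(res$x, problem$reaction_ids)
  resid <- max(abs(problem$S %*% v))
  cg_assert(resid <= 1e-6, sprintf("steady-state residual %.3g > 1e-6", resid),
            class = "numerical")
  list(status = "optimal", objective = res$objective, fluxes = v)
}

#' Flux variability analysis and blocked-reaction classification
#'
#' For every reaction, minimizes and maximizes its flux over the feasible
#' region, optionally with the objective constrained to at least
#' `fix_objective_fraction` of its optimum. A reaction is blocked when both
#' extremes are within `tol_blocked` of zero; blocked classification uses
#' fraction 0 (blocked means "cannot carry flux in any feasible state").
#'
#' With `values = FALSE` only the blocked flag is guaranteed: reactions seen
#' carrying flux in a previously computed solution are skipped, which is much
#' faster on large models but leaves their exact min/max as NA.
#'
#' @param problem a `flux_problem`.
#' @param fix_objective_fraction proportion in `[0, 1]` of the FBA optimum to
#'   enforce; 0 disables the constraint.
#' @param tol_blocked zero tolerance for the blocked test (default 1e-9).
#' @param values compute exact min/max for every reaction (default TRUE).
#' @return an object of class `fva_result`: data.frame `ranges` (reaction,
#'   min, max, blocked) and `blocked_percentage`.
#' @export
fva <- function(problem, fix_objective_fraction = 0, tol_blocked = 1e-9,
                values = TRUE) {
  cg_assert(inherits(problem, "flux_problem"), "flux_problem required")
  cg_assert(fix_objective_fraction >= 0 && fix_objective_fraction <= 1,
            "fix_objective_fraction must be in [0, 1]")
  S <- problem$S
  lower <- problem$lower
  upper <- problem$upper
  b <- rep(0, nrow(S))
  if (fix_objective_fraction > 0) {
    base <- fba(problem)
    if (base$status != "optimal") {
      cg_stop(sprintf("base problem is %s", base$status), class = "fva_status")
    }
    # c'v - s = f * opt, s >= 0  (adds one row and one slack column)
    S <- rbind(S, problem$objective)
    S <- cbind(S, c(rep(0, nrow(S) - 1), -1))
    lower <- c(lower, 0)
    upper <- c(upper, sum(abs(problem$objective) * pmax(abs(problem$lower),
                                                        abs(problem$upper))))
    b <- c(b, fix_objective_fraction * base$objective)
  }
  n <- length(problem$reaction_ids)
  Sm <- as.matrix(S)
  storage.mode(Sm) <- "double"
  res <- fva_bounded_cpp(Sm, as.numeric(lower), as.numeric(upper),
                         as.numeric(b), n, isTRUE(values), 1e-9, tol_blocked)
  if (res$status != 0) {
    cg_stop(sprintf("FVA base problem status %d (infeasible or breakdown)",
                    res$status), class = "fva_status")
  }
  ranges <- data.frame(reaction = problem$reaction_ids, min = res$min,
                       max = res$max, blocked = res$blocked,
                       stringsAsFactors = FALSE)
  blocked <- res$blocked
  structure(list(ranges = ranges,
                 blocked_percentage = 100 * mean(blocked),
                 fix_objective_fraction = fix_objective_fraction,
                 tol_blocked = tol_blocked),
            class = "fva_result")
}

#' @export
print.fva_result <- function(x, ...) {
  cat(sprintf("fva_result: %d reactions, %.2f%% blocked (fraction %.2f)\n",
              nrow(x$ranges), x$blocked_percentage, x$fix_objective_fraction))
  invisible(x)
}

#' Parsimonious gapfilling against the universal network
#'
#' Finds a small set of catalog reactions whose addition lets the model's
#' biomass objective carry flux on the given medium. With at most
#' `exhaustive_limit` candidate reactions the minimal-cardinality subset is
#' found by exhaustive search; above it, a greedy scope-expansion heuristic
#' (add the candidate that brings the most missing biomass precursors, then
#' the most new compounds, into the producible scope) runs first and the
#' result is pruned reverse-greedily, which is near-minimal but not certified.
#'
#' @param model an `organism_model` whose biomass optimum is ~0 on the medium.
#' @param universal the `universal_network` supplying candidates.
#' @param medium medium spec as in [flux_problem()].
#' @param exhaustive_limit candidate count at or below which the search is
#'   exhaustive (default 12). Set to 0 to force the greedy path.
#' @param tol growth tolerance (default 1e-9).
#' @return an object of class `gapfill_result`: `status`
#'   ("already_feasible" / "filled" / "unfillable"), `added` (reaction ids),
#'   `optimum` (post-fill biomass), `method` ("exhaustive" / "greedy").
#' @export
gapfill <- function(model, universal, medium = default_medium(universal),
                    exhaustive_limit = 12, tol = 1e-9) {
  cg_assert(inherits(model, "organism_model"), "organism_model required")
  growth <- function(mod) {
    r <- fba(flux_problem(mod, medium = medium))
    if (r$status != "optimal") 0 else r$objective
  }
  g0 <- growth(model)
  if (g0 > tol) {
    return(structure(list(status = "already_feasible", added = character(0),
                          optimum = g0, method = "none"),
                     class = "gapfill_result"))
  }
  candidates <- sort(setdiff(names(universal$reactions), names(model$reactions)))
  full <- add_reactions_to_model(model, universal, candidates)
  g_full <- growth(full)
  if (g_full <= tol) {
    return(structure(list(status = "unfillable", added = character(0),
                          optimum = g_full, method = "none"),
                     class = "gapfill_result"))
  }

  if (length(candidates) <= exhaustive_limit) {
    for (k in seq_along(candidates)) {
      subsets <- utils::combn(candidates, k, simplify = FALSE)
      for (sub in subsets) {
        g <- growth(add_reactions_to_model(model, universal, sub))
        if (g > tol) {
          return(structure(list(status = "filled", added = sub, optimum = g,
                                method = "exhaustive"),
                           class = "gapfill_result"))
        }
      }
    }
    # full set grows but no subset does -- only possible if candidates == set
    return(structure(list(status = "filled", added = candidates,
                          optimum = g_full, method = "exhaustive"),
                     class = "gapfill_result"))
  }

  # greedy scope expansion toward the model's biomass precursors
  targets <- model$biomass_precursors
  model_rids <- setdiff(names(model$reactions), model$biomass_reaction)
  seeds_avail <- names(medium) %||% character(0)
  scope_of <- function(extra) {
    network_scope(universal, seeds_avail,
                  intersect(c(model_rids, extra), names(universal$reactions)))
  }
  added <- character(0)
  repeat {
    sc <- scope_of(added)
    missing <- setdiff(targets, sc)
    if (!length(missing)) break
    best <- NULL; best_key <- c(-1, -1)
    for (cand in setdiff(candidates, added)) {
      sc2 <- scope_of(c(added, cand))
      key <- c(length(intersect(sc2, missing)), length(sc2))
      if (key[1] > best_key[1] ||
          (key[1] == best_key[1] && key[2] > best_key[2])) {
        best <- cand; best_key <- key
      }
    }
    if (is.null(best) || best_key[1] == 0 && best_key[2] <= length(sc)) {
      # scope stalled; fall back to every remaining candidate, prune below
      added <- candidates
      break
    }
    added <- c(added, best)
  }
  g <- growth(add_reactions_to_model(model, universal, added))
  if (g <= tol) added <- candidates  # scope was optimistic; use full set
  # reverse-greedy pruning
  for (rid in rev(added)) {
    trial <- setdiff(added, rid)
    if (growth(add_reactions_to_model(model, universal, trial)) > tol) {
      added <- trial
    }
  }
  g <- growth(add_reactions_to_model(model, universal, added))
  structure(list(status = "filled", added = sort(added), optimum = g,
                 method = "greedy"),
            class = "gapfill_result")
}

#' @export
print.gapfill_result <- function(x, ...) {
  cat(sprintf("gapfill_result [%s/%s]: %d reactions added, optimum %.4g\n",
              x$status, x$method, length(x$added), x$optimum))
  invisible(x)
}
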