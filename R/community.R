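# Compartmentalized community models: member internals live in uniquely
# labeled compartments c1..cn, and everything any member transports crosses
# into one shared extracellular pool e0 that every member with a matching
# transporter can access.

#' Merge organism models into a compartmentalized community model
#'
#' Member k's internal compartment "c" is relabeled `c<k>`; the extracellular
#' side of every member transport reaction is rewired to the shared
#' compartment `e0`. Reaction ids are prefixed with the member label so member
#' reaction counts are preserved exactly. One open secretion exchange reaction
#' is added per distinct `e0` compound (uptake is closed by default and opened
#' by the medium at flux-analysis time).
#'
#' @param models list of `organism_model`s with unique member labels.
#' @return an object of class `community_model`: `members` (label -> original
#'   model), `member_compartments`, merged `reactions`, `compounds`
#'   (instances), `exchanges`.
#' @export
merge_models <- function(models) {
  cg_assert(length(models) >= 1, "need at least one model")
  labels <- vapply(models, `[[`, character(1), "member_label")
  if (anyDuplicated(labels)) {
    cg_stop("duplicate member labels", class = "duplicate_member")
  }
  members <- stats::setNames(models, labels)
  member_comp <- stats::setNames(sprintf("c%d", seq_along(labels)), labels)

  reactions <- list()
  for (k in seq_along(labels)) {
    lab <- labels[k]
    for (r in members[[k]]$reactions) {
      st <- r$stoich
      st$compartment <- ifelse(st$compartment == "c", member_comp[[lab]], "e0")
      rid <- paste0(lab, ":", r$id)
      r2 <- r
      r2$id <- rid
      r2$member <- lab
      r2$stoich <- st
      reactions[[rid]] <- r2
    }
  }

  inst <- unique(do.call(rbind, lapply(reactions, function(r)
    r$stoich[, c("compound", "compartment")])))
  ext <- sort(unique(inst$compound[inst$compartment == "e0"]))
  for (cid in ext) {
    rid <- paste0("EX_", cid)
    reactions[[rid]] <- list(
      id = rid, lower = 0, upper = 1000, reversible = FALSE, transport = FALSE,
      member = NA_character_,
      stoich = data.frame(compound = cid, compartment = "e0", coeff = -1,
                          stringsAsFactors = FALSE))
  }
  inst <- inst[order(inst$compound, inst$compartment), ]
  rownames(inst) <- NULL

  structure(list(
    members = members,
    member_compartments = member_comp,
    reactions = reactions,
    compounds = inst,
    exchanges = paste0("EX_", ext)
  ), class = "community_model")
}

#' @export
print.community_model <- function(x, ...) {
  cat(sprintf("community_model: %d members, %d reactions, %d compound instances (%d in e0)\n",
              length(x$members), length(x$reactions), nrow(x$compounds),
              sum(x$compounds$compartment == "e0")))
  invisible(x)
}

#' Metabolite census of a community model
#'
#' Reports the three community-level counts: total predicted metabolites
#' (compound instances across all compartments, duplicates not removed),
#' total extracellular metabolites, and unique metabolites (distinct base
#' compound ids after stripping compartments). With the default
#' `shared_counting = "per_member"`, each member's own compound instances --
#' including its extracellular instances -- are counted once per member, so
#' a compound exported by three members contributes three to the total; with
#' `"global"`, shared-pool instances are counted once for the community.
#'
#' @param community a `community_model`.
#' @param shared_counting `"per_member"` (default) or `"global"`.
#' @return an object of class `census_report`: `taxa`, `total_predicted`,
#'   `total_extracellular`, `unique_metabolites`, `per_member_counts`,
#'   and the `shared_counting` convention used.
#' @export
census <- function(community, shared_counting = c("per_member", "global")) {
  shared_counting <- match.arg(shared_counting)
  cg_assert(inherits(community, "community_model"), "community_model required")
  per_member <- vapply(community$members, function(m) nrow(m$compounds),
                       integer(1))
  if (shared_counting == "per_member") {
    total <- sum(per_member)
  } else {
    n_ext_per_member <- vapply(community$members, function(m)
      sum(m$compounds$compartment == "e"), integer(1))
    shared <- sum(community$compounds$compartment == "e0")
    total <- sum(per_member - n_ext_per_member) + shared
  }
  uniq <- length(unique(unlist(lapply(community$members, function(m)
    unique(m$compounds$compound)))))
  extra <- sum(community$compounds$compartment == "e0")
  structure(list(
    taxa = length(community$members),
    total_predicted = total,
    total_extracellular = extra,
    unique_metabolites = uniq,
    per_member_counts = per_member,
    shared_counting = shared_counting
  ), class = "census_report")
}

#' @export
print.census_report <- function(x, ...) {
  cat(sprintf("census_report: %d taxa | total %d | extracellular %d | unique %d (%s counting)\n",
              x$taxa, x$total_predicted, x$total_extracellular,
              x$unique_metabolites, x$shared_counting))
  invisible(x)
}

#' Unique-metabolite set of a community (or of a model list)
#' @param x a `community_model` or list of `organism_model`s.
#' @return sorted character vector of distinct base compound ids.
#' @export
unique_metabolite_set <- function(x) {
  if (is.null(x)) return(character(0))
  models <- if (inherits(x, "community_model")) x$members else x
  sort(unique(unlist(lapply(models, model_compound_ids))))
}

#' Cumulative unique-metabolite saturation curve
#'
#' For models ordered (by convention) by descending abundance, entry k is the
#' number of distinct base compounds over the first k models. The curve is
#' non-decreasing; with core/accessory-structured organisms its increments
#' shrink, the saturation regime expected from metabolic redundancy.
#'
#' @param models list of `organism_model`s.
#' @return integer vector of cumulative unique counts.
#' @export
saturation_curve <- function(models) {
  cg_assert(length(models) >= 1, "need at least one model")
  seen <- character(0)
  out <- integer(length(models))
  for (k in seq_along(models)) {
    seen <- union(seen, model_compound_ids(models[[k]]))
    out[k] <- length(seen)
  }
  out
}
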