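# Draft metabolic model construction: one organism's reactions are drawn from
# the universal catalog via its gene-reaction map, spontaneous catalog
# reactions are always added, and a biomass reaction is assembled over the
# catalog's biomass precursors gated by whether the genome can produce them.

default_bounds <- function(reversible) {
  if (reversible) c(-1000, 1000) else c(0, 1000)
}

# expand a catalog reaction into compartment-tagged stoichiometry:
# cytosolic chemistry in "c"; transporters move their compound between "c"
# (coefficient -1) and "e" (+1) so the catalog's one-compound-each-side
# invariant is realized at model level.
compartmentalize_reaction <- function(rxn) {
  if (isTRUE(rxn$transport)) {
    cid <- rxn$compound
    data.frame(compound = c(cid, cid), compartment = c("c", "e"),
               coeff = c(-1, 1), stringsAsFactors = FALSE)
  } else {
    data.frame(compound = names(rxn$stoich), compartment = "c",
               coeff = unname(rxn$stoich), stringsAsFactors = FALSE)
  }
}

#' Build a draft metabolic model for one organism
#'
#' The model's reactions are the genome's mapped reactions plus every
#' spontaneous reaction of the catalog. A biomass precursor enters the biomass
#' reaction if the model carries at least one reaction able to produce it
#' (forward product, or substrate of a reversible reaction) -- a stand-in for
#' gating biomass components on annotated subsystems. A biomass with zero
#' precursors is an error, not a silent zero-growth model.
#'
#' @param genome an `organism_genome`.
#' @param universal the `universal_network` it draws from.
#' @param member_label label used when merging into a community.
#' @param provenance `"reference"` or `"mag"`.
#' @return an object of class `organism_model`: named reaction list (each with
#'   `id`, `lower`, `upper`, `reversible`, `stoich` data.frame of
#'   compound/compartment/coeff), `compounds` (compound-instance data.frame),
#'   `biomass_reaction`, `objective`, `biomass_precursors`.
#' @export
build_draft_model <- function(genome, universal, member_label = genome$organism_id,
                              provenance = c("reference", "mag")) {
  provenance <- match.arg(provenance)
  cg_assert(inherits(genome, "organism_genome"), "organism_genome required")
  cg_assert(inherits(universal, "universal_network"), "universal_network required")
  mapped <- unique(unname(genome$gene_reaction_map))
  if (!length(mapped)) {
    cg_stop("genome maps zero reactions; empty model not allowed",
            class = "empty_model")
  }
  cg_assert(all(mapped %in% names(universal$reactions)),
            "genome maps reactions absent from the universal network")
  spont <- names(universal$reactions)[vapply(universal$reactions, `[[`,
                                             logical(1), "spontaneous")]
  rxn_ids <- sort(unique(c(mapped, spont)))

  reactions <- lapply(rxn_ids, function(rid) {
    r <- universal$reactions[[rid]]
    b <- default_bounds(r$reversible)
    list(id = rid, lower = b[1], upper = b[2], reversible = r$reversible,
         transport = isTRUE(r$transport),
         stoich = compartmentalize_reaction(r))
  })
  names(reactions) <- rxn_ids

  # biomass gating: a precursor is included if >= 1 model reaction produces it
  producible <- unique(unlist(lapply(reactions, function(r) {
    st <- r$stoich[r$stoich$compartment == "c", ]
    c(st$compound[st$coeff > 0],
      if (r$reversible) st$compound[st$coeff < 0])
  })))
  precursors <- intersect(universal$biomass_precursors, producible)
  if (!length(precursors)) {
    cg_stop("no biomass precursor is producible by this genome (degenerate model)",
            class = "degenerate_biomass")
  }
  reactions[["bio1"]] <- list(
    id = "bio1", lower = 0, upper = 1000, reversible = FALSE, transport = FALSE,
    stoich = data.frame(compound = precursors, compartment = "c",
                        coeff = -1, stringsAsFactors = FALSE)
  )

  inst <- unique(do.call(rbind, lapply(reactions, function(r)
    r$stoich[, c("compound", "compartment")])))
  inst <- inst[order(inst$compound, inst$compartment), ]
  rownames(inst) <- NULL

  structure(list(
    model_id = paste0("model_", member_label),
    member_label = member_label,
    provenance = provenance,
    reactions = reactions,
    compounds = inst,
    biomass_reaction = "bio1",
    objective = "bio1",
    biomass_precursors = precursors
  ), class = "organism_model")
}

#' @export
print.organism_model <- function(x, ...) {
  cat(sprintf("organism_model %s [%s]: %d reactions, %d compound instances, %d biomass precursors\n",
              x$model_id, x$provenance, length(x$reactions), nrow(x$compounds),
              length(x$biomass_precursors)))
  invisible(x)
}

#' Base (compartment-stripped) compound ids of a model
#' @param model an `organism_model`.
#' @return sorted character vector of distinct compound ids.
#' @export
model_compound_ids <- function(model) {
  sort(unique(model$compounds$compound))
}

#' Choose a reference genome among candidates for one species
#'
#' Picks the candidate with the highest feature count; ties break to the
#' lexicographically smallest organism id. An empty candidate list signals
#' that no publicly available reference exists for the species.
#'
#' @param candidates list of `organism_genome`s.
#' @return the chosen `organism_genome`.
#' @export
choose_reference_genome <- function(candidates) {
  if (!length(candidates)) {
    cg_stop("no publicly available reference genome for this taxon",
            class = "no_reference")
  }
  fc <- vapply(candidates, `[[`, numeric(1), "feature_count")
  ids <- vapply(candidates, `[[`, character(1), "organism_id")
  candidates[[order(-fc, ids)[1]]]
}

#' Add catalog reactions to an existing model (gapfilling support)
#'
#' Appends the given universal reactions (compartmentalized as in
#' [build_draft_model()]) and refreshes the compound-instance set. The biomass
#' reaction is left untouched.
#'
#' @param model an `organism_model`.
#' @param universal the `universal_network`.
#' @param reaction_ids catalog reaction ids to add.
#' @return the augmented `organism_model`.
#' @export
add_reactions_to_model <- function(model, universal, reaction_ids) {
  reaction_ids <- setdiff(reaction_ids, names(model$reactions))
  if (!length(reaction_ids)) return(model)
  cg_assert(all(reaction_ids %in% names(universal$reactions)),
            "unknown reaction ids")
  for (rid in reaction_ids) {
    r <- universal$reactions[[rid]]
    b <- default_bounds(r$reversible)
    model$reactions[[rid]] <- list(
      id = rid, lower = b[1], upper = b[2], reversible = r$reversible,
      transport = isTRUE(r$transport), stoich = compartmentalize_reaction(r))
  }
  inst <- unique(do.call(rbind, lapply(model$reactions, function(r)
    r$stoich[, c("compound", "compartment")])))
  inst <- inst[order(inst$compound, inst$compartment), ]
  rownames(inst) <- NULL
  model$compounds <- inst
  model
}
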