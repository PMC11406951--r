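# Hand-built fixtures: tiny universal networks, genomes and models with fully
# known structure, so expected values can be computed by direct set algebra
# or enumeration in the tests themselves.

rxn_spec <- function(id, stoich, reversible = FALSE, spontaneous = FALSE,
                     transport = FALSE, compound = NA_character_) {
  list(id = id, stoich = stoich, reversible = reversible,
       spontaneous = spontaneous, transport = transport, compound = compound)
}

make_universal <- function(compound_ids, reactions, seeds, precursors,
                           external_ids = NULL, core = character(0),
                           accessory = list(), extra_transports = character(0)) {
  ext <- rep(NA_character_, length(compound_ids))
  if (!is.null(external_ids)) {
    ext[match(names(external_ids), compound_ids)] <- unname(external_ids)
  }
  names(reactions) <- vapply(reactions, `[[`, character(1), "id")
  structure(list(
    compounds = data.frame(id = compound_ids,
                           name = paste0("name_", compound_ids),
                           external_id = ext, stringsAsFactors = FALSE),
    reactions = reactions,
    seeds = seeds,
    biomass_precursors = precursors,
    modules = list(core = core, accessory = accessory,
                   extra_transports = extra_transports),
    params = list()
  ), class = "universal_network")
}

make_genome <- function(organism_id, reaction_ids, ancestor_id = organism_id) {
  genes <- sprintf("%s_g%03d", organism_id, seq_along(reaction_ids))
  structure(list(
    organism_id = organism_id,
    ancestor_id = ancestor_id,
    gene_set = genes,
    gene_reaction_map = stats::setNames(reaction_ids, genes),
    feature_count = length(genes),
    module_ids = integer(0)
  ), class = "organism_genome")
}

make_mag_record <- function(mag_id, source_id, completeness, contamination,
                            ancestor_id = source_id) {
  structure(list(
    mag_id = mag_id,
    genome = make_genome(mag_id, "r_dummy", ancestor_id = ancestor_id),
    completeness = completeness,
    contamination = contamination,
    source_organism = source_id
  ), class = "mag_record")
}

# linear chain S -> A -> B -> P with a seed transporter; biomass on P
chain_universal <- function() {
  make_universal(
    compound_ids = c("S", "A", "B", "P"),
    reactions = list(
      rxn_spec("t_S", c(S = -1), reversible = TRUE, transport = TRUE,
               compound = "S"),
      rxn_spec("r1", c(S = -1, A = 1)),
      rxn_spec("r2", c(A = -1, B = 1)),
      rxn_spec("r3", c(B = -1, P = 1))
    ),
    seeds = "S",
    precursors = "P"
  )
}

# cross-feeding world: orgA makes and exports y from S; orgB imports y and
# converts it to P. biomass precursors {y, P}: A's biomass consumes y,
# B's consumes y and P.
crossfeed_universal <- function() {
  make_universal(
    compound_ids = c("S", "y", "P"),
    reactions = list(
      rxn_spec("t_S", c(S = -1), reversible = TRUE, transport = TRUE,
               compound = "S"),
      rxn_spec("t_y", c(y = -1), reversible = TRUE, transport = TRUE,
               compound = "y"),
      rxn_spec("rA", c(S = -1, y = 1)),
      rxn_spec("rB", c(y = -1, P = 1))
    ),
    seeds = "S",
    precursors = c("y", "P")
  )
}

crossfeed_models <- function() {
  u <- crossfeed_universal()
  list(
    universal = u,
    A = build_draft_model(make_genome("orgA", c("t_S", "rA", "t_y")), u,
                          member_label = "A"),
    B = build_draft_model(make_genome("orgB", c("t_y", "rB")), u,
                          member_label = "B")
  )
}

# a bare flux problem from explicit pieces (rows = species, cols = reactions)
make_flux_problem <- function(S, lower, upper, objective) {
  cvec <- stats::setNames(rep(0, ncol(S)), colnames(S))
  cvec[names(objective)] <- objective
  structure(list(S = S, lower = stats::setNames(lower, colnames(S)),
                 upper = stats::setNames(upper, colnames(S)),
                 objective = cvec, reaction_ids = colnames(S), tol = 1e-9),
            class = "flux_problem")
}

# random small flux problem with clean +/-1, +/-2 coefficients: a chain with
# open ends plus random extra reactions (some of which dead-end)
random_small_flux_problem <- function(n_species = 6, n_rxn = 10, seed = 1) {
  set.seed(seed)
  sp <- paste0("m", seq_len(n_species))
  S <- matrix(0, n_species, n_rxn,
              dimnames = list(sp, paste0("v", seq_len(n_rxn))))
  # exchange in for m1, out for m2
  S[1, 1] <- 1
  S[2, 2] <- -1
  for (j in 3:n_rxn) {
    k <- sample(n_species, 2)
    S[k[1], j] <- -sample(1:2, 1)
    S[k[2], j] <- sample(1:2, 1)
  }
  rev <- c(FALSE, FALSE, runif(n_rxn - 2) < 0.4)
  lower <- ifelse(rev, -10, 0)
  upper <- rep(10, n_rxn)
  make_flux_problem(S, lower, upper, stats::setNames(1, "v2"))
}
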