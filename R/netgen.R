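# Synthetic-data generation: universal reaction catalogs, module-structured
# organism genomes, simulated MAGs, relative-abundance tables and untargeted
# metabolomics tables. These emulate the statistical structure of real
# community-modeling inputs (log-normal species abundances, MAG
# incompleteness/contamination, partial KEGG-style identifier coverage)
# without any sequence-level simulation.

#' Generate a universal reaction network
#'
#' Builds the global catalog of compounds and stoichiometric reactions from
#' which all synthetic organisms draw, playing the role that a biochemistry
#' database (e.g. ModelSEED's) plays for real draft reconstructions.
#'
#' Compounds are ordered and partitioned into seeds (the first few), a core
#' block, and module compounds assigned to `n_accessory_modules` pathway-like
#' modules. Reachability of every compound from the seeds holds by
#' construction: each non-seed compound receives one irreversible "backbone"
#' reaction consuming only earlier compounds from its own partition's allowed
#' set (core compounds draw on seeds and earlier core; module compounds draw
#' on seeds, core, and earlier compounds of the same module). Core backbone
#' plus one transporter per seed form the core every organism shares; each
#' module's backbone, together with randomly assigned accessory conversions,
#' forms one sampleable module. Biomass precursors live in the core, so any
#' organism carrying the core can grow, while most of the catalog's
#' metabolite diversity sits in the modules -- shared core plus distinct
#' accessory modules is what makes cumulative unique-metabolite curves
#' saturate rather than explode or stay flat.
#'
#' @param n_compounds number of compounds (>= 10).
#' @param n_reactions number of reactions (>= n_compounds).
#' @param transport_fraction fraction of reactions that are transporters, in
#'   `[0, 0.5]`. At least one transporter per seed compound is always created.
#' @param seed integer seed; identical arguments give identical catalogs.
#' @param ext_id_fraction fraction of compounds carrying a KEGG-style external
#'   id ("C" + 5 digits). The complement drives downstream "data loss".
#' @param n_accessory_modules number of accessory modules the non-core
#'   reactions are partitioned into.
#' @param core_fraction fraction of non-seed compounds placed in the shared
#'   core block (biomass precursors are drawn from it).
#' @param spontaneous_fraction fraction of accessory reactions flagged
#'   spontaneous (added to every draft model without gene support).
#' @return an object of class `universal_network` with fields `compounds`
#'   (data.frame: id, name, external_id), `reactions` (named list of reaction
#'   records), `seeds`, `biomass_precursors`, and `modules` (`$core` plus
#'   `$accessory`, a list of reaction-id vectors).
#' @export
generate_universal_network <- function(n_compounds, n_reactions,
                                       transport_fraction = 0.2,
                                       seed = 1,
                                       ext_id_fraction = 0.7,
                                       n_accessory_modules = 20,
                                       core_fraction = 0.15,
                                       spontaneous_fraction = 0.05) {
  cg_assert(n_compounds >= 10, "n_compounds must be >= 10")
  cg_assert(n_reactions >= n_compounds, "n_reactions must be >= n_compounds")
  cg_assert(transport_fraction >= 0 && transport_fraction <= 0.5,
            "transport_fraction must be in [0, 0.5]")
  cg_assert(ext_id_fraction >= 0 && ext_id_fraction <= 1,
            "ext_id_fraction must be in [0, 1]")

  with_seed(derive_seed(seed, "netgen/universal"), {
    cids <- sprintf("cpd%05d", seq_len(n_compounds))
    n_seeds <- max(3L, round(0.05 * n_compounds))
    seeds <- cids[seq_len(n_seeds)]

    ext <- rep(NA_character_, n_compounds)
    n_ext <- round(ext_id_fraction * n_compounds)
    if (n_ext > 0) {
      which_ext <- sort(sample.int(n_compounds, n_ext))
      ext[which_ext] <- sprintf("C%05d", sample.int(99999, n_ext))
    }
    compounds <- data.frame(
      id = cids,
      name = sprintf("compound_%d", seq_len(n_compounds)),
      external_id = ext,
      stringsAsFactors = FALSE
    )

    reactions <- list()
    k <- 0L
    new_rid <- function() {
      k <<- k + 1L
      sprintf("rxn%05d", k)
    }
    add_rxn <- function(stoich, reversible, spontaneous = FALSE,
                        transport = FALSE, compound = NA_character_) {
      rid <- new_rid()
      reactions[[rid]] <<- list(
        id = rid, stoich = stoich, reversible = reversible,
        spontaneous = spontaneous, transport = transport, compound = compound
      )
      rid
    }

    # compound partition: seeds | core block | module compounds
    n_core <- max(2L, round(core_fraction * (n_compounds - n_seeds)))
    core_cids <- cids[n_seeds + seq_len(n_core)]
    mod_cids <- cids[(n_seeds + n_core + 1L):n_compounds]
    n_mod <- max(1L, min(n_accessory_modules, length(mod_cids)))
    mod_of <- stats::setNames(rep_len(seq_len(n_mod), length(mod_cids)),
                              mod_cids)

    # backbone: every non-seed compound producible from earlier compounds of
    # its allowed set (keeps each module self-contained given seeds + core)
    core_backbone <- character(0)
    module_rxns <- replicate(n_mod, character(0), simplify = FALSE)
    for (i in (n_seeds + 1L):n_compounds) {
      cid <- cids[i]
      allowed <- if (cid %in% core_cids) {
        c(seeds, core_cids[seq_len(match(cid, core_cids) - 1L)])
      } else {
        same <- mod_cids[mod_of[mod_cids] == mod_of[[cid]]]
        c(seeds, core_cids, same[match(same, cids) < i])
      }
      ns <- min(length(allowed), sample(1:2, 1))
      subs <- sample(allowed, ns)
      st <- c(stats::setNames(rep(-1, ns), subs), stats::setNames(1, cid))
      rid <- add_rxn(st, reversible = FALSE)
      if (cid %in% core_cids) core_backbone <- c(core_backbone, rid)
      else module_rxns[[mod_of[[cid]]]] <- c(module_rxns[[mod_of[[cid]]]], rid)
    }

    # transporters: one per seed (core), rest over random other compounds
    n_backbone <- n_compounds - n_seeds
    n_transport <- max(n_seeds, round(transport_fraction * n_reactions))
    n_transport <- min(n_transport, n_reactions - n_backbone)
    cg_assert(n_transport >= n_seeds,
              "reaction budget too small for seed transporters",
              class = "generation_failure")
    seed_transports <- vapply(seeds, function(s)
      add_rxn(stats::setNames(-1, s), reversible = TRUE, transport = TRUE,
              compound = s), character(1))
    extra_pool <- setdiff(cids, seeds)
    n_extra_t <- n_transport - n_seeds
    extra_transports <- character(0)
    if (n_extra_t > 0) {
      tc <- sample(extra_pool, min(n_extra_t, length(extra_pool)))
      extra_transports <- vapply(tc, function(s)
        add_rxn(stats::setNames(-1, s), reversible = TRUE, transport = TRUE,
                compound = s), character(1))
    }

    # accessory conversions: random substrates -> products, each assigned to
    # a random module (they may dead-end, feeding blocked-reaction counts)
    n_accessory <- n_reactions - n_backbone - length(seed_transports) -
      length(extra_transports)
    for (j in seq_len(n_accessory)) {
      ns <- sample(1:2, 1)
      np <- sample(1:2, 1)
      picks <- sample(cids, ns + np)
      st <- c(stats::setNames(rep(-1, ns), picks[seq_len(ns)]),
              stats::setNames(rep(1, np), picks[ns + seq_len(np)]))
      rid <- add_rxn(st, reversible = stats::runif(1) < 0.3,
                     spontaneous = stats::runif(1) < spontaneous_fraction)
      m <- sample.int(n_mod, 1)
      module_rxns[[m]] <- c(module_rxns[[m]], rid)
    }

    n_prec <- min(8L, max(2L, round(n_compounds / 25)))
    biomass_precursors <- sort(sample(core_cids, min(n_prec, length(core_cids))))
    modules <- lapply(module_rxns, sort)

    net <- structure(list(
      compounds = compounds,
      reactions = reactions,
      seeds = seeds,
      biomass_precursors = biomass_precursors,
      modules = list(core = sort(unname(c(core_backbone, seed_transports))),
                     accessory = lapply(modules, unname),
                     extra_transports = sort(unname(extra_transports))),
      params = list(n_compounds = n_compounds, n_reactions = n_reactions,
                    transport_fraction = transport_fraction, seed = seed,
                    ext_id_fraction = ext_id_fraction)
    ), class = "universal_network")

    reach <- network_scope(net, net$seeds)
    if (!all(biomass_precursors %in% reach)) {
      cg_stop("biomass precursor unreachable from seed compounds",
              class = "generation_failure")
    }
    net
  })
}

#' @export
print.universal_network <- function(x, ...) {
  cat(sprintf(
    "universal_network: %d compounds, %d reactions (%d transport, %d spontaneous)\n",
    nrow(x$compounds), length(x$reactions),
    sum(vapply(x$reactions, `[[`, logical(1), "transport")),
    sum(vapply(x$reactions, `[[`, logical(1), "spontaneous"))))
  cat(sprintf("  seeds: %d; biomass precursors: %d; accessory modules: %d\n",
              length(x$seeds), length(x$biomass_precursors),
              length(x$modules$accessory)))
  invisible(x)
}

#' Boolean network expansion (scope) over a reaction set
#'
#' Computes the set of compounds producible from a starting compound set under
#' the all-substrates-required firing rule: a reaction fires forward once all
#' its substrates are available (and backward too, if reversible). Transport
#' reactions do not change the compound set at catalog level (the transported
#' compound is the same chemical species on both sides).
#'
#' @param universal a `universal_network`.
#' @param start character vector of available compound ids.
#' @param reaction_ids reactions to expand over (default: whole catalog).
#' @return character vector of reachable compound ids (includes `start`).
#' @export
network_scope <- function(universal, start,
                          reaction_ids = names(universal$reactions)) {
  rxns <- universal$reactions[reaction_ids]
  have <- unique(start)
  repeat {
    added <- FALSE
    for (r in rxns) {
      if (r$transport) next
      st <- r$stoich
      subs <- names(st)[st < 0]
      prods <- names(st)[st > 0]
      if (all(subs %in% have)) {
        new <- setdiff(prods, have)
        if (length(new)) { have <- c(have, new); added <- TRUE }
      }
      if (r$reversible && all(prods %in% have)) {
        new <- setdiff(subs, have)
        if (length(new)) { have <- c(have, new); added <- TRUE }
      }
    }
    if (!added) break
  }
  sort(have)
}

#' Sample an organism genome from a universal network
#'
#' An organism is the network core (backbone plus seed transporters, shared by
#' every organism drawn from the same catalog) plus `n_modules` accessory
#' modules sampled without replacement, plus a share of the non-core
#' transporters. Each non-spontaneous reaction is encoded by exactly one gene.
#'
#' @param universal a `universal_network`.
#' @param n_modules number of accessory modules (>= 1).
#' @param seed integer seed.
#' @param organism_id identifier; defaults to a seed-derived id.
#' @param ancestor_id species identity used as the dereplication/strain proxy;
#'   strain variants of one species share it. Defaults to `organism_id`.
#' @param transport_draw fraction of the catalog's non-core transporters this
#'   organism carries (drawn at random).
#' @return an object of class `organism_genome`.
#' @export
sample_organism_genome <- function(universal, n_modules, seed = 1,
                                   organism_id = sprintf("org_seed%d", seed),
                                   ancestor_id = organism_id,
                                   transport_draw = 0.3) {
  cg_assert(inherits(universal, "universal_network"), "universal_network required")
  cg_assert(n_modules >= 1, "n_modules must be >= 1")
  n_avail <- length(universal$modules$accessory)
  if (n_modules > n_avail) {
    cg_stop(sprintf("n_modules (%d) exceeds available accessory modules (%d)",
                    n_modules, n_avail), class = "precondition")
  }
  with_seed(derive_seed(seed, paste0("netgen/organism/", organism_id)), {
    picked <- sort(sample.int(n_avail, n_modules))
    rxns <- c(universal$modules$core,
              unlist(universal$modules$accessory[picked], use.names = FALSE))
    et <- universal$modules$extra_transports
    if (length(et)) {
      n_t <- round(transport_draw * length(et))
      if (n_t > 0) rxns <- c(rxns, sample(et, n_t))
    }
    rxns <- sort(unique(rxns))
    spont <- vapply(universal$reactions[rxns], `[[`, logical(1), "spontaneous")
    coding <- rxns[!spont]
    genes <- sprintf("%s_g%04d", organism_id, seq_along(coding))
    structure(list(
      organism_id = organism_id,
      ancestor_id = ancestor_id,
      gene_set = genes,
      gene_reaction_map = stats::setNames(coding, genes),
      feature_count = length(genes),
      module_ids = picked
    ), class = "organism_genome")
  })
}

#' @export
print.organism_genome <- function(x, ...) {
  cat(sprintf("organism_genome %s (ancestor %s): %d genes -> %d reactions\n",
              x$organism_id, x$ancestor_id, x$feature_count,
              length(unique(x$gene_reaction_map))))
  invisible(x)
}

#' Simulate a metagenome-assembled genome from a source organism
#'
#' Emulates MAG incompleteness and contamination at the gene level: a fraction
#' `completeness` of the source genes is retained uniformly at random, and
#' foreign genes from other pool organisms are added until the foreign/total
#' ratio reaches `contamination`/100 (the largest foreign count `f` with
#' `100 f / (kept + f) <= contamination`). Realized percentages are recorded;
#' quality classification is applied downstream, never computed from sequence.
#'
#' @param source an `organism_genome`.
#' @param completeness target completeness percentage in (0, 100].
#' @param contamination target contamination percentage in \\[0, 100).
#' @param pool list of other `organism_genome`s contamination is drawn from;
#'   required non-empty when contamination > 0.
#' @param seed integer seed.
#' @param mag_id identifier (default derived from the source id).
#' @return an object of class `mag_record` with fields `mag_id`, `genome`,
#'   `completeness`, `contamination` (both realized), `source_organism`.
#' @export
simulate_mag <- function(source, completeness, contamination = 0,
                         pool = list(), seed = 1,
                         mag_id = paste0("mag_", source$organism_id)) {
  cg_assert(inherits(source, "organism_genome"), "source must be an organism_genome")
  cg_assert(completeness > 0 && completeness <= 100,
            "completeness must be in (0, 100]")
  cg_assert(contamination >= 0 && contamination < 100,
            "contamination must be in [0, 100)")
  if (contamination > 0 && length(pool) == 0) {
    cg_stop("contamination > 0 requires a non-empty pool", class = "precondition")
  }
  with_seed(derive_seed(seed, paste0("netgen/mag/", mag_id)), {
    n_src <- length(source$gene_set)
    n_keep <- round(completeness / 100 * n_src)
    keep <- sort(sample(source$gene_set, n_keep))

    f <- if (contamination > 0) {
      floor(contamination * n_keep / (100 - contamination))
    } else 0L
    while (f > 0 && 100 * f / (n_keep + f) > contamination) f <- f - 1L
    foreign_genes <- character(0)
    foreign_map <- character(0)
    if (f > 0) {
      pool_maps <- lapply(pool, function(g) {
        m <- g$gene_reaction_map
        m[setdiff(names(m), source$gene_set)]
      })
      all_foreign <- do.call(c, pool_maps)
      all_foreign <- all_foreign[!duplicated(names(all_foreign))]
      f <- min(f, length(all_foreign))
      if (f > 0) {
        pick <- sample(seq_along(all_foreign), f)
        foreign_map <- all_foreign[pick]
        foreign_genes <- names(foreign_map)
      }
    }
    genes <- c(keep, foreign_genes)
    gmap <- c(source$gene_reaction_map[keep], foreign_map)
    genome <- structure(list(
      organism_id = mag_id,
      ancestor_id = source$ancestor_id,
      gene_set = genes,
      gene_reaction_map = gmap,
      feature_count = length(genes),
      module_ids = source$module_ids
    ), class = "organism_genome")
    structure(list(
      mag_id = mag_id,
      genome = genome,
      completeness = 100 * n_keep / n_src,
      contamination = if (length(genes)) 100 * length(foreign_genes) / length(genes) else 0,
      source_organism = source$organism_id,
      requested = c(completeness = completeness, contamination = contamination)
    ), class = "mag_record")
  })
}

#' @export
print.mag_record <- function(x, ...) {
  cat(sprintf("mag_record %s (source %s): completeness %.2f%%, contamination %.2f%%, %d genes\n",
              x$mag_id, x$source_organism, x$completeness, x$contamination,
              length(x$genome$gene_set)))
  invisible(x)
}

#' Sample a relative-abundance table
#'
#' Emulates a species-level taxonomic profiler output: per sample, independent
#' log-normal weights per species, normalized to percentages summing to 100.
#'
#' @param organisms list of `organism_genome`s or a character vector of ids.
#' @param n_samples samples in this group (>= 1).
#' @param lognormal_sigma sdlog of the log-normal weights (> 0).
#' @param seed integer seed.
#' @param group group label for the sample columns.
#' @return an object of class `abundance_table` with fields `species`,
#'   `groups` (label -> sample columns) and `abundance` (species x samples
#'   percentage matrix).
#' @export
sample_abundance_table <- function(organisms, n_samples, lognormal_sigma = 1,
                                   seed = 1, group = "group1") {
  species <- if (is.character(organisms)) organisms
             else vapply(organisms, `[[`, character(1), "organism_id")
  cg_assert(length(species) >= 2, "need at least 2 organisms")
  cg_assert(n_samples >= 1, "n_samples must be >= 1")
  cg_assert(lognormal_sigma > 0, "lognormal_sigma must be > 0")
  with_seed(derive_seed(seed, paste0("netgen/abundance/", group)), {
    m <- matrix(0, nrow = length(species), ncol = n_samples,
                dimnames = list(species,
                                sprintf("%s_s%02d", group, seq_len(n_samples))))
    for (j in seq_len(n_samples)) {
      w <- stats::rlnorm(length(species), meanlog = 0, sdlog = lognormal_sigma)
      m[, j] <- 100 * w / sum(w)
    }
    structure(list(
      species = species,
      groups = stats::setNames(list(colnames(m)), group),
      abundance = m
    ), class = "abundance_table")
  })
}

#' Combine abundance tables over the same species into one multi-group table
#' @param ... `abundance_table`s with identical species sets.
#' @return a single `abundance_table`.
#' @export
merge_abundance_tables <- function(...) {
  tabs <- list(...)
  cg_assert(length(tabs) >= 1, "no tables given")
  sp <- tabs[[1]]$species
  for (t in tabs) cg_assert(identical(sort(t$species), sort(sp)),
                            "species sets differ across tables")
  ab <- do.call(cbind, lapply(tabs, function(t) t$abundance[sp, , drop = FALSE]))
  groups <- do.call(c, lapply(tabs, `[[`, "groups"))
  cg_assert(!anyDuplicated(names(groups)), "duplicate group labels")
  cg_assert(!anyDuplicated(colnames(ab)), "duplicate sample names")
  structure(list(species = sp, groups = groups, abundance = ab),
            class = "abundance_table")
}

#' Simulate an untargeted metabolomics table
#'
#' One row per true exometabolome compound, carrying the compound's external
#' (KEGG-style) id unless the compound is selected for identifier loss or the
#' catalog never assigned one. A small fraction of identified rows receive a
#' replicate external id (a second id for the same metabolite). `n_host_extras`
#' rows with fresh ids absent from the catalog emulate host/diet metabolites.
#' Abundances are log-normal positives with missingness; every row retains at
#' least one measured value (missingness models sample dropout, not detection
#' failure -- all-absent metabolites are simply not rows of the table).
#'
#' @param true_exometabolome character vector of compound ids.
#' @param universal the `universal_network` supplying names/external ids.
#' @param id_loss_rate fraction of rows whose external id is dropped, in
#'   `[0, 1)`. `round(id_loss_rate * n)` rows (among those with ids) lose theirs.
#' @param n_host_extras rows with ids unmatched against the catalog.
#' @param n_samples number of sample columns (>= 1).
#' @param seed integer seed.
#' @param group group label for sample columns.
#' @param replicate_id_fraction fraction of identified rows given one
#'   replicate id.
#' @param missing_rate per-cell missingness probability.
#' @return object of class `metabolomics_table`: `rows` (data.frame: name,
#'   external_id, replicate_ids ";"-separated), `abundance` matrix, `groups`.
#' @export
simulate_metabolomics <- function(true_exometabolome, universal,
                                  id_loss_rate = 0.3, n_host_extras = 40,
                                  n_samples = 4, seed = 1, group = "group1",
                                  replicate_id_fraction = 0.07,
                                  missing_rate = 0.15) {
  cg_assert(id_loss_rate >= 0 && id_loss_rate < 1,
            "id_loss_rate must be in [0, 1)")
  cg_assert(n_samples >= 1, "n_samples must be >= 1")
  cmp <- universal$compounds
  true <- sort(unique(true_exometabolome))
  cg_assert(all(true %in% cmp$id), "true exometabolome outside the catalog")
  with_seed(derive_seed(seed, paste0("netgen/metabolomics/", group)), {
    idx <- match(true, cmp$id)
    name <- cmp$name[idx]
    ext <- cmp$external_id[idx]

    n_loss <- round(id_loss_rate * length(true))
    with_id <- which(!is.na(ext))
    if (n_loss > 0 && length(with_id) > 0) {
      lose <- sample(with_id, min(n_loss, length(with_id)))
      ext[lose] <- NA_character_
    }

    used_ids <- c(stats::na.omit(cmp$external_id), stats::na.omit(ext))
    fresh_id <- function(n) {
      out <- character(0)
      while (length(out) < n) {
        cand <- sprintf("C%05d", sample.int(99999, n - length(out) + 5))
        cand <- setdiff(cand, c(used_ids, out))
        out <- c(out, cand)
      }
      used_ids <<- c(used_ids, out[seq_len(n)])
      out[seq_len(n)]
    }

    rep_ids <- rep(NA_character_, length(true))
    id_rows <- which(!is.na(ext))
    n_rep <- round(replicate_id_fraction * length(id_rows))
    if (n_rep > 0) {
      rr <- sample(id_rows, n_rep)
      rep_ids[rr] <- fresh_id(n_rep)
    }

    if (n_host_extras > 0) {
      name <- c(name, sprintf("host_metabolite_%d", seq_len(n_host_extras)))
      ext <- c(ext, fresh_id(n_host_extras))
      rep_ids <- c(rep_ids, rep(NA_character_, n_host_extras))
    }
    n_rows <- length(name)
    ab <- matrix(stats::rlnorm(n_rows * n_samples, meanlog = 2, sdlog = 1),
                 nrow = n_rows,
                 dimnames = list(NULL, sprintf("%s_m%02d", group,
                                               seq_len(n_samples))))
    miss <- matrix(stats::runif(n_rows * n_samples) < missing_rate,
                   nrow = n_rows)
    keep_one <- sample.int(n_samples, n_rows, replace = TRUE)
    miss[cbind(seq_len(n_rows), keep_one)] <- FALSE
    ab[miss] <- NA_real_

    structure(list(
      rows = data.frame(name = name, external_id = ext,
                        replicate_ids = rep_ids, stringsAsFactors = FALSE),
      abundance = ab,
      groups = stats::setNames(list(colnames(ab)), group)
    ), class = "metabolomics_table")
  })
}
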