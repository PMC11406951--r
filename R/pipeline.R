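# End-to-end experiment orchestration: simulate a community world, run the
# reference-guided and MAG-guided selection strategies, build and merge
# models, compute census/validation/enrichment reports, and (optionally)
# gapfill and classify blocked reactions.

#' Experiment configuration with defaults
#'
#' Defaults describe the synthetic world the pipeline emulates: two sample
#' groups of 15 profiles each (30 in total), species abundances log-normal
#' within sample, 30 organisms drawn from a 200-compound / 400-reaction
#' catalog, abundance cutoffs 5 / 2.5 / 1 / 0.5 percent, MAG completeness
#' uniform on 55-99 percent with zero contamination, ~30 percent external-id
#' loss on the metabolomics side, and significance at q < 0.05. Gapfilling
#' and blocked-reaction classification are off by default (they multiply
#' runtime and are reported by dedicated stages when enabled).
#'
#' @param seed integer run seed; all stage seeds derive from it.
#' @param n_organisms community size.
#' @param n_compounds,n_reactions,transport_fraction,ext_id_fraction catalog
#'   generation parameters (see [generate_universal_network()]).
#' @param n_modules_per_organism accessory modules per organism.
#' @param n_accessory_modules modules the catalog is partitioned into.
#' @param core_fraction fraction of non-seed compounds in the shared core.
#' @param groups named integer vector: samples per group.
#' @param lognormal_sigma abundance dispersion (sdlog).
#' @param cutoffs strictly decreasing abundance cutoffs (percent).
#' @param completeness_range,contamination_range uniform ranges for simulated
#'   MAG quality (percent).
#' @param reference_max_candidates reference genomes available per species
#'   are drawn uniformly from 1..this.
#' @param reference_strain_retention probability a reference genome retains
#'   each gene of the sample strain. 1 (default) makes references exact
#'   supersets of zero-contamination MAGs, the regime in which the
#'   MAG-within-reference containment property is exact; values below 1
#'   emulate strain-level deviation of public genomes from sample strains.
#' @param p_no_reference probability a species has no public reference genome
#'   (it is then excluded with a recorded reason).
#' @param id_loss_rate,n_host_extras,n_metabolomics_samples metabolomics
#'   simulation parameters.
#' @param q_threshold enrichment significance threshold (strict <).
#' @param gapfill run the gapfilling stage and fold-change accounting.
#' @param fva classify blocked reactions per input model.
#' @param out_dir if non-NULL, persist intermediates and reports there.
#' @return a validated list of class `experiment_config`.
#' @export
experiment_config <- function(seed = 1,
                              n_organisms = 30,
                              n_compounds = 300,
                              n_reactions = 600,
                              transport_fraction = 0.2,
                              ext_id_fraction = 0.7,
                              n_modules_per_organism = 3,
                              n_accessory_modules = 30,
                              core_fraction = 0.15,
                              groups = c(group1 = 15, group2 = 15),
                              lognormal_sigma = 1.5,
                              cutoffs = c(5, 2.5, 1, 0.5),
                              completeness_range = c(55, 99),
                              contamination_range = c(0, 0),
                              reference_max_candidates = 3,
                              reference_strain_retention = 1,
                              p_no_reference = 0,
                              id_loss_rate = 0.3,
                              n_host_extras = 40,
                              n_metabolomics_samples = 4,
                              q_threshold = 0.05,
                              gapfill = FALSE,
                              fva = FALSE,
                              out_dir = NULL) {
  cg_assert(all(diff(cutoffs) < 0), "cutoffs must be strictly decreasing")
  cg_assert(all(cutoffs > 0), "cutoffs must be positive")
  cg_assert(n_organisms >= 1, "n_organisms must be >= 1")
  cg_assert(!is.null(names(groups)) && all(nzchar(names(groups))),
            "groups must be a named vector")
  cg_assert(all(groups >= 1), "each group needs >= 1 sample")
  cg_assert(completeness_range[1] > 0 && completeness_range[2] <= 100 &&
            diff(completeness_range) >= 0, "bad completeness_range")
  cg_assert(contamination_range[1] >= 0 && contamination_range[2] < 100 &&
            diff(contamination_range) >= 0, "bad contamination_range")
  cg_assert(id_loss_rate >= 0 && id_loss_rate < 1, "bad id_loss_rate")
  cg_assert(q_threshold > 0 && q_threshold < 1, "bad q_threshold")
  structure(as.list(environment()), class = "experiment_config")
}

#' Fold change between pre- and post-gapfilling counts
#' @param pre count before (> 0).
#' @param post count after.
#' @return `post / pre` rounded to 2 decimals.
#' @export
fold_change <- function(pre, post) {
  cg_assert(length(pre) == 1 && length(post) == 1, "scalar counts required")
  if (!is.finite(pre) || pre <= 0) {
    cg_stop("pre-count must be > 0", class = "precondition")
  }
  round_half_up(post / pre, 2)
}

# uniform draw on a range under a derived seed
draw_range <- function(n, range, seed, label) {
  with_seed(derive_seed(seed, label), {
    if (diff(range) == 0) rep(range[1], n)
    else stats::runif(n, range[1], range[2])
  })
}

# strain-variant reference genomes for one species: each variant keeps each
# gene of the sample strain with probability `retention` (public reference
# genomes deviate from the strain actually present in the samples), same
# ancestor id. retention = 1 reproduces the strain exactly.
reference_candidates <- function(org, n, seed, retention = 1) {
  with_seed(derive_seed(seed, paste0("pipeline/refs/", org$organism_id)), {
    lapply(seq_len(n), function(j) {
      keep <- if (retention >= 1) rep(TRUE, length(org$gene_set))
              else stats::runif(length(org$gene_set)) < retention
      if (!any(keep)) keep[1] <- TRUE
      genes <- org$gene_set[keep]
      structure(list(
        organism_id = sprintf("%s_ref%d", org$organism_id, j),
        ancestor_id = org$ancestor_id,
        gene_set = genes,
        gene_reaction_map = org$gene_reaction_map[genes],
        feature_count = length(genes),
        module_ids = org$module_ids
      ), class = "organism_genome")
    })
  })
}

build_or_exclude <- function(genomes, universal, provenance, selection) {
  models <- list()
  for (lab in names(genomes)) {
    mod <- tryCatch(
      build_draft_model(genomes[[lab]], universal, member_label = lab,
                        provenance = provenance),
      commgem_error = function(e) e)
    if (inherits(mod, "commgem_error")) {
      selection <- exclude_taxa(selection, lab, conditionMessage(mod))
    } else {
      models[[lab]] <- mod
    }
  }
  list(models = models, selection = selection)
}

#' Run the full reference-guided vs MAG-guided comparison
#'
#' Executes every stage for both approaches in each sample group: catalog and
#' organism generation, abundance profiling, cutoff-based reference selection
#' (with reference-genome choice and recorded exclusions), MAG simulation
#' with quality tiers, dereplication and the taxon-count-normalized
#' condition, draft building, compartmentalized merging, census, saturation
#' curves, metabolomics validation, Venn complementarity and pathway
#' enrichment comparison, plus optional gapfilling fold accounting and
#' blocked-reaction percentages. Fully deterministic under `config$seed`.
#'
#' @param config an `experiment_config`.
#' @return an object of class `report_bundle`; see [report_tables()].
#' @export
run_comparison <- function(config) {
  cg_assert(inherits(config, "experiment_config"), "experiment_config required")
  s <- config$seed
  stage <- function(label) derive_seed(s, label)

  universal <- generate_universal_network(
    config$n_compounds, config$n_reactions, config$transport_fraction,
    seed = stage("universal"), ext_id_fraction = config$ext_id_fraction,
    n_accessory_modules = config$n_accessory_modules,
    core_fraction = config$core_fraction)

  organisms <- lapply(seq_len(config$n_organisms), function(k)
    sample_organism_genome(universal, config$n_modules_per_organism,
                           seed = stage(sprintf("organism/%03d", k)),
                           organism_id = sprintf("org%03d", k)))
  names(organisms) <- vapply(organisms, `[[`, character(1), "organism_id")

  tables <- lapply(names(config$groups), function(g) {
    if (config$n_organisms == 1) {
      # degenerate single-member community: trivially 100% everywhere
      cols <- sprintf("%s_s%02d", g, seq_len(config$groups[[g]]))
      m <- matrix(100, nrow = 1, ncol = length(cols),
                  dimnames = list(names(organisms), cols))
      structure(list(species = names(organisms),
                     groups = stats::setNames(list(cols), g),
                     abundance = m), class = "abundance_table")
    } else {
      sample_abundance_table(organisms, config$groups[[g]],
                             config$lognormal_sigma,
                             seed = stage(paste0("abundance/", g)), group = g)
    }
  })
  abundance <- if (length(tables) > 1) do.call(merge_abundance_tables, tables)
               else tables[[1]]

  idmap <- external_id_map(universal)
  pathways <- module_pathways(universal)
  background <- sort(unique(idmap[!is.na(idmap)]))

  # which species have public reference genomes, and how many
  n_cand <- with_seed(stage("refcounts"), {
    n <- sample.int(config$reference_max_candidates, config$n_organisms,
                    replace = TRUE)
    n[stats::runif(config$n_organisms) < config$p_no_reference] <- 0L
    n
  })
  names(n_cand) <- names(organisms)
  ref_genomes <- lapply(names(organisms), function(o) {
    if (n_cand[[o]] == 0) return(list())
    reference_candidates(organisms[[o]], n_cand[[o]], s,
                         retention = config$reference_strain_retention)
  })
  names(ref_genomes) <- names(organisms)

  ref_model_cache <- new.env(parent = emptyenv())
  ref_model_for <- function(taxon) {
    if (!is.null(ref_model_cache[[taxon]])) return(ref_model_cache[[taxon]])
    genome <- choose_reference_genome(ref_genomes[[taxon]])
    m <- build_draft_model(genome, universal, member_label = taxon,
                           provenance = "reference")
    ref_model_cache[[taxon]] <- m
    m
  }

  groups_out <- list()
  for (g in names(config$groups)) {
    means <- mean_relative_abundance(abundance, g)

    # ---- reference-guided conditions (one per cutoff) ----
    ref_conditions <- list()
    for (cutoff in config$cutoffs) {
      sel <- select_by_cutoff(means, cutoff)
      models <- list()
      for (taxon in sel$taxa_detected) {
        m <- tryCatch(ref_model_for(taxon), commgem_error = function(e) e)
        if (inherits(m, "commgem_error")) {
          sel <- exclude_taxa(sel, taxon, conditionMessage(m))
        } else {
          models[[taxon]] <- m
        }
      }
      if (length(models)) {
        comm <- merge_models(unname(models))
        cns <- census(comm)
      } else {
        comm <- NULL
        cns <- structure(list(
          taxa = 0L, total_predicted = 0L, total_extracellular = 0L,
          unique_metabolites = 0L, per_member_counts = integer(0),
          shared_counting = "per_member"), class = "census_report")
      }
      ref_conditions[[sprintf("%g%%", cutoff)]] <- list(
        selection = sel, models = models, community = comm, census = cns)
    }

    # ---- MAG-guided conditions ----
    comp <- draw_range(config$n_organisms, config$completeness_range, s,
                       paste0("mag/comp/", g))
    cont <- draw_range(config$n_organisms, config$contamination_range, s,
                       paste0("mag/cont/", g))
    mags <- lapply(seq_along(organisms), function(k)
      simulate_mag(organisms[[k]], comp[k], cont[k],
                   pool = organisms[-k],
                   seed = stage(sprintf("mag/%s/%03d", g, k)),
                   mag_id = sprintf("mag_%s_%s", g, names(organisms)[k])))
    tier <- vapply(mags, function(m)
      classify_mag_quality(m$completeness, m$contamination), character(1))
    usable <- dereplicate_mags(mags[tier != "fail"])
    usable_tier <- vapply(usable, function(m)
      classify_mag_quality(m$completeness, m$contamination), character(1))

    empty_census <- structure(list(
      taxa = 0L, total_predicted = 0L, total_extracellular = 0L,
      unique_metabolites = 0L, per_member_counts = integer(0),
      shared_counting = "per_member"), class = "census_report")
    mag_condition <- function(mag_list, label, params) {
      labs <- vapply(mag_list, `[[`, character(1), "mag_id")
      sel <- new_selection_result("mag", params, taxa_detected = labs)
      genomes <- stats::setNames(lapply(mag_list, `[[`, "genome"), labs)
      be <- build_or_exclude(genomes, universal, "mag", sel)
      if (!length(be$models)) {
        return(list(selection = be$selection, models = list(),
                    community = NULL, census = empty_census))
      }
      comm <- merge_models(unname(be$models))
      list(selection = be$selection, models = be$models, community = comm,
           census = census(comm))
    }
    n_ref_at_min <- length(ref_conditions[[length(ref_conditions)]]$selection$taxa_used)
    mag_conditions <- list(
      high = mag_condition(usable[usable_tier == "high"], "high",
                           list(tiers = "high")),
      high_medium = mag_condition(usable, "high_medium",
                                  list(tiers = c("high", "medium"))),
      normalized = mag_condition(
        normalize_mag_count(usable, max(1, n_ref_at_min)), "normalized",
        list(tiers = "high", normalize_to = n_ref_at_min))
    )

    # ---- validation ----
    true_exo <- sort(unique(unlist(lapply(names(organisms), function(o) {
      m <- tryCatch(
        build_draft_model(organisms[[o]], universal, member_label = o),
        commgem_error = function(e) NULL)
      if (is.null(m)) return(character(0))
      m$compounds$compound[m$compounds$compartment == "e"]
    }))))
    metab <- simulate_metabolomics(
      true_exo, universal, id_loss_rate = config$id_loss_rate,
      n_host_extras = config$n_host_extras,
      n_samples = config$n_metabolomics_samples,
      seed = stage(paste0("metabolomics/", g)), group = g)
    presence <- to_presence(metab, g)

    all_conditions <- c(ref_conditions, mag_conditions)
    validations <- lapply(all_conditions, function(cond)
      match_predictions(unique_metabolite_set(cond$community), idmap, presence))

    # ---- complementarity and enrichment (reference finest cutoff vs
    #      MAG high+medium, mirroring the headline comparison) ----
    ref_set <- unique_metabolite_set(
      ref_conditions[[length(ref_conditions)]]$community)
    mag_set <- unique_metabolite_set(mag_conditions$high_medium$community)
    venn_unique <- venn(ref_set, mag_set)
    venn_confirmed <- venn(
      validations[[length(ref_conditions)]]$confirmed_ids,
      validations$high_medium$confirmed_ids)

    mapped <- function(ids) {
      e <- idmap[ids]
      sort(unique(e[!is.na(e)]))
    }
    enr_ref <- enrichment(mapped(ref_set), background, pathways,
                          config$q_threshold, label = "reference")
    enr_mag <- enrichment(mapped(mag_set), background, pathways,
                          config$q_threshold, label = "mag")
    enr_combined <- enrichment(mapped(combine_lists(ref_set, mag_set)),
                               background, pathways, config$q_threshold,
                               label = "combined")
    enr_compare <- compare_enrichment(enr_ref, enr_mag, config$q_threshold)

    # saturation: reference models at the finest cutoff, by descending mean
    fin <- ref_conditions[[length(ref_conditions)]]
    sat_order <- fin$selection$taxa_used
    saturation <- if (length(sat_order)) saturation_curve(fin$models[sat_order])
                  else integer(0)

    # ---- optional gapfilling fold accounting ----
    gapfill_report <- NULL
    if (isTRUE(config$gapfill)) {
      medium <- default_medium(universal)
      fill_all <- function(models) {
        lapply(models, function(m) {
          gf <- gapfill(m, universal, medium)
          if (gf$status == "filled") add_reactions_to_model(m, universal, gf$added)
          else m
        })
      }
      gf_pair <- function(cond) {
        if (is.null(cond$community)) return(NULL)
        pre <- census(cond$community)
        post_models <- fill_all(cond$models)
        post <- census(merge_models(unname(post_models)))
        list(pre = pre, post = post,
             fold_total = fold_change(pre$total_predicted, post$total_predicted),
             fold_unique = fold_change(pre$unique_metabolites,
                                       post$unique_metabolites))
      }
      gapfill_report <- list(
        reference = gf_pair(ref_conditions[[length(ref_conditions)]]),
        mag_normalized = gf_pair(mag_conditions$normalized))
    }

    # ---- optional blocked-reaction percentages (reference, finest cutoff) ----
    blocked <- NULL
    if (isTRUE(config$fva)) {
      medium <- default_medium(universal)
      blocked <- vapply(fin$models, function(m)
        fva(flux_problem(m, medium = medium), values = FALSE)$blocked_percentage,
        numeric(1))
    }

    groups_out[[g]] <- list(
      means = means,
      conditions = all_conditions,
      validations = validations,
      venn_unique = venn_unique,
      venn_confirmed = venn_confirmed,
      enrichment = list(reference = enr_ref, mag = enr_mag,
                        combined = enr_combined, compare = enr_compare),
      saturation = saturation,
      gapfill = gapfill_report,
      blocked = blocked,
      mag_tiers = table(tier)
    )
  }

  bundle <- structure(list(
    config = config,
    universal = universal,
    abundance = abundance,
    groups = groups_out
  ), class = "report_bundle")

  if (!is.null(config$out_dir)) write_report_bundle(bundle, config$out_dir)
  bundle
}

#' Census/validation summary tables of a report bundle
#'
#' One row per group x condition in the canonical parameter order (cutoffs
#' descending, then MAG high / high+medium / normalized), with the taxa
#' detected and used counts, the three census metrics and the validation
#' bookkeeping -- the layout of the study-style summary tables.
#'
#' @param bundle a `report_bundle`.
#' @return data.frame.
#' @export
report_tables <- function(bundle) {
  rows <- list()
  for (g in names(bundle$groups)) {
    go <- bundle$groups[[g]]
    for (cond_name in names(go$conditions)) {
      cond <- go$conditions[[cond_name]]
      v <- go$validations[[cond_name]]
      cn <- cond$census
      rows[[length(rows) + 1]] <- data.frame(
        group = g,
        approach = cond$selection$approach,
        condition = cond_name,
        taxa_detected = length(cond$selection$taxa_detected),
        taxa_used = length(cond$selection$taxa_used),
        total_predicted = cn$total_predicted,
        total_extracellular = cn$total_extracellular,
        unique_metabolites = cn$unique_metabolites,
        confirmed = v$confirmed_count,
        data_loss_pct = v$data_loss_pct,
        confirmed_pct = v$confirmed_pct,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' @export
print.report_bundle <- function(x, ...) {
  cat(sprintf("report_bundle: %d groups, seed %d\n", length(x$groups),
              x$config$seed))
  print(report_tables(x))
  invisible(x)
}

#' Persist a report bundle and its intermediates
#'
#' Writes the catalog (JSON), abundance table (TSV), per-condition model
#' JSONs and community SBML, the summary table (TSV), and the venn /
#' enrichment / saturation reports (JSON) under `dir`.
#'
#' @param bundle a `report_bundle`.
#' @param dir output directory (created if needed).
#' @export
write_report_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_network_json(bundle$universal, file.path(dir, "universal_network.json"))
  write_abundance_tsv(bundle$abundance, file.path(dir, "abundance.tsv"))
  utils::write.table(report_tables(bundle), file.path(dir, "summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (g in names(bundle$groups)) {
    go <- bundle$groups[[g]]
    gd <- file.path(dir, g)
    dir.create(gd, showWarnings = FALSE)
    for (cond_name in names(go$conditions)) {
      cd <- file.path(gd, gsub("[^A-Za-z0-9_.]", "_", cond_name))
      dir.create(cd, showWarnings = FALSE)
      cond <- go$conditions[[cond_name]]
      for (m in cond$models) {
        write_model_json(m, file.path(cd, paste0(m$member_label, ".json")))
      }
      if (!is.null(cond$community)) {
        write_community_sbml(cond$community, file.path(cd, "community.sbml"))
      }
    }
    jsonlite::write_json(list(
      venn_unique = list(overlap = go$venn_unique$overlap$count,
                         only_reference = go$venn_unique$only_a$count,
                         only_mag = go$venn_unique$only_b$count),
      venn_confirmed = list(overlap = go$venn_confirmed$overlap$count,
                            only_reference = go$venn_confirmed$only_a$count,
                            only_mag = go$venn_confirmed$only_b$count),
      enrichment_compare = go$enrichment$compare,
      saturation = go$saturation,
      blocked = as.list(go$blocked %||% list()),
      gapfill = if (is.null(go$gapfill)) NULL else list(
        reference = go$gapfill$reference[c("fold_total", "fold_unique")],
        mag_normalized = go$gapfill$mag_normalized[c("fold_total", "fold_unique")])
    ), file.path(gd, "reports.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}
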