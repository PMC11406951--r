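# Readers and writers for the package's external formats: JSON dialects for
# catalogs, genomes and models; SBML Level 3 with fbc flux bounds for models;
# taxonomic-profiler-style TSV for abundance tables; TSV for metabolomics.

#' @name commgem-io
#' @title File formats
#' @description JSON round-trips preserve every field; the SBML round-trip
#'   preserves reactions, bounds and compartment tags at the document-model
#'   level. Abundance tables use the taxonomic-profiler convention: a
#'   `clade_name` column with `s__`-prefixed species and one percentage
#'   column per sample.
NULL

#' Write / read a universal network as JSON
#' @param universal a `universal_network`.
#' @param path file path.
#' @export
write_network_json <- function(universal, path) {
  obj <- list(
    compounds = universal$compounds,
    reactions = lapply(unname(universal$reactions), function(r) {
      list(id = r$id, stoich = as.list(r$stoich), reversible = r$reversible,
           spontaneous = r$spontaneous, transport = r$transport,
           compound = r$compound)
    }),
    seeds = universal$seeds,
    biomass_precursors = universal$biomass_precursors,
    modules = universal$modules,
    params = universal$params
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null", pretty = FALSE)
  invisible(path)
}

#' @rdname write_network_json
#' @export
read_network_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  reactions <- lapply(obj$reactions, function(r) {
    list(id = r$id,
         stoich = stats::setNames(as.numeric(unlist(r$stoich)), names(r$stoich)),
         reversible = isTRUE(r$reversible),
         spontaneous = isTRUE(r$spontaneous),
         transport = isTRUE(r$transport),
         compound = if (is.null(r$compound)) NA_character_ else r$compound)
  })
  names(reactions) <- vapply(reactions, `[[`, character(1), "id")
  cmp <- do.call(rbind, lapply(obj$compounds, function(x)
    data.frame(id = x$id, name = x$name,
               external_id = if (is.null(x$external_id)) NA_character_ else x$external_id,
               stringsAsFactors = FALSE)))
  structure(list(
    compounds = cmp,
    reactions = reactions,
    seeds = unlist(obj$seeds),
    biomass_precursors = unlist(obj$biomass_precursors),
    modules = list(core = unlist(obj$modules$core),
                   accessory = lapply(obj$modules$accessory, unlist),
                   extra_transports = unlist(obj$modules$extra_transports) %||% character(0)),
    params = obj$params
  ), class = "universal_network")
}

#' Write / read an organism genome as JSON
#' @param genome an `organism_genome`.
#' @param path file path.
#' @export
write_genome_json <- function(genome, path) {
  obj <- list(
    organism_id = genome$organism_id,
    ancestor_id = genome$ancestor_id,
    feature_count = genome$feature_count,
    genes = Map(function(g, r) list(gene = g, reaction = r),
                names(genome$gene_reaction_map),
                unname(genome$gene_reaction_map)),
    module_ids = genome$module_ids
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_genome_json
#' @export
read_genome_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  genes <- vapply(obj$genes, `[[`, character(1), "gene")
  rxns <- vapply(obj$genes, `[[`, character(1), "reaction")
  structure(list(
    organism_id = obj$organism_id,
    ancestor_id = obj$ancestor_id,
    gene_set = genes,
    gene_reaction_map = stats::setNames(rxns, genes),
    feature_count = obj$feature_count,
    module_ids = unlist(obj$module_ids)
  ), class = "organism_genome")
}

#' Write / read an organism model as JSON
#' @param model an `organism_model`.
#' @param path file path.
#' @export
write_model_json <- function(model, path) {
  obj <- list(
    model_id = model$model_id,
    member_label = model$member_label,
    provenance = model$provenance,
    biomass_reaction = model$biomass_reaction,
    objective = model$objective,
    biomass_precursors = model$biomass_precursors,
    reactions = lapply(unname(model$reactions), function(r) {
      list(id = r$id, lower = r$lower, upper = r$upper,
           reversible = r$reversible, transport = isTRUE(r$transport),
           stoich = r$stoich)
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  reactions <- lapply(obj$reactions, function(r) {
    st <- do.call(rbind, lapply(r$stoich, function(s)
      data.frame(compound = s$compound, compartment = s$compartment,
                 coeff = as.numeric(s$coeff), stringsAsFactors = FALSE)))
    list(id = r$id, lower = as.numeric(r$lower), upper = as.numeric(r$upper),
         reversible = isTRUE(r$reversible), transport = isTRUE(r$transport),
         stoich = st)
  })
  names(reactions) <- vapply(reactions, `[[`, character(1), "id")
  inst <- unique(do.call(rbind, lapply(reactions, function(r)
    r$stoich[, c("compound", "compartment")])))
  inst <- inst[order(inst$compound, inst$compartment), ]
  rownames(inst) <- NULL
  structure(list(
    model_id = obj$model_id,
    member_label = obj$member_label,
    provenance = obj$provenance,
    reactions = reactions,
    compounds = inst,
    biomass_reaction = obj$biomass_reaction,
    objective = obj$objective,
    biomass_precursors = unlist(obj$biomass_precursors)
  ), class = "organism_model")
}

# ---- SBML Level 3 (+ fbc flux bounds) ------------------------------------

sbml_ns_core <- "http://www.sbml.org/sbml/level3/version1/core"
sbml_ns_fbc <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

#' Write an organism model as SBML Level 3 with fbc flux bounds
#'
#' Species ids follow the `M_<compound>_<compartment>` convention and
#' reactions `R_<id>`; flux bounds are shared `fbc:lowerFluxBound` /
#' `fbc:upperFluxBound` parameters; the biomass reaction is the active
#' maximization objective.
#'
#' @param model an `organism_model`.
#' @param path file path.
#' @export
write_model_sbml <- function(model, path) {
  doc <- xml2::xml_new_root(
    "sbml", xmlns = sbml_ns_core, "xmlns:fbc" = sbml_ns_fbc,
    level = "3", version = "1", "fbc:required" = "false")
  mdl <- xml2::xml_add_child(doc, "model", id = gsub("[^A-Za-z0-9_]", "_", model$model_id),
                             "fbc:strict" = "true")

  comps <- sort(unique(model$compounds$compartment))
  lc <- xml2::xml_add_child(mdl, "listOfCompartments")
  for (cc in comps) xml2::xml_add_child(lc, "compartment", id = cc,
                                        constant = "true")

  ls <- xml2::xml_add_child(mdl, "listOfSpecies")
  for (i in seq_len(nrow(model$compounds))) {
    xml2::xml_add_child(ls, "species",
      id = sprintf("M_%s_%s", model$compounds$compound[i],
                   model$compounds$compartment[i]),
      compartment = model$compounds$compartment[i],
      hasOnlySubstanceUnits = "false", boundaryCondition = "false",
      constant = "false")
  }

  fmt <- function(x) sprintf("%.17g", x)
  bounds <- unique(unlist(lapply(model$reactions, function(r) c(r$lower, r$upper))))
  bid <- stats::setNames(sprintf("fb_%d", seq_along(bounds)), fmt(bounds))
  lp <- xml2::xml_add_child(mdl, "listOfParameters")
  for (i in seq_along(bounds)) {
    xml2::xml_add_child(lp, "parameter", id = unname(bid[i]),
                        value = fmt(bounds[i]), constant = "true")
  }

  lr <- xml2::xml_add_child(mdl, "listOfReactions")
  for (r in model$reactions) {
    rn <- xml2::xml_add_child(lr, "reaction",
      id = paste0("R_", r$id), reversible = tolower(as.character(r$reversible)),
      fast = "false",
      "fbc:lowerFluxBound" = unname(bid[fmt(r$lower)]),
      "fbc:upperFluxBound" = unname(bid[fmt(r$upper)]))
    st <- r$stoich
    reac <- st[st$coeff < 0, ]
    prod <- st[st$coeff > 0, ]
    if (nrow(reac)) {
      n1 <- xml2::xml_add_child(rn, "listOfReactants")
      for (i in seq_len(nrow(reac))) {
        xml2::xml_add_child(n1, "speciesReference",
          species = sprintf("M_%s_%s", reac$compound[i], reac$compartment[i]),
          stoichiometry = fmt(-reac$coeff[i]),
          constant = "true")
      }
    }
    if (nrow(prod)) {
      n2 <- xml2::xml_add_child(rn, "listOfProducts")
      for (i in seq_len(nrow(prod))) {
        xml2::xml_add_child(n2, "speciesReference",
          species = sprintf("M_%s_%s", prod$compound[i], prod$compartment[i]),
          stoichiometry = fmt(prod$coeff[i]),
          constant = "true")
      }
    }
  }

  lo <- xml2::xml_add_child(mdl, "fbc:listOfObjectives",
                            "fbc:activeObjective" = "obj")
  ob <- xml2::xml_add_child(lo, "fbc:objective", "fbc:id" = "obj",
                            "fbc:type" = "maximize")
  lf <- xml2::xml_add_child(ob, "fbc:listOfFluxObjectives")
  xml2::xml_add_child(lf, "fbc:fluxObjective",
                      "fbc:reaction" = paste0("R_", model$objective),
                      "fbc:coefficient" = "1")

  meta <- xml2::xml_add_child(mdl, "notes")
  body <- xml2::xml_add_child(meta, "p")
  xml2::xml_set_text(body, jsonlite::toJSON(list(
    member_label = model$member_label, provenance = model$provenance,
    biomass_reaction = model$biomass_reaction,
    biomass_precursors = model$biomass_precursors,
    transport = names(model$reactions)[vapply(model$reactions, function(r)
      isTRUE(r$transport), logical(1))]
  ), auto_unbox = TRUE))
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read an SBML Level 3 (+ fbc) organism model written by [write_model_sbml()]
#' @param path file path.
#' @return an `organism_model`.
#' @export
read_model_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- c(s = sbml_ns_core, fbc = sbml_ns_fbc)
  mdl <- xml2::xml_find_first(doc, ".//s:model", ns)

  params <- xml2::xml_find_all(mdl, ".//s:listOfParameters/s:parameter", ns)
  pval <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                          xml2::xml_attr(params, "id"))
  sp <- xml2::xml_find_all(mdl, ".//s:listOfSpecies/s:species", ns)
  sp_comp <- stats::setNames(xml2::xml_attr(sp, "compartment"),
                             xml2::xml_attr(sp, "id"))
  strip_species <- function(sid) {
    comp <- sp_comp[sid]
    cid <- sub("^M_", "", sid)
    cid <- substr(cid, 1, nchar(cid) - nchar(comp) - 1)
    list(compound = cid, compartment = unname(comp))
  }

  notes <- xml2::xml_text(xml2::xml_find_first(mdl, ".//s:notes/s:p", ns))
  meta <- jsonlite::fromJSON(notes)

  rx <- xml2::xml_find_all(mdl, ".//s:listOfReactions/s:reaction", ns)
  reactions <- lapply(rx, function(node) {
    rid <- sub("^R_", "", xml2::xml_attr(node, "id"))
    lower <- unname(pval[xml2::xml_attr(node, "lowerFluxBound")])
    upper <- unname(pval[xml2::xml_attr(node, "upperFluxBound")])
    rev <- identical(xml2::xml_attr(node, "reversible"), "true")
    get_side <- function(xp, sgn) {
      refs <- xml2::xml_find_all(node, xp, ns)
      if (!length(refs)) return(NULL)
      do.call(rbind, lapply(refs, function(ref) {
        s <- strip_species(xml2::xml_attr(ref, "species"))
        data.frame(compound = s$compound, compartment = s$compartment,
                   coeff = sgn * as.numeric(xml2::xml_attr(ref, "stoichiometry")),
                   stringsAsFactors = FALSE)
      }))
    }
    st <- rbind(get_side(".//s:listOfReactants/s:speciesReference", -1),
                get_side(".//s:listOfProducts/s:speciesReference", 1))
    list(id = rid, lower = lower, upper = upper, reversible = rev,
         transport = rid %in% meta$transport, stoich = st)
  })
  names(reactions) <- vapply(reactions, `[[`, character(1), "id")

  inst <- unique(do.call(rbind, lapply(reactions, function(r)
    r$stoich[, c("compound", "compartment")])))
  inst <- inst[order(inst$compound, inst$compartment), ]
  rownames(inst) <- NULL

  obj_node <- xml2::xml_find_first(mdl, ".//fbc:fluxObjective", ns)
  objective <- sub("^R_", "", xml2::xml_attr(obj_node, "reaction"))

  structure(list(
    model_id = xml2::xml_attr(mdl, "id"),
    member_label = meta$member_label,
    provenance = meta$provenance,
    reactions = reactions,
    compounds = inst,
    biomass_reaction = meta$biomass_reaction,
    objective = objective,
    biomass_precursors = meta$biomass_precursors
  ), class = "organism_model")
}

#' Write a community model as SBML (compartments c1..cn plus e0)
#' @param community a `community_model`.
#' @param path file path.
#' @export
write_community_sbml <- function(community, path) {
  fake <- structure(list(
    model_id = "community",
    member_label = "community",
    provenance = "reference",
    reactions = community$reactions,
    compounds = community$compounds,
    biomass_reaction = "community",
    objective = names(community$reactions)[1],
    biomass_precursors = character(0)
  ), class = "organism_model")
  write_model_sbml(fake, path)
}

# ---- TSV tables -----------------------------------------------------------

#' Write / read an abundance table as taxonomic-profiler-style TSV
#'
#' One `clade_name` column with `s__`-prefixed species ids, one percentage
#' column per sample. Group membership is encoded in a `# group:` header
#' comment line so the file round-trips.
#'
#' @param table an `abundance_table`.
#' @param path file path.
#' @export
write_abundance_tsv <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (g in names(table$groups)) {
    writeLines(sprintf("# group:%s\t%s", g,
                       paste(table$groups[[g]], collapse = "\t")), con)
  }
  df <- data.frame(clade_name = paste0("s__", table$species),
                   table$abundance, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_abundance_tsv
#' @export
read_abundance_tsv <- function(path) {
  lines <- readLines(path)
  ghead <- grep("^# group:", lines, value = TRUE)
  groups <- list()
  for (h in ghead) {
    parts <- strsplit(sub("^# group:", "", h), "\t")[[1]]
    groups[[parts[1]]] <- parts[-1]
  }
  df <- utils::read.table(text = lines[!grepl("^#", lines)], sep = "\t",
                          header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  species <- sub("^s__", "", df$clade_name)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- species
  if (!length(groups)) groups <- list(group1 = colnames(m))
  structure(list(species = species, groups = groups, abundance = m),
            class = "abundance_table")
}

#' Write / read a metabolomics table as TSV
#'
#' Columns: name, external_id, replicate_ids (";"-separated), then one
#' abundance column per sample (empty cells are missing values).
#'
#' @param metabolomics a `metabolomics_table`.
#' @param path file path.
#' @export
write_metabolomics_tsv <- function(metabolomics, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (g in names(metabolomics$groups)) {
    writeLines(sprintf("# group:%s\t%s", g,
                       paste(metabolomics$groups[[g]], collapse = "\t")), con)
  }
  df <- cbind(metabolomics$rows, as.data.frame(metabolomics$abundance))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' @rdname write_metabolomics_tsv
#' @export
read_metabolomics_tsv <- function(path) {
  lines <- readLines(path)
  ghead <- grep("^# group:", lines, value = TRUE)
  groups <- list()
  for (h in ghead) {
    parts <- strsplit(sub("^# group:", "", h), "\t")[[1]]
    groups[[parts[1]]] <- parts[-1]
  }
  df <- utils::read.table(text = lines[!grepl("^#", lines)], sep = "\t",
                          header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE, na.strings = "")
  rows <- df[, c("name", "external_id", "replicate_ids")]
  ab <- as.matrix(df[, setdiff(colnames(df), colnames(rows)), drop = FALSE])
  if (!length(groups)) groups <- list(group1 = colnames(ab))
  structure(list(rows = rows, abundance = ab, groups = groups),
            class = "metabolomics_table")
}
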