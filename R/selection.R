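# Input-selection strategies: reference-guided (mean relative-abundance
# cutoffs on a taxonomic profile) and MAG-guided (quality tiers, dereplication
# at an identity threshold, optional normalization of the input-taxon count).

#' Mean relative abundance per species within a sample group
#'
#' Arithmetic mean over all samples of the group. Species absent from a sample
#' (abundance matrices store them explicitly as 0) contribute zeros: a species
#' at 10% in one of two samples has a mean of 5%.
#'
#' @param table an `abundance_table`.
#' @param group group label.
#' @return named numeric vector, species -> mean percentage.
#' @export
mean_relative_abundance <- function(table, group) {
  cg_assert(inherits(table, "abundance_table"), "abundance_table required")
  if (!group %in% names(table$groups)) {
    cg_stop(sprintf("unknown group '%s'", group), class = "unknown_group")
  }
  cols <- table$groups[[group]]
  cg_assert(length(cols) >= 1, "group has no samples")
  rowMeans(table$abundance[, cols, drop = FALSE])
}

new_selection_result <- function(approach, parameters, taxa_detected,
                                 taxa_used = taxa_detected,
                                 exclusions = NULL) {
  if (is.null(exclusions)) {
    exclusions <- data.frame(taxon = character(0), reason = character(0),
                             stringsAsFactors = FALSE)
  }
  cg_assert(all(taxa_used %in% taxa_detected), "taxa_used must be within taxa_detected")
  cg_assert(all(nzchar(exclusions$reason)), "exclusion reasons must be non-empty")
  structure(list(approach = approach, parameters = parameters,
                 taxa_detected = taxa_detected, taxa_used = taxa_used,
                 exclusions = exclusions),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("selection_result [%s]: %d detected, %d used (%d excluded)\n",
              x$approach, length(x$taxa_detected), length(x$taxa_used),
              nrow(x$exclusions)))
  invisible(x)
}

#' Select species by a mean relative-abundance cutoff
#'
#' Inclusive threshold (mean >= cutoff); ordering is by descending mean, then
#' species id, so selections at decreasing cutoffs are nested prefixes.
#'
#' @param means named numeric, species -> mean percentage.
#' @param cutoff percentage cutoff (> 0).
#' @return a `selection_result` (approach "reference").
#' @export
select_by_cutoff <- function(means, cutoff) {
  cg_assert(cutoff > 0, "cutoff must be > 0")
  keep <- means[means >= cutoff]
  ord <- order(-keep, names(keep))
  new_selection_result("reference", list(cutoff = cutoff),
                       taxa_detected = names(keep)[ord])
}

#' Exclude taxa from a selection with a recorded reason
#'
#' Used when a detected taxon cannot be used (e.g. no reference genome is
#' available), feeding the "detected (used)" bracketed reporting convention.
#'
#' @param selection a `selection_result`.
#' @param taxa taxa to drop from `taxa_used`.
#' @param reason non-empty reason string.
#' @return the updated `selection_result`.
#' @export
exclude_taxa <- function(selection, taxa, reason) {
  cg_assert(inherits(selection, "selection_result"), "selection_result required")
  cg_assert(is.character(reason) && nzchar(reason), "reason must be non-empty")
  taxa <- intersect(taxa, selection$taxa_used)
  if (!length(taxa)) return(selection)
  selection$taxa_used <- setdiff(selection$taxa_used, taxa)
  selection$exclusions <- rbind(
    selection$exclusions,
    data.frame(taxon = taxa, reason = reason, stringsAsFactors = FALSE)
  )
  selection
}

#' Classify MAG quality from completeness and contamination
#'
#' High quality: completeness > 90 (strict) and contamination < 5.
#' Medium quality: completeness >= 50 and contamination < 10 (and not high).
#' Everything else fails. The three tiers partition `[0,100]^2`.
#'
#' @param completeness,contamination percentages in `[0, 100]`; vectorized.
#' @return character vector in `c("high", "medium", "fail")`.
#' @export
classify_mag_quality <- function(completeness, contamination) {
  cg_assert(length(completeness) == length(contamination),
            "inputs must have equal length")
  cg_assert(all(completeness >= 0 & completeness <= 100) &&
            all(contamination >= 0 & contamination <= 100),
            "percentages must be in [0, 100]")
  high <- completeness > 90 & contamination < 5
  medium <- !high & completeness >= 50 & contamination < 10
  ifelse(high, "high", ifelse(medium, "medium", "fail"))
}

# pairwise Jaccard similarity of two gene sets
gene_jaccard <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0) return(1)
  length(intersect(a, b)) / u
}

#' Dereplicate MAGs at an identity threshold
#'
#' Collapses near-identical MAGs to one representative per cluster, the
#' highest-completeness member (ties: lexicographically smallest mag id).
#' The identity proxy is declared ancestry in synthetic mode (`"ancestry"`,
#' the default: MAGs cluster when their genomes share `ancestor_id`) or
#' gene-set Jaccard similarity with single-linkage clustering (`"jaccard"`)
#' for externally supplied genomes. Average nucleotide identity itself is
#' deliberately not computed.
#'
#' @param mags list of `mag_record`s.
#' @param identity_threshold proportion in (0, 1]; used by the Jaccard proxy.
#' @param method `"ancestry"` or `"jaccard"`.
#' @return list of representative `mag_record`s (input order of survivors).
#' @export
dereplicate_mags <- function(mags, identity_threshold = 0.99,
                             method = c("ancestry", "jaccard")) {
  method <- match.arg(method)
  cg_assert(identity_threshold > 0 && identity_threshold <= 1,
            "identity_threshold must be in (0, 1]")
  if (!length(mags)) return(mags)
  n <- length(mags)
  if (method == "ancestry") {
    key <- vapply(mags, function(m) m$genome$ancestor_id, character(1))
    cluster <- match(key, unique(key))
  } else {
    # single-linkage over pairwise Jaccard >= threshold (union-find)
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (gene_jaccard(mags[[i]]$genome$gene_set,
                       mags[[j]]$genome$gene_set) >= identity_threshold) {
        parent[find(j)] <- find(i)
      }
    }
    cluster <- vapply(seq_len(n), find, integer(1))
  }
  comp <- vapply(mags, `[[`, numeric(1), "completeness")
  ids <- vapply(mags, `[[`, character(1), "mag_id")
  keep <- logical(n)
  for (cl in unique(cluster)) {
    members <- which(cluster == cl)
    best <- members[order(-comp[members], ids[members])][1]
    keep[best] <- TRUE
  }
  mags[keep]
}

#' Keep the n most complete high-quality MAGs
#'
#' Normalizes the MAG-guided input-taxon count to a reference-guided count:
#' filters to the high tier, sorts by completeness descending (ties:
#' contamination ascending, then mag id) and takes the first `n`. If fewer
#' than `n` high-quality MAGs exist, all are returned with attribute
#' `shortfall` set to the deficit.
#'
#' @param mags list of `mag_record`s.
#' @param n target count (>= 1).
#' @return list of `mag_record`s, possibly with attribute `shortfall`.
#' @export
normalize_mag_count <- function(mags, n) {
  cg_assert(is.numeric(n) && length(n) == 1 && n >= 1, "n must be >= 1")
  tier <- vapply(mags, function(m)
    classify_mag_quality(m$completeness, m$contamination), character(1))
  high <- mags[tier == "high"]
  comp <- vapply(high, `[[`, numeric(1), "completeness")
  cont <- vapply(high, `[[`, numeric(1), "contamination")
  ids <- vapply(high, `[[`, character(1), "mag_id")
  high <- high[order(-comp, cont, ids)]
  if (length(high) < n) {
    out <- high
    attr(out, "shortfall") <- n - length(high)
    return(out)
  }
  high[seq_len(n)]
}
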