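# Validation of predicted metabolite sets against untargeted metabolomics
# (presence/absence conversion, identifier bookkeeping, Venn complementarity)
# and pathway over-representation analysis (cumulative hypergeometric tail
# with Benjamini-Hochberg false-discovery-rate correction).

#' Convert a metabolomics table to a presence id set for one group
#'
#' A metabolite is present when it has a non-missing, positive abundance in
#' at least one sample of the group. The returned set contains the primary
#' external ids of present metabolites plus their replicate ids (a replicate
#' id is a second identifier for the same metabolite and confirms it equally).
#'
#' @param metabolomics a `metabolomics_table`.
#' @param group group label.
#' @return character vector of external ids.
#' @export
to_presence <- function(metabolomics, group) {
  cg_assert(inherits(metabolomics, "metabolomics_table"),
            "metabolomics_table required")
  if (!group %in% names(metabolomics$groups)) {
    cg_stop(sprintf("unknown group '%s'", group), class = "unknown_group")
  }
  cols <- metabolomics$groups[[group]]
  cg_assert(length(cols) >= 1, "group has no samples")
  ab <- metabolomics$abundance[, cols, drop = FALSE]
  present <- apply(ab, 1, function(x) any(!is.na(x) & x > 0))
  rows <- metabolomics$rows[present, , drop = FALSE]
  ids <- c(rows$external_id,
           unlist(strsplit(rows$replicate_ids[!is.na(rows$replicate_ids)], ";")))
  sort(unique(ids[!is.na(ids)]))
}

#' Construct a validation report from its bookkeeping fields
#'
#' The report's arithmetic identities are:
#' `data_loss_pct = 100 (unique - mappable) / unique` and
#' `confirmed_pct = 100 confirmed / mappable`, both reported to 2 decimals.
#' Either `mappable_count` or `data_loss_pct` may be supplied; giving the
#' loss percentage reconstructs the (possibly fractional) mappable count as
#' `unique * (1 - data_loss_pct / 100)`, which is how printed summary tables
#' are audited from their integer rows.
#'
#' @param unique_count number of distinct predicted metabolites.
#' @param confirmed_count metabolites confirmed by metabolomics.
#' @param mappable_count metabolites carrying an external id (optional).
#' @param data_loss_pct percentage lacking an external id (optional).
#' @param confirmed_ids,venn optional id bookkeeping carried along.
#' @return an object of class `validation_report`.
#' @export
validation_report <- function(unique_count, confirmed_count,
                              mappable_count = NULL, data_loss_pct = NULL,
                              confirmed_ids = NULL, venn = NULL) {
  cg_assert(unique_count >= 0 && confirmed_count >= 0, "counts must be >= 0")
  cg_assert(!is.null(mappable_count) || !is.null(data_loss_pct),
            "supply mappable_count or data_loss_pct")
  if (is.null(mappable_count)) {
    cg_assert(data_loss_pct >= 0 && data_loss_pct <= 100,
              "data_loss_pct must be in [0, 100]")
    mappable_count <- unique_count * (1 - data_loss_pct / 100)
  }
  cg_assert(confirmed_count <= mappable_count + 1e-9 &&
            mappable_count <= unique_count + 1e-9,
            "need confirmed <= mappable <= unique")
  dl <- if (unique_count > 0) 100 * (unique_count - mappable_count) / unique_count else 0
  cp <- if (mappable_count > 0) 100 * confirmed_count / mappable_count else 0
  structure(list(
    unique_count = unique_count,
    mappable_count = mappable_count,
    confirmed_count = confirmed_count,
    data_loss_pct = round_half_up(dl, 2),
    confirmed_pct = round_half_up(cp, 2),
    confirmed_ids = confirmed_ids,
    venn = venn
  ), class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("validation_report: unique %s | mappable %s | confirmed %d | data loss %.2f%% | confirmed %.2f%%\n",
              format(x$unique_count), format(round(x$mappable_count, 2)),
              x$confirmed_count, x$data_loss_pct, x$confirmed_pct))
  invisible(x)
}

#' Match predicted unique metabolites against a metabolomics presence set
#'
#' Mappable metabolites are the predicted unique compounds with a non-missing
#' external id; confirmed metabolites are mappable ones whose id occurs in
#' the presence set. Distinct compounds sharing one external id are counted
#' once by id (with a warning), since id equality is all the metabolomics
#' side can resolve.
#'
#' @param unique_ids character vector of predicted unique compound ids.
#' @param id_map named character vector, compound id -> external id (NA for
#'   compounds without one); e.g. built from a universal network.
#' @param presence character vector of externally measured ids
#'   (see [to_presence()]).
#' @return a `validation_report` with `confirmed_ids` attached.
#' @export
match_predictions <- function(unique_ids, id_map, presence) {
  unique_ids <- unique(unique_ids)
  ext <- id_map[unique_ids]
  ext <- ext[!is.na(ext)]
  if (anyDuplicated(ext)) {
    warning("duplicate external ids map to distinct compounds; counting once by id")
  }
  ids <- unique(unname(ext))
  confirmed <- intersect(ids, presence)
  validation_report(
    unique_count = length(unique_ids),
    confirmed_count = length(confirmed),
    mappable_count = length(ids),
    confirmed_ids = sort(confirmed)
  )
}

#' Compound id -> external id map of a universal network
#' @param universal a `universal_network`.
#' @return named character vector (NA where no external id was assigned).
#' @export
external_id_map <- function(universal) {
  stats::setNames(universal$compounds$external_id, universal$compounds$id)
}

#' Two-set Venn partition
#' @param a,b character id sets.
#' @return object of class `venn_partition` with `overlap`, `only_a`,
#'   `only_b` (each a list of `count` and `ids`).
#' @export
venn <- function(a, b) {
  a <- unique(a); b <- unique(b)
  part <- list(
    overlap = sort(intersect(a, b)),
    only_a = sort(setdiff(a, b)),
    only_b = sort(setdiff(b, a))
  )
  structure(list(
    overlap = list(count = length(part$overlap), ids = part$overlap),
    only_a = list(count = length(part$only_a), ids = part$only_a),
    only_b = list(count = length(part$only_b), ids = part$only_b)
  ), class = "venn_partition")
}

#' @export
print.venn_partition <- function(x, ...) {
  cat(sprintf("venn_partition: overlap %d | only A %d | only B %d\n",
              x$overlap$count, x$only_a$count, x$only_b$count))
  invisible(x)
}

#' Merge two predicted metabolite lists, removing duplicates
#' @param a,b character id sets.
#' @return sorted union.
#' @export
combine_lists <- function(a, b) sort(union(a, b))

#' Over-representation p-values by the cumulative hypergeometric tail
#'
#' For each pathway, with `N` the background size, `K` the pathway's
#' annotated members within the background, `n` the mapped test-set size and
#' `k` the test-set hits, computes the upper tail `P(X >= k)` of the
#' hypergeometric distribution. Test ids outside the background are excluded
#' from `n` and reported in the `unmapped` attribute.
#'
#' @param test character id set to test.
#' @param background character background id set (non-empty).
#' @param pathways named list, pathway id -> character id set.
#' @return data.frame (pathway, k, K, n, N, p) with attribute `unmapped`.
#' @export
hypergeom_ora <- function(test, background, pathways) {
  background <- unique(background)
  if (!length(background)) cg_stop("empty background", class = "precondition")
  test <- unique(test)
  unmapped <- setdiff(test, background)
  test <- intersect(test, background)
  N <- length(background)
  n <- length(test)
  out <- do.call(rbind, lapply(names(pathways), function(pw) {
    K <- length(intersect(pathways[[pw]], background))
    k <- length(intersect(test, intersect(pathways[[pw]], background)))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(pathway = pw, k = k, K = K, n = n, N = N, p = p,
               stringsAsFactors = FALSE)
  }))
  if (is.null(out)) {
    out <- data.frame(pathway = character(0), k = integer(0), K = integer(0),
                      n = integer(0), N = integer(0), p = numeric(0))
  }
  attr(out, "unmapped") <- sort(unmapped)
  out
}

#' Benjamini-Hochberg step-up q-values
#'
#' Sorts the p-values ascending, computes `q_(i) = min_{j >= i} p_(j) m / j`
#' capped at 1, and maps the result back to the input order.
#'
#' @param pvalues numeric vector with all values in (0, 1].
#' @return numeric vector of q-values in input order.
#' @export
bh_correct <- function(pvalues) {
  cg_assert(all(pvalues > 0 & pvalues <= 1), "p-values must be in (0, 1]")
  m <- length(pvalues)
  if (m == 0) return(numeric(0))
  ord <- order(pvalues)
  p_sorted <- pvalues[ord]
  q_sorted <- p_sorted * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q_sorted <- pmin(q_sorted, 1)
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

#' Pathway enrichment: ORA p-values, BH q-values and a significance call
#'
#' @param test,background,pathways as in [hypergeom_ora()].
#' @param q_threshold significance threshold; strictly `q < q_threshold`.
#' @param label source label carried in the result.
#' @return object of class `enrichment_result`: `table` (pathway, k, K, n, N,
#'   p, q, significant), `significant` (pathway ids), `q_threshold`, `label`.
#' @export
enrichment <- function(test, background, pathways, q_threshold = 0.05,
                       label = "test") {
  tab <- hypergeom_ora(test, background, pathways)
  tab$q <- if (nrow(tab)) bh_correct(tab$p) else numeric(0)
  tab$significant <- tab$q < q_threshold
  structure(list(
    table = tab,
    significant = sort(tab$pathway[tab$significant]),
    q_threshold = q_threshold,
    label = label,
    unmapped = attr(tab, "unmapped")
  ), class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("enrichment_result [%s]: %d pathways tested, %d significant (q < %g)\n",
              x$label, nrow(x$table), length(x$significant), x$q_threshold))
  invisible(x)
}

#' Compare two enrichment results at a q threshold
#'
#' Set comparison of the significant pathway sets (strictly `q < threshold`;
#' a pathway at exactly the threshold is not significant).
#'
#' @param results_a,results_b `enrichment_result`s over the same pathway
#'   universe.
#' @param q_threshold threshold (default 0.05).
#' @return list with `shared`, `only_a`, `only_b` pathway id vectors.
#' @export
compare_enrichment <- function(results_a, results_b, q_threshold = 0.05) {
  cg_assert(setequal(results_a$table$pathway, results_b$table$pathway),
            "pathway universes differ")
  sig <- function(r) r$table$pathway[r$table$q < q_threshold]
  a <- sig(results_a); b <- sig(results_b)
  list(shared = sort(intersect(a, b)),
       only_a = sort(setdiff(a, b)),
       only_b = sort(setdiff(b, a)))
}

#' Synthetic pathway annotations from a universal network
#'
#' Uses the catalog's accessory modules as pathway-like compound sets: each
#' pathway is the external-id-mappable compound set touched by one module's
#' reactions. Stands in for real pathway databases in synthetic mode.
#'
#' @param universal a `universal_network`.
#' @return named list, pathway id -> external id set.
#' @export
module_pathways <- function(universal) {
  idmap <- external_id_map(universal)
  mods <- universal$modules$accessory
  out <- lapply(seq_along(mods), function(i) {
    cids <- unique(unlist(lapply(universal$reactions[mods[[i]]],
                                 function(r) names(r$stoich))))
    ids <- idmap[cids]
    sort(unique(ids[!is.na(ids)]))
  })
  names(out) <- sprintf("PWY%03d", seq_along(mods))
  out[vapply(out, length, integer(1)) > 0]
}
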