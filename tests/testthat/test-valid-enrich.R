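# Metabolomics validation bookkeeping, Venn partitions, over-representation
# analysis and Benjamini-Hochberg correction.

make_metab <- function(primary_ids, replicate_ids = rep(NA_character_,
                                                        length(primary_ids)),
                       abundance = NULL, group = "g1") {
  n <- length(primary_ids)
  if (is.null(abundance)) {
    abundance <- matrix(1, nrow = n, ncol = 2,
                        dimnames = list(NULL, c("g1_m01", "g1_m02")))
  }
  structure(list(
    rows = data.frame(name = paste0("met", seq_len(n)),
                      external_id = primary_ids,
                      replicate_ids = replicate_ids, stringsAsFactors = FALSE),
    abundance = abundance,
    groups = stats::setNames(list(colnames(abundance)), group)
  ), class = "metabolomics_table")
}

test_that("to_presence applies the >=1-sample rule and includes replicates", {
  ab <- matrix(c(5, NA, NA, NA, NA, NA, 0, 3), nrow = 4,
               dimnames = list(NULL, c("g1_m01", "g1_m02")))
  tab <- make_metab(c("C00001", "C00002", "C00003", "C00004"),
                    c(NA, NA, NA, "C00099"), abundance = ab)
  pres <- to_presence(tab, "g1")
  # row 1 measured once -> present; row 2 all-missing -> absent;
  # row 3 zero then missing -> absent; row 4 present, brings its replicate
  expect_setequal(pres, c("C00001", "C00004", "C00099"))
  expect_error(to_presence(tab, "nope"), class = "commgem_unknown_group")
})

test_that("presence counts reproduce the replicate-id bookkeeping", {
  # 489 primary ids plus 34 replicate ids -> 523 ids searched
  primary <- sprintf("C%05d", 1:489)
  reps <- c(sprintf("C%05d", 90001:90034), rep(NA, 489 - 34))
  tab <- make_metab(primary, reps)
  expect_length(to_presence(tab, "g1"), 523)
})

test_that("validation_report arithmetic is closed and matches the examples", {
  vr <- match_predictions(
    unique_ids = paste0("cpd", 1:10),
    id_map = stats::setNames(c(sprintf("C%05d", 1:7), rep(NA, 3)),
                             paste0("cpd", 1:10)),
    presence = sprintf("C%05d", c(1, 2, 3, 4, 90)))
  expect_equal(vr$unique_count, 10)
  expect_equal(vr$mappable_count, 7)
  expect_equal(vr$confirmed_count, 4)
  expect_equal(vr$data_loss_pct, 30.00)
  expect_equal(vr$confirmed_pct, 57.14)

  # closure: recomputing the percentages from the integer fields
  expect_equal(vr$data_loss_pct,
               round(100 * (vr$unique_count - vr$mappable_count) /
                     vr$unique_count, 2))
  expect_equal(vr$confirmed_pct,
               round(100 * vr$confirmed_count / vr$mappable_count, 2))

  # duplicate external ids: counted once, with a warning
  expect_warning(
    vr2 <- match_predictions(c("a", "b"),
                             stats::setNames(c("C1", "C1"), c("a", "b")),
                             "C1"))
  expect_equal(vr2$mappable_count, 1)
  expect_equal(vr2$confirmed_count, 1)

  expect_error(validation_report(10, 5), class = "commgem_precondition")
  expect_error(validation_report(10, 9, mappable_count = 8),
               class = "commgem_precondition")
})

test_that("venn partitions obey the count identities", {
  ids <- function(n, prefix) sprintf("%s%05d", prefix, seq_len(n))
  same <- venn(ids(10, "x"), ids(10, "x"))
  expect_equal(same$only_a$count, 0)
  expect_equal(same$only_b$count, 0)
  expect_equal(same$overlap$count, 10)

  # |A| = 1500, |B| = 1543, overlap 1475
  ov <- ids(1475, "o")
  a <- c(ov, ids(25, "a"))
  b <- c(ov, ids(68, "b"))
  vp <- venn(a, b)
  expect_equal(vp$overlap$count, 1475)
  expect_equal(vp$only_a$count, 25)
  expect_equal(vp$only_b$count, 68)
  expect_equal(vp$overlap$count + vp$only_a$count, length(unique(a)))
  expect_equal(vp$overlap$count + vp$only_b$count, length(unique(b)))
  expect_length(intersect(vp$only_a$ids, vp$only_b$ids), 0)

  # combined list size by inclusion-exclusion: 1500 + 1543 - 1475 = 1568
  expect_length(combine_lists(a, b), 1568)
  expect_equal(combine_lists(ids(3, "p"), ids(4, "q")),
               sort(c(ids(3, "p"), ids(4, "q"))))
  expect_equal(combine_lists(ids(3, "p"), c(ids(3, "p"), "z")),
               sort(c(ids(3, "p"), "z")))
})

test_that("hypergeometric tail matches direct enumeration", {
  bg <- sprintf("b%02d", 1:20)
  pw <- list(P1 = bg[1:5])
  test <- c(bg[1:4], bg[10])  # k = 4 of K = 5, n = 5, N = 20
  res <- hypergeom_ora(test, bg, pw)
  expect_equal(res$k, 4)
  expect_equal(res$p, 76 / 15504, tolerance = 1e-12)
  expect_equal(res$p, enum_hyper_tail(4, 5, 20, 5), tolerance = 1e-12)

  # k = 0 -> p = 1 exactly; test = background -> k = K and p = 1
  expect_equal(hypergeom_ora(bg[6:10], bg, list(P = bg[1:3]))$p, 1)
  full <- hypergeom_ora(bg, bg, pw)
  expect_equal(full$k, full$K)
  expect_equal(full$p, 1)

  # unmapped test ids are excluded from n and reported
  res2 <- hypergeom_ora(c(test, "zz"), bg, pw)
  expect_equal(res2$n, 5)
  expect_equal(attr(res2, "unmapped"), "zz")

  expect_error(hypergeom_ora(test, character(0), pw),
               class = "commgem_precondition")
})

test_that("ORA equals the exact combinatorial oracle for all N <= 12", {
  for (N in c(6, 9, 12)) {
    bg <- sprintf("c%02d", seq_len(N))
    for (K in c(2, floor(N / 2))) {
      for (n in c(2, floor(N / 2), N)) {
        for (k in 0:min(K, n)) {
          if (k < max(0, n - (N - K))) next
          test <- c(bg[seq_len(k)], bg[K + seq_len(n - k)])
          if (n - k > N - K) next
          p <- hypergeom_ora(test, bg, list(P = bg[seq_len(K)]))$p
          expect_equal(p, enum_hyper_tail(k, K, N, n), tolerance = 1e-12,
                       info = sprintf("N=%d K=%d n=%d k=%d", N, K, n, k))
        }
      }
    }
  }
})

test_that("bh_correct is the step-up procedure", {
  expect_equal(bh_correct(0.03), 0.03)
  expect_equal(bh_correct(c(0.001, 0.02, 0.04)), c(0.003, 0.03, 0.04))
  expect_equal(bh_correct(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_correct(c(0.1, 0)), class = "commgem_precondition")
  expect_error(bh_correct(c(0.1, 1.2)), class = "commgem_precondition")

  set.seed(12)
  for (i in 1:10) {
    p <- runif(sample(3:40, 1))
    q <- bh_correct(p)
    expect_equal(q, p.adjust(p, "BH"))  # independent route
    # sorted-q monotone along sorted p
    expect_true(all(diff(q[order(p)]) >= -1e-12))
    # BH never declares more than raw thresholding at the same alpha
    for (alpha in c(0.01, 0.05, 0.1)) {
      expect_lte(sum(q < alpha), sum(p < alpha))
    }
  }
})

test_that("compare_enrichment uses a strict threshold and set logic", {
  fake <- function(q, label) {
    structure(list(
      table = data.frame(pathway = names(q), k = 1, K = 2, n = 3, N = 10,
                         p = unname(q), q = unname(q),
                         significant = unname(q) < 0.05),
      significant = names(q)[q < 0.05], q_threshold = 0.05, label = label
    ), class = "enrichment_result")
  }
  a <- fake(c(P1 = 0.01, P2 = 0.05, P3 = 0.2), "a")
  b <- fake(c(P1 = 0.01, P2 = 0.002, P3 = 0.9), "b")
  cmp <- compare_enrichment(a, b)
  expect_equal(cmp$shared, "P1")
  expect_equal(cmp$only_b, "P2")  # q exactly 0.05 in a is NOT significant
  expect_length(cmp$only_a, 0)
  expect_equal(compare_enrichment(a, a)$only_a, character(0))
})

test_that("a planted differential pathway is recovered (Monte-Carlo power)", {
  N <- 200
  bg <- sprintf("m%04d", seq_len(N))
  pathways <- split(bg, rep(1:10, each = 20))
  names(pathways) <- sprintf("PW%02d", 1:10)
  hits <- 0
  for (seed in 1:20) {
    set.seed(seed)
    base <- sample(bg, 40)
    # approach A additionally predicts the whole planted pathway PW01
    test_a <- union(base, pathways$PW01)
    test_b <- base
    ea <- enrichment(test_a, bg, pathways, label = "a")
    eb <- enrichment(test_b, bg, pathways, label = "b")
    cmp <- compare_enrichment(ea, eb)
    if ("PW01" %in% cmp$only_a && !"PW01" %in% cmp$only_b) hits <- hits + 1
  }
  expect_gte(hits / 20, 0.9)
})

test_that("combining lists can change enrichment conclusions (regression)", {
  # the planted pathway is split between the two approaches; only the
  # union pushes it over the threshold
  # each list hits 7 of the 16 pathway members (p ~ 0.065, not significant);
  # the union hits 13 with n = 59 (p ~ 0.007, significant after BH)
  N <- 120
  bg <- sprintf("u%04d", seq_len(N))
  pw <- list(SPLIT = bg[1:16], OTHER = bg[17:32])
  noise <- bg[33:120]
  a <- c(bg[1:7], noise[1:23])
  b <- c(bg[7:13], noise[24:46])
  ea <- enrichment(a, bg, pw, label = "a")
  eb <- enrichment(b, bg, pw, label = "b")
  eu <- enrichment(combine_lists(a, b), bg, pw, label = "union")
  expect_false("SPLIT" %in% ea$significant)
  expect_false("SPLIT" %in% eb$significant)
  expect_true("SPLIT" %in% eu$significant)
})
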