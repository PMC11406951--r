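# Compartmentalized merging, census metrics and saturation curves.

toy_model <- function(label, compounds) {
  # minimal organism_model whose compound set is given directly; one internal
  # reaction per compound pair keeps the invariant compounds == referenced
  st <- data.frame(compound = compounds, compartment = "c",
                   coeff = c(-1, rep(1, length(compounds) - 1)),
                   stringsAsFactors = FALSE)
  structure(list(
    model_id = paste0("model_", label), member_label = label,
    provenance = "reference",
    reactions = list(r1 = list(id = "r1", lower = 0, upper = 1000,
                               reversible = FALSE, transport = FALSE,
                               stoich = st),
                     bio1 = list(id = "bio1", lower = 0, upper = 1000,
                                 reversible = FALSE, transport = FALSE,
                                 stoich = st[1, ])),
    compounds = data.frame(compound = compounds, compartment = "c",
                           stringsAsFactors = FALSE),
    biomass_reaction = "bio1", objective = "bio1",
    biomass_precursors = compounds[1]
  ), class = "organism_model")
}

test_that("merge relabels compartments and preserves member reactions", {
  cf <- crossfeed_models()
  comm <- merge_models(list(cf$A, cf$B))
  expect_equal(unname(comm$member_compartments), c("c1", "c2"))
  # member reaction counts preserved (exchanges excluded)
  n_member_rxns <- sum(!grepl("^EX_", names(comm$reactions)))
  expect_equal(n_member_rxns, length(cf$A$reactions) + length(cf$B$reactions))
  # everything transported appears in e0
  expect_true("y" %in% comm$compounds$compound[comm$compounds$compartment == "e0"])
  # e0 compounds were referenced by >= 1 member transport reaction
  e0 <- comm$compounds$compound[comm$compounds$compartment == "e0"]
  transported <- unique(unlist(lapply(list(cf$A, cf$B), function(m)
    vapply(Filter(function(r) isTRUE(r$transport), m$reactions),
           function(r) r$stoich$compound[1], ""))))
  expect_true(all(e0 %in% transported))

  expect_error(merge_models(list(cf$A, cf$A)),
               class = "commgem_duplicate_member")
})

test_that("cross-fed compound supports a coupled flux solution (LP oracle)", {
  cf <- crossfeed_models()
  # B alone on the seed medium cannot grow: y is unavailable
  alone <- fba(flux_problem(cf$B, medium = default_medium(cf$universal)))
  expect_equal(alone$objective, 0)
  # in the community, B's biomass can carry flux using A's exported y
  comm <- merge_models(list(cf$A, cf$B))
  fp <- flux_problem(comm, medium = default_medium(cf$universal),
                     objective = "B:bio1")
  coupled <- fba(fp)
  expect_equal(coupled$status, "optimal")
  expect_gt(coupled$objective, 1e-6)
})

test_that("merge order does not change the unique metabolite set", {
  cf <- crossfeed_models()
  ab <- unique_metabolite_set(merge_models(list(cf$A, cf$B)))
  ba <- unique_metabolite_set(merge_models(list(cf$B, cf$A)))
  expect_identical(ab, ba)
})

test_that("census arithmetic: totals, uniques, extracellular", {
  m1 <- toy_model("A", c("x", "y"))
  m2 <- toy_model("B", c("y", "z"))
  cn <- census(merge_models(list(m1, m2)))
  expect_equal(cn$total_predicted, 4)
  expect_equal(cn$unique_metabolites, 3)
  expect_equal(cn$taxa, 2)
  expect_equal(cn$total_extracellular, 0)  # no transporters in these toys
  expect_equal(sum(cn$per_member_counts), cn$total_predicted)

  # m identical members with c compounds: total m*c, unique c
  ms <- lapply(1:4, function(k) toy_model(paste0("t", k), c("u", "v", "w")))
  cn2 <- census(merge_models(ms))
  expect_equal(cn2$total_predicted, 12)
  expect_equal(cn2$unique_metabolites, 3)

  # single model: unique equals the model's own dedup count
  cn1 <- census(merge_models(list(m1)))
  expect_equal(cn1$unique_metabolites, length(unique(m1$compounds$compound)))
  expect_equal(cn1$taxa, 1)
})

test_that("census totals equal the independent per-member summation oracle", {
  net <- generate_universal_network(120, 240, 0.2, seed = 21)
  models <- lapply(1:8, function(k)
    build_draft_model(sample_organism_genome(net, 2, seed = 100 + k,
                                             organism_id = sprintf("o%02d", k)),
                      net))
  comm <- merge_models(models)
  cn <- census(comm)
  oracle_total <- sum(vapply(models, function(m) nrow(m$compounds), 1L))
  expect_equal(cn$total_predicted, oracle_total)
  oracle_unique <- length(unique(unlist(lapply(models, model_compound_ids))))
  expect_equal(cn$unique_metabolites, oracle_unique)
  expect_lte(cn$unique_metabolites, cn$total_predicted)
  expect_lte(cn$total_extracellular, cn$total_predicted)

  # global shared counting collapses e0 duplicates to one per compound
  cng <- census(comm, shared_counting = "global")
  n_e_instances <- sum(vapply(models, function(m)
    sum(m$compounds$compartment == "e"), 1L))
  expect_equal(cng$total_predicted,
               oracle_total - n_e_instances + cn$total_extracellular)
})

test_that("census is additive over member partition (set identity)", {
  net <- generate_universal_network(100, 200, 0.2, seed = 31)
  models <- lapply(1:6, function(k)
    build_draft_model(sample_organism_genome(net, 2, seed = 40 + k,
                                             organism_id = sprintf("p%02d", k)),
                      net))
  u_all <- unique_metabolite_set(merge_models(models))
  u1 <- unique_metabolite_set(merge_models(models[1:3]))
  u2 <- unique_metabolite_set(merge_models(models[4:6]))
  expect_identical(u_all, sort(union(u1, u2)))
  # adding a member never decreases the unique count
  for (k in 2:6) {
    expect_gte(length(unique_metabolite_set(merge_models(models[1:k]))),
               length(unique_metabolite_set(merge_models(models[1:(k - 1)]))))
  }
})

test_that("saturation curves: flat, linear, and concave on average", {
  ident <- lapply(1:5, function(k) toy_model(paste0("i", k), c("a", "b")))
  expect_equal(saturation_curve(ident), c(2, 2, 2, 2, 2))

  disj <- lapply(1:4, function(k)
    toy_model(paste0("d", k), paste0("c", k, "_", 1:3)))
  expect_equal(saturation_curve(disj), c(3, 6, 9, 12))

  # module-structured organisms: increments non-increasing on average over
  # 20 seeds. Sign test: the within-seed Kendall trend of increment vs rank
  # must be negative in at least 15/20 seeds (one-sided binomial p < 0.01),
  # and the seed-averaged first increment must exceed the last.
  incs <- matrix(0, nrow = 20, ncol = 11)
  trend_neg <- 0
  for (seed in 1:20) {
    net <- generate_universal_network(100, 200, 0.2, seed = seed,
                                      n_accessory_modules = 10)
    models <- lapply(1:12, function(k)
      build_draft_model(sample_organism_genome(net, 2, seed = 50 + k,
                                               organism_id = sprintf("s%02d", k)),
                        net))
    curve <- saturation_curve(models)
    expect_true(all(diff(curve) >= 0))
    incs[seed, ] <- diff(curve)
    if (cor(seq_len(11), diff(curve), method = "kendall") < 0) {
      trend_neg <- trend_neg + 1
    }
  }
  expect_gte(trend_neg, 15)
  avg <- colMeans(incs)
  expect_lt(avg[length(avg)], avg[1])
})
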