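# Synthetic-data generator: preconditions, determinism, construction
# guarantees, and the statistical invariants of the generated tables.

test_that("generate_universal_network enforces preconditions and determinism", {
  expect_error(generate_universal_network(10, 0, 0.2, seed = 1),
               class = "commgem_precondition")
  expect_error(generate_universal_network(5, 40, 0.2, seed = 1),
               class = "commgem_precondition")
  expect_error(generate_universal_network(20, 40, 0.9, seed = 1),
               class = "commgem_precondition")

  a <- generate_universal_network(60, 120, 0.2, seed = 7)
  b <- generate_universal_network(60, 120, 0.2, seed = 7)
  expect_identical(a, b)
  # byte-identical serialization
  fa <- tempfile(); fb <- tempfile()
  write_network_json(a, fa); write_network_json(b, fb)
  expect_identical(readLines(fa), readLines(fb))
  d <- generate_universal_network(60, 120, 0.2, seed = 8)
  expect_false(identical(a, d))
})

test_that("every biomass precursor is reachable from the seeds (BFS oracle)", {
  net <- generate_universal_network(200, 400, 0.2, seed = 1)
  # independent fixed-point reachability over the reaction hypergraph:
  # a reaction fires when all substrates are present (both ways if reversible)
  have <- net$seeds
  repeat {
    n0 <- length(have)
    for (r in net$reactions) {
      if (r$transport) next
      subs <- names(r$stoich)[r$stoich < 0]
      prods <- names(r$stoich)[r$stoich > 0]
      if (all(subs %in% have)) have <- union(have, prods)
      if (r$reversible && all(prods %in% have)) have <- union(have, subs)
    }
    if (length(have) == n0) break
  }
  expect_true(all(net$biomass_precursors %in% have))
  # invariants: reactions reference only cataloged compounds
  all_ref <- unique(unlist(lapply(net$reactions, function(r) names(r$stoich))))
  expect_true(all(all_ref %in% net$compounds$id))
  # transport reactions reference exactly one compound
  tr <- Filter(function(r) r$transport, net$reactions)
  expect_true(all(vapply(tr, function(r) length(unique(names(r$stoich))), 1L) == 1))
})

test_that("organisms share the core and are module unions (set-union oracle)", {
  net <- generate_universal_network(80, 160, 0.2, seed = 3,
                                    n_accessory_modules = 6)
  o1 <- sample_organism_genome(net, 2, seed = 7, organism_id = "o1")
  o2 <- sample_organism_genome(net, 2, seed = 8, organism_id = "o2")
  core_coding <- Filter(function(r) {
    !net$reactions[[r]]$spontaneous
  }, net$modules$core)
  expect_true(all(core_coding %in% o1$gene_reaction_map))
  expect_true(all(core_coding %in% o2$gene_reaction_map))

  # determinism
  expect_identical(sample_organism_genome(net, 1, seed = 7, organism_id = "x"),
                   sample_organism_genome(net, 1, seed = 7, organism_id = "x"))

  # all modules -> reaction set equals the union of module reaction sets
  # (restricted to gene-coding reactions; transports drawn separately)
  all_mod <- sample_organism_genome(net, length(net$modules$accessory),
                                    seed = 5, organism_id = "full",
                                    transport_draw = 1)
  expected <- sort(unique(c(net$modules$core,
                            unlist(net$modules$accessory),
                            net$modules$extra_transports)))
  expected <- Filter(function(r) !net$reactions[[r]]$spontaneous, expected)
  expect_setequal(unname(all_mod$gene_reaction_map), expected)

  expect_error(sample_organism_genome(net, 99, seed = 1),
               class = "commgem_precondition")
  expect_equal(all_mod$feature_count, length(all_mod$gene_set))
})

test_that("simulate_mag retains/contaminates genes exactly as specified", {
  net <- generate_universal_network(60, 120, 0.2, seed = 2)
  src <- sample_organism_genome(net, 3, seed = 1, organism_id = "src")
  pool <- lapply(1:3, function(k)
    sample_organism_genome(net, 3, seed = 10 + k,
                           organism_id = paste0("pool", k)))

  ident <- simulate_mag(src, 100, 0, seed = 1)
  expect_setequal(ident$genome$gene_set, src$gene_set)
  expect_equal(ident$completeness, 100)
  expect_equal(ident$contamination, 0)

  m60 <- simulate_mag(src, 60, 0, seed = 3)
  expect_equal(length(m60$genome$gene_set), round(0.6 * length(src$gene_set)))
  expect_true(all(m60$genome$gene_set %in% src$gene_set))

  # f = largest integer with 100 f / (kept + f) <= contamination; enumerate
  src100 <- make_genome("src100", paste0("r", 1:100))
  pool100 <- list(make_genome("poolA", paste0("q", 1:80)))
  mg <- simulate_mag(src100, 90, 5, pool = pool100, seed = 4)
  kept <- sum(mg$genome$gene_set %in% src100$gene_set)
  expect_equal(kept, 90)
  f_oracle <- 0
  for (f in 0:50) if (100 * f / (90 + f) <= 5) f_oracle <- f
  foreign <- length(mg$genome$gene_set) - kept
  expect_equal(foreign, f_oracle)   # = 4
  expect_equal(mg$contamination, 100 * 4 / 94, tolerance = 1e-12)

  # realized percentages agree with recomputation from the gene sets
  expect_equal(mg$completeness, 100 * kept / 100)
  expect_equal(mg$contamination,
               100 * foreign / length(mg$genome$gene_set))

  expect_error(simulate_mag(src, 90, 5, pool = list(), seed = 1),
               class = "commgem_precondition")
  expect_error(simulate_mag(src, 0, 0, seed = 1),
               class = "commgem_precondition")
})

test_that("MAG gene counts are monotone in completeness (contamination 0)", {
  net <- generate_universal_network(60, 120, 0.2, seed = 2)
  src <- sample_organism_genome(net, 3, seed = 1, organism_id = "src")
  sizes <- vapply(c(30, 50, 70, 90), function(cc)
    length(simulate_mag(src, cc, 0, seed = 5)$genome$gene_set), 1L)
  expect_true(all(diff(sizes) > 0))
  for (cc in c(30, 50, 70, 90)) {
    expect_true(all(simulate_mag(src, cc, 0, seed = 5)$genome$gene_set %in%
                    src$gene_set))
  }
})

test_that("abundance tables are normalized, symmetric and reproducible", {
  orgs <- c("sp1", "sp2")
  tab <- sample_abundance_table(orgs, 5, lognormal_sigma = 1e-8, seed = 1)
  expect_true(all(abs(tab$abundance - 50) < 1e-4))

  tab2 <- sample_abundance_table(paste0("sp", 1:5), 30, 1, seed = 11)
  expect_true(all(abs(colSums(tab2$abundance) - 100) < 1e-6))
  expect_true(all(tab2$abundance >= 0))

  # independent re-simulation oracle: same generator sequence, re-drawn here
  expected <- local({
    m <- 2147483647; h <- 5381
    for (b in utf8ToInt("netgen/abundance/group1")) h <- (h * 33 + b) %% m
    set.seed(as.integer((h * 31 + (11 %% m) * 7919) %% m))
    mm <- matrix(0, 5, 30)
    for (j in 1:30) {
      w <- rlnorm(5, 0, 1)
      mm[, j] <- 100 * w / sum(w)
    }
    rowMeans(mm)
  })
  expect_equal(unname(rowMeans(tab2$abundance)), expected, tolerance = 1e-12)

  expect_error(sample_abundance_table(orgs, 5, lognormal_sigma = 0, seed = 1),
               class = "commgem_precondition")
  expect_error(sample_abundance_table("one", 5, 1, seed = 1),
               class = "commgem_precondition")
})

test_that("simulate_metabolomics handles id loss, extras and replicates", {
  net <- generate_universal_network(100, 200, 0.2, seed = 9,
                                    ext_id_fraction = 1)
  true <- net$compounds$id
  idmap <- external_id_map(net)

  m0 <- simulate_metabolomics(true, net, id_loss_rate = 0, n_host_extras = 0,
                              n_samples = 3, seed = 1,
                              replicate_id_fraction = 0)
  expect_setequal(m0$rows$external_id, unname(idmap[true]))

  m3 <- simulate_metabolomics(true, net, id_loss_rate = 0.3, n_host_extras = 0,
                              n_samples = 3, seed = 2)
  expect_equal(sum(is.na(m3$rows$external_id)), 30)

  m5 <- simulate_metabolomics(true[1:40], net, id_loss_rate = 0,
                              n_host_extras = 5, n_samples = 3, seed = 3,
                              replicate_id_fraction = 0)
  ids <- m5$rows$external_id[!is.na(m5$rows$external_id)]
  unmatched <- setdiff(ids, idmap)  # set-difference oracle
  expect_length(unmatched, 5)

  # replicate ids never collide with any primary id
  mr <- simulate_metabolomics(true, net, id_loss_rate = 0.2, n_host_extras = 10,
                              n_samples = 4, seed = 4,
                              replicate_id_fraction = 0.2)
  reps <- mr$rows$replicate_ids[!is.na(mr$rows$replicate_ids)]
  expect_length(intersect(reps, mr$rows$external_id), 0)
  # every row keeps at least one measured value
  expect_true(all(apply(mr$abundance, 1, function(x) any(!is.na(x)))))

  expect_error(simulate_metabolomics(true, net, id_loss_rate = 1, 0, 3, 1),
               class = "commgem_precondition")
})
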