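test_that("neo-mutation gain counts totals and first appearances", {
  nw <- neo_mutation_gain(toy_catalog(), toy_stages())
  expect_equal(nw$table$total, c(1, 2, 2))
  expect_equal(nw$table$neo, c(1, 1, 1))
  expect_equal(nw$peaks, character(0))

  # single-stage catalog: neo = total
  one <- toy_catalog()
  one <- mutation_catalog(one[one$stage == "S2", ])
  nw1 <- neo_mutation_gain(one, stage_model("S2"))
  expect_equal(nw1$table$neo, nw1$table$total)

  # a gene seen at a later stage but not earlier counts as neo there
  cat2 <- mutation_catalog(data.frame(
    patient = "P1", sample = c("h1", "t1"), stage = c("HYP", "Tis"),
    gene = c("TP53", "FAT4"), chrom = "1", pos = c(1, 2),
    ref = "C", alt = "T", context = "ACA"))
  nw2 <- neo_mutation_gain(cat2, stage_model(c("HYP", "Tis")), key = "gene")
  expect_equal(nw2$table$neo[nw2$table$stage == "Tis"], 1)

  # empty catalog: zero counts, no peaks
  nw0 <- neo_mutation_gain(mutation_catalog(toy_catalog()[0, ]),
                           toy_stages())
  expect_equal(nw0$table$total, c(0, 0, 0))
  expect_equal(nw0$peaks, character(0))

  # unknown stage rejected
  expect_error(neo_mutation_gain(toy_catalog(), stage_model(c("S1", "S2"))),
               "not in stage model")
})

test_that("neo-mutation invariants hold on generated catalogs", {
  cfg <- sim_config(n_patients = 5, seed = 21,
                    stage_loads = setNames(rep(8, 9),
                                           default_stage_model()$stages))
  catalog <- gen_mutation_catalog(cfg)
  nw <- neo_mutation_gain(catalog, cfg$stages)
  keys <- unique(paste(catalog$chrom, catalog$pos, catalog$ref,
                       catalog$alt, sep = ":"))
  expect_equal(sum(nw$table$neo), length(keys))
  expect_equal(nw$table$neo[1], nw$table$total[1])

  # invariant to record order and duplicated records
  shuf <- mutation_catalog(catalog[sample(nrow(catalog)), ])
  dup <- mutation_catalog(rbind(as.data.frame(catalog),
                                as.data.frame(catalog[1:50, ])))
  expect_equal(neo_mutation_gain(shuf, cfg$stages)$table, nw$table)
  expect_equal(neo_mutation_gain(dup, cfg$stages)$table, nw$table)
})

test_that("phase partitioner opens a phase at each interior peak", {
  sm7 <- stage_model(paste0("t", 1:7))
  pp <- partition_phases(c(5, 1, 9, 2, 2, 8, 1), sm7)
  expect_equal(unname(pp$phases), list(1:2, 3:5, 6:7))

  # monotone decreasing series: a single phase
  pp1 <- partition_phases(c(9, 7, 5, 3, 1, 1, 0), sm7)
  expect_equal(unname(pp1$phases), list(1:7))

  # plateau peak reported at its leftmost stage
  pp2 <- partition_phases(c(1, 5, 5, 2, 8, 1, 0), sm7)
  expect_equal(unname(pp2$phases), list(1L, 2:4, 5:7))

  # partition property over random series: disjoint, ordered, exhaustive
  withr::with_seed(99, for (i in 1:50) {
    x <- rpois(9, 5)
    pp <- partition_phases(x, default_stage_model())
    expect_equal(sort(unname(unlist(pp$phases))), 1:9)
  })
})

test_that("mutation frequency is mutated-samples over cohort size", {
  cat3 <- mutation_catalog(data.frame(
    patient = "P1", sample = paste0("s", c(1, 2, 3, 1)),
    stage = "S1", gene = c("A", "A", "A", "B"), chrom = "1",
    pos = c(1, 1, 1, 2), ref = "C", alt = "T", context = "ACA"))
  mf <- mutation_frequency(cat3, 10)
  expect_equal(mf$frequency[mf$gene == "A"], 0.3)
  expect_equal(mf$frequency[mf$gene == "B"], 0.1)
  mf2 <- mutation_frequency(cat3, 3)
  expect_equal(mf2$frequency[mf2$gene == "A"], 1)
  expect_error(mutation_frequency(cat3, 0), "n_samples")
})

test_that("co-occurrence Fisher test matches hypergeometric enumeration", {
  # [[3,0],[0,3]] -> p = 0.1 by full enumeration over 6-sample tables
  cat6 <- mutation_catalog(data.frame(
    patient = "P1", sample = paste0("s", c(1:3, 1:3)), stage = "S1",
    gene = rep(c("A", "B"), each = 3), chrom = "1", pos = c(1, 1, 1, 2, 2, 2),
    ref = "C", alt = "T", context = "ACA"))
  ct <- cooccurrence_test(cat6, "A", "B", 6)
  expect_equal(ct$p, 0.1, tolerance = 1e-12)

  # balanced table -> independence, p = 1
  cat4 <- mutation_catalog(data.frame(
    patient = "P1", sample = paste0("s", c(1, 2, 1, 3)), stage = "S1",
    gene = rep(c("A", "B"), each = 2), chrom = "1", pos = c(1, 1, 2, 2),
    ref = "C", alt = "T", context = "ACA"))
  expect_equal(cooccurrence_test(cat4, "A", "B", 4)$p, 1)

  # absent gene: p = 1, odds ratio undefined
  ct0 <- cooccurrence_test(cat6, "Z", "B", 6)
  expect_equal(ct0$p, 1)
  expect_true(ct0$or_undefined)

  expect_error(cooccurrence_test(cat6, "A", "B", 2), "smaller than")
})

test_that("Fisher p equals exhaustive enumeration for all tables n <= 12", {
  for (n in 2:12) {
    for (a in 0:n) for (b in 0:(n - a)) for (c in 0:(n - a - b)) {
      d <- n - a - b - c
      tab <- matrix(c(a, b, c, d), 2)
      if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
      expect_equal(fisher.test(tab)$p.value, fisher2x2_enum(tab),
                   tolerance = 1e-12)
    }
  }
})

test_that("SCNA cis-effects recover planted monotone coupling", {
  cfg <- sim_config(samples_per_substage = 10, noise_sd = 0.3, seed = 13)
  sc <- gen_scna(cfg, n_genes = 60, n_cis = 10, coupling = 1)
  res <- scna_cis_effects(sc$scna, log2(sc$expr))
  cis <- res[res$gene %in% sc$cis_genes, ]
  bg <- res[!res$gene %in% sc$cis_genes & !res$undefined, ]
  expect_true(all(cis$rho > 0))
  expect_true(all(cis$fdr < 0.05))
  expect_lt(abs(mean(bg$rho)), 0.1)

  # perfectly monotone coupling: rho = 1 / -1
  scna <- named_matrix(rep(c(-1, 0, 1, 2), 2), 2, 4, c("g", "s"))
  expr <- named_matrix(rep(c(4, 3, 2, 1), 2), 2, 4, c("g", "s"))
  res2 <- scna_cis_effects(scna, expr, min_pairs = 3)
  expect_equal(res2$rho, c(-1, -1))

  # constant copy state: undefined, excluded from BH
  scna[2, ] <- 0
  res3 <- scna_cis_effects(scna, expr, min_pairs = 3)
  expect_true(res3$undefined[2])
  expect_true(is.na(res3$fdr[2]))
})
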