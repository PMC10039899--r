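test_that("FOT normalization divides by observed column totals", {
  m <- named_matrix(c(2, 3, 5, 10, NA, 30), 3, 2)
  f <- fot_normalize(m)
  expect_equal(unname(f[, 1]), c(0.2, 0.3, 0.5))
  # missing entry: remaining entries renormalized over the observed total
  expect_equal(unname(f[, 2]), c(0.25, NA, 0.75))
  expect_equal(colSums(f, na.rm = TRUE), c(s1 = 1, s2 = 1), tolerance = 1e-12)

  # single-protein column normalizes to 1
  expect_equal(unname(fot_normalize(named_matrix(7, 1, 1))[1, 1]), 1)

  # invariant to per-sample rescaling
  m2 <- sweep(m, 2, c(10, 0.1), "*")
  expect_equal(fot_normalize(m2), f)

  # all-zero column names the offending sample
  m3 <- m; m3[, 2] <- 0
  expect_error(fot_normalize(m3), "s2")
})

test_that("flooring replaces only sub-floor observed values by default", {
  m <- named_matrix(c(1e-6, 2e-5, NA, 0.5), 2, 2)
  f <- apply_floor(m)
  expect_equal(unname(f[1, 1]), 1e-5)
  expect_equal(unname(f[2, 1]), 2e-5)
  expect_true(is.na(f[1, 2]))
  expect_equal(min(f, na.rm = TRUE), 1e-5)
  f2 <- apply_floor(m, impute_missing = TRUE)
  expect_equal(unname(f2[1, 2]), 1e-5)
  # floor 0 is the identity
  expect_equal(apply_floor(m, floor = 0), m)
})

test_that("E1/E2 filters apply the peptide and prevalence rules strictly", {
  ann <- data.frame(sample = paste0("s", 1:10),
                    substage = rep(c("a", "b"), each = 5))
  m <- named_matrix(rep(NA_real_, 30), 3, 10)
  m[1, 1] <- 2e-5          # 20% of substage a: not more than 20% -> dropped
  m[2, 1:2] <- 2e-5        # 40% of substage a -> kept
  m[3, 6:10] <- 2e-5       # 100% of substage b -> kept
  e2 <- filter_features(m, ann, mode = "E2")
  expect_equal(rownames(e2), c("f2", "f3"))
  expect_equal(min(e2), 1e-5)   # missing entries imputed at the floor

  # literal all-substage reading keeps nothing here
  e2b <- filter_features(m, ann, mode = "E2", all_substages = TRUE)
  expect_equal(nrow(e2b), 0)

  # E1: 1 unique peptide dropped, 2 kept; sub-floor max FOT dropped
  m2 <- named_matrix(rep(2e-5, 30), 3, 10)
  m2[3, ] <- 1e-6
  pep <- c(f1 = 1, f2 = 2, f3 = 5)
  e1 <- filter_features(m2, mode = "E1", min_peptides = pep)
  expect_equal(rownames(e1), "f2")
  expect_error(filter_features(m2, mode = "E1"), "peptide")
})

test_that("Kruskal-Wallis differential table matches the rank formula", {
  # fully separated ranks (1,2,3) vs (4,5,6) vs (7,8,9): H = 7.2
  m <- rbind(f1 = 1:9, f2 = rep(1, 9))
  colnames(m) <- paste0("s", 1:9)
  ann <- data.frame(sample = paste0("s", 1:9),
                    substage = rep(c("a", "b", "c"), each = 3))
  dep <- suppressWarnings(stage_dep(m, ann))
  expect_equal(dep$statistic[1], 7.2, tolerance = 1e-12)
  expect_true(is.na(dep$statistic[2]) || dep$statistic[2] == 0)

  # group with < 2 samples excluded with a warning
  ann2 <- ann; ann2$substage[9] <- "d"
  expect_warning(stage_dep(m, ann2), "excluding")
})

test_that("null features produce uniform p-values and no flags", {
  withr::with_seed(42, {
    m <- named_matrix(2^rnorm(2000 * 30, 20, 1), 2000, 30)
    ann <- data.frame(sample = colnames(m),
                      substage = rep(c("a", "b", "c"), each = 10))
    dep <- stage_dep(m, ann)
    ks <- suppressWarnings(ks.test(dep$p, "punif"))
    expect_gt(ks$p.value, 0.01)
    expect_equal(sum(dep$flagged), 0)
  })
})

test_that("BH adjustment equals the step-up oracle by enumeration", {
  withr::with_seed(7, {
    for (n in c(1, 2, 5, 10)) {
      for (rep in 1:20) {
        p <- runif(n)
        expect_equal(p.adjust(p, "BH"), bh_enum(p), tolerance = 1e-12)
      }
    }
  })
})

test_that("planted substage-high proteins are recovered with high sensitivity", {
  subs <- paste0("ss", 1:4)
  cfg <- sim_config(stages = stage_model(subs), neo_peaks = character(0),
                    substages = subs, samples_per_substage = 15,
                    n_proteins = 500, dropout = 0,
                    wave_spec = list(list(name = "p1", substages = "ss2",
                                          log2fc = 2, prop = 0.1)),
                    seed = 17)
  ex <- gen_expression(cfg)
  fot <- apply_floor(fot_normalize(ex$matrix))
  dep <- stage_dep(fot, ex$annotations)
  planted <- ex$truth$protein[!is.na(ex$truth$panel)]
  sens <- mean(dep$flagged[dep$feature %in% planted] &
                 dep$best_group[dep$feature %in% planted] == "ss2")
  expect_gte(sens, 0.9)
})

test_that("zero effect sizes yield no DEP calls beyond the nominal rate", {
  subs <- paste0("ss", 1:4)
  cfg <- sim_config(stages = stage_model(subs), neo_peaks = character(0),
                    substages = subs, samples_per_substage = 10,
                    n_proteins = 400, dropout = 0,
                    wave_spec = list(list(name = "p1", substages = "ss1",
                                          log2fc = 1e-9, prop = 0.1)),
                    seed = 19)
  ex <- gen_expression(cfg)
  dep <- stage_dep(apply_floor(fot_normalize(ex$matrix)), ex$annotations)
  expect_lte(sum(dep$fdr < 0.05, na.rm = TRUE), 2)
})

test_that("wave panels respect contiguity and degenerate cuts", {
  subs <- paste0("ss", 1:6)
  cfg <- sim_config(stages = stage_model(subs), neo_peaks = character(0),
                    substages = subs, samples_per_substage = 10,
                    n_proteins = 300, dropout = 0, seed = 23,
                    wave_spec = lapply(1:3, function(i)
                      list(name = paste0("p", i),
                           substages = subs[(2 * i - 1):(2 * i)],
                           log2fc = 2, prop = 0.1)))
  ex <- gen_expression(cfg)
  fot <- apply_floor(fot_normalize(ex$matrix))
  dep <- stage_dep(fot, ex$annotations)
  wv <- build_waves(fot, ex$annotations, dep, n_panels = 3)
  # panels are contiguous blocks in substage order
  expect_true(all(diff(wv$substages$panel) >= 0))
  expect_equal(sort(unique(wv$substages$panel)), 1:3)
  # identity cut: one panel per substage
  wv6 <- build_waves(fot, ex$annotations, dep, n_panels = 6)
  expect_equal(wv6$substages$panel, 1:6)
  # proteins disjoint across panels
  expect_equal(anyDuplicated(wv$proteins$protein), 0)
})

test_that("SAM with s0 = 0 reduces to the unequal-variance t statistic", {
  withr::with_seed(11, {
    m <- named_matrix(rnorm(100 * 16), 100, 16)
    lab <- rep(c("g1", "g2"), each = 8)
    sr <- sam_two_class(m, lab, s0 = 0, n_perm = 10, delta = 0, seed = 2)
    tref <- apply(m, 1, function(x) {
      tt <- t.test(x[9:16], x[1:8])  # mean2 - mean1 orientation
      unname(tt$statistic)
    })
    expect_equal(sr$table$d, unname(tref), tolerance = 1e-12)
  })
})

test_that("SAM permutation FDR is honest on null data and exhaustive for tiny n", {
  withr::with_seed(12, {
    m <- named_matrix(rnorm(300 * 12), 300, 12)
    lab <- rep(c("a", "b"), each = 6)
    sr <- sam_two_class(m, lab, s0 = "auto", n_perm = 5000, delta = 1.2,
                        seed = 3)
    # n_perm > C(12,6) = 924 triggers exhaustive enumeration
    expect_equal(sr$n_perm, choose(12, 6))
    if (sum(sr$table$called) > 0) expect_gte(sr$fdr, 0.5)
  })
})

test_that("consensus clustering finds two well-separated blobs exactly", {
  withr::with_seed(14, {
    m <- named_matrix(rnorm(100 * 24), 100, 24)
    m[1:20, 13:24] <- m[1:20, 13:24] + 6
    cc <- consensus_cluster(m, k_range = 2:4, reps = 25, seed = 6)
    expect_equal(cc$chosen_k, 2)
    truth <- rep(1:2, each = 12)
    expect_equal(mclust::adjustedRandIndex(cc$labels[["k2"]], truth), 1)
    # block structure: within-pair consensus 1, between 0
    C <- cc$consensus[["k2"]]
    expect_equal(min(C[1:12, 1:12]), 1)
    expect_equal(max(C[1:12, 13:24]), 0)
    # symmetry and range
    expect_equal(C, t(C))
    expect_true(all(C >= 0 & C <= 1))
  })
})

test_that("single-rep consensus degenerates to one k-means co-membership", {
  withr::with_seed(15, {
    m <- named_matrix(rnorm(50 * 12), 50, 12)
    cc <- consensus_cluster(m, k_range = 2, reps = 1, p_item = 1, seed = 7)
    C <- cc$consensus[["k2"]]
    expect_true(all(C %in% c(0, 1)))
  })
})

test_that("match-between-runs transfers hidden features under an RT warp", {
  cfg <- sim_config(seed = 25)
  # identity map, no noise: every hidden-but-present feature recovered
  pf <- gen_peptide_features(cfg, n_peptides = 120, rt_map = c(0, 1, 0))
  out <- suppressWarnings(mbr_impute(pf, "ref", rt_tol = 0.5))
  tr <- attr(pf, "truth")$acc1
  mbr <- out[out$source == "mbr", ]
  expect_equal(sort(mbr$peptide), sort(tr$hidden))
  expect_equal(attr(out, "rt_models")$acc1$model, "linear")
  # imputed intensities equal the donor-run matched features
  direct <- pf[pf$run == "acc1" & !pf$identified, ]
  expect_equal(sort(mbr$intensity),
               sort(direct$intensity[match(paste0("feat_", mbr$peptide),
                                           direct$peptide)]))

  # absent features stay missing
  expect_false(any(mbr$peptide %in% tr$absent))

  # quadratic warp with zero noise: quadratic model, exact RT recovery
  pf2 <- gen_peptide_features(cfg, n_peptides = 120,
                              rt_map = c(2, 0.9, 0.005))
  out2 <- suppressWarnings(mbr_impute(pf2, "ref", rt_tol = 0.5))
  expect_equal(attr(out2, "rt_models")$acc1$model, "quadratic")
  tr2 <- attr(pf2, "truth")$acc1
  mbr2 <- out2[out2$source == "mbr", ]
  expect_equal(sort(mbr2$peptide), sort(tr2$hidden))

  # too few shared peptides: pair skipped with a warning
  pf3 <- pf[pf$run == "ref" | pf$peptide %in% pf$peptide[1:3], ]
  expect_warning(mbr_impute(pf3, "ref", min_shared = 50), "skipped")
})
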