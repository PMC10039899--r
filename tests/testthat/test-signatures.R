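test_that("spectrum construction collapses to pyrimidine-centered channels", {
  # G>A in T[G]C collapses to C>T at G[C]A
  cat_g <- one_class_catalog(3, ref = "G", alt = "A", context = "TGC")
  sp <- build_spectrum(cat_g)
  expect_equal(unname(sp[1, "G[C>T]A"]), 3)
  expect_equal(sum(sp), 3)

  # direct tally: 10 records of one class fill one channel
  sp10 <- build_spectrum(one_class_catalog(10, context = "TCA"))
  expect_equal(unname(sp10[1, "T[C>T]A"]), 10)
  expect_equal(rowSums(sp10), c(s1 = 10))

  # empty catalog: all-zero spectrum
  sp0 <- build_spectrum(mutation_catalog(toy_catalog()[0, ]))
  expect_equal(sum(sp0), 0)
  expect_equal(ncol(sp0), 96)

  # reverse-complementing every record leaves the spectrum unchanged
  cfg <- sim_config(n_patients = 3, seed = 31)
  catalog <- gen_mutation_catalog(cfg)
  rc <- as.data.frame(catalog)
  flip <- function(b) c(A = "T", C = "G", G = "C", T = "A")[b]
  rc$ref <- unname(flip(rc$ref)); rc$alt <- unname(flip(rc$alt))
  rc$context <- vapply(strsplit(rc$context, ""), function(x)
    paste(rev(unname(flip(x))), collapse = ""), "")
  expect_equal(build_spectrum(mutation_catalog(rc)), build_spectrum(catalog),
               ignore_attr = TRUE)
})

test_that("ambiguous-context records are skipped and counted", {
  df <- as.data.frame(one_class_catalog(4))
  df$context[2] <- "NCN"
  sp <- build_spectrum(mutation_catalog(df))
  expect_equal(sum(sp), 3)
  expect_equal(attr(sp, "skipped"), 1)
})

test_that("rank-1 factorization recovers the generating profile exactly", {
  p <- toy_signature_profiles(1)[, 1]
  loads <- c(100, 200, 300, 400)
  spec <- round(outer(loads, p) * 10)
  dimnames(spec) <- list(paste0("s", 1:4), sbs96_channels())
  m <- extract_signatures(spec, k_range = 1, n_restarts = 3, seed = 1)
  expect_gt(cosine_sim(m$signatures[, 1], p), 0.999)
  # exposures proportional to loads
  e <- m$exposures[1, ]
  expect_gt(cor(e, loads), 0.999)
  # reconstruction conserves sample totals approximately
  recon <- colSums(m$signatures %*% m$exposures)
  expect_equal(unname(recon), unname(rowSums(spec)), tolerance = 0.01)
})

test_that("divergence trace is non-increasing and errors are raised", {
  spec <- gen_signature_spectrum(toy_signature_profiles(2), 30, load = 100,
                                 seed = 3)$spectrum
  m <- extract_signatures(spec, k_range = 2, n_restarts = 2, seed = 2)
  expect_true(all(diff(m$trace) <= 1e-8 * abs(m$trace[-length(m$trace)])))
  zero <- spec * 0L
  expect_error(extract_signatures(zero, k_range = 2), "all-zero")
  expect_error(extract_signatures(spec, k_range = integer(0)), "empty")
  expect_error(extract_signatures(spec, k_range = 40), "rank")
})

test_that("cosine matching aligns channels and reports ties", {
  P <- toy_signature_profiles(3)
  self <- cosine_match(P, P)
  expect_equal(self$cosine, rep(1, 3), tolerance = 1e-12)
  expect_equal(self$best_match, colnames(P))

  # orthogonal one-hot profiles have cosine 0
  ch <- sbs96_channels()
  a <- matrix(0, 96, 1, dimnames = list(ch, "a")); a[1, 1] <- 1
  b <- matrix(0, 96, 1, dimnames = list(ch, "b")); b[2, 1] <- 1
  expect_equal(cosine_match(a, b)$cosine, 0)

  # average of two equal-norm refs ties; broken by reference order
  refs <- cbind(a, b); colnames(refs) <- c("r1", "r2")
  avg <- (a + b) / 2; colnames(avg) <- "avg"
  cm <- cosine_match(avg, refs)
  expect_true(cm$tie)
  expect_equal(cm$best_match, "r1")

  # channel order mismatch is an error
  bad <- P; rownames(bad) <- rev(rownames(bad))
  expect_silent(cosine_match(P, bad))   # same label set, reordered
  rownames(bad)[1] <- "XXX"
  expect_error(cosine_match(P, bad), "channel labels")
})

test_that("APOBEC enrichment scores TCW concentration against background", {
  # all C>T at TCW with background fraction 0.25 -> score 4
  ap <- apobec_enrichment(one_class_catalog(10, context = "TCA"),
                          background = c(tcw = 25, c = 100))
  expect_equal(ap$score, 4)
  expect_true(ap$testable)

  # TCW fraction equal to background: score 1, not significant
  df <- rbind(as.data.frame(one_class_catalog(5, context = "TCA")),
              as.data.frame(one_class_catalog(15, context = "ACA")))
  df$pos <- seq_len(20)
  ap2 <- apobec_enrichment(mutation_catalog(df),
                           background = c(tcw = 25, c = 100))
  expect_equal(ap2$score, 1)
  expect_gte(ap2$p, 0.5)

  # zero C-class mutations: untestable
  ap3 <- apobec_enrichment(one_class_catalog(10, ref = "T", alt = "G",
                                             context = "ATA"))
  expect_false(ap3$testable)
  expect_false(ap3$enriched)

  expect_error(apobec_enrichment(one_class_catalog(5),
                                 background = c(tcw = 0, c = 100)),
               "tcw")
})

test_that("signature-phase association uses exact and fallback tests", {
  flags <- matrix(c(rep(TRUE, 3), rep(FALSE, 3)), ncol = 1,
                  dimnames = list(NULL, "S1"))
  ph <- rep(c("NT", "ADV"), each = 3)
  res <- signature_phase_association(flags, ph)
  expect_equal(res$p, 0.1, tolerance = 1e-12)
  expect_equal(res$test, "fisher")

  # identical proportions -> p = 1
  flags2 <- matrix(rep(c(TRUE, FALSE), 4), ncol = 1,
                   dimnames = list(NULL, "S1"))
  res2 <- signature_phase_association(flags2, rep(c("a", "b"), each = 4))
  expect_equal(res2$p, 1)

  # three phases use the chi-square fallback
  res3 <- signature_phase_association(
    matrix(rep(c(TRUE, FALSE), 6), ncol = 1, dimnames = list(NULL, "S1")),
    rep(c("a", "b", "c"), each = 4))
  expect_equal(res3$test, "chisq")
})

test_that("the shipped synthetic reference catalog loads and matches", {
  path <- system.file("extdata", "synthetic_reference_signatures.tsv",
                      package = "stagewave")
  ref <- read_matrix(path)
  expect_equal(dim(ref), c(96L, 5L))
  expect_equal(unname(colSums(ref)), rep(1, 5), tolerance = 1e-4)
  sim <- gen_signature_spectrum(ref[, 1, drop = FALSE], 20, load = 500,
                                seed = 47)
  model <- extract_signatures(sim$spectrum, k_range = 1, n_restarts = 3,
                              seed = 4)
  cm <- cosine_match(model, ref)
  expect_equal(cm$best_match, "SynthRef1")
  expect_gt(cm$cosine, 0.99)
})
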