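#' Canonical 96-channel substitution classes
#'
#' Single-base substitutions collapsed to the pyrimidine strand
#' (C>A, C>G, C>T, T>A, T>C, T>G), each in 16 flanking-base contexts,
#' labelled `"A[C>A]A"` style and ordered substitution-major.
#'
#' @return Character vector of length 96.
#' @export
sbs96_channels <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  unlist(lapply(subs, function(s) {
    ref <- substr(s, 1, 1)
    as.vector(t(outer(bases, bases, function(p, q)
      paste0(p, "[", s, "]", q))))
  }))
}

REVCOMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

revcomp <- function(x) {
  vapply(strsplit(x, ""), function(b)
    paste(rev(unname(REVCOMP[b])), collapse = ""), "")
}

# Collapse a (ref, alt, context) record to its pyrimidine-centered
# channel label, or NA if a base is ambiguous.
classify_sbs96 <- function(ref, alt, context) {
  bad <- grepl("N", context, fixed = TRUE) | !ref %in% c("A", "C", "G", "T") |
    !alt %in% c("A", "C", "G", "T")
  pur <- ref %in% c("A", "G")
  ref2 <- ifelse(pur, unname(REVCOMP[ref]), ref)
  alt2 <- ifelse(pur, unname(REVCOMP[alt]), alt)
  ctx2 <- context
  ctx2[pur] <- revcomp(context[pur])
  lab <- paste0(substr(ctx2, 1, 1), "[", ref2, ">", alt2, "]",
                substr(ctx2, 3, 3))
  lab[bad] <- NA_character_
  lab
}

#' Build a 96-channel mutational spectrum
#'
#' Tallies each sample's single-base substitutions into the 96
#' pyrimidine-centered channels; purine-reference records are
#' reverse-complemented first. Records with ambiguous (N) bases are
#' skipped and counted in the `skipped` attribute.
#'
#' @param catalog A `mutation_catalog`.
#' @param samples Optional sample ordering for the rows; defaults to the
#'   sorted samples present.
#' @return Samples x 96 integer matrix with channel labels as column
#'   names and attribute `skipped`.
#' @export
build_spectrum <- function(catalog, samples = NULL) {
  channels <- sbs96_channels()
  lab <- classify_sbs96(catalog$ref, catalog$alt, catalog$context)
  keep <- !is.na(lab)
  samples <- samples %||% sort(unique(catalog$sample))
  spec <- matrix(0L, length(samples), 96,
                 dimnames = list(samples, channels))
  if (any(keep)) {
    tab <- table(factor(catalog$sample[keep], levels = samples),
                 factor(lab[keep], levels = channels))
    spec[] <- as.integer(tab)
  }
  attr(spec, "skipped") <- sum(!keep)
  spec
}

# One KL-divergence multiplicative-update NMF run: V (96 x n) ~ W %*% H.
# Returns W (96 x k), H (k x n) and the divergence trace.
nmf_kl_fit <- function(V, k, max_iter, tol, eps = 1e-12) {
  p <- nrow(V); n <- ncol(V)
  W <- matrix(runif(p * k, 0.1, 1), p, k) * sqrt(mean(V) / k)
  H <- matrix(runif(k * n, 0.1, 1), k, n) * sqrt(mean(V) / k)
  kl_div <- function(WH) {
    pos <- V > 0
    sum(V[pos] * log(V[pos] / WH[pos])) - sum(V) + sum(WH)
  }
  WH <- W %*% H
  trace <- kl_div(WH)
  for (it in seq_len(max_iter)) {
    R <- V / (WH + eps)
    H <- H * (crossprod(W, R) / pmax(colSums(W), eps))
    WH <- W %*% H
    R <- V / (WH + eps)
    W <- W * (tcrossprod(R, H) / rep(pmax(rowSums(H), eps), each = p))
    WH <- W %*% H
    if (it %% 10L == 0L || it == max_iter) {
      d <- kl_div(WH)
      trace <- c(trace, d)
      last <- trace[length(trace) - 1L]
      if (is.finite(last) && (last - d) < tol * max(abs(last), 1)) break
    }
  }
  list(W = W, H = H, divergence = trace[length(trace)], trace = trace)
}

#' Extract mutational signatures by KL-divergence NMF
#'
#' Factorizes the spectrum into nonnegative signature profiles and
#' per-sample exposures using multiplicative updates under the
#' Kullback-Leibler divergence, with random restarts. The factorization
#' rank is selected as the candidate with the highest cophenetic
#' correlation of the restart-consensus matrix (samples co-assigned to
#' the same dominant signature), the standard stability criterion for
#' signature number. Profiles are renormalized to sum to one, with
#' exposures rescaled so the reconstruction is conserved.
#'
#' @param spectrum Samples x 96 count matrix from [build_spectrum()].
#' @param k_range Candidate ranks (each < min(n samples, 96)).
#' @param n_restarts Random restarts per rank (best divergence kept; all
#'   restarts feed the consensus).
#' @param max_iter,tol Multiplicative-update iteration cap and relative
#'   divergence tolerance for early stopping.
#' @param seed Master seed; restart seeds are derived deterministically.
#' @return A `signature_model`: `signatures` (96 x k, columns on the
#'   simplex), `exposures` (k x samples), `k`, `cophenetic` (per rank),
#'   `divergence` (per rank, best restart) and `trace` (divergence trace
#'   of the winning fit).
#' @export
extract_signatures <- function(spectrum, k_range = 2:5, n_restarts = 30L,
                               max_iter = 300L, tol = 1e-4, seed = 1L) {
  assert_matrix(spectrum, "spectrum")
  if (!length(k_range)) stopf("k_range is empty")
  if (ncol(spectrum) != 96L) stopf("spectrum must have 96 channels")
  keep <- rowSums(spectrum) > 0
  if (!any(keep)) stopf("all-zero spectrum")
  V <- t(spectrum[keep, , drop = FALSE])          # 96 x n
  n <- ncol(V)
  if (max(k_range) >= min(n, 96L))
    stopf("max rank must be < min(n_samples, 96)")
  coph <- div <- setNames(numeric(length(k_range)), paste0("k", k_range))
  fits <- vector("list", length(k_range))
  for (ki in seq_along(k_range)) {
    k <- k_range[ki]
    best <- NULL
    consensus <- matrix(0, n, n)
    for (r in seq_len(n_restarts)) {
      fit <- withr::with_seed(derive_seed(seed, k * 1000L + r),
                              nmf_kl_fit(V, k, max_iter, tol))
      if (is.null(best) || fit$divergence < best$divergence) best <- fit
      memb <- apply(fit$H, 2, which.max)
      consensus <- consensus + outer(memb, memb, "==")
    }
    consensus <- consensus / n_restarts
    d <- as.dist(1 - consensus)
    coph[ki] <- if (sd(d) == 0) 1 else {
      hc <- hclust(d, method = "average")
      cor(d, cophenetic(hc))
    }
    div[ki] <- best$divergence
    fits[[ki]] <- best
  }
  ki <- which.max(coph)
  k <- k_range[ki]; fit <- fits[[ki]]
  scale <- colSums(fit$W)
  W <- sweep(fit$W, 2, scale, "/")
  H <- fit$H * scale
  colnames(W) <- rownames(H) <- paste0("Sig", seq_len(k))
  rownames(W) <- rownames(V)
  colnames(H) <- colnames(V)
  structure(list(signatures = W, exposures = H, k = k,
                 cophenetic = coph, divergence = div, trace = fit$trace),
            class = "signature_model")
}

#' @export
print.signature_model <- function(x, ...) {
  cat("<signature_model> k =", x$k, "signatures,",
      ncol(x$exposures), "samples\n")
  cat("cophenetic:", paste(names(x$cophenetic),
                           round(x$cophenetic, 3), collapse = "  "), "\n")
  invisible(x)
}

#' Match extracted signatures to a reference catalog
#'
#' Computes cosine similarity between each extracted signature profile and
#' every reference profile (channel order is aligned by label) and reports
#' the best match; exact ties are broken by reference order and recorded.
#'
#' @param model A `signature_model` (or a 96 x k profile matrix with
#'   channel rownames).
#' @param ref 96 x m reference profile matrix, channel labels as rownames.
#' @return Data frame `signature`, `best_match`, `cosine`, `tie`; the full
#'   similarity matrix is in attribute `cosine_matrix`.
#' @export
cosine_match <- function(model, ref) {
  W <- if (inherits(model, "signature_model")) model$signatures else model
  if (is.null(rownames(W)) || is.null(rownames(ref)))
    stopf("profiles must carry channel labels as rownames")
  if (!setequal(rownames(W), rownames(ref)))
    stopf("channel labels of signatures and reference do not match")
  ref <- ref[rownames(W), , drop = FALSE]
  cm <- matrix(NA_real_, ncol(W), ncol(ref),
               dimnames = list(colnames(W), colnames(ref)))
  for (i in seq_len(ncol(W)))
    for (j in seq_len(ncol(ref)))
      cm[i, j] <- cosine_sim(W[, i], ref[, j])
  best <- apply(cm, 1, which.max)
  tie <- vapply(seq_len(nrow(cm)), function(i)
    sum(abs(cm[i, ] - cm[i, best[i]]) < 1e-12) > 1L, TRUE)
  out <- data.frame(signature = rownames(cm),
                    best_match = colnames(cm)[best],
                    cosine = cm[cbind(seq_len(nrow(cm)), best)],
                    tie = tie, stringsAsFactors = FALSE)
  attr(out, "cosine_matrix") <- cm
  out
}

#' APOBEC enrichment per sample
#'
#' Scores each sample's enrichment of cytosine mutations (C>T and C>G
#' after pyrimidine-strand collapsing) at the APOBEC-characteristic TCW
#' motif (T\[C\]A / T\[C\]T) relative to the background availability of TCW
#' contexts among cytosines: score = (mut_tCw / mut_C) / (bg_TCW / bg_C).
#' Significance is a one-sided Fisher test of the mutation counts against
#' the background counts, BH-adjusted over testable samples.
#'
#' @param catalog A `mutation_catalog`.
#' @param background Named numeric `c(tcw = , c = )` giving the territory
#'   counts of TCW motifs and of cytosines; `NULL` uses the
#'   uniform-context fallback (2 of the 16 flanking contexts are TCW).
#' @param alpha BH-FDR threshold for the enriched flag.
#' @param min_mut Minimum C-class mutation count for a sample to be
#'   testable.
#' @param score_threshold Minimum enrichment score for the enriched flag.
#' @return Data frame `sample`, `mut_c`, `mut_tcw`, `score`, `p`, `fdr`,
#'   `testable`, `enriched`.
#' @export
apobec_enrichment <- function(catalog, background = NULL, alpha = 0.05,
                              min_mut = 5L, score_threshold = 2) {
  bg <- background %||% c(tcw = 2, c = 16)
  if (!all(c("tcw", "c") %in% names(bg)) || bg[["tcw"]] <= 0)
    stopf("background must supply positive 'tcw' and 'c' counts")
  lab <- classify_sbs96(catalog$ref, catalog$alt, catalog$context)
  keep <- !is.na(lab)
  sub <- sub(".*\\[(.*)\\].*", "\\1", lab[keep])
  cclass <- sub %in% c("C>T", "C>G")
  tcw <- cclass & grepl("^T\\[C>[TG]\\][AT]$", lab[keep])
  samp <- catalog$sample[keep]
  samples <- sort(unique(catalog$sample))
  mut_c <- as.integer(table(factor(samp[cclass], levels = samples)))
  mut_tcw <- as.integer(table(factor(samp[tcw], levels = samples)))
  bg_frac <- bg[["tcw"]] / bg[["c"]]
  score <- (mut_tcw / mut_c) / bg_frac
  testable <- mut_c >= min_mut
  p <- rep(NA_real_, length(samples))
  for (i in which(testable)) {
    tab <- matrix(c(mut_tcw[i], mut_c[i] - mut_tcw[i],
                    bg[["tcw"]], bg[["c"]] - bg[["tcw"]]), nrow = 2,
                  byrow = TRUE)
    p[i] <- fisher.test(tab, alternative = "greater")$p.value
  }
  fdr <- rep(NA_real_, length(samples))
  fdr[testable] <- p.adjust(p[testable], method = "BH")
  data.frame(sample = samples, mut_c = mut_c, mut_tcw = mut_tcw,
             score = ifelse(mut_c > 0, score, NA_real_), p = p, fdr = fdr,
             testable = testable,
             enriched = testable & !is.na(score) &
               score > score_threshold & fdr < alpha,
             stringsAsFactors = FALSE)
}

#' Association between signature activity and progression phase
#'
#' Tests, per signature, whether a binary activity flag (or dominant-
#' signature assignment) is associated with the phase labels: the exact
#' Fisher test for 2x2 tables, a chi-square test for larger tables.
#'
#' @param flags Logical matrix samples x signatures (or a factor of
#'   dominant assignments, expanded to indicators).
#' @param phases Factor/character of phase labels per sample; empty
#'   levels are dropped with a warning.
#' @return Data frame `signature`, `p`, `test`, plus per-phase positive
#'   proportions.
#' @export
signature_phase_association <- function(flags, phases) {
  if (is.factor(flags) || is.character(flags)) {
    f <- factor(flags)
    flags <- sapply(levels(f), function(l) f == l)
  }
  flags <- as.matrix(flags)
  ph <- factor(phases)
  if (any(table(ph) == 0)) {
    warnf("dropping empty phase level(s)")
    ph <- droplevels(ph)
  }
  res <- lapply(colnames(flags) %||% seq_len(ncol(flags)), function(s) {
    x <- flags[, s]
    tab <- table(ph, factor(x, levels = c(FALSE, TRUE)))
    prop <- tapply(x, ph, mean)
    if (nlevels(ph) == 2L) {
      list(p = fisher.test(tab)$p.value, test = "fisher", prop = prop)
    } else {
      list(p = suppressWarnings(chisq.test(tab)$p.value),
           test = "chisq", prop = prop)
    }
  })
  out <- data.frame(
    signature = colnames(flags) %||% paste0("S", seq_len(ncol(flags))),
    p = vapply(res, `[[`, 0, "p"),
    test = vapply(res, `[[`, "", "test"), stringsAsFactors = FALSE)
  props <- do.call(rbind, lapply(res, `[[`, "prop"))
  colnames(props) <- paste0("prop_", colnames(props))
  cbind(out, props)
}
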