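#' Construct a somatic mutation catalog
#'
#' A mutation catalog is a long-form table of somatic single-nucleotide
#' variants keyed by (patient, sample, stage, variant), with the
#' trinucleotide context of each variant on the reported strand.
#'
#' @param df Data frame with columns `patient`, `sample`, `stage`, `gene`,
#'   `chrom`, `pos` (1-based), `ref`, `alt`, `context` (3-character string;
#'   middle base must equal `ref`).
#' @return The validated data frame with class `mutation_catalog`.
#' @export
mutation_catalog <- function(df) {
  need <- c("patient", "sample", "stage", "gene", "chrom", "pos",
            "ref", "alt", "context")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("missing catalog column(s): %s",
                          paste(miss, collapse = ", "))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (any(df$ref == df$alt)) stopf("ref and alt alleles must differ")
  bad <- nchar(df$context) != 3L | substr(df$context, 2, 2) != df$ref
  if (any(bad))
    stopf("%d record(s) have a context inconsistent with the ref allele",
          sum(bad))
  class(df) <- c("mutation_catalog", "data.frame")
  df
}

variant_key <- function(catalog, key = c("variant", "gene")) {
  key <- match.arg(key)
  if (key == "variant")
    paste(catalog$chrom, catalog$pos, catalog$ref, catalog$alt, sep = ":")
  else
    as.character(catalog$gene)
}

# Strict local maxima of a series over interior positions, with plateau
# handling: a maximal run of equal values counts as one peak (reported at
# its leftmost index) when both flanking values exist and are strictly
# lower. Endpoints never qualify.
local_peaks <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  peaks <- integer(0)
  for (i in seq_along(r$values)) {
    if (i == 1L || i == length(r$values)) next
    if (r$values[i] > r$values[i - 1L] && r$values[i] > r$values[i + 1L])
      peaks <- c(peaks, starts[i])
  }
  peaks
}

#' Neo-mutation gain across ordered stages
#'
#' For each stage, counts the mutation keys observed at that stage (total)
#' and those observed at that stage but at no earlier stage (neo). Stages
#' where the neo series attains a strict interior local maximum are
#' reported as peaks, and a phase partition is derived from them.
#'
#' Neo status is decided cohort-wide by default: a key is neo at the
#' earliest stage at which any patient carries it. With
#' `per_patient = TRUE` keys are tracked per patient, so the same variant
#' can be neo in several patients.
#'
#' @param catalog A `mutation_catalog`.
#' @param stages A `stage_model`; every record's stage must be listed.
#' @param key Count distinct variants (`"variant"`, default) or distinct
#'   mutated genes (`"gene"`).
#' @param per_patient Track first appearance per patient instead of
#'   cohort-wide.
#' @param phase_names Optional names for the derived phases.
#' @return A `neo_wave_result`: a list with `table` (stage, total, neo,
#'   is_peak, phase), `peaks` (stage labels) and `phases` (the partition).
#' @export
neo_mutation_gain <- function(catalog, stages, key = c("variant", "gene"),
                              per_patient = FALSE, phase_names = NULL) {
  key <- match.arg(key)
  labs <- stages$stages
  if (nrow(catalog)) {
    unknown <- setdiff(unique(catalog$stage), labs)
    if (length(unknown))
      stopf("catalog stage(s) not in stage model: %s",
            paste(unknown, collapse = ", "))
  }
  k <- variant_key(catalog, key)
  if (per_patient) k <- paste(catalog$patient, k, sep = "|")
  st <- factor(catalog$stage, levels = labs)
  total <- neo <- integer(length(labs))
  seen <- character(0)
  for (i in seq_along(labs)) {
    ki <- unique(k[as.integer(st) == i])
    total[i] <- length(ki)
    neo[i] <- length(setdiff(ki, seen))
    seen <- c(seen, setdiff(ki, seen))
  }
  peaks <- local_peaks(neo)
  part <- phase_blocks(length(labs), peaks, phase_names)
  phase <- rep(names(part), lengths(part))
  res <- list(
    table = data.frame(stage = labs, total = total, neo = neo,
                       is_peak = seq_along(labs) %in% peaks,
                       phase = phase, stringsAsFactors = FALSE),
    peaks = labs[peaks],
    phases = part,
    key = key
  )
  class(res) <- "neo_wave_result"
  res
}

#' @export
print.neo_wave_result <- function(x, ...) {
  cat("<neo_wave_result> key =", x$key, "\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

phase_blocks <- function(n_stages, peak_idx, phase_names = NULL) {
  peak_idx <- sort(unique(as.integer(peak_idx)))
  bounds <- c(1L, peak_idx, n_stages + 1L)
  if (length(peak_idx) && peak_idx[1L] == 1L) bounds <- bounds[-1L]
  blocks <- list()
  for (i in seq_len(length(bounds) - 1L))
    blocks[[i]] <- seq(bounds[i], bounds[i + 1L] - 1L)
  nm <- phase_names %||% paste0("phase", seq_along(blocks))
  if (length(nm) != length(blocks))
    stopf("expected %d phase name(s), got %d", length(blocks), length(nm))
  names(blocks) <- nm
  blocks
}

#' Partition stages into phases at neo-mutation peaks
#'
#' Each detected peak stage opens a new phase; the block before the first
#' peak is the initial phase. With no peaks a single phase covers all
#' stages.
#'
#' @param neo A `neo_wave_result` (or a plain numeric neo series).
#' @param stages The `stage_model` the series was computed on.
#' @param phase_names Optional character vector naming the phases.
#' @return A `stage_model` with the derived phase partition.
#' @export
partition_phases <- function(neo, stages, phase_names = NULL) {
  series <- if (inherits(neo, "neo_wave_result")) neo$table$neo else as.numeric(neo)
  if (length(series) != length(stages$stages))
    stopf("neo series length (%d) != number of stages (%d)",
          length(series), length(stages$stages))
  blocks <- phase_blocks(length(series), local_peaks(series), phase_names)
  stage_model(stages$stages, phases = blocks)
}

#' Per-gene mutation frequency
#'
#' Frequency is the number of samples carrying at least one mutation in
#' the gene divided by the cohort sample count.
#'
#' @param catalog A `mutation_catalog`.
#' @param n_samples Total number of profiled samples (>= 1).
#' @return Data frame with columns `gene`, `n_mutated`, `frequency`,
#'   sorted by decreasing frequency.
#' @export
mutation_frequency <- function(catalog, n_samples) {
  if (length(n_samples) != 1L || is.na(n_samples) || n_samples < 1)
    stopf("n_samples must be a single count >= 1")
  tab <- tapply(catalog$sample, catalog$gene,
                function(s) length(unique(s)))
  n_mut <- as.integer(tab)
  if (any(n_mut > n_samples))
    stopf("a gene is mutated in more samples than n_samples")
  out <- data.frame(gene = names(tab), n_mutated = n_mut,
                    frequency = n_mut / n_samples,
                    stringsAsFactors = FALSE)
  out[order(-out$frequency, out$gene), , drop = FALSE]
}

#' Mutation co-occurrence test for a gene pair
#'
#' Builds the sample-level 2x2 table (mutated / wild-type in each gene)
#' and applies the two-sided Fisher exact test (minimum-likelihood
#' convention: the p-value sums hypergeometric probabilities of tables no
#' more likely than the observed one).
#'
#' @param catalog A `mutation_catalog`.
#' @param gene_a,gene_b Gene symbols (zero mutated samples allowed).
#' @param n_samples Cohort sample count; must be at least the size of the
#'   union of mutated samples.
#' @return List with `table` (2x2), `odds_ratio` (conditional MLE; `NA`
#'   with `or_undefined = TRUE` when a margin is empty) and `p` (two-sided).
#' @export
cooccurrence_test <- function(catalog, gene_a, gene_b, n_samples) {
  sa <- unique(catalog$sample[catalog$gene == gene_a])
  sb <- unique(catalog$sample[catalog$gene == gene_b])
  if (n_samples < length(union(sa, sb)))
    stopf("n_samples (%d) smaller than the union of mutated samples (%d)",
          n_samples, length(union(sa, sb)))
  both <- length(intersect(sa, sb))
  tab <- matrix(c(both, length(sb) - both,
                  length(sa) - both,
                  n_samples - length(union(sa, sb))),
                nrow = 2,
                dimnames = list(c("B_mut", "B_wt"), c("A_mut", "A_wt")))
  ft <- fisher.test(tab)
  undef <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
  list(table = tab,
       odds_ratio = if (undef) NA_real_ else unname(ft$estimate),
       or_undefined = undef,
       p = if (undef) 1 else ft$p.value)
}

#' SCNA cis-effects on protein abundance
#'
#' Correlates per-gene copy-number states (GISTIC-thresholded integers in
#' -2..2) with protein abundance across shared samples using Spearman rank
#' correlation, with Benjamini-Hochberg adjustment over tested genes.
#' Genes whose copy state (or abundance) is constant over complete pairs
#' are flagged undefined and excluded from the adjustment, as are genes
#' exceeding the missingness ceiling.
#'
#' @param scna Genes x samples integer matrix with values in -2..2.
#' @param expr Features x samples abundance matrix (`NA` = missing);
#'   rownames shared with `scna` define the common genes.
#' @param max_na_frac Maximum fraction of missing abundance values per
#'   gene (default 2/3, i.e. genes with < 66.7 percent missing are tested).
#' @param min_pairs Minimum complete pairs per gene (default 3).
#' @return Data frame `gene`, `n`, `rho`, `p`, `fdr`, `undefined`.
#' @export
scna_cis_effects <- function(scna, expr, max_na_frac = 2 / 3,
                             min_pairs = 3L) {
  assert_matrix(scna, "scna"); assert_matrix(expr, "expr")
  if (!all(scna %in% -2:2 | is.na(scna)))
    stopf("scna values must be integer states in -2..2")
  genes <- intersect(rownames(scna), rownames(expr))
  samples <- intersect(colnames(scna), colnames(expr))
  if (!length(genes))
    return(data.frame(gene = character(0), n = integer(0),
                      rho = numeric(0), p = numeric(0), fdr = numeric(0),
                      undefined = logical(0)))
  if (length(samples) < min_pairs) stopf("fewer than %d shared samples", min_pairs)
  res <- lapply(genes, function(g) {
    cs <- scna[g, samples]; ab <- expr[g, samples]
    ok <- !is.na(cs) & !is.na(ab)
    if (mean(is.na(ab)) >= max_na_frac || sum(ok) < min_pairs)
      return(c(n = sum(ok), rho = NA, p = NA, undef = 1))
    if (length(unique(cs[ok])) < 2L || length(unique(ab[ok])) < 2L)
      return(c(n = sum(ok), rho = NA, p = NA, undef = 1))
    ct <- suppressWarnings(
      cor.test(cs[ok], ab[ok], method = "spearman", exact = FALSE))
    c(n = sum(ok), rho = unname(ct$estimate), p = ct$p.value, undef = 0)
  })
  m <- do.call(rbind, res)
  out <- data.frame(gene = genes, n = as.integer(m[, "n"]),
                    rho = m[, "rho"], p = m[, "p"],
                    fdr = NA_real_, undefined = m[, "undef"] == 1,
                    stringsAsFactors = FALSE)
  tested <- !out$undefined
  out$fdr[tested] <- p.adjust(out$p[tested], method = "BH")
  rownames(out) <- NULL
  out
}
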