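#' Adjust phosphosite abundance by the protein counterpart
#'
#' Divides each phosphosite's abundance by its parent protein's abundance
#' in the same sample (linear scale), removing total-protein trends from
#' the phosphorylation signal. Sites whose protein is not quantified pass
#' through unadjusted and are flagged; sites with a zero counterpart in a
#' sample become `NA` (unstable ratio).
#'
#' @param phospho Sites x samples matrix; site ids `"GENE_S123"` style
#'   unless `site_map` is given.
#' @param protein Proteins x samples matrix (gene symbols as rownames).
#' @param site_map Optional data frame `site`, `protein`; by default the
#'   protein is the site id up to the last underscore.
#' @return Adjusted matrix with attributes `unadjusted` (site ids passed
#'   through) and `unstable` (count of zero-counterpart cells).
#' @export
adjust_phospho <- function(phospho, protein, site_map = NULL) {
  assert_matrix(phospho, "phospho"); assert_matrix(protein, "protein")
  samples <- intersect(colnames(phospho), colnames(protein))
  if (!length(samples)) stopf("no shared samples")
  prot_of <- if (is.null(site_map)) {
    sub("_[^_]+$", "", rownames(phospho))
  } else {
    site_map$protein[match(rownames(phospho), site_map$site)]
  }
  out <- phospho[, samples, drop = FALSE]
  unadj <- character(0)
  unstable <- 0L
  for (i in seq_len(nrow(out))) {
    p <- prot_of[i]
    if (is.na(p) || !p %in% rownames(protein)) {
      unadj <- c(unadj, rownames(out)[i])
      next
    }
    denom <- protein[p, samples]
    zero <- !is.na(denom) & denom == 0
    unstable <- unstable + sum(zero & !is.na(out[i, ]))
    denom[zero] <- NA
    out[i, ] <- out[i, ] / denom
  }
  attr(out, "unadjusted") <- unadj
  attr(out, "unstable") <- unstable
  out
}

#' Filter phosphosites by observation prevalence
#'
#' Retains sites observed (non-missing) in at least `min_frac` of the
#' samples.
#'
#' @param phospho Sites x samples matrix.
#' @param min_frac Minimum observed fraction, default 0.3.
#' @return Filtered matrix.
#' @export
site_prevalence_filter <- function(phospho, min_frac = 0.3) {
  assert_matrix(phospho, "phospho")
  keep <- rowMeans(!is.na(phospho)) >= min_frac
  phospho[keep, , drop = FALSE]
}

#' Kinase-substrate enrichment analysis (KSEA)
#'
#' For each kinase, compares the mean log2 fold change of its quantified
#' substrate sites against the global site distribution:
#' z = (mean_substrates - mean_all) * sqrt(m) / sd_all, with m the
#' quantified substrate count; two-sided normal p-values with
#' Benjamini-Hochberg adjustment over reported kinases.
#'
#' @param site_log2fc Named numeric vector of per-site log2 fold changes.
#' @param ks_map Data frame `kinase`, `site` (one substrate per row).
#' @param min_m Minimum quantified substrate count to report, default 3.
#' @return A `kinase_activity_table` data frame: `kinase`, `m`,
#'   `mean_log2fc`, `z`, `p`, `fdr`, ordered by decreasing |z|.
#' @export
ksea <- function(site_log2fc, ks_map, min_m = 3L) {
  fc <- site_log2fc[is.finite(site_log2fc)]
  if (!length(fc)) stopf("no finite site fold changes")
  if (is.null(names(fc))) stopf("site_log2fc must be named by site id")
  mu <- mean(fc)
  delta <- sd(fc)
  if (!is.finite(delta) || delta == 0)
    stopf("degenerate input: site fold changes have zero dispersion")
  kin <- split(ks_map$site, ks_map$kinase)
  rows <- lapply(names(kin), function(k) {
    subs <- intersect(unique(kin[[k]]), names(fc))
    m <- length(subs)
    if (m < min_m) return(NULL)
    ms <- mean(fc[subs])
    z <- (ms - mu) * sqrt(m) / delta
    data.frame(kinase = k, m = m, mean_log2fc = ms, z = z,
               p = 2 * pnorm(-abs(z)), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(structure(data.frame(kinase = character(0), m = integer(0),
                                mean_log2fc = numeric(0), z = numeric(0),
                                p = numeric(0), fdr = numeric(0)),
                     class = c("kinase_activity_table", "data.frame")))
  out$fdr <- p.adjust(out$p, method = "BH")
  out <- out[order(-abs(out$z)), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("kinase_activity_table", "data.frame")
  out
}

#' Stage-resolved kinase and substrate trends
#'
#' Computes, per stage (or other grouping level), each site's log2 fold
#' change of that group versus the rest and the resulting KSEA z-profile
#' per kinase; in parallel, a differential table of the kinases' own
#' protein abundance. A kinase is reported concordant when the sign of
#' its substrate z-profile agrees with the sign of its own abundance
#' contrast across groups.
#'
#' @param phospho Adjusted sites x samples matrix (linear scale).
#' @param protein Proteins x samples matrix (kinase abundances; linear
#'   scale).
#' @param annotations Sample annotations with `sample` and the grouping
#'   column.
#' @param ks_map Data frame `kinase`, `site`.
#' @param grouping Grouping column, default `"stage"`.
#' @param min_m Minimum substrates per kinase, default 3.
#' @param floor Floor applied before taking log2, default `1e-5`.
#' @return List with `z_profile` (kinases x groups), `kinase_dep`
#'   (a `dep_table` for kinase proteins present in `protein`),
#'   `concordance` (data frame kinase, agreement fraction), `skipped`
#'   (kinases absent from the protein matrix).
#' @export
kinase_substrate_trends <- function(phospho, protein, annotations, ks_map,
                                    grouping = "stage", min_m = 3L,
                                    floor = 1e-5) {
  ann <- annotations[match(colnames(phospho), annotations$sample), ]
  g <- factor(ann[[grouping]])
  lp <- log2(apply_floor(phospho, floor, impute_missing = FALSE))
  zprof <- NULL
  for (lev in levels(g)) {
    fc <- rowMeans(lp[, g == lev, drop = FALSE], na.rm = TRUE) -
      rowMeans(lp[, g != lev, drop = FALSE], na.rm = TRUE)
    kt <- ksea(fc, ks_map, min_m = min_m)
    zcol <- setNames(kt$z, kt$kinase)
    zprof <- if (is.null(zprof)) data.frame(row.names = names(zcol),
                                            lev = zcol, check.names = FALSE)
             else {
               all_k <- union(rownames(zprof), names(zcol))
               zprof <- zprof[match(all_k, rownames(zprof)), , drop = FALSE]
               rownames(zprof) <- all_k
               zprof[[lev]] <- zcol[match(all_k, names(zcol))]
               zprof
             }
    names(zprof)[names(zprof) == "lev"] <- lev
  }
  zprof <- as.matrix(zprof)
  kinases <- rownames(zprof)
  present <- kinases[kinases %in% rownames(protein)]
  skipped <- setdiff(kinases, present)
  if (length(skipped))
    warnf("kinase(s) absent from protein matrix, skipped: %s",
          paste(skipped, collapse = ", "))
  kdep <- NULL; conc <- NULL
  if (length(present)) {
    kmat <- protein[present, colnames(phospho), drop = FALSE]
    kdep <- stage_dep(kmat, annotations, grouping = grouping)
    lk <- log2(apply_floor(kmat, floor))
    conc <- data.frame(kinase = present, agreement = vapply(present,
      function(k) {
        prof <- vapply(levels(g), function(lev)
          mean(lk[k, g == lev], na.rm = TRUE) -
            mean(lk[k, g != lev], na.rm = TRUE), 0)
        z <- zprof[k, levels(g)]
        ok <- is.finite(prof) & is.finite(z) & (prof != 0 | z != 0)
        if (!any(ok)) return(NA_real_)
        mean(sign(prof[ok]) == sign(z[ok]))
      }, 0), stringsAsFactors = FALSE)
  }
  list(z_profile = zprof, kinase_dep = kdep, concordance = conc,
       skipped = skipped)
}
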