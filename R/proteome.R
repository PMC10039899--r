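#' FOT normalization of an iBAQ abundance matrix
#'
#' Converts per-sample iBAQ intensities to fraction-of-total (FOT): each
#' observed value is divided by the column total over observed entries, so
#' every sample's observed values sum to one.
#'
#' @param mat Features x samples nonnegative matrix, `NA` = missing.
#' @return Matrix of the same shape on the FOT scale.
#' @export
fot_normalize <- function(mat) {
  assert_matrix(mat, "abundance matrix")
  if (any(mat < 0, na.rm = TRUE)) stopf("abundances must be nonnegative")
  tot <- colSums(mat, na.rm = TRUE)
  bad <- tot <= 0 | colSums(!is.na(mat)) == 0
  if (any(bad))
    stopf("sample(s) with no positive observed value: %s",
          paste(colnames(mat)[bad], collapse = ", "))
  sweep(mat, 2, tot, "/")
}

#' Floor small FOT values
#'
#' Observed values below the floor are replaced by the floor (the
#' conventional small-value adjustment for FOT matrices). Missing entries
#' are set to the floor only when `impute_missing = TRUE` (the convention
#' used by the substage-prevalence filter).
#'
#' @param mat FOT matrix.
#' @param floor Floor value, default `1e-5`.
#' @param impute_missing Also replace `NA` entries by the floor.
#' @return Floored matrix.
#' @export
apply_floor <- function(mat, floor = 1e-5, impute_missing = FALSE) {
  out <- mat
  out[!is.na(out) & out < floor] <- floor
  if (impute_missing) out[is.na(out)] <- floor
  out
}

#' Feature filtering for label-free proteomes
#'
#' Two filtering conventions for FOT matrices:
#' * `"E1"` keeps proteins supported by at least two unique strict
#'   peptides whose cohort-maximum FOT is at least the floor, after
#'   removing an optional exclusion list (e.g. keratins).
#' * `"E2"` keeps proteins identified in more than `min_frac` (strictly)
#'   of the samples of at least one substage, then floors the matrix with
#'   missing entries imputed at the floor.
#'
#' @param mat FOT matrix (features x samples).
#' @param annotations Data frame with a `sample` column matching
#'   `colnames(mat)` and a `substage` column (required for E2).
#' @param mode `"E1"` or `"E2"`.
#' @param min_peptides Named vector of unique-peptide counts per protein
#'   (required for E1).
#' @param exclude Character vector of feature ids to drop under E1.
#' @param min_frac E2 prevalence threshold (strict), default 0.2.
#' @param floor FOT floor, default `1e-5`.
#' @param all_substages Literal E2 reading: require prevalence in every
#'   substage rather than at least one. Default `FALSE`.
#' @return Filtered (and, for E2, floored) matrix.
#' @export
filter_features <- function(mat, annotations = NULL,
                            mode = c("E2", "E1"), min_peptides = NULL,
                            exclude = NULL, min_frac = 0.2, floor = 1e-5,
                            all_substages = FALSE) {
  mode <- match.arg(mode)
  assert_matrix(mat, "abundance matrix")
  if (mode == "E1") {
    if (is.null(min_peptides))
      stopf("E1 filtering requires a unique-peptide count table")
    pep <- min_peptides[rownames(mat)]
    pep[is.na(pep)] <- 0
    maxfot <- apply(mat, 1, function(x) suppressWarnings(max(x, na.rm = TRUE)))
    keep <- pep >= 2 & is.finite(maxfot) & maxfot >= floor &
      !rownames(mat) %in% (exclude %||% character(0))
    mat[keep, , drop = FALSE]
  } else {
    if (is.null(annotations) || is.null(annotations$substage))
      stopf("E2 filtering requires substage annotations")
    ann <- annotations[match(colnames(mat), annotations$sample), ]
    sub <- factor(ann$substage)
    prev <- sapply(levels(sub), function(s) {
      idx <- which(sub == s)
      rowMeans(!is.na(mat[, idx, drop = FALSE]))
    })
    prev <- matrix(prev, nrow = nrow(mat))
    keep <- if (all_substages) apply(prev > min_frac, 1, all)
            else apply(prev > min_frac, 1, any)
    apply_floor(mat[keep, , drop = FALSE], floor, impute_missing = TRUE)
  }
}

# Kruskal-Wallis H with tie correction, vectorized over features.
kw_stat <- function(x, g) {
  ok <- !is.na(x)
  x <- x[ok]; g <- droplevels(g[ok])
  if (nlevels(g) < 2L || any(table(g) < 1L)) return(c(NA, NA))
  kt <- kruskal.test(x, g)
  c(unname(kt$statistic), kt$p.value)
}

#' Stage-resolved differential expression
#'
#' Per feature, a Kruskal-Wallis rank test across the grouping (substage,
#' stage or phase), Benjamini-Hochberg adjustment over tested features,
#' and a one-vs-rest linear-scale ratio of group means. A feature is
#' flagged when its FDR clears `alpha` and its best one-vs-rest ratio
#' reaches `up` (up direction) or falls to `down` (down direction).
#'
#' @param mat Floored FOT matrix (features x samples).
#' @param annotations Data frame with `sample` plus the grouping column.
#' @param grouping Name of the grouping column, default `"substage"`.
#' @param alpha FDR threshold, default 0.05.
#' @param up,down One-vs-rest ratio thresholds (defaults 2 and 0.5).
#' @return A `dep_table` data frame: `feature`, `statistic`, `p`, `fdr`,
#'   `best_group`, `ratio_up`, `worst_group`, `ratio_down`, `direction`,
#'   `flagged`; per-group means in attribute `group_means`.
#' @export
stage_dep <- function(mat, annotations, grouping = "substage",
                      alpha = 0.05, up = 2, down = 0.5) {
  assert_matrix(mat, "abundance matrix")
  ann <- annotations[match(colnames(mat), annotations$sample), ]
  g <- factor(ann[[grouping]])
  small <- names(which(table(g) < 2L))
  if (length(small)) {
    warnf("excluding group(s) with < 2 samples: %s",
          paste(small, collapse = ", "))
    keep <- !g %in% small
    mat <- mat[, keep, drop = FALSE]
    g <- droplevels(g[keep])
  }
  if (nlevels(g) < 2L) stopf("need >= 2 groups with >= 2 samples")
  stats <- t(apply(mat, 1, kw_stat, g = g))
  gm <- t(apply(mat, 1, function(x) tapply(x, g, mean, na.rm = TRUE)))
  colnames(gm) <- levels(g)
  rest <- t(vapply(seq_len(nrow(mat)), function(i) {
    x <- mat[i, ]
    vapply(levels(g), function(l) mean(x[g != l], na.rm = TRUE), 0)
  }, numeric(nlevels(g))))
  ratio <- gm / rest
  bi <- apply(ratio, 1, function(r) if (all(is.na(r))) NA_integer_ else which.max(r))
  wi <- apply(ratio, 1, function(r) if (all(is.na(r))) NA_integer_ else which.min(r))
  ii <- seq_len(nrow(mat))
  out <- data.frame(
    feature = rownames(mat),
    statistic = stats[, 1], p = stats[, 2],
    fdr = p.adjust(stats[, 2], method = "BH"),
    best_group = levels(g)[bi],
    ratio_up = ratio[cbind(ii, bi)],
    worst_group = levels(g)[wi],
    ratio_down = ratio[cbind(ii, wi)],
    stringsAsFactors = FALSE)
  up_flag <- !is.na(out$fdr) & out$fdr < alpha & !is.na(out$ratio_up) &
    out$ratio_up >= up
  down_flag <- !is.na(out$fdr) & out$fdr < alpha & !is.na(out$ratio_down) &
    out$ratio_down <= down
  out$direction <- ifelse(up_flag, "up", ifelse(down_flag, "down", "none"))
  out$flagged <- up_flag | down_flag
  attr(out, "group_means") <- gm
  attr(out, "grouping") <- grouping
  class(out) <- c("dep_table", "data.frame")
  out
}

# Contiguity-constrained average-linkage agglomeration of ordered items.
# d is a full symmetric distance matrix; only adjacent blocks may merge.
# Returns the block membership for every cut size 1..n.
constrained_agglomerate <- function(d) {
  n <- nrow(d)
  cuts <- vector("list", n)
  blocks <- as.list(seq_len(n))
  cuts[[n]] <- rep(seq_len(n), lengths(blocks))
  while (length(blocks) > 1L) {
    m <- length(blocks)
    h <- vapply(seq_len(m - 1L), function(i)
      mean(d[blocks[[i]], blocks[[i + 1L]], drop = FALSE]), 0)
    j <- which.min(h)
    blocks[[j]] <- c(blocks[[j]], blocks[[j + 1L]])
    blocks[[j + 1L]] <- NULL
    memb <- integer(n)
    for (b in seq_along(blocks)) memb[blocks[[b]]] <- b
    cuts[[length(blocks)]] <- memb
  }
  cuts
}

mean_silhouette <- function(d, memb) {
  n <- length(memb)
  if (length(unique(memb)) < 2L) return(-Inf)
  s <- vapply(seq_len(n), function(i) {
    own <- memb == memb[i]; own[i] <- FALSE
    a <- if (any(own)) mean(d[i, own]) else 0
    b <- min(vapply(setdiff(unique(memb), memb[i]), function(k)
      mean(d[i, memb == k]), 0))
    if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }, 0)
  mean(s)
}

#' Build co-expression wave panels from substage-high proteins
#'
#' For each substage, the proteins flagged high there (from
#' [stage_dep()]) define a substage-high set; its mean expression profile
#' over substages is the substage's fingerprint. Substages are clustered
#' by 1 - Pearson correlation of these fingerprints under a contiguity
#' constraint (only adjacent substages may merge), and the tree is cut
#' into panels; proteins are assigned to the panel of their defining
#' substage. Substages with an empty high set inherit their overall mean
#' profile and are recorded in attribute `empty_substages`.
#'
#' @param mat Floored FOT matrix used for the profiles.
#' @param annotations Sample annotations with `sample` and the grouping
#'   column used by `dep`.
#' @param dep A `dep_table` from [stage_dep()].
#' @param n_panels Number of panels; `NULL` selects the contiguous cut
#'   with the best mean silhouette.
#' @param substage_order Optional explicit ordering of the substages;
#'   defaults to the factor level order of the grouping column.
#' @return A `wave_panels` object: `substages` (data frame substage,
#'   panel), `proteins` (data frame protein, substage, panel),
#'   `n_panels`, `profiles`.
#' @export
build_waves <- function(mat, annotations, dep, n_panels = NULL,
                        substage_order = NULL) {
  grouping <- attr(dep, "grouping") %||% "substage"
  ann <- annotations[match(colnames(mat), annotations$sample), ]
  g <- factor(ann[[grouping]],
              levels = substage_order %||% levels(factor(ann[[grouping]])))
  subs <- levels(g)
  gm <- t(apply(mat, 1, function(x) tapply(x, g, mean, na.rm = TRUE)))
  colnames(gm) <- subs
  high <- lapply(subs, function(s)
    dep$feature[dep$flagged & dep$direction == "up" &
                  !is.na(dep$best_group) & dep$best_group == s])
  names(high) <- subs
  empty <- subs[lengths(high) == 0L]
  prof <- t(vapply(subs, function(s) {
    feats <- high[[s]]
    if (!length(feats)) colMeans(gm) else
      colMeans(gm[feats, , drop = FALSE])
  }, numeric(length(subs))))
  if (length(empty))
    warnf("substage(s) with empty high set use the global profile: %s",
          paste(empty, collapse = ", "))
  cc <- suppressWarnings(cor(t(prof)))
  cc[is.na(cc)] <- 1
  d <- 1 - cc
  cuts <- constrained_agglomerate(d)
  if (is.null(n_panels)) {
    sil <- vapply(2:max(2L, length(subs) - 1L), function(k)
      mean_silhouette(d, cuts[[k]]), 0)
    n_panels <- (2:max(2L, length(subs) - 1L))[which.max(sil)]
  }
  if (n_panels < 1L || n_panels > length(subs))
    stopf("n_panels must be in 1..%d", length(subs))
  memb <- cuts[[n_panels]]
  sub_tab <- data.frame(substage = subs, panel = memb,
                        stringsAsFactors = FALSE)
  prot <- do.call(rbind, lapply(subs, function(s) {
    feats <- high[[s]]
    if (!length(feats)) return(NULL)
    data.frame(protein = feats, substage = s,
               panel = memb[match(s, subs)], stringsAsFactors = FALSE)
  }))
  prot <- prot %||% data.frame(protein = character(0),
                               substage = character(0), panel = integer(0))
  structure(list(substages = sub_tab, proteins = prot,
                 n_panels = n_panels, profiles = prof),
            class = "wave_panels",
            empty_substages = empty)
}

#' @export
print.wave_panels <- function(x, ...) {
  cat("<wave_panels>", x$n_panels, "panels over",
      nrow(x$substages), "substages;", nrow(x$proteins), "proteins\n")
  print(x$substages, row.names = FALSE)
  invisible(x)
}

# SAM d-statistic: (mean2 - mean1) / (s + s0), s the unequal-variance
# standard error.
sam_d <- function(mat, g1, g2, s0) {
  m1 <- rowMeans(mat[, g1, drop = FALSE])
  m2 <- rowMeans(mat[, g2, drop = FALSE])
  v1 <- apply(mat[, g1, drop = FALSE], 1, var)
  v2 <- apply(mat[, g2, drop = FALSE], 1, var)
  s <- sqrt(v1 / length(g1) + v2 / length(g2))
  list(d = (m2 - m1) / (s + s0), s = s)
}

# Tusher-style fudge factor: the percentile of s minimizing the
# coefficient of variation of window-wise MADs of d.
sam_s0_auto <- function(r, s) {
  cand <- quantile(s, seq(0, 1, by = 0.05), names = FALSE)
  qs <- quantile(s, seq(0, 1, by = 0.01), names = FALSE)
  win <- cut(s, unique(qs), include.lowest = TRUE)
  cv <- vapply(cand, function(s0) {
    d <- r / (s + s0)
    v <- tapply(d, win, mad)
    v <- v[!is.na(v)]
    if (mean(v) == 0) Inf else sd(v) / mean(v)
  }, 0)
  cand[which.min(cv)]
}

#' Significance analysis of microarrays (two-class unpaired)
#'
#' Computes the SAM d-statistic d = (mean2 - mean1) / (s + s0) per
#' feature, with the fudge factor s0 chosen by the coefficient-of-
#' variation-minimizing percentile rule when `"auto"`. Expected order
#' statistics come from label permutations (exhaustive when fewer
#' distinct permutations exist than requested); features are called where
#' the sorted d departs from its expectation by more than `delta`, and
#' the permutation FDR is the median count of permuted d-values beyond
#' the call cutoffs divided by the number of calls. When `fdr_target` is
#' given instead of `delta`, the smallest delta meeting the target is
#' selected.
#'
#' @param mat Features x samples matrix (typically log2 scale).
#' @param labels Two-level factor/character over samples.
#' @param s0 Fudge factor, or `"auto"`.
#' @param n_perm Number of label permutations.
#' @param delta Call threshold on |sorted d - expected d|.
#' @param fdr_target If set, pick the smallest delta with estimated FDR
#'   below this value.
#' @param seed RNG seed for the permutations.
#' @return A list of class `sam_result`: `table` (feature, d, expected d,
#'   called, direction), `s0`, `delta`, `fdr`, `cutoffs`.
#' @export
sam_two_class <- function(mat, labels, s0 = "auto", n_perm = 200L,
                          delta = NULL, fdr_target = NULL, seed = 1L) {
  assert_matrix(mat, "matrix")
  lab <- factor(labels)
  if (nlevels(lab) != 2L) stopf("labels must have exactly two levels")
  g1 <- which(lab == levels(lab)[1L]); g2 <- which(lab == levels(lab)[2L])
  if (length(g1) < 2L || length(g2) < 2L)
    stopf("each group needs >= 2 samples")
  base <- sam_d(mat, g1, g2, 0)
  s0v <- if (identical(s0, "auto")) sam_s0_auto(base$d * base$s, base$s)
         else as.numeric(s0)
  d <- sam_d(mat, g1, g2, s0v)$d
  n <- ncol(mat)
  n_distinct <- choose(n, length(g1))
  perms <- if (n_perm >= n_distinct) {
    combn(n, length(g1), simplify = FALSE)
  } else {
    withr::with_seed(derive_seed(seed, 7L), replicate(
      n_perm, sample(n, length(g1)), simplify = FALSE))
  }
  dstar <- vapply(perms, function(p1)
    sort(sam_d(mat, p1, setdiff(seq_len(n), p1), s0v)$d),
    numeric(nrow(mat)))
  dbar <- rowMeans(dstar)
  ord <- order(d)
  dsort <- d[ord]
  eval_delta <- function(del) {
    calls <- abs(dsort - dbar) > del
    up <- calls & dsort > dbar
    dn <- calls & dsort < dbar
    cutup <- if (any(up)) min(dsort[up]) else Inf
    cutlo <- if (any(dn)) max(dsort[dn]) else -Inf
    ncalled <- sum(calls)
    if (ncalled == 0L) return(list(calls = calls, fdr = 0,
                                   cutoffs = c(cutlo, cutup)))
    false <- colSums(dstar >= cutup) + colSums(dstar <= cutlo)
    list(calls = calls, fdr = min(1, median(false) / ncalled),
         cutoffs = c(cutlo, cutup))
  }
  if (is.null(delta) && !is.null(fdr_target)) {
    grid <- sort(unique(quantile(abs(dsort - dbar),
                                 seq(0, 1, length.out = 201),
                                 names = FALSE)))
    delta <- Inf
    for (del in grid) {
      ev <- eval_delta(del)
      if (sum(ev$calls) > 0L && ev$fdr < fdr_target) { delta <- del; break }
    }
  }
  if (is.null(delta)) delta <- 0
  ev <- eval_delta(delta)
  called <- logical(nrow(mat)); called[ord] <- ev$calls
  tab <- data.frame(feature = rownames(mat), d = d, expected_d = NA_real_,
                    called = called,
                    direction = ifelse(d > 0, "up", "down"),
                    stringsAsFactors = FALSE)
  tab$expected_d[ord] <- dbar
  structure(list(table = tab, s0 = s0v, delta = delta, fdr = ev$fdr,
                 cutoffs = ev$cutoffs, n_perm = length(perms)),
            class = "sam_result")
}

#' @export
print.sam_result <- function(x, ...) {
  cat("<sam_result> s0 =", signif(x$s0, 4), " delta =", signif(x$delta, 4),
      " calls =", sum(x$table$called), " FDR =", signif(x$fdr, 3), "\n")
  invisible(x)
}

#' Consensus clustering by subsampled k-means
#'
#' For each candidate k, repeatedly subsamples `ceiling(p_item * n)`
#' samples without replacement, runs k-means on Euclidean distance, and
#' accumulates the consensus matrix consensus(i, j) = co-clustered count
#' / co-sampled count. The number of clusters is chosen by the largest
#' relative increase of the area under the consensus CDF (k = 2 scored by
#' its absolute area); final labels come from average-linkage
#' hierarchical clustering of 1 - consensus.
#'
#' @param mat Features x samples matrix; samples are clustered.
#' @param k_range Candidate cluster numbers, default `2:10`.
#' @param reps Subsampling repetitions per k, default 1000.
#' @param p_item Sample subsampling proportion, default 0.8.
#' @param seed RNG seed.
#' @return A `consensus_result`: `consensus` (list per k), `auc`,
#'   `delta_auc`, `chosen_k`, `labels` (per k), `empty_restarts`.
#' @export
consensus_cluster <- function(mat, k_range = 2:10, reps = 1000L,
                              p_item = 0.8, seed = 1L) {
  assert_matrix(mat, "matrix")
  n <- ncol(mat)
  if (n < 2L * max(k_range)) stopf("need at least 2 * max(k) samples")
  X <- t(mat)
  m <- ceiling(p_item * n)
  cons <- labels <- list()
  auc <- setNames(numeric(length(k_range)), paste0("k", k_range))
  empty_events <- 0L
  for (ki in seq_along(k_range)) {
    k <- k_range[ki]
    M <- I <- matrix(0, n, n)
    for (r in seq_len(reps)) {
      km <- withr::with_seed(derive_seed(seed, ki * 100000L + r), {
        idx <- sample(n, m)
        cl <- NULL
        for (try in 1:5) {
          cl <- tryCatch(kmeans(X[idx, , drop = FALSE], centers = k,
                                nstart = 1, iter.max = 100),
                         error = function(e) NULL)
          if (!is.null(cl)) break
          empty_events <- empty_events + 1L
        }
        list(idx = idx, cluster = cl$cluster)
      })
      if (is.null(km$cluster)) next
      idx <- km$idx
      I[idx, idx] <- I[idx, idx] + 1
      same <- outer(km$cluster, km$cluster, "==")
      M[idx, idx] <- M[idx, idx] + same
    }
    C <- ifelse(I > 0, M / I, 0)
    diag(C) <- 1
    dimnames(C) <- list(colnames(mat), colnames(mat))
    cons[[ki]] <- C
    v <- sort(C[upper.tri(C)])
    # area under the empirical CDF of consensus values over [0, 1]
    cdf <- ecdf_area(v)
    auc[ki] <- cdf
    hc <- hclust(as.dist(1 - C), method = "average")
    labels[[ki]] <- cutree(hc, k)
  }
  names(cons) <- names(labels) <- paste0("k", k_range)
  delta <- numeric(length(k_range))
  delta[1] <- auc[1]
  if (length(k_range) > 1)
    delta[-1] <- diff(auc) / auc[-length(auc)]
  names(delta) <- names(auc)
  chosen <- k_range[which.max(delta)]
  structure(list(consensus = cons, auc = auc, delta_auc = delta,
                 chosen_k = chosen, labels = labels,
                 empty_restarts = empty_events, k_range = k_range),
            class = "consensus_result")
}

ecdf_area <- function(v) {
  # trapezoid-free exact area under the step CDF on [0, 1]
  n <- length(v)
  if (n == 0L) return(0)
  x <- c(0, sort(v), 1)
  F <- c(0, seq_len(n) / n, 1)
  sum(F[-length(F)] * diff(x))
}

#' @export
print.consensus_result <- function(x, ...) {
  cat("<consensus_result> chosen k =", x$chosen_k, "\n")
  print(round(rbind(auc = x$auc, delta = x$delta_auc), 4))
  invisible(x)
}

#' Match-between-runs retention-time imputation
#'
#' Transfers peptide quantifications from a donor (reference) run into
#' runs where the peptide was not identified. For each acceptor run a
#' retention-time map is regressed on the peptides identified in both
#' runs: a linear fit first, then a quadratic fit if the linear R^2 falls
#' below `r2_threshold`, keeping the better model. For each donor-only
#' peptide the acceptor RT is predicted, and an unidentified acceptor
#' feature within the m/z tolerance (ppm) and RT tolerance is transferred
#' as an MBR-imputed identification (flagged `"mbr"`).
#'
#' @param features Data frame with columns `run`, `peptide`, `mz`, `rt`,
#'   `intensity`, `identified` (logical).
#' @param reference_run Donor run id.
#' @param r2_threshold Linear-fit adequacy threshold, default 0.995.
#' @param mz_tol_ppm m/z tolerance in parts per million, default 10.
#' @param rt_tol Absolute RT tolerance (same units as `rt`), default 1.
#' @param min_shared Minimum shared identified peptides per run pair,
#'   default 6; pairs below it are skipped with a warning.
#' @return The feature table with transferred rows marked
#'   `source = "mbr"` (original rows `source = "direct"`); per-run model
#'   summaries in attribute `rt_models`.
#' @export
mbr_impute <- function(features, reference_run, r2_threshold = 0.995,
                       mz_tol_ppm = 10, rt_tol = 1, min_shared = 6L) {
  need <- c("run", "peptide", "mz", "rt", "intensity", "identified")
  miss <- setdiff(need, names(features))
  if (length(miss)) stopf("missing feature column(s): %s",
                          paste(miss, collapse = ", "))
  features$source <- "direct"
  donor <- features[features$run == reference_run & features$identified, ]
  if (!nrow(donor)) stopf("reference run has no identified peptides")
  models <- list()
  out <- features
  for (acc in setdiff(unique(features$run), reference_run)) {
    acc_all <- features[features$run == acc, ]
    acc_id <- acc_all[acc_all$identified, ]
    shared <- intersect(donor$peptide, acc_id$peptide)
    if (length(shared) < min_shared) {
      warnf("run pair (%s, %s): only %d shared peptides, skipped",
            reference_run, acc, length(shared))
      next
    }
    x <- donor$rt[match(shared, donor$peptide)]
    y <- acc_id$rt[match(shared, acc_id$peptide)]
    fit_lin <- lm(y ~ x)
    r2_lin <- summary(fit_lin)$r.squared
    fit <- fit_lin; kind <- "linear"; r2 <- r2_lin
    if (r2_lin < r2_threshold) {
      fit_quad <- lm(y ~ x + I(x^2))
      r2_quad <- summary(fit_quad)$r.squared
      if (r2_quad > r2_lin) { fit <- fit_quad; kind <- "quadratic"; r2 <- r2_quad }
    }
    models[[acc]] <- list(model = kind, r2 = r2)
    hidden <- donor[!donor$peptide %in% acc_id$peptide, ]
    if (!nrow(hidden)) next
    pool <- acc_all[!acc_all$identified, ]
    for (i in seq_len(nrow(hidden))) {
      rt_pred <- unname(predict(fit, data.frame(x = hidden$rt[i])))
      if (!nrow(pool)) next
      dm <- abs(pool$mz - hidden$mz[i]) / hidden$mz[i] * 1e6
      dr <- abs(pool$rt - rt_pred)
      cand <- which(dm <= mz_tol_ppm & dr <= rt_tol)
      if (!length(cand)) next
      j <- cand[which.min(dr[cand])]
      row <- pool[j, ]
      row$peptide <- hidden$peptide[i]
      row$identified <- TRUE
      row$source <- "mbr"
      out <- rbind(out, row)
      pool <- pool[-j, , drop = FALSE]
    }
  }
  rownames(out) <- NULL
  attr(out, "rt_models") <- models
  out
}
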