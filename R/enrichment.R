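#' Read a GMT gene-set file
#'
#' Tab-separated lines: set name, description, member ids.
#'
#' @param path File path.
#' @return Named list of character vectors; descriptions in attribute
#'   `description`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3L
  if (any(bad)) stopf("malformed GMT line(s): %s",
                      paste(which(bad), collapse = ", "))
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, "", 1L)
  attr(sets, "description") <- setNames(vapply(parts, `[[`, "", 2L),
                                        names(sets))
  sets
}

#' Over-representation analysis (hypergeometric test)
#'
#' For each gene set, the upper-tail hypergeometric probability of
#' observing at least the overlap between the hit list and the set within
#' the universe, with Benjamini-Hochberg adjustment across sets. The
#' differential score `q_signed` is the signed -log10 FDR
#' (sign from `direction`).
#'
#' @param hits Character vector of hit features (must lie in `universe`).
#' @param sets Named list of gene sets (intersected with the universe;
#'   sets empty after intersection are dropped with a warning).
#' @param universe Character vector of all testable features.
#' @param direction +1 or -1, the sign attached to `q_signed`.
#' @return Data frame `set`, `size`, `overlap`, `p`, `fdr`, `q_signed`.
#' @export
ora_test <- function(hits, sets, universe, direction = 1) {
  universe <- unique(universe)
  if (!length(universe)) stopf("empty universe")
  if (!all(hits %in% universe)) stopf("hits must be a subset of the universe")
  hits <- unique(hits)
  sets <- lapply(sets, intersect, universe)
  empty <- lengths(sets) == 0L
  if (any(empty)) {
    warnf("dropping empty set(s) after universe intersection: %s",
          paste(names(sets)[empty], collapse = ", "))
    sets <- sets[!empty]
  }
  N <- length(universe); n <- length(hits)
  out <- data.frame(
    set = names(sets),
    size = lengths(sets),
    overlap = vapply(sets, function(s) length(intersect(s, hits)), 0L),
    stringsAsFactors = FALSE)
  out$p <- phyper(out$overlap - 1L, out$size, N - out$size, n,
                  lower.tail = FALSE)
  out$fdr <- p.adjust(out$p, method = "BH")
  out$q_signed <- sign(direction) * -log10(out$fdr)
  rownames(out) <- NULL
  out
}

# Weighted running-sum enrichment score of one set over a ranked list.
# Returns ES and the running sum.
gsea_es <- function(rank_names, scores, set, weight = 1) {
  N <- length(rank_names)
  inset <- rank_names %in% set
  m <- sum(inset)
  if (m == 0L || m >= N) return(list(es = NA_real_, running = numeric(N)))
  w <- abs(scores)^weight
  hit <- ifelse(inset, w, 0)
  hitsum <- sum(hit)
  if (hitsum == 0) hit[inset] <- 1 / m else hit <- hit / hitsum
  miss <- ifelse(inset, 0, 1 / (N - m))
  running <- cumsum(hit - miss)
  es <- running[which.max(abs(running))]
  list(es = es, running = running)
}

#' Preranked gene-set enrichment analysis
#'
#' Computes the weighted Kolmogorov-Smirnov-like running-sum enrichment
#' score for each set over a ranked feature list (hit increments
#' proportional to |score|^weight, miss decrements 1/(N - m)), with
#' gene-label permutations for significance: NES = ES / mean(|permuted
#' ES| of the same sign), nominal p by the same-sign permutation tail
#' (reported with the (r + 1) / (n + 1) lower bound, never exactly 0),
#' and FDR by the pooled positive/negative null convention. Ties in the
#' ranking are broken by stable feature order.
#'
#' @param scores Named numeric vector of ranking scores (any order; will
#'   be sorted decreasing).
#' @param sets Named list of feature sets.
#' @param weight Score weight, default 1 (0 gives the unweighted KS
#'   statistic).
#' @param n_perm Gene-label permutations, default 1000 (values below 100
#'   draw a warning).
#' @param seed RNG seed.
#' @param min_size,max_size Set-size bounds after intersection with the
#'   ranked list.
#' @return Data frame `set`, `size`, `es`, `nes`, `p`, `fdr`,
#'   `leading_edge` (comma-separated members).
#' @export
gsea_preranked <- function(scores, sets, weight = 1, n_perm = 1000L,
                           seed = 1L, min_size = 2L, max_size = 500L) {
  if (is.null(names(scores))) stopf("scores must be named")
  if (any(!is.finite(scores))) stopf("ranking scores must be finite")
  if (n_perm < 100L) warnf("n_perm < 100 gives unstable estimates")
  ord <- order(-scores, seq_along(scores))   # stable tie-break
  rk <- names(scores)[ord]
  sc <- unname(scores[ord])
  N <- length(rk)
  sets <- lapply(sets, intersect, rk)
  sizes <- lengths(sets)
  if (any(sizes > N)) stopf("a set is larger than the ranked list")
  keep <- sizes >= min_size & sizes <= max_size
  sets <- sets[keep]
  if (!length(sets))
    return(data.frame(set = character(0), size = integer(0),
                      es = numeric(0), nes = numeric(0), p = numeric(0),
                      fdr = numeric(0), leading_edge = character(0)))
  obs <- lapply(sets, function(s) gsea_es(rk, sc, s, weight))
  es <- vapply(obs, `[[`, 0, "es")
  # permutation null per set size (gene-label permutation = random set)
  uniq_m <- unique(lengths(sets))
  null_es <- withr::with_seed(derive_seed(seed, 13L), {
    out <- list()
    for (m in uniq_m) {
      out[[as.character(m)]] <- vapply(seq_len(n_perm), function(i)
        gsea_es(rk, sc, sample(rk, m), weight)$es, 0)
    }
    out
  })
  nes <- p <- numeric(length(sets))
  null_nes <- list()
  for (i in seq_along(sets)) {
    nn <- null_es[[as.character(length(sets[[i]]))]]
    same <- if (es[i] >= 0) nn[nn >= 0] else nn[nn < 0]
    denom <- mean(abs(same))
    nes[i] <- if (length(same) && denom > 0) es[i] / denom else NA_real_
    p[i] <- if (length(same))
      (sum(abs(same) >= abs(es[i])) + 1) / (length(same) + 1) else NA_real_
    null_nes[[i]] <- if (length(same) && denom > 0) nn / denom else numeric(0)
  }
  pooled <- unlist(null_nes)
  fdr <- vapply(seq_along(sets), function(i) {
    if (is.na(nes[i])) return(NA_real_)
    if (nes[i] >= 0) {
      num <- mean(pooled >= nes[i])
      den <- mean(nes[!is.na(nes)] >= nes[i])
    } else {
      num <- mean(pooled <= nes[i])
      den <- mean(nes[!is.na(nes)] <= nes[i])
    }
    if (den == 0) return(NA_real_)
    min(1, max(num, 1 / (n_perm + 1)) / den)
  }, 0)
  lead <- vapply(seq_along(sets), function(i) {
    run <- obs[[i]]$running
    pk <- which.max(abs(run))
    inset <- rk %in% sets[[i]]
    members <- if (es[i] >= 0) rk[seq_len(pk)][inset[seq_len(pk)]]
               else rk[pk:N][inset[pk:N]]
    paste(members, collapse = ",")
  }, "")
  data.frame(set = names(sets), size = lengths(sets), es = es, nes = nes,
             p = p, fdr = fdr, leading_edge = lead,
             stringsAsFactors = FALSE, row.names = NULL)
}
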