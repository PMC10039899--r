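# Shared fixtures built in code.

# The five-record toy catalog: keys A@{S1,S2}, B@{S2,S3}, C@{S3}.
toy_catalog <- function() {
  mutation_catalog(data.frame(
    patient = "P1",
    sample = c("x1", "x2", "x2", "x3", "x3"),
    stage = c("S1", "S2", "S2", "S3", "S3"),
    gene = c("A", "A", "B", "B", "C"),
    chrom = "1",
    pos = c(10, 10, 20, 20, 30),
    ref = "C", alt = "T", context = "ACA",
    stringsAsFactors = FALSE))
}

toy_stages <- function() stage_model(c("S1", "S2", "S3"))

# Catalog with n identical-class records for one sample.
one_class_catalog <- function(n = 10, ref = "C", alt = "T",
                              context = "TCA", sample = "s1") {
  mutation_catalog(data.frame(
    patient = "P1", sample = sample, stage = "NT", gene = "G1",
    chrom = "1", pos = seq_len(n), ref = ref, alt = alt,
    context = context, stringsAsFactors = FALSE))
}

named_matrix <- function(data, nr, nc, prefix = c("f", "s")) {
  matrix(data, nr, nc,
         dimnames = list(paste0(prefix[1], seq_len(nr)),
                         paste0(prefix[2], seq_len(nc))))
}

# Brute-force two-sided Fisher p for a 2x2 table by hypergeometric
# enumeration (minimum-likelihood convention).
fisher2x2_enum <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- vapply(lo:hi, function(x)
    choose(m, x) * choose(n, k - x) / choose(m + n, k), 0)
  p_obs <- probs[tab[1, 1] - lo + 1]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Brute-force upper-tail hypergeometric P(X >= k) by enumeration.
hyper_upper_enum <- function(k, set_size, universe_size, n_hits) {
  xs <- k:min(set_size, n_hits)
  sum(vapply(xs, function(x)
    choose(set_size, x) * choose(universe_size - set_size, n_hits - x) /
      choose(universe_size, n_hits), 0))
}

# Step-up BH oracle.
bh_enum <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(1, adj)
  out
}
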