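#' @keywords internal
"_PACKAGE"

#' @importFrom stats as.dist cophenetic cor cor.test cutree dist fisher.test hclust
#'   kmeans kruskal.test lm mad median p.adjust phyper plogis pnorm predict
#'   quantile rbinom rgamma rlnorm rnorm rpois runif sd setNames var chisq.test
#'   coef rbeta
#' @importFrom utils head tail combn packageVersion
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Cosine similarity between two vectors
#'
#' @param a,b Numeric vectors of equal length.
#' @return Cosine similarity in `[-1, 1]`; `NA` if either vector has zero
#'   norm.
#' @export
cosine_sim <- function(a, b) {
  stopifnot(length(a) == length(b))
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(NA_real_)
  sum(a * b) / (na * nb)
}

# Derive a child seed from a master seed and a stream index; kept below
# 2^31 so it is always a valid R integer.
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(stream) * 16807) %% 2147483629L)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

assert_matrix <- function(x, what = "matrix") {
  if (!is.matrix(x) || !is.numeric(x))
    stopf("%s must be a numeric matrix", what)
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stopf("%s must have row and column names", what)
  invisible(x)
}
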