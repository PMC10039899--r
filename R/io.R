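#' Read a MAF-like somatic mutation TSV
#'
#' Tab-separated with a header; required columns `patient`, `sample`,
#' `stage`, `gene`, `chrom`, `pos` (1-based, fully closed), `ref`, `alt`,
#' `context`. Rows with `ref == alt` are rejected and rows with an
#' ambiguous (N) context base are skipped; both are reported with their
#' line numbers in attributes `rejected` and `skipped`.
#'
#' @param path File path.
#' @return A `mutation_catalog`.
#' @export
read_maf_like <- function(path) {
  df <- as.data.frame(data.table::fread(path, sep = "\t",
                                        colClasses = list(character = "chrom")))
  need <- c("patient", "sample", "stage", "gene", "chrom", "pos", "ref",
            "alt", "context")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("missing required column(s): %s",
                          paste(miss, collapse = ", "))
  line <- seq_len(nrow(df)) + 1L   # header is line 1
  rej <- df$ref == df$alt
  skip <- grepl("N", df$context, fixed = TRUE)
  keep <- !rej & !skip
  out <- mutation_catalog(df[keep, need, drop = FALSE])
  attr(out, "rejected") <- line[rej]
  attr(out, "skipped") <- line[skip & !rej]
  out
}

#' @rdname read_maf_like
#' @param catalog A `mutation_catalog` to write.
#' @export
write_maf_like <- function(catalog, path) {
  data.table::fwrite(as.data.frame(catalog), path, sep = "\t", na = "NA",
                     quote = FALSE)
  invisible(path)
}

#' Read / write an abundance matrix TSV
#'
#' First column holds unique feature ids; remaining columns are samples.
#' Missing cells are empty or `"NA"`; numeric parsing is strict
#' (scientific notation accepted).
#'
#' @param path File path.
#' @return Features x samples numeric matrix.
#' @export
read_matrix <- function(path) {
  dt <- data.table::fread(path, sep = "\t", na.strings = c("", "NA"))
  ids <- as.character(dt[[1L]])
  if (anyDuplicated(ids)) stopf("duplicate feature id(s): %s",
                                paste(unique(ids[duplicated(ids)]),
                                      collapse = ", "))
  m <- as.matrix(dt[, -1L, drop = FALSE])
  if (!is.numeric(m)) stopf("non-numeric cell(s) in matrix body")
  rownames(m) <- ids
  m
}

#' @rdname read_matrix
#' @param mat Matrix to write.
#' @param id_col Name for the feature-id column, default `"feature"`.
#' @export
write_matrix <- function(mat, path, id_col = "feature") {
  df <- data.table::as.data.table(mat, keep.rownames = id_col)
  data.table::fwrite(df, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' Read a sample-annotation TSV
#'
#' Requires a `sample` column; other columns (patient, substage, stage,
#' phase, ...) pass through.
#'
#' @param path File path.
#' @return Data frame.
#' @export
read_annotations <- function(path) {
  df <- as.data.frame(data.table::fread(path, sep = "\t"))
  if (!"sample" %in% names(df)) stopf("annotation file needs a 'sample' column")
  if (anyDuplicated(df$sample)) stopf("duplicate sample id(s)")
  df
}

# Write a result table with a provenance header (version, seed,
# parameter hash) as leading comment lines.
write_result <- function(df, path, seed = NA, params = list()) {
  tmp <- tempfile()
  writeLines(yaml::as.yaml(params), tmp)
  hash <- unname(tools::md5sum(tmp))
  unlink(tmp)
  hdr <- c(sprintf("# stagewave %s", as.character(packageVersion("stagewave"))),
           sprintf("# seed: %s", seed),
           sprintf("# params_md5: %s", hash))
  writeLines(hdr, path)
  data.table::fwrite(df, path, sep = "\t", na = "NA", quote = FALSE,
                     append = TRUE, col.names = TRUE)
  invisible(path)
}
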