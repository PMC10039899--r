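#' Simulate a full synthetic cohort to disk
#'
#' Writes the TSV inputs the analysis pipeline reads (mutation catalog,
#' expression matrix, phosphosite and protein matrices, kinase-substrate
#' map, SCNA matrix, sample annotations) plus ground-truth sidecar files
#' (planted panels, signature profiles, kinase shifts) for test
#' harnesses.
#'
#' @param cfg A `sim_config`.
#' @param out_dir Output directory (created if needed).
#' @param ks_map Optional kinase-substrate map; default gives each
#'   configured kinase 20 substrate sites.
#' @return Invisibly, the named list of written paths.
#' @export
simulate_cohort <- function(cfg, out_dir, ks_map = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ks_map <- ks_map %||% do.call(rbind, lapply(names(cfg$kinase_spec),
    function(k) data.frame(kinase = k,
                           site = sprintf("%sSUB%02d_S1", k, 1:20),
                           stringsAsFactors = FALSE)))
  catalog <- gen_mutation_catalog(cfg)
  expr <- gen_expression(cfg)
  phos <- gen_phospho(cfg, ks_map)
  scna <- gen_scna(cfg)
  p <- function(f) file.path(out_dir, f)
  write_maf_like(catalog, p("mutations.tsv"))
  write_matrix(expr$matrix, p("expression.tsv"))
  data.table::fwrite(expr$annotations, p("annotations.tsv"), sep = "\t",
                     quote = FALSE)
  write_matrix(phos$phospho, p("phospho.tsv"), id_col = "site")
  write_matrix(phos$protein, p("phospho_protein.tsv"))
  data.table::fwrite(ks_map, p("ks_map.tsv"), sep = "\t", quote = FALSE)
  write_matrix(scna$scna, p("scna.tsv"), id_col = "gene")
  write_matrix(scna$expr, p("scna_expression.tsv"), id_col = "gene")
  # ground-truth sidecars
  data.table::fwrite(expr$truth, p("truth_panels.tsv"), sep = "\t",
                     quote = FALSE)
  write_matrix(cfg$signature_profiles, p("truth_signatures.tsv"),
               id_col = "channel")
  shifts <- do.call(rbind, lapply(names(cfg$kinase_spec), function(k)
    data.frame(kinase = k, stage = names(cfg$kinase_spec[[k]]),
               shift = unname(cfg$kinase_spec[[k]]),
               stringsAsFactors = FALSE)))
  data.table::fwrite(shifts, p("truth_kinase_shifts.tsv"), sep = "\t",
                     quote = FALSE)
  data.table::fwrite(data.frame(gene = scna$cis_genes),
                     p("truth_cis_genes.tsv"), sep = "\t", quote = FALSE)
  invisible(list(dir = out_dir,
                 mutations = p("mutations.tsv"),
                 expression = p("expression.tsv"),
                 annotations = p("annotations.tsv"),
                 phospho = p("phospho.tsv"),
                 phospho_protein = p("phospho_protein.tsv"),
                 ks_map = p("ks_map.tsv"),
                 scna = p("scna.tsv"),
                 scna_expression = p("scna_expression.tsv")))
}

#' Run the stage-resolved analysis pipeline
#'
#' Executes the analysis stages in dependency order on a directory of
#' input TSVs (as written by [simulate_cohort()] or assembled by hand):
#' FOT normalization, substage filtering, differential expression, wave
#' panels and consensus clustering on the proteome; neo-mutation waves,
#' 96-channel spectrum, signature extraction and APOBEC enrichment on
#' the mutation catalog; counterpart adjustment and KSEA on the
#' phosphoproteome; SCNA cis-effects. Every output TSV carries a
#' provenance header (package version, seed, parameter hash). Re-running
#' with the same inputs, config and seed reproduces the outputs
#' byte-identically.
#'
#' @param config Named list (or path to a YAML file) with elements
#'   `in_dir`, `out_dir`, `seed`, and optional threshold overrides
#'   (`alpha`, `up`, `down`, `floor`, `min_frac`, `k_range`, `reps`,
#'   `p_item`, `sig_k_range`, `sig_restarts`, `n_panels`, `min_m`).
#'   Unknown keys are rejected.
#' @return Invisibly, a named list of result objects.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  known <- c("in_dir", "out_dir", "seed", "alpha", "up", "down", "floor",
             "min_frac", "k_range", "reps", "p_item", "sig_k_range",
             "sig_restarts", "n_panels", "min_m", "stages", "grouping")
  unknown <- setdiff(names(config), known)
  if (length(unknown)) stopf("unknown config key(s): %s",
                             paste(unknown, collapse = ", "))
  for (k in c("in_dir", "out_dir", "seed"))
    if (is.null(config[[k]])) stopf("config key '%s' is required", k)
  ind <- config$in_dir
  need <- c("mutations.tsv", "expression.tsv", "annotations.tsv",
            "phospho.tsv", "phospho_protein.tsv", "ks_map.tsv",
            "scna.tsv", "scna_expression.tsv")
  missing_in <- need[!file.exists(file.path(ind, need))]
  if (length(missing_in))
    stopf("missing input file(s): %s", paste(missing_in, collapse = ", "))
  seed <- as.integer(config$seed)
  alpha <- config$alpha %||% 0.05
  up <- config$up %||% 2; down <- config$down %||% 0.5
  floor <- config$floor %||% 1e-5
  min_frac <- config$min_frac %||% 0.2
  grouping <- config$grouping %||% "substage"
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  outp <- function(f) file.path(config$out_dir, f)
  hash_keys <- setdiff(sort(names(config)), c("in_dir", "out_dir"))
  wr <- function(df, f) write_result(df, outp(f), seed = seed,
                                     params = config[hash_keys])

  catalog <- read_maf_like(file.path(ind, "mutations.tsv"))
  ann <- read_annotations(file.path(ind, "annotations.tsv"))
  stages <- stage_model(config$stages %||%
                          default_stage_model()$stages)

  # genomics: neo-mutation waves + phases
  neo <- neo_mutation_gain(catalog, stages)
  wr(neo$table, "neo_waves.tsv")

  # signatures + APOBEC
  spec <- build_spectrum(catalog)
  sig <- extract_signatures(spec, k_range = config$sig_k_range %||% 2:4,
                            n_restarts = config$sig_restarts %||% 10L,
                            seed = seed)
  wr(data.table::as.data.table(sig$signatures, keep.rownames = "channel"),
     "signatures.tsv")
  wr(data.table::as.data.table(t(sig$exposures), keep.rownames = "sample"),
     "exposures.tsv")
  apo <- apobec_enrichment(catalog)
  wr(apo, "apobec.tsv")

  # proteome
  ibaq <- read_matrix(file.path(ind, "expression.tsv"))
  fot <- fot_normalize(ibaq)
  fot <- filter_features(fot, ann, mode = "E2", min_frac = min_frac,
                         floor = floor)
  dep <- stage_dep(fot, ann, grouping = grouping, alpha = alpha,
                   up = up, down = down)
  wr(dep, "dep.tsv")
  waves <- build_waves(fot, ann, dep, n_panels = config$n_panels %||% NULL)
  wr(waves$proteins, "wave_proteins.tsv")
  wr(waves$substages, "wave_substages.tsv")
  cons <- consensus_cluster(log2(fot), k_range = config$k_range %||% 2:6,
                            reps = config$reps %||% 100L,
                            p_item = config$p_item %||% 0.8, seed = seed)
  wr(data.frame(sample = colnames(fot),
                cluster = cons$labels[[paste0("k", cons$chosen_k)]]),
     "clusters.tsv")

  # phospho: counterpart adjustment + KSEA (phase contrast: last vs first)
  phospho <- read_matrix(file.path(ind, "phospho.tsv"))
  prot <- read_matrix(file.path(ind, "phospho_protein.tsv"))
  ks_map <- as.data.frame(data.table::fread(file.path(ind, "ks_map.tsv")))
  adj <- adjust_phospho(site_prevalence_filter(phospho), prot)
  pann <- ann[match(colnames(adj), ann$sample), ]
  lv <- levels(factor(pann$stage))
  lp <- log2(apply_floor(adj, floor))
  grp <- pann$stage == lv[length(lv)]
  refg <- pann$stage == lv[1L]
  fc <- rowMeans(lp[, grp, drop = FALSE], na.rm = TRUE) -
    rowMeans(lp[, refg, drop = FALSE], na.rm = TRUE)
  kact <- ksea(fc[is.finite(fc)], ks_map, min_m = config$min_m %||% 3L)
  wr(kact, "ksea.tsv")

  # SCNA cis-effects
  scna <- read_matrix(file.path(ind, "scna.tsv"))
  sexpr <- read_matrix(file.path(ind, "scna_expression.tsv"))
  cis <- scna_cis_effects(scna, sexpr)
  wr(cis, "scna_cis.tsv")

  invisible(list(neo = neo, signatures = sig, apobec = apo, dep = dep,
                 waves = waves, consensus = cons, ksea = kact, cis = cis))
}
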