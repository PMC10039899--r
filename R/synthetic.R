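#' Synthetic cohort configuration
#'
#' Bundles the ground-truth parameters for the synthetic progression
#' cohort: the ordered stage model, per-stage mutation loads and
#' neo-mutation burst stages, generating signature mixtures, the protein
#' wave panels (substage block, log2 effect, proportion of proteins),
#' dropout behaviour, and per-kinase stage shifts. Defaults emulate the
#' structure of a nine-stage esophageal progression cohort: neo-mutation
#' bursts at the Tis and T2 stages (the two phase boundaries), eight
#' contiguous wave panels with log2 effect 2, and a lognormal label-free
#' abundance model with abundance-dependent dropout.
#'
#' @param stages A `stage_model`; default [default_stage_model()].
#' @param substages Ordered substage labels; default the stage labels.
#' @param substage_stage Named map substage -> stage; default identity.
#' @param n_patients Number of patients, default 30.
#' @param samples_per_substage Samples per substage for the expression
#'   generators, default 30.
#' @param stage_loads Per-stage expected new-mutation count (Poisson),
#'   default 30 per stage.
#' @param neo_peaks Stage labels receiving an extra neo-mutation burst,
#'   default `c("Tis", "T2")`.
#' @param neo_burst Expected extra mutations at each peak stage, default
#'   four times the mean stage load.
#' @param loss_rate Per-stage probability that a carried variant is lost,
#'   default 0 (fully cumulative).
#' @param signature_profiles 96 x K matrix of generating signature
#'   profiles (columns on the simplex); default three well-separated
#'   synthetic profiles.
#' @param signature_mix Stages x K mixing-weight matrix (rows on the
#'   simplex); default uniform.
#' @param n_genes Gene pool size for mutation placement, default 500.
#' @param n_proteins Number of proteins, default 2000.
#' @param wave_spec List of panels, each
#'   `list(name =, substages =, log2fc =, prop =)`; panels must be
#'   protein-disjoint (proportions summing to at most 1). Default: eight
#'   panels over stages 2-9, log2 effect 2, 5 percent of proteins each.
#' @param base_log2 Mean baseline log2 abundance, default 17.
#' @param between_sd SD of per-protein baseline log2 means, default 2.
#' @param noise_sd Within-protein lognormal noise (log2 SD), default 0.5.
#' @param dropout Overall dropout rate at the median abundance (logistic
#'   in log2 abundance, decreasing with abundance), default 0.2; 0
#'   disables missingness.
#' @param dropout_slope Logistic slope per log2 unit, default 1.
#' @param kinase_spec Named list kinase -> named per-stage log2 shift
#'   vector; default two kinases shifted +2 in the advanced stages.
#' @param n_background_sites Non-substrate phosphosites, default 500.
#' @param seed Master seed, default 1.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(stages = default_stage_model(),
                       substages = NULL, substage_stage = NULL,
                       n_patients = 30L, samples_per_substage = 30L,
                       stage_loads = NULL, neo_peaks = c("Tis", "T2"),
                       neo_burst = NULL, loss_rate = 0,
                       signature_profiles = NULL, signature_mix = NULL,
                       n_genes = 500L, n_proteins = 2000L,
                       wave_spec = NULL, base_log2 = 17, between_sd = 2,
                       noise_sd = 0.5, dropout = 0.2, dropout_slope = 1,
                       kinase_spec = NULL, n_background_sites = 500L,
                       seed = 1L) {
  labs <- stages$stages
  substages <- substages %||% labs
  substage_stage <- substage_stage %||% setNames(labs, labs)[substages]
  if (!all(substage_stage %in% labs))
    stopf("substage_stage maps to unknown stage label(s)")
  stage_loads <- stage_loads %||% setNames(rep(30, length(labs)), labs)
  if (is.null(names(stage_loads))) names(stage_loads) <- labs
  if (any(stage_loads < 0)) stopf("stage loads must be nonnegative")
  unknown <- setdiff(neo_peaks, labs)
  if (length(unknown))
    stopf("neo_peaks stage(s) not in stage model: %s",
          paste(unknown, collapse = ", "))
  neo_burst <- neo_burst %||% 4 * mean(stage_loads)
  signature_profiles <- signature_profiles %||% toy_signature_profiles(3L)
  K <- ncol(signature_profiles)
  if (nrow(signature_profiles) != 96L)
    stopf("signature profiles must have 96 channels")
  if (any(abs(colSums(signature_profiles) - 1) > 1e-8))
    stopf("signature profiles must sum to 1")
  signature_mix <- signature_mix %||%
    matrix(1 / K, length(labs), K, dimnames = list(labs, colnames(signature_profiles)))
  if (any(abs(rowSums(signature_mix) - 1) > 1e-8))
    stopf("signature mixing weights must sum to 1 per stage")
  if (nrow(signature_mix) != length(labs))
    stopf("signature_mix needs one row per stage")
  wave_spec <- wave_spec %||% default_wave_spec(substages)
  props <- vapply(wave_spec, `[[`, 0, "prop")
  if (sum(props) > 1 + 1e-8) stopf("panel proportions exceed 1")
  for (p in wave_spec) {
    if (p$log2fc <= 0) stopf("panel effect size must be > 0")
    if (!all(p$substages %in% substages))
      stopf("panel '%s' references unknown substage(s)", p$name)
  }
  kinase_spec <- kinase_spec %||% default_kinase_spec(labs)
  if (is.null(stages$phases)) {
    # phases implied by the planted neo-mutation bursts
    pk <- sort(match(neo_peaks, labs))
    pk <- pk[pk > 1L]
    nb <- length(pk) + 1L
    nms <- if (nb == 3L) c("NT", "IEN", "A-ESCC") else paste0("phase", seq_len(nb))
    stages <- stage_model(labs, phases = phase_blocks(length(labs), pk, nms))
  }
  cfg <- list(stages = stages, substages = substages,
              substage_stage = substage_stage, n_patients = n_patients,
              samples_per_substage = samples_per_substage,
              stage_loads = stage_loads, neo_peaks = neo_peaks,
              neo_burst = neo_burst, loss_rate = loss_rate,
              signature_profiles = signature_profiles,
              signature_mix = signature_mix, n_genes = n_genes,
              n_proteins = n_proteins, wave_spec = wave_spec,
              base_log2 = base_log2, between_sd = between_sd,
              noise_sd = noise_sd, dropout = dropout,
              dropout_slope = dropout_slope, kinase_spec = kinase_spec,
              n_background_sites = n_background_sites,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

default_wave_spec <- function(substages) {
  n <- length(substages)
  picks <- if (n >= 9L) 2:9 else seq_len(min(8L, n))
  lapply(seq_along(picks), function(i)
    list(name = paste0("panel", i), substages = substages[picks[i]],
         log2fc = 2, prop = 0.05))
}

default_kinase_spec <- function(stage_labels) {
  late <- tail(stage_labels, 2)
  mid <- stage_labels[ceiling(length(stage_labels) / 2)]
  list(
    KIN1 = setNames(ifelse(stage_labels %in% late, 2, 0), stage_labels),
    KIN2 = setNames(ifelse(stage_labels %in% mid, 2, 0), stage_labels))
}

#' Well-separated toy signature profiles
#'
#' K synthetic 96-channel profiles, each concentrated on a disjoint block
#' of channels (pairwise cosine well below 0.3), for generator defaults
#' and recovery tests.
#'
#' @param k Number of profiles (up to 6).
#' @return 96 x k matrix, columns on the simplex, channel rownames.
#' @export
toy_signature_profiles <- function(k = 3L) {
  stopifnot(k >= 1L, k <= 6L)
  ch <- sbs96_channels()
  W <- matrix(0.001, 96, k, dimnames = list(ch, paste0("True", seq_len(k))))
  for (j in seq_len(k)) {
    block <- ((j - 1L) * 16L + 1L):(j * 16L)
    W[block, j] <- W[block, j] + seq(1, 2, length.out = 16L)
  }
  sweep(W, 2, colSums(W), "/")
}

channel_parts <- function(channel) {
  data.frame(
    five = substr(channel, 1, 1),
    ref = substr(channel, 3, 3),
    alt = substr(channel, 5, 5),
    three = substr(channel, 7, 7), stringsAsFactors = FALSE)
}

#' Generate a stage-resolved somatic mutation catalog
#'
#' Simulates a cumulative mutation process per patient: at each stage a
#' Poisson(stage load) number of never-seen variants arises (plus an
#' extra Poisson burst at the configured neo-peak stages), carried
#' variants persist into later stages except for an optional per-stage
#' loss rate, and every variant's 96-channel class is drawn from that
#' stage's signature mixture. Each simulated variant has a unique genomic
#' key; half the records are stored on the purine strand to exercise
#' pyrimidine collapsing. Sample ids are `patient_stage`.
#'
#' @param cfg A `sim_config`.
#' @return A `mutation_catalog` with attribute `truth` (per-variant
#'   originating stage and signature).
#' @export
gen_mutation_catalog <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  labs <- cfg$stages$stages
  ch <- sbs96_channels()
  parts <- channel_parts(ch)
  withr::with_seed(derive_seed(cfg$seed, 101L), {
    pos_counter <- 0L
    recs <- list()
    truth <- list()
    for (p in seq_len(cfg$n_patients)) {
      pid <- sprintf("P%03d", p)
      active <- NULL
      for (si in seq_along(labs)) {
        st <- labs[si]
        if (!is.null(active) && cfg$loss_rate > 0 && nrow(active)) {
          keep <- runif(nrow(active)) >= cfg$loss_rate
          active <- active[keep, , drop = FALSE]
        }
        n_new <- rpois(1, cfg$stage_loads[[st]]) +
          if (st %in% cfg$neo_peaks) rpois(1, cfg$neo_burst) else 0L
        if (n_new > 0) {
          mix <- cfg$signature_mix[si, ]
          sig <- sample(seq_along(mix), n_new, replace = TRUE, prob = mix)
          chan <- vapply(sig, function(s)
            sample(96L, 1L, prob = cfg$signature_profiles[, s]), 0L)
          flip <- runif(n_new) < 0.5
          ref <- ifelse(flip, unname(REVCOMP[parts$ref[chan]]),
                        parts$ref[chan])
          alt <- ifelse(flip, unname(REVCOMP[parts$alt[chan]]),
                        parts$alt[chan])
          ctx_pyr <- paste0(parts$five[chan], parts$ref[chan],
                            parts$three[chan])
          ctx <- ifelse(flip, revcomp(ctx_pyr), ctx_pyr)
          new <- data.frame(
            gene = sprintf("G%04d", sample(cfg$n_genes, n_new, replace = TRUE)),
            chrom = as.character(sample(1:22, n_new, replace = TRUE)),
            pos = pos_counter + seq_len(n_new) * 10L,
            ref = ref, alt = alt, context = ctx,
            origin_stage = st, signature = colnames(cfg$signature_profiles)[sig],
            stringsAsFactors = FALSE)
          pos_counter <- pos_counter + n_new * 10L
          active <- rbind(active, new)
          truth[[length(truth) + 1L]] <- new
        }
        if (!is.null(active) && nrow(active)) {
          recs[[length(recs) + 1L]] <- data.frame(
            patient = pid, sample = paste(pid, st, sep = "_"), stage = st,
            active[, c("gene", "chrom", "pos", "ref", "alt", "context")],
            stringsAsFactors = FALSE)
        }
      }
    }
    cat_df <- if (length(recs)) do.call(rbind, recs) else
      data.frame(patient = character(0), sample = character(0),
                 stage = character(0), gene = character(0),
                 chrom = character(0), pos = integer(0), ref = character(0),
                 alt = character(0), context = character(0))
    out <- mutation_catalog(cat_df)
    attr(out, "truth") <- if (length(truth)) do.call(rbind, truth) else NULL
    out
  })
}

sim_samples <- function(cfg) {
  subs <- cfg$substages
  n <- cfg$samples_per_substage
  ann <- do.call(rbind, lapply(seq_along(subs), function(i)
    data.frame(sample = sprintf("%s_r%02d", subs[i], seq_len(n)),
               patient = sprintf("P%03d", ((seq_len(n) - 1L) %% cfg$n_patients) + 1L),
               substage = subs[i],
               stage = unname(cfg$substage_stage[subs[i]]),
               stringsAsFactors = FALSE)))
  phases <- cfg$stages$phases
  ann$phase <- if (is.null(phases)) NA_character_ else
    stage_phase(cfg$stages, ann$stage)
  ann
}

apply_dropout <- function(lmat, rate, slope) {
  if (rate <= 0) return(lmat)
  med <- median(lmat, na.rm = TRUE)
  pmiss <- pmin(1, 2 * rate * plogis(-slope * (lmat - med)))
  lmat[matrix(runif(length(lmat)), nrow(lmat)) < pmiss] <- NA
  lmat
}

#' Generate a wave-structured protein abundance matrix
#'
#' Baseline per-protein lognormal abundances (per-protein log2 means
#' drawn once, multiplicative lognormal noise per sample); panel proteins
#' are up-shifted by their log2 effect within their substage block;
#' dropout is applied with probability logistic-decreasing in log2
#' abundance. Returned on the linear (iBAQ-like) scale.
#'
#' @param cfg A `sim_config`.
#' @return List: `matrix` (proteins x samples, `NA` = missing),
#'   `annotations` (sample, patient, substage, stage, phase), `truth`
#'   (data frame protein, panel).
#' @export
gen_expression <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  ann <- sim_samples(cfg)
  prot <- sprintf("PROT%05d", seq_len(cfg$n_proteins))
  withr::with_seed(derive_seed(cfg$seed, 202L), {
    n_each <- vapply(cfg$wave_spec, function(p)
      round(p$prop * cfg$n_proteins), 0)
    idx <- 0L
    membership <- rep(NA_character_, cfg$n_proteins)
    for (i in seq_along(cfg$wave_spec)) {
      take <- idx + seq_len(n_each[i])
      membership[take] <- cfg$wave_spec[[i]]$name
      idx <- idx + n_each[i]
    }
    mu <- rnorm(cfg$n_proteins, cfg$base_log2, cfg$between_sd)
    lmat <- matrix(rnorm(cfg$n_proteins * nrow(ann), 0, cfg$noise_sd),
                   cfg$n_proteins, nrow(ann),
                   dimnames = list(prot, ann$sample)) + mu
    for (i in seq_along(cfg$wave_spec)) {
      p <- cfg$wave_spec[[i]]
      rows <- which(membership == p$name)
      cols <- which(ann$substage %in% p$substages)
      if (length(rows) && length(cols))
        lmat[rows, cols] <- lmat[rows, cols] + p$log2fc
    }
    lmat <- apply_dropout(lmat, cfg$dropout, cfg$dropout_slope)
    list(matrix = 2^lmat,
         annotations = ann,
         truth = data.frame(protein = prot, panel = membership,
                            stringsAsFactors = FALSE))
  })
}

#' Generate a kinase-driven phosphosite matrix
#'
#' Substrate sites of each configured kinase receive that kinase's
#' stage-specific log2 shift plus noise; background sites receive noise
#' only. A paired total-protein matrix (parent proteins and the kinases
#' themselves, baseline abundances) is emitted for counterpart
#' adjustment.
#'
#' @param cfg A `sim_config`.
#' @param ks_map Data frame `kinase`, `site`; every kinase in
#'   `cfg$kinase_spec` must appear with a nonempty substrate set.
#' @return List: `phospho` (sites x samples), `protein` (proteins x
#'   samples), `annotations`, `truth` (the kinase_spec).
#' @export
gen_phospho <- function(cfg, ks_map) {
  stopifnot(inherits(cfg, "sim_config"))
  shifted <- names(cfg$kinase_spec)[vapply(cfg$kinase_spec,
                                           function(s) any(s != 0), TRUE)]
  for (k in shifted)
    if (!k %in% ks_map$kinase || !length(ks_map$site[ks_map$kinase == k]))
      stopf("kinase '%s' has an empty substrate set in ks_map", k)
  ann <- sim_samples(cfg)
  sites <- unique(c(ks_map$site,
                    sprintf("BGP%04d_S1", seq_len(cfg$n_background_sites))))
  genes <- unique(c(sub("_[^_]+$", "", sites), names(cfg$kinase_spec),
                    unique(ks_map$kinase)))
  withr::with_seed(derive_seed(cfg$seed, 303L), {
    mu <- rnorm(length(sites), cfg$base_log2, cfg$between_sd)
    lmat <- matrix(rnorm(length(sites) * nrow(ann), 0, cfg$noise_sd),
                   length(sites), nrow(ann),
                   dimnames = list(sites, ann$sample)) + mu
    for (k in names(cfg$kinase_spec)) {
      shift <- cfg$kinase_spec[[k]]
      subs <- intersect(unique(ks_map$site[ks_map$kinase == k]), sites)
      if (!length(subs)) next
      for (st in names(shift)) {
        if (shift[[st]] == 0) next
        cols <- which(ann$stage == st)
        if (length(cols))
          lmat[subs, cols] <- lmat[subs, cols] + shift[[st]]
      }
    }
    lmat <- apply_dropout(lmat, cfg$dropout, cfg$dropout_slope)
    gmu <- rnorm(length(genes), cfg$base_log2, cfg$between_sd)
    gmat <- matrix(rnorm(length(genes) * nrow(ann), 0, cfg$noise_sd),
                   length(genes), nrow(ann),
                   dimnames = list(genes, ann$sample)) + gmu
    list(phospho = 2^lmat, protein = 2^gmat, annotations = ann,
         truth = cfg$kinase_spec)
  })
}

#' Generate a copy-number matrix with planted cis-effects
#'
#' Integer copy states in -2..2 per gene and sample; designated cis-genes
#' have protein abundance monotonically coupled to the copy state (log2
#' shift of `coupling` per copy-state unit) with lognormal noise.
#'
#' @param cfg A `sim_config`.
#' @param n_genes Number of genes, default 200.
#' @param n_cis Number of cis-coupled genes, default 20.
#' @param coupling Log2 shift per copy-state unit for cis genes, default
#'   0.5 (0 plants no effect).
#' @param state_probs Probabilities over states -2..2.
#' @return List: `scna` (genes x samples), `expr` (genes x samples),
#'   `annotations`, `cis_genes`.
#' @export
gen_scna <- function(cfg, n_genes = 200L, n_cis = 20L, coupling = 0.5,
                     state_probs = c(0.05, 0.2, 0.5, 0.2, 0.05)) {
  stopifnot(inherits(cfg, "sim_config"))
  ann <- sim_samples(cfg)
  genes <- sprintf("CN%04d", seq_len(n_genes))
  withr::with_seed(derive_seed(cfg$seed, 404L), {
    scna <- matrix(sample(-2:2, n_genes * nrow(ann), replace = TRUE,
                          prob = state_probs),
                   n_genes, nrow(ann), dimnames = list(genes, ann$sample))
    mu <- rnorm(n_genes, cfg$base_log2, cfg$between_sd)
    lmat <- matrix(rnorm(n_genes * nrow(ann), 0, cfg$noise_sd),
                   n_genes, nrow(ann),
                   dimnames = list(genes, ann$sample)) + mu
    cis <- genes[seq_len(n_cis)]
    if (coupling != 0 && n_cis > 0)
      lmat[cis, ] <- lmat[cis, ] + coupling * scna[cis, ]
    list(scna = scna, expr = 2^lmat, annotations = ann, cis_genes = cis)
  })
}

#' Generate per-run peptide features with a retention-time warp
#'
#' A donor (reference) run of identified peptides plus acceptor runs
#' whose retention times follow a configurable linear or quadratic map of
#' the donor times plus noise. A stated fraction of peptides is hidden in
#' the acceptor runs (present as unidentified features) and a further
#' fraction is absent entirely.
#'
#' @param cfg A `sim_config` (supplies the seed).
#' @param n_peptides Number of peptides, default 200.
#' @param n_runs Total runs including the reference, default 2.
#' @param rt_map Numeric coefficients `c(a, b, c)` of the acceptor map
#'   `a + b * rt + c * rt^2`; default identity `c(0, 1, 0)`.
#' @param rt_noise_sd RT noise SD in the acceptor runs, default 0.
#' @param hidden_frac Fraction of peptides unidentified-but-present in
#'   acceptors, default 0.2.
#' @param absent_frac Fraction of peptides absent from acceptors, default
#'   0.05.
#' @return Data frame `run`, `peptide`, `mz`, `rt`, `intensity`,
#'   `identified`, with attribute `truth` (hidden/absent peptides per
#'   run).
#' @export
gen_peptide_features <- function(cfg, n_peptides = 200L, n_runs = 2L,
                                 rt_map = c(0, 1, 0), rt_noise_sd = 0,
                                 hidden_frac = 0.2, absent_frac = 0.05) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(derive_seed(cfg$seed, 505L), {
    pep <- sprintf("PEP%04d", seq_len(n_peptides))
    mz <- runif(n_peptides, 300, 1500)
    rt0 <- runif(n_peptides, 5, 95)
    inten <- rlnorm(n_peptides, log(1e6), 1)
    rows <- list(data.frame(run = "ref", peptide = pep, mz = mz, rt = rt0,
                            intensity = inten, identified = TRUE,
                            stringsAsFactors = FALSE))
    truth <- list()
    for (r in seq_len(n_runs - 1L)) {
      run <- paste0("acc", r)
      rt <- rt_map[1] + rt_map[2] * rt0 + rt_map[3] * rt0^2 +
        rnorm(n_peptides, 0, rt_noise_sd)
      status <- sample(c("id", "hidden", "absent"), n_peptides,
                       replace = TRUE,
                       prob = c(1 - hidden_frac - absent_frac,
                                hidden_frac, absent_frac))
      keep <- status != "absent"
      rows[[length(rows) + 1L]] <- data.frame(
        run = run, peptide = ifelse(status == "hidden",
                                    paste0("feat_", pep), pep)[keep],
        mz = mz[keep], rt = rt[keep],
        intensity = (inten * rlnorm(n_peptides, 0, 0.1))[keep],
        identified = (status == "id")[keep], stringsAsFactors = FALSE)
      truth[[run]] <- list(hidden = pep[status == "hidden"],
                           absent = pep[status == "absent"])
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "truth") <- truth
    out
  })
}

#' Generate sample spectra from planted signature mixtures
#'
#' Draws per-sample signature exposures from a symmetric Dirichlet
#' (sparse for `alpha < 1`, giving each sample a dominant signature, the
#' regime in which stability-based rank selection is meaningful), scales
#' them to the target mutation load, and samples Poisson counts per
#' 96-channel from the mixed profile.
#'
#' @param profiles 96 x K generating profile matrix (columns on the
#'   simplex).
#' @param n_samples Number of samples.
#' @param load Expected mutations per sample, default 400.
#' @param alpha Dirichlet concentration, default 0.3.
#' @param seed RNG seed.
#' @return List: `spectrum` (samples x 96 counts), `exposures`
#'   (samples x K ground truth).
#' @export
gen_signature_spectrum <- function(profiles, n_samples, load = 400,
                                   alpha = 0.3, seed = 1L) {
  K <- ncol(profiles)
  stopifnot(nrow(profiles) == 96L)
  withr::with_seed(derive_seed(seed, 606L), {
    g <- matrix(rgamma(n_samples * K, shape = alpha), n_samples, K)
    expo <- g / rowSums(g) * load
    mu <- expo %*% t(profiles)
    spec <- matrix(rpois(length(mu), mu), n_samples, 96,
                   dimnames = list(sprintf("s%03d", seq_len(n_samples)),
                                   rownames(profiles)))
    list(spectrum = spec, exposures = expo)
  })
}
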