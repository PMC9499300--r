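#' Default planted deleterious variants emulating a discovery cohort
#'
#' Thirty-six deleterious variants across 25 genes whose aggregate carrier
#' prevalence is close to 29% of a 100-patient cohort: one recurrent
#' frameshift at carrier probability 0.04, one recurrent stopgain at 0.02,
#' and 34 near-singleton variants at 0.0083.  The mutation-type mix
#' (12 nonsynonymous, 11 stopgain, 7 frameshift deletions, 6 frameshift
#' insertions) and the pathway mix (12 DNA methylation, 7 DDR, 6 tyrosine
#' protein kinase, 4 GPCR signaling, 4 peroxisome, 1 each MAPK/ERK, ErbB,
#' cell cycle) mirror the structure such a cohort exhibits.
#'
#' @return A tibble with columns `gene`, `pathway`, `is_ddr`,
#'   `consequence`, `carrier_probability`, `reference_af`, `true_tier5`,
#'   `enriched`.
#' @export
default_planted_variants <- function() {
  genes <- c(
    # 12 DNA methylation-pathway variants over 7 genes
    "KMT2C", "KMT2C", "KMT2C", "DNMT3A", "DNMT3A", "MYH7", "MYH7",
    "PABPC1", "TET2", "KDM5A", "SETD2", "NSD1",
    # 7 DDR variants
    "FANCI", "PMS2", "RAD9B", "RAD54B", "BRCA2", "ATM", "MSH2",
    # 6 tyrosine-protein kinase variants
    "CHD4", "CHD4", "EGFR", "ERBB3", "FGFR3", "NTRK1",
    # 4 GPCR signaling
    "ADGRG1", "LDLR", "ITGA6", "GRM8",
    # 4 peroxisome
    "SUGCT", "SUGCT", "SUGCT", "SUGCT",
    # 1 MAPK/ERK, 1 ErbB, 1 cell cycle
    "MAP3K1", "ERBB2", "NUP98"
  )
  pathway <- c(
    rep("DNA_methylation", 12), rep("DDR", 7),
    rep("tyrosine_protein_kinase", 6), rep("GPCR_signaling", 4),
    rep("peroxisome", 4), "MAPK_ERK", "ErbB", "cell_cycle"
  )
  consequence <- c(
    # DNA methylation block
    "stopgain", "frameshift_insertion", "nonsynonymous_SNV", "stopgain",
    "nonsynonymous_SNV", "stopgain", "nonsynonymous_SNV",
    "frameshift_deletion", "stopgain", "nonsynonymous_SNV",
    "frameshift_insertion", "nonsynonymous_SNV",
    # DDR block
    "stopgain", "nonsynonymous_SNV", "frameshift_deletion", "stopgain",
    "frameshift_insertion", "nonsynonymous_SNV", "stopgain",
    # tyrosine-protein kinase block
    "nonsynonymous_SNV", "stopgain", "nonsynonymous_SNV",
    "frameshift_deletion", "nonsynonymous_SNV", "frameshift_insertion",
    # GPCR block
    "stopgain", "frameshift_deletion", "frameshift_deletion",
    "nonsynonymous_SNV",
    # peroxisome block (one recurrent frameshift deletion)
    "frameshift_deletion", "stopgain", "frameshift_insertion",
    "nonsynonymous_SNV",
    # singles
    "stopgain", "frameshift_insertion", "stopgain"
  )
  carrier_probability <- rep(0.0083, 36)
  carrier_probability[29] <- 0.04 # recurrent SUGCT-like frameshift
  carrier_probability[1] <- 0.02  # recurrent KMT2C-like stopgain
  reference_af <- rep(0, 36)
  reference_af[c(4, 13, 22, 29)] <- 5e-5
  tibble::tibble(
    gene = genes,
    pathway = pathway,
    is_ddr = pathway == "DDR",
    consequence = consequence,
    carrier_probability = carrier_probability,
    reference_af = reference_af,
    true_tier5 = ifelse(consequence == "nonsynonymous_SNV",
                        "LikelyPathogenic", "Pathogenic"),
    enriched = reference_af < carrier_probability / 2
  )
}

#' Planted variants for enrichment-recovery benchmarking
#'
#' Thirty-six variants of which 15 carry a strong case-only signal
#' (carrier probability 0.04, absent or nearly absent from the reference)
#' and 21 are frequency-matched nulls (case carrier probability equal to
#' the population carrier rate implied by the reference allele frequency).
#' The 15 signal genes comprise 3 DDR genes and 12 non-DDR genes, so a
#' novel-gene call over these results has a known answer.
#'
#' @return A tibble shaped like [default_planted_variants()].
#' @export
recovery_planted_variants <- function() {
  signal_genes <- c(
    "FANCI", "PMS2", "RAD9B", # DDR
    "ADGRG1", "CHD4", "DNMT3A", "ERBB3", "GRHL1", "HMBS",
    "LDLR", "MYH7", "MYO6", "NT5C2", "NUP98", "SUGCT"
  )
  signal_pathway <- c(
    rep("DDR", 3),
    "GPCR_signaling", "tyrosine_protein_kinase", "DNA_methylation",
    "tyrosine_protein_kinase", "other", "hydrolase", "GPCR_signaling",
    "DNA_methylation", "other", "other", "cell_cycle", "peroxisome"
  )
  null_genes <- sprintf("NULLG%02d", 1:21)
  null_af <- 0.003
  tibble::tibble(
    gene = c(signal_genes, null_genes),
    pathway = c(signal_pathway, rep("other", 21)),
    is_ddr = c(rep(TRUE, 3), rep(FALSE, 12), rep(FALSE, 21)),
    consequence = c(
      rep(c("stopgain", "frameshift_deletion", "nonsynonymous_SNV"), 5),
      rep("nonsynonymous_SNV", 21)
    ),
    carrier_probability = c(rep(0.04, 15), rep(1 - (1 - null_af)^2, 21)),
    reference_af = c(rep(0, 15), rep(null_af, 21)),
    true_tier5 = c(rep("Pathogenic", 15), rep("LikelyPathogenic", 21)),
    enriched = c(rep(TRUE, 15), rep(FALSE, 21))
  )
}

#' Default metastasis-model genes and effects
#'
#' Six genes whose uncertain-significance carrier status feeds the
#' metastasis logit, each carried by about 15% of patients with a log-odds
#' effect of 1.5 (odds ratio about 4.5, a strong but plausible effect for
#' a risk gene).
#'
#' @return A tibble of `gene`, `carrier_probability`, `beta`.
#' @export
default_model_genes <- function() {
  tibble::tibble(
    gene = c("COL1A1", "CSF3R", "ERBB2", "ITGB8", "TSC1", "TSC2"),
    carrier_probability = 0.15,
    beta = 1.5
  )
}

#' Default clinical logit coefficients
#'
#' @return A list with `intercept`, `log10_psa`, `isup` (per-gene effects
#'   come from [default_model_genes()]).
#' @export
default_clinical_beta <- function() {
  list(intercept = -4.5, log10_psa = 0.8, isup = 0.5)
}

#' Configuration for the synthetic-cohort generator
#'
#' @param seed Integer seed; all randomness flows from it through named
#'   sub-streams so adding one artifact does not perturb another.
#' @param n_patients Cohort size (default 100; a paired validation cohort
#'   conventionally uses 167).
#' @param n_ref_individuals Diploid individuals in the emulated population
#'   reference (default 9,197, i.e. AN = 18,394).
#' @param planted Planted deleterious variants, see
#'   [default_planted_variants()].
#' @param background_rate Expected benign/VUS background variants per
#'   patient (default 40).
#' @param model_genes Genes with uncertain-significance variants feeding
#'   the metastasis logit, see [default_model_genes()].
#' @param clinical_beta Logit coefficients, see [default_clinical_beta()].
#' @param isup_probs Probabilities of ISUP grades 1-5 (defaults mirror a
#'   high-risk East Asian cohort: 15, 1, 1, 33, 50 per hundred).
#' @param sample_prefix Prefix for generated sample identifiers.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed,
                             n_patients = 100,
                             n_ref_individuals = 9197,
                             planted = default_planted_variants(),
                             background_rate = 40,
                             model_genes = default_model_genes(),
                             clinical_beta = default_clinical_beta(),
                             isup_probs = c(15, 1, 1, 33, 50) / 100,
                             sample_prefix = "P") {
  if (missing(seed)) abort("seed is mandatory")
  if (any(planted$carrier_probability < 0 | planted$carrier_probability > 1)) {
    abort("carrier_probability must lie in [0, 1]")
  }
  if (any(planted$reference_af < 0 | planted$reference_af > 1)) {
    abort("reference_af must lie in [0, 1]")
  }
  if (n_ref_individuals <= 0) abort("n_ref_individuals must be positive")
  structure(
    list(
      seed = as.integer(seed), n_patients = as.integer(n_patients),
      n_ref_individuals = as.integer(n_ref_individuals), planted = planted,
      background_rate = background_rate, model_genes = model_genes,
      clinical_beta = clinical_beta, isup_probs = isup_probs,
      sample_prefix = sample_prefix
    ),
    class = "synthetic_config"
  )
}

planted_coordinates <- function(planted) {
  n <- nrow(planted)
  idx <- seq_len(n)
  ref <- ifelse(planted$consequence == "frameshift_deletion", "GA", "G")
  alt <- dplyr::case_when(
    planted$consequence == "frameshift_deletion" ~ "G",
    planted$consequence == "frameshift_insertion" ~ "GA",
    planted$consequence == "splicing" ~ "C",
    TRUE ~ "A"
  )
  tibble::tibble(
    chrom = as.character((idx - 1) %% 22 + 1),
    pos = 1000000L + idx * 1000L,
    ref = ref, alt = alt,
    rsid = sprintf("rsS%04d", idx)
  )
}

new_variant_row <- function(coords, gene, consequence, exonic, depth,
                            strand_bias, af, carriers, vaf, evidence) {
  tibble::tibble(
    chrom = coords$chrom, pos = coords$pos, ref = coords$ref,
    alt = coords$alt, rsid = coords$rsid,
    depth = depth, strand_bias = strand_bias,
    ac_case = length(carriers), carriers = list(carriers),
    carrier_vaf = list(vaf),
    gene = gene, consequence = consequence, exonic = exonic,
    af_exac_eas = ifelse(af > 0, af, NA_real_),
    af_kg_eas = NA_real_,
    af_gnomad_eas = af,
    evidence = evidence, annotated = TRUE
  )
}

#' Generate a synthetic cohort with known ground truth
#'
#' Draws planted deleterious variants (per-patient Bernoulli carriers with
#' QC fields guaranteed to pass the default filters and ACMG evidence
#' codes realizing the planted tier), uncertain-significance variants in
#' the model genes, a background of benign/VUS variants with population
#' allele frequencies from a Beta(0.5, 2000) truncated below 1%, and
#' clinical covariates whose metastasis logit depends on PSA, ISUP grade
#' and the model-gene indicators.  Deterministic given the config seed.
#'
#' @param cfg A [synthetic_config()].
#' @return A list with `variants` (annotated variant tibble as
#'   [read_cohort()] would produce), `samples`, `clinical`, and `truth`
#'   (planted table with realized carriers, model-gene carriers, clinical
#'   coefficients, background tier labels).
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  n <- cfg$n_patients
  samples <- sprintf("%s%04d", cfg$sample_prefix, seq_len(n))
  planted <- cfg$planted

  # --- planted deleterious variants ------------------------------------
  set.seed(substream_seed(cfg$seed, "variants"))
  coords <- planted_coordinates(planted)
  planted_rows <- vector("list", nrow(planted))
  realized_carriers <- vector("list", nrow(planted))
  for (i in seq_len(nrow(planted))) {
    carriers <- samples[runif(n) < planted$carrier_probability[i]]
    realized_carriers[[i]] <- carriers
    vaf <- round(0.35 + 0.3 * runif(length(carriers)), 3)
    evidence <- if (planted$true_tier5[i] == "Pathogenic") {
      "PVS1,PS1,PM2"
    } else {
      "PVS1,PM2"
    }
    planted_rows[[i]] <- new_variant_row(
      coords[i, ], planted$gene[i], planted$consequence[i], TRUE,
      depth = sample(60:200, 1), strand_bias = round(runif(1, 0, 20), 2),
      af = planted$reference_af[i], carriers = carriers, vaf = vaf,
      evidence = evidence
    )
  }

  # --- model-gene VUS variants -----------------------------------------
  mg <- cfg$model_genes
  model_rows <- vector("list", nrow(mg))
  model_carriers <- vector("list", nrow(mg))
  for (i in seq_len(nrow(mg))) {
    carriers <- samples[runif(n) < mg$carrier_probability[i]]
    model_carriers[[i]] <- carriers
    coords_i <- tibble::tibble(
      chrom = as.character((i - 1) %% 22 + 1), pos = 5000000L + i * 1000L,
      ref = "C", alt = "T", rsid = sprintf("rsM%04d", i)
    )
    model_rows[[i]] <- new_variant_row(
      coords_i, mg$gene[i], "nonsynonymous_SNV", TRUE,
      depth = sample(60:200, 1), strand_bias = round(runif(1, 0, 20), 2),
      af = 0.002,
      carriers = carriers,
      vaf = round(0.35 + 0.3 * runif(length(carriers)), 3),
      evidence = "PM2"
    )
  }
  names(model_carriers) <- mg$gene

  # --- background benign/VUS variants ----------------------------------
  set.seed(substream_seed(cfg$seed, "background"))
  bg <- NULL
  bg_truth <- NULL
  if (cfg$background_rate > 0) {
    mean_2af <- 2 * 0.5 / 2000.5 # expected per-variant carrier rate
    n_bg <- round(cfg$background_rate / mean_2af)
    af <- rbeta(n_bg, 0.5, 2000)
    af <- pmin(af, 0.0099)
    k_alleles <- rbinom(n_bg, 2L * n, af)
    keep <- which(k_alleles > 0)
    bg_rows <- vector("list", length(keep))
    tier <- ifelse(runif(length(keep)) < 0.594, "VUS", "Benign")
    for (j in seq_along(keep)) {
      i <- keep[j]
      alleles <- sample(samples, k_alleles[i], replace = TRUE)
      carriers <- unique(alleles)
      coords_i <- tibble::tibble(
        chrom = as.character((i - 1) %% 22 + 1),
        pos = 10000000L + i * 10L,
        ref = "T", alt = "C", rsid = NA_character_
      )
      row <- new_variant_row(
        coords_i, sprintf("BGGENE%05d", i), "nonsynonymous_SNV", TRUE,
        depth = sample(60:200, 1), strand_bias = round(runif(1, 0, 20), 2),
        af = round(af[i], 6),
        carriers = carriers,
        vaf = round(0.35 + 0.3 * runif(length(carriers)), 3),
        evidence = if (tier[j] == "Benign") "BS1,BS2" else ""
      )
      row$ac_case <- as.integer(k_alleles[i])
      bg_rows[[j]] <- row
    }
    bg <- dplyr::bind_rows(bg_rows)
    bg_truth <- tibble::tibble(
      variant = variant_key(bg$chrom, bg$pos, bg$ref, bg$alt),
      true_tier3 = ifelse(tier == "Benign", "benign", "VUS"),
      population_af = af[keep]
    )
  }

  # --- clinical covariates ---------------------------------------------
  set.seed(substream_seed(cfg$seed, "clinical"))
  age <- pmin(pmax(round(stats::rnorm(n, 69, 8)), 45), 90)
  psa <- round(rlnorm(n, 3, 1.2), 1)
  isup <- sample(1:5, n, replace = TRUE, prob = cfg$isup_probs)
  beta <- cfg$clinical_beta
  eta <- beta$intercept + beta$log10_psa * log10(psa + 1) + beta$isup * isup
  for (i in seq_len(nrow(mg))) {
    eta <- eta + mg$beta[i] * (samples %in% model_carriers[[i]])
  }
  metastasis <- ifelse(runif(n) < plogis(eta), "M1", "M0")
  clinical <- tibble::tibble(
    sample_id = samples, age = age, psa = psa, isup = isup,
    metastasis = metastasis,
    crpc_within_1yr = runif(n) < 0.25
  )

  # only observed variants appear in a cohort call set
  observed <- function(rows) rows[vapply(rows, function(r) r$ac_case > 0, logical(1))]
  variants <- dplyr::bind_rows(c(observed(planted_rows), observed(model_rows), list(bg)))
  truth <- list(
    planted = dplyr::bind_cols(
      coords,
      planted,
      tibble::tibble(carriers = realized_carriers)
    ),
    model_carriers = model_carriers,
    clinical_beta = c(
      intercept = beta$intercept, log10_psa = beta$log10_psa,
      isup = beta$isup, setNames(mg$beta, mg$gene)
    ),
    background = bg_truth
  )
  list(variants = variants, samples = samples, clinical = clinical, truth = truth)
}

#' Generate the matching population reference allele-count table
#'
#' Every row carries `an = 2 * n_ref_individuals`.  Planted variants get
#' `ac = round(reference_af * an)`; model-gene and background variants get
#' `ac` drawn from `Binomial(an, af)`.  Rows with `ac = 0` are omitted,
#' as population databases do not list unobserved variants.
#'
#' @param cfg A [synthetic_config()].
#' @param cohort The list returned by [generate_cohort()] for `cfg`.
#' @return A reference tibble (`chrom, pos, ref, alt, ac, an`).
#' @export
generate_reference <- function(cfg, cohort) {
  stopifnot(inherits(cfg, "synthetic_config"))
  an <- 2L * cfg$n_ref_individuals
  set.seed(substream_seed(cfg$seed, "reference"))
  v <- cohort$variants
  af <- dplyr::coalesce(v$af_gnomad_eas, v$af_exac_eas, 0)
  key_planted <- variant_key(
    cohort$truth$planted$chrom, cohort$truth$planted$pos,
    cohort$truth$planted$ref, cohort$truth$planted$alt
  )
  key <- variant_key(v$chrom, v$pos, v$ref, v$alt)
  is_planted <- key %in% key_planted
  ac <- integer(nrow(v))
  ac[is_planted] <- as.integer(round(af[is_planted] * an))
  ac[!is_planted] <- rbinom(sum(!is_planted), an, af[!is_planted])
  out <- tibble::tibble(
    chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt,
    ac = ac, an = an
  )
  out[out$ac > 0, , drop = FALSE]
}

#' Generate the panel and gene-set artifacts for a synthetic study
#'
#' The panel contains every planted and model gene plus decoys up to
#' `total_genes` rows; the GMT includes a PI3K-Akt-like set overlapping the
#' model genes.
#'
#' @param cfg A [synthetic_config()].
#' @param total_genes Total panel size including decoys (default 1166).
#' @return A list with `panel` (tibble) and `sets` (named list).
#' @export
generate_panel_and_sets <- function(cfg, total_genes = 1166) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(substream_seed(cfg$seed, "panel"))
  planted <- cfg$planted |>
    dplyr::distinct(.data$gene, .keep_all = TRUE) |>
    dplyr::select("gene", "pathway", "is_ddr")
  model <- tibble::tibble(
    gene = setdiff(cfg$model_genes$gene, planted$gene),
    pathway = "other", is_ddr = FALSE
  )
  core <- dplyr::bind_rows(planted, model)
  n_decoys <- max(0, total_genes - nrow(core))
  vocab <- pathway_vocabulary()
  decoys <- tibble::tibble(
    gene = sprintf("DECOY%04d", seq_len(n_decoys)),
    pathway = vocab[(seq_len(n_decoys) - 1) %% length(vocab) + 1],
    is_ddr = FALSE
  )
  panel <- dplyr::bind_rows(core, decoys) |>
    dplyr::transmute(
      symbol = .data$gene,
      categories = "hereditary_cancer",
      pathway = .data$pathway,
      is_ddr = .data$is_ddr,
      lof_mechanism = TRUE
    )
  pi3k <- c(cfg$model_genes$gene, sample(decoys$gene, min(40, n_decoys)))
  sets <- list(
    PI3K_AKT_like = pi3k,
    PROSTATE_CANCER_like = c(
      cfg$model_genes$gene[1:3],
      sample(decoys$gene, min(20, n_decoys))
    ),
    RANDOM_SET_A = sample(panel$symbol, min(30, nrow(panel))),
    RANDOM_SET_B = sample(panel$symbol, min(50, nrow(panel)))
  )
  list(panel = validate_panel(panel), sets = sets)
}

#' Generate a paired discovery/validation study
#'
#' Two cohorts drawn from the same planted-variant configuration (default
#' sizes 100 and 167), one shared population reference, and the panel and
#' gene-set artifacts.
#'
#' @param seed Integer seed.
#' @param n_discovery,n_validation Cohort sizes.
#' @param ... Further arguments passed to [synthetic_config()].
#' @return A list with `discovery`, `validation` (each a
#'   [generate_cohort()] result), `reference`, `panel`, `sets`, and the
#'   two configs.
#' @export
simulate_study <- function(seed, n_discovery = 100, n_validation = 167, ...) {
  cfg_a <- synthetic_config(seed = seed * 2L + 1L, n_patients = n_discovery,
                            sample_prefix = "HK", ...)
  cfg_b <- synthetic_config(seed = seed * 2L + 2L, n_patients = n_validation,
                            sample_prefix = "SH", ...)
  discovery <- generate_cohort(cfg_a)
  validation <- generate_cohort(cfg_b)
  reference <- generate_reference(cfg_a, discovery)
  artifacts <- generate_panel_and_sets(cfg_a)
  list(
    discovery = discovery, validation = validation,
    reference = reference, panel = artifacts$panel, sets = artifacts$sets,
    config_discovery = cfg_a, config_validation = cfg_b
  )
}
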