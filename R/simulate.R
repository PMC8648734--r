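#' Simulation configuration for synthetic multi-study cohorts
#'
#' Bundles every knob of the synthetic-data generator. The defaults describe a
#' compact multi-study TWAS design: a handful of studies with unequal size and
#' case:control imbalance, LD-structured biallelic dosages, sparse cis-eQTL
#' weight models with substantial cross-tissue sharing, and a liability-scale
#' logistic phenotype driven by the true genetically regulated expression of a
#' few causal genes plus sex and age.
#'
#' @param n_studies Number of studies.
#' @param n_per_study Integer vector of per-study sample sizes (recycled to
#'   `n_studies`).
#' @param case_fraction Target case fraction per study, strictly inside (0,1).
#' @param n_variants Total number of simulated variants.
#' @param n_genes Number of genes; genes occupy consecutive non-overlapping
#'   cis windows of `snps_per_gene` variants.
#' @param n_tissues Number of tissue-specific weight models per gene.
#' @param ld_rho AR(1) correlation of the latent Gaussian haplotype process
#'   within an LD block, in \[0,1).
#' @param block_size Number of variants per LD block.
#' @param maf_range Range (min,max) of target minor-allele frequencies,
#'   within (0, 0.5\].
#' @param snps_per_gene Candidate cis SNPs per gene.
#' @param weight_sparsity Probability a candidate cis SNP carries a nonzero
#'   weight in the causal tissue.
#' @param cross_tissue_sharing Probability a nonzero causal-tissue weight is
#'   shared (copied, scaled by a per-tissue factor) into another tissue.
#' @param tissue_factor_sd Standard deviation of the per-tissue scaling
#'   factor around 1; 0 makes shared weights identical across tissues.
#' @param n_causal_genes Number of genes with nonzero liability effect.
#' @param effect_sd Liability-scale standard deviation of causal gene effects.
#' @param covar_effects Named numeric vector `c(sex=, age=)` of log-odds
#'   covariate effects (age standardized).
#' @param n_genetic_pcs Number of simulated genetic principal components
#'   carried as covariates (null by construction).
#' @param seed Default seed used when an operation is not given one.
#' @return Object of class `simulation_config` (a validated list).
#' @export
simulation_config <- function(n_studies = 2L,
                              n_per_study = c(1500L, 1500L),
                              case_fraction = 0.45,
                              n_variants = 500L,
                              n_genes = 50L,
                              n_tissues = 5L,
                              ld_rho = 0.85,
                              block_size = 10L,
                              maf_range = c(0.05, 0.5),
                              snps_per_gene = 10L,
                              weight_sparsity = 0.2,
                              cross_tissue_sharing = 0.7,
                              tissue_factor_sd = 0.2,
                              n_causal_genes = 5L,
                              effect_sd = 0.3,
                              covar_effects = c(sex = 0.2, age = 0.3),
                              n_genetic_pcs = 4L,
                              seed = 1L) {
  cfg <- list(
    n_studies = as.integer(n_studies),
    n_per_study = as.integer(rep_len(n_per_study, n_studies)),
    case_fraction = rep_len(as.numeric(case_fraction), n_studies),
    n_variants = as.integer(n_variants),
    n_genes = as.integer(n_genes),
    n_tissues = as.integer(n_tissues),
    ld_rho = as.numeric(ld_rho),
    block_size = as.integer(block_size),
    maf_range = as.numeric(maf_range),
    snps_per_gene = as.integer(snps_per_gene),
    weight_sparsity = as.numeric(weight_sparsity),
    cross_tissue_sharing = as.numeric(cross_tissue_sharing),
    tissue_factor_sd = as.numeric(tissue_factor_sd),
    n_causal_genes = as.integer(n_causal_genes),
    effect_sd = as.numeric(effect_sd),
    covar_effects = covar_effects,
    n_genetic_pcs = as.integer(n_genetic_pcs),
    seed = as.integer(seed)
  )
  validate_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_config <- function(cfg) {
  counts <- c("n_studies", "n_variants", "n_genes", "n_tissues", "block_size",
              "snps_per_gene")
  for (nm in counts) {
    if (cfg[[nm]] < 1L) stop("invalid config: ", nm, " must be >= 1")
  }
  if (any(cfg$n_per_study < 1L)) stop("invalid config: n_per_study must be >= 1")
  if (any(cfg$case_fraction <= 0 | cfg$case_fraction >= 1)) {
    stop("invalid config: case_fraction must be strictly inside (0,1)")
  }
  if (length(cfg$maf_range) != 2L || cfg$maf_range[1] > cfg$maf_range[2] ||
      cfg$maf_range[1] <= 0 || cfg$maf_range[2] > 0.5) {
    stop("invalid config: maf_range must be (min,max) within (0, 0.5] with min <= max")
  }
  if (cfg$ld_rho < 0 || cfg$ld_rho >= 1) stop("invalid config: ld_rho must be in [0,1)")
  if (cfg$weight_sparsity < 0 || cfg$weight_sparsity > 1) {
    stop("invalid config: weight_sparsity must be a proportion")
  }
  if (cfg$cross_tissue_sharing < 0 || cfg$cross_tissue_sharing > 1) {
    stop("invalid config: cross_tissue_sharing must be a proportion")
  }
  if (cfg$n_genes * cfg$snps_per_gene > cfg$n_variants) {
    stop("invalid config: n_genes * snps_per_gene exceeds n_variants; ",
         "cannot place non-overlapping cis windows")
  }
  if (!all(c("sex", "age") %in% names(cfg$covar_effects))) {
    stop("invalid config: covar_effects must name sex and age")
  }
  invisible(cfg)
}

# Deterministic sub-seed derivation so every module-level rerun reproduces.
# Kept below 2^31 - 1.
derive_seed <- function(seed, stream) {
  (as.numeric(seed) * 1000003 + stream) %% 2147483647
}

#' Variant map shared across studies
#'
#' Positions, alleles and target MAFs of the simulated variants. The same map
#' underlies every study of a multi-study set, so weight models trained
#' against it apply everywhere.
#'
#' @param config A `simulation_config`.
#' @param seed Integer seed.
#' @return data.frame with `rsid`, `chrom`, `pos`, `ref`, `alt`,
#'   `maf_target`.
#' @export
simulate_variant_map <- function(config, seed = config$seed) {
  set.seed(derive_seed(seed, 1))
  m <- config$n_variants
  data.frame(
    rsid = sprintf("rs%06d", seq_len(m)),
    chrom = "1",
    pos = seq_len(m) * 5000L,  # evenly spaced cis map, 1-based
    ref = "A",
    alt = "G",
    maf_target = stats::runif(m, config$maf_range[1], config$maf_range[2]),
    stringsAsFactors = FALSE
  )
}

#' Simulate LD-structured genotype dosages
#'
#' Two haplotypes per individual are drawn from a Gaussian copula with AR(1)
#' correlation `ld_rho` inside each block of `block_size` variants and
#' independence across blocks; each latent value is thresholded at the
#' variant's MAF quantile, and the dosage is the haplotype sum, so values lie
#' in \{0,1,2\}. Per-variant imputation quality R-squared is simulated as
#' Uniform(0.3, 1) so downstream quality filters have nonzero effect.
#'
#' @param config A `simulation_config`.
#' @param seed Integer seed.
#' @param variant_map Optional precomputed map from [simulate_variant_map()]
#'   (so several studies share one map); defaults to generating one.
#' @param n Number of individuals; defaults to the first study size.
#' @return A `dosage_matrix`: list with `values` (n x m matrix), `variant_meta`
#'   (rsid, chrom, pos, ref, alt, maf, r2), `sample_ids`.
#' @export
simulate_genotypes <- function(config, seed = config$seed,
                               variant_map = NULL,
                               n = config$n_per_study[1]) {
  validate_config(config)
  if (is.null(variant_map)) variant_map <- simulate_variant_map(config, seed)
  set.seed(derive_seed(seed, 2))
  m <- nrow(variant_map)
  rho <- config$ld_rho
  bs <- config$block_size
  thr <- stats::qnorm(1 - variant_map$maf_target)  # alt allele carried above threshold

  draw_haplotypes <- function() {
    z <- matrix(0, nrow = n, ncol = m)
    for (j in seq_len(m)) {
      e <- stats::rnorm(n)
      if ((j - 1L) %% bs == 0L) {
        z[, j] <- e
      } else {
        z[, j] <- rho * z[, j - 1L] + sqrt(1 - rho^2) * e
      }
    }
    z
  }
  hap1 <- sweep(draw_haplotypes(), 2, thr, ">")
  hap2 <- sweep(draw_haplotypes(), 2, thr, ">")
  dos <- hap1 + hap2
  storage.mode(dos) <- "double"
  sample_ids <- sprintf("ind_%05d", seq_len(n))
  dimnames(dos) <- list(sample_ids, variant_map$rsid)

  alt_freq <- colMeans(dos) / 2
  meta <- variant_map
  meta$maf <- pmin(alt_freq, 1 - alt_freq)
  meta$alt_freq <- alt_freq
  meta$r2 <- stats::runif(m, 0.3, 1.0)
  meta$maf_target <- NULL

  structure(list(values = dos, variant_meta = meta, sample_ids = sample_ids),
            class = "dosage_matrix")
}

#' Simulate sparse tissue-specific eQTL weight models
#'
#' Genes occupy consecutive non-overlapping windows of `snps_per_gene`
#' variants. In the causal tissue (the first tissue), each candidate SNP
#' carries a nonzero weight with probability `weight_sparsity`, drawn from a
#' normal and then rescaled so the model-predicted expression has
#' approximately unit variance under Hardy-Weinberg (making liability effects
#' comparable across genes). A nonzero causal-tissue weight is copied into
#' each other tissue with probability `cross_tissue_sharing`, scaled by that
#' tissue's factor (drawn once per tissue around 1 with sd
#' `tissue_factor_sd`); candidate SNPs with no causal-tissue weight may gain a
#' tissue-private weight with the residual probability
#' `weight_sparsity * (1 - cross_tissue_sharing)`.
#'
#' @param variant_map Variant table from [simulate_variant_map()] or the
#'   `variant_meta` of a `dosage_matrix`.
#' @param config A `simulation_config`.
#' @param seed Integer seed.
#' @return Named list of `weight_model` objects, keyed `GENE@TISSUE`. Each has
#'   `gene`, `gene_chrom`, `gene_tss`, `tissue`, and an `entries` data.frame
#'   (rsid, chrom, pos, ref, alt, effect_allele, weight).
#' @export
simulate_weight_models <- function(variant_map, config, seed = config$seed) {
  validate_config(config)
  if (config$n_genes * config$snps_per_gene > nrow(variant_map)) {
    stop("invalid config: n_genes * snps_per_gene exceeds available variants")
  }
  set.seed(derive_seed(seed, 3))
  tissues <- tissue_labels(config)
  genes <- gene_labels(config)
  spg <- config$snps_per_gene
  tissue_factor <- c(1, 1 + stats::rnorm(config$n_tissues - 1L, 0, config$tissue_factor_sd))

  models <- list()
  for (g in seq_len(config$n_genes)) {
    idx <- ((g - 1L) * spg + 1L):(g * spg)
    win <- variant_map[idx, , drop = FALSE]
    nz_causal <- stats::rbinom(spg, 1L, config$weight_sparsity) == 1L
    w_causal <- ifelse(nz_causal, stats::rnorm(spg), 0)
    # unit predicted-expression variance under HWE, ignoring LD
    hwe_var <- sum(w_causal^2 * 2 * win$maf * (1 - win$maf))
    if (hwe_var > 0) w_causal <- w_causal / sqrt(hwe_var)
    for (t in seq_len(config$n_tissues)) {
      if (t == 1L) {
        w <- w_causal
      } else {
        shared <- nz_causal & (stats::runif(spg) < config$cross_tissue_sharing)
        w <- ifelse(shared, w_causal * tissue_factor[t], 0)
        private_p <- config$weight_sparsity * (1 - config$cross_tissue_sharing)
        private <- !nz_causal & (stats::runif(spg) < private_p)
        if (any(private)) {
          wp <- stats::rnorm(sum(private))
          hv <- 2 * win$maf[private] * (1 - win$maf[private])
          w[private] <- wp / sqrt(max(sum(wp^2 * hv), 1e-12))
        }
      }
      keep <- w != 0
      entries <- data.frame(
        rsid = win$rsid[keep], chrom = win$chrom[keep], pos = win$pos[keep],
        ref = win$ref[keep], alt = win$alt[keep],
        effect_allele = win$alt[keep], weight = w[keep],
        stringsAsFactors = FALSE
      )
      key <- paste0(genes[g], "@", tissues[t])
      models[[key]] <- structure(list(
        gene = genes[g], gene_chrom = win$chrom[1], gene_tss = win$pos[1],
        tissue = tissues[t], entries = entries
      ), class = "weight_model")
    }
  }
  models
}

tissue_labels <- function(config) sprintf("tissue_%02d", seq_len(config$n_tissues))
gene_labels <- function(config) sprintf("gene_%04d", seq_len(config$n_genes))

#' Ground-truth liability record
#'
#' Samples the causal gene set and liability-scale effects. Effects of
#' non-causal genes are exactly zero; the liability operates through the
#' causal tissue's weight models.
#'
#' @param config A `simulation_config`.
#' @param seed Integer seed.
#' @param causal_genes Optional explicit causal gene ids (overrides sampling).
#' @param effects Optional explicit named effect vector (overrides sampling).
#' @return List with `causal_genes`, `liability_effects` (named by gene),
#'   `causal_tissue`, `intercept` (NA until fitted by [simulate_phenotype()]).
#' @export
simulate_truth <- function(config, seed = config$seed,
                           causal_genes = NULL, effects = NULL) {
  genes <- gene_labels(config)
  if (is.null(causal_genes)) {
    set.seed(derive_seed(seed, 4))
    causal_genes <- sort(sample(genes, min(config$n_causal_genes, length(genes))))
  }
  stopifnot(all(causal_genes %in% genes))
  if (is.null(effects)) {
    effects <- stats::rnorm(length(causal_genes), 0, config$effect_sd)
    names(effects) <- causal_genes
  }
  list(causal_genes = causal_genes,
       liability_effects = effects,
       causal_tissue = tissue_labels(config)[1],
       intercept = NA_real_)
}

#' Simulate phenotype and covariates from the liability model
#'
#' Case probability is
#' \deqn{P(y_i = 1) = \mathrm{logit}^{-1}(\alpha + \sum_g \beta_g
#'   \mathrm{GReX}_{ig} + \gamma_{sex} sex_i + \gamma_{age} age'_i)}
#' with GReX computed from the causal tissue's weight models and age
#' standardized. The intercept \eqn{\alpha} is found by bisection so the
#' expected case fraction matches the target within 1e-6. Sex is Bernoulli(0.5);
#' age is Normal(75, 8) truncated to \[60, 95\] (a late-onset design, shared by
#' cases and controls); genetic PCs are standard normal null covariates.
#'
#' @param dosages A `dosage_matrix` for the cohort.
#' @param models Weight-model list from [simulate_weight_models()].
#' @param truth Truth record from [simulate_truth()].
#' @param config A `simulation_config`.
#' @param seed Integer seed.
#' @param case_fraction Target case fraction (defaults to the first study's).
#' @return List with `phenotype` (0/1 vector), `covariates` (data.frame IID,
#'   SEX, AGE, PC1..), `intercept` (fitted alpha), `grex_true` (matrix of true
#'   causal-tissue GReX for the causal genes), `liability`.
#' @export
simulate_phenotype <- function(dosages, models, truth, config,
                               seed = config$seed,
                               case_fraction = config$case_fraction[1]) {
  stopifnot(truth$causal_tissue %in% vapply(models, `[[`, "", "tissue"))
  set.seed(derive_seed(seed, 5))
  n <- length(dosages$sample_ids)
  sex <- stats::rbinom(n, 1L, 0.5)
  age <- stats::rnorm(n, 75, 8)
  age <- pmin(pmax(age, 60), 95)
  pcs <- matrix(stats::rnorm(n * config$n_genetic_pcs), nrow = n)
  colnames(pcs) <- paste0("PC", seq_len(config$n_genetic_pcs))
  age_std <- as.numeric(scale(age))

  lin <- config$covar_effects[["sex"]] * sex + config$covar_effects[["age"]] * age_std
  grex_true <- NULL
  if (length(truth$causal_genes) > 0 && any(truth$liability_effects != 0)) {
    causal_keys <- paste0(truth$causal_genes, "@", truth$causal_tissue)
    causal_models <- models[intersect(causal_keys, names(models))]
    if (length(causal_models) > 0) {
      gx <- impute_grex(dosages, causal_models, warn_empty = FALSE)
      grex_true <- gx$values
      for (g in truth$causal_genes) {
        key <- paste0(g, "@", truth$causal_tissue)
        if (key %in% colnames(grex_true)) {
          lin <- lin + truth$liability_effects[[g]] * grex_true[, key]
        }
      }
    }
  }

  f <- function(alpha) mean(stats::plogis(alpha + lin)) - case_fraction
  lo <- -50; hi <- 50
  if (f(lo) > 0 || f(hi) < 0) {
    stop("configuration error: cannot bracket the intercept for case fraction ",
         case_fraction, " (liability range [", round(min(lin), 2), ", ",
         round(max(lin), 2), "])")
  }
  alpha <- stats::uniroot(f, c(lo, hi), tol = 1e-9)$root
  stopifnot(abs(f(alpha)) < 1e-6)

  y <- stats::rbinom(n, 1L, stats::plogis(alpha + lin))
  covariates <- data.frame(IID = dosages$sample_ids, SEX = sex, AGE = age,
                           stringsAsFactors = FALSE)
  covariates <- cbind(covariates, as.data.frame(pcs))
  list(phenotype = y, covariates = covariates, intercept = alpha,
       grex_true = grex_true, liability = lin)
}

#' Simulate one study cohort
#'
#' Convenience wrapper drawing genotypes, covariates and phenotype for one
#' study of a multi-study design, against a shared variant map / model set.
#'
#' @inheritParams simulate_phenotype
#' @param study Study index in `1..n_studies`.
#' @param variant_map Shared variant map.
#' @return List (`study_id`, `dosages`, `phenotype`, `covariates`,
#'   `intercept`).
#' @export
simulate_cohort <- function(config, models, truth, study = 1L,
                            seed = config$seed, variant_map = NULL) {
  if (is.null(variant_map)) variant_map <- simulate_variant_map(config, seed)
  study_seed <- derive_seed(seed, 100 + study)
  dos <- simulate_genotypes(config, seed = study_seed, variant_map = variant_map,
                            n = config$n_per_study[study])
  ph <- simulate_phenotype(dos, models, truth, config, seed = study_seed,
                           case_fraction = config$case_fraction[study])
  list(study_id = sprintf("study_%02d", study), dosages = dos,
       phenotype = ph$phenotype, covariates = ph$covariates,
       intercept = ph$intercept)
}

#' Simulate a complete multi-study set
#'
#' @param config A `simulation_config`.
#' @param seed Integer seed.
#' @param gwas If `TRUE`, also compute per-study GWAS summary statistics and
#'   the in-cohort LD reference via [compute_gwas_summary()].
#' @return List with `variant_map`, `models`, `truth`, `cohorts` (list of
#'   study cohorts) and, if requested, `summary` (per-study list of
#'   `stats`/`ld`).
#' @export
simulate_study_set <- function(config, seed = config$seed, gwas = FALSE) {
  validate_config(config)
  variant_map <- simulate_variant_map(config, seed)
  models <- simulate_weight_models(variant_map, config, seed)
  truth <- simulate_truth(config, seed)
  cohorts <- lapply(seq_len(config$n_studies), function(s) {
    simulate_cohort(config, models, truth, study = s, seed = seed,
                    variant_map = variant_map)
  })
  out <- list(variant_map = variant_map, models = models, truth = truth,
              cohorts = cohorts)
  if (gwas) {
    out$summary <- lapply(cohorts, compute_gwas_summary, models = models)
  }
  out
}

#' Per-variant GWAS summary statistics and in-cohort LD reference
#'
#' Runs an ordinary (non-Firth) logistic Wald test per variant, adjusting for
#' sex, standardized age and genetic PCs — the standard single-variant GWAS
#' model behind published summary statistics. The LD reference holds, per
#' gene, the empirical dosage covariance of the gene's model variants and the
#' per-variant dosage variances, computed in the same cohort (playing the
#' "reference population" role). Monomorphic variants are recorded with z = 0
#' and flagged, and excluded from the covariance.
#'
#' @param cohort A cohort list as produced by [simulate_cohort()].
#' @param models Weight-model list (defines the per-gene LD variant sets).
#' @return List with `stats` (data.frame SNP, CHR, POS, A1, A2, FRQ, BETA,
#'   SE, Z, P, N, R2, MONOMORPHIC) and `ld` (per gene: `variants`, `gamma`,
#'   `sigma2`).
#' @export
compute_gwas_summary <- function(cohort, models) {
  y <- cohort$phenotype
  stopifnot(all(y %in% c(0, 1)))
  dos <- cohort$dosages
  n <- length(y)
  covar <- covariate_design(cohort$covariates)
  meta <- dos$variant_meta
  m <- nrow(meta)

  beta <- se <- rep(NA_real_, m)
  mono <- apply(dos$values, 2, function(d) stats::var(d) == 0)
  base_fit <- stats::glm.fit(covar, y, family = stats::binomial())
  start <- c(base_fit$coefficients, 0)
  for (j in seq_len(m)) {
    if (mono[j]) next
    X <- cbind(covar, dose = dos$values[, j])
    fit <- suppressWarnings(
      stats::glm.fit(X, y, family = stats::binomial(), start = start)
    )
    k <- ncol(X)
    w <- fit$weights
    XtWX <- crossprod(X * sqrt(w))
    v <- tryCatch(chol2inv(chol(XtWX))[k, k], error = function(e) NA_real_)
    beta[j] <- fit$coefficients[k]
    se[j] <- sqrt(v)
  }
  z <- ifelse(mono, 0, beta / se)
  p <- ifelse(mono, 1, 2 * stats::pnorm(-abs(z)))
  stats <- data.frame(
    SNP = meta$rsid, CHR = meta$chrom, POS = meta$pos,
    A1 = meta$alt, A2 = meta$ref, FRQ = meta$alt_freq,
    BETA = ifelse(mono, 0, beta), SE = se, Z = z, P = p, N = n,
    R2 = meta$r2, MONOMORPHIC = mono,
    stringsAsFactors = FALSE
  )

  list(stats = stats, ld = ld_reference(dos, models))
}

# Internal: intercept + SEX + standardized AGE + PCs design from a covariate
# table as written by the simulator (IID, SEX, AGE, PC1..).
covariate_design <- function(covariates) {
  pcs <- grep("^PC[0-9]+$", names(covariates), value = TRUE)
  X <- cbind(
    `(Intercept)` = 1,
    SEX = covariates$SEX,
    AGE = as.numeric(scale(covariates$AGE))
  )
  if (length(pcs) > 0) X <- cbind(X, as.matrix(covariates[pcs]))
  X
}
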