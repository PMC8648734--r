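small_cfg <- function(...) {
  args <- utils::modifyList(
    list(n_studies = 1, n_per_study = 400, n_variants = 100,
         n_genes = 10, n_tissues = 3),
    list(...)
  )
  do.call(simulation_config, args)
}

test_that("identical config and seed give bit-identical outputs", {
  cfg <- small_cfg(seed = 7)
  a <- simulate_genotypes(cfg, seed = 7)
  b <- simulate_genotypes(cfg, seed = 7)
  expect_identical(a$values, b$values)
  expect_identical(a$variant_meta, b$variant_meta)
  ma <- simulate_weight_models(a$variant_meta, cfg, seed = 7)
  mb <- simulate_weight_models(b$variant_meta, cfg, seed = 7)
  expect_identical(ma, mb)
})

test_that("dosages lie in [0,2] and metadata aligns with columns", {
  d <- simulate_genotypes(small_cfg(seed = 2))
  expect_true(all(d$values >= 0 & d$values <= 2))
  expect_equal(nrow(d$variant_meta), ncol(d$values))
  expect_true(all(d$variant_meta$r2 > 0 & d$variant_meta$r2 <= 1))
  expect_true(all(d$variant_meta$pos >= 1))
})

test_that("ld_rho = 0 gives independent adjacent variants", {
  cfg <- small_cfg(n_per_study = 2000, ld_rho = 0, seed = 5)
  d <- simulate_genotypes(cfg)
  r2 <- sapply(1:(ncol(d$values) - 1), function(j) {
    cor(d$values[, j], d$values[, j + 1])^2
  })
  expect_lt(mean(r2), 0.01)
})

test_that("realized MAF is within 3 binomial SDs of the target", {
  cfg <- simulation_config(n_studies = 1, n_per_study = 5000, n_variants = 20,
                           n_genes = 2, maf_range = c(0.3, 0.3), seed = 9)
  d <- simulate_genotypes(cfg, n = 5000)
  tol <- 3 * sqrt(0.3 * 0.7 / (2 * 5000))
  expect_true(all(abs(d$variant_meta$maf - 0.3) < tol))
})

test_that("adjacent-pair r2 increases monotonically with ld_rho", {
  r2_at <- sapply(c(0, 0.3, 0.6, 0.9), function(rho) {
    cfg <- simulation_config(n_studies = 1, n_per_study = 5000,
                             n_variants = 50, n_genes = 5, ld_rho = rho,
                             seed = 31)
    d <- simulate_genotypes(cfg, n = 5000)
    mean(sapply(1:49, function(j) {
      if (j %% cfg$block_size == 0) return(NA)  # block boundary
      cor(d$values[, j], d$values[, j + 1])^2
    }), na.rm = TRUE)
  })
  expect_true(all(diff(r2_at) > 0))
})

test_that("invalid configurations are rejected", {
  expect_error(simulation_config(maf_range = c(0, 0.6)), "maf_range")
  expect_error(simulation_config(case_fraction = 1), "case_fraction")
  expect_error(simulation_config(n_genes = 100, snps_per_gene = 10,
                                 n_variants = 500), "non-overlapping")
  expect_error(simulation_config(ld_rho = 1), "ld_rho")
})

test_that("weight sparsity controls the nonzero count per causal model", {
  cfg <- simulation_config(n_studies = 1, n_per_study = 100,
                           n_variants = 2000, n_genes = 200,
                           snps_per_gene = 10, weight_sparsity = 0.5,
                           n_tissues = 2, seed = 13)
  vm <- simulate_variant_map(cfg)
  models <- simulate_weight_models(vm, cfg)
  causal <- models[grepl("tissue_01$", names(models))]
  counts <- vapply(causal, function(m) nrow(m$entries), integer(1))
  # mean of 200 Binomial(10, 0.5) draws: 3 SDs of the mean
  expect_lt(abs(mean(counts) - 5), 3 * sqrt(10 * 0.25 / 200))
})

test_that("zero sparsity gives empty models and no GReX columns", {
  cfg <- small_cfg(weight_sparsity = 0, seed = 3)
  d <- simulate_genotypes(cfg)
  models <- simulate_weight_models(d$variant_meta, cfg)
  expect_true(all(vapply(models, function(m) nrow(m$entries), integer(1)) == 0))
  gx <- impute_grex(d, models, warn_empty = FALSE)
  expect_equal(ncol(gx$values), 0)
})

test_that("full sharing with unit tissue factors copies weights exactly", {
  cfg <- small_cfg(cross_tissue_sharing = 1, tissue_factor_sd = 0,
                   weight_sparsity = 0.5, seed = 21)
  vm <- simulate_variant_map(cfg)
  models <- simulate_weight_models(vm, cfg)
  for (g in unique(vapply(models, `[[`, "", "gene"))) {
    keys <- names(models)[startsWith(names(models), paste0(g, "@"))]
    ref <- models[[keys[1]]]$entries
    for (k in keys[-1]) {
      expect_equal(models[[k]]$entries$rsid, ref$rsid)
      expect_equal(models[[k]]$entries$weight, ref$weight)
    }
  }
})

test_that("null liability model hits the target case fraction", {
  cfg <- simulation_config(n_studies = 1, n_per_study = 10000,
                           n_variants = 50, n_genes = 5,
                           case_fraction = 0.3, n_causal_genes = 0,
                           covar_effects = c(sex = 0, age = 0), seed = 17)
  d <- simulate_genotypes(cfg, n = 10000)
  models <- simulate_weight_models(d$variant_meta, cfg)
  truth <- simulate_truth(cfg, causal_genes = character(0),
                          effects = numeric(0))
  ph <- simulate_phenotype(d, models, truth, cfg, case_fraction = 0.3)
  expect_lt(abs(mean(ph$phenotype) - 0.3), 3 * sqrt(0.3 * 0.7 / 10000))
})

test_that("realized case fraction tracks the target across 20 seeds", {
  cfg <- simulation_config(n_studies = 1, n_per_study = 500, n_variants = 50,
                           n_genes = 5, case_fraction = 0.45, seed = 1)
  vm <- simulate_variant_map(cfg, seed = 1)
  models <- simulate_weight_models(vm, cfg, seed = 1)
  truth <- simulate_truth(cfg, seed = 1)
  fr <- sapply(1:20, function(s) {
    d <- simulate_genotypes(cfg, seed = s, variant_map = vm, n = 500)
    mean(simulate_phenotype(d, models, truth, cfg, seed = s)$phenotype)
  })
  expect_lt(abs(mean(fr) - 0.45), 3 * sqrt(0.45 * 0.55 / (20 * 500)))
})

test_that("logistic regression on true GReX recovers the liability effect", {
  cfg <- simulation_config(n_studies = 1, n_per_study = 20000,
                           n_variants = 50, n_genes = 5, n_tissues = 1,
                           weight_sparsity = 0.5, seed = 23)
  d <- simulate_genotypes(cfg, n = 20000)
  models <- simulate_weight_models(d$variant_meta, cfg)
  truth <- simulate_truth(cfg, causal_genes = "gene_0001",
                          effects = c(gene_0001 = 0.5))
  ph <- simulate_phenotype(d, models, truth, cfg)
  gx <- ph$grex_true[, "gene_0001@tissue_01"]
  fit <- glm(ph$phenotype ~ gx + ph$covariates$SEX + scale(ph$covariates$AGE),
             family = binomial())
  ci <- suppressMessages(confint.default(fit, "gx"))
  expect_true(ci[1] <= 0.5 && 0.5 <= ci[2])
  # monotonicity: cases carry higher causal GReX under a positive effect
  expect_gt(mean(gx[ph$phenotype == 1]), mean(gx[ph$phenotype == 0]))
})

test_that("per-variant GWAS z agrees with an independent textbook Wald refit", {
  cfg <- small_cfg(n_per_study = 1500, seed = 29)
  set <- simulate_study_set(cfg)
  coh <- set$cohorts[[1]]
  gs <- compute_gwas_summary(coh, set$models)
  pick <- seq(1, 100, by = 10)
  refit_z <- sapply(pick, function(j) {
    d <- coh$dosages$values[, j]
    f <- glm(coh$phenotype ~ d + coh$covariates$SEX +
               scale(coh$covariates$AGE) + coh$covariates$PC1 +
               coh$covariates$PC2 + coh$covariates$PC3 + coh$covariates$PC4,
             family = binomial())
    summary(f)$coefficients["d", "z value"]
  })
  expect_gt(cor(gs$stats$Z[pick], refit_z), 0.99)
})

test_that("LD reference diagonals equal empirical dosage variances", {
  cfg <- small_cfg(seed = 37)
  set <- simulate_study_set(cfg)
  gs <- compute_gwas_summary(set$cohorts[[1]], set$models)
  g <- names(gs$ld)[1]
  v <- gs$ld[[g]]$variants
  expect_equal(gs$ld[[g]]$sigma2,
               apply(set$cohorts[[1]]$dosages$values[, v, drop = FALSE], 2, var))
  expect_equal(gs$ld[[g]]$gamma, t(gs$ld[[g]]$gamma))
})

test_that("null variants rarely reach |z| = 4 and monomorphics are flagged", {
  cfg <- simulation_config(n_studies = 1, n_per_study = 2000, n_variants = 50,
                           n_genes = 5, n_causal_genes = 0, seed = 41)
  set <- simulate_study_set(cfg)
  coh <- set$cohorts[[1]]
  # force a monomorphic column
  coh$dosages$values[, 3] <- 0
  gs <- compute_gwas_summary(coh, set$models)
  expect_true(gs$stats$MONOMORPHIC[3])
  expect_equal(gs$stats$Z[3], 0)
  expect_true(all(abs(gs$stats$Z[!gs$stats$MONOMORPHIC]) < 4.5))
})
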