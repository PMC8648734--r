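fake_stats <- function(rsid, z, a1 = "G", a2 = "A", frq = 0.3, r2 = 1, n = 1000) {
  data.frame(SNP = rsid, CHR = "1", POS = seq_along(rsid) * 1000,
             A1 = rep_len(a1, length(rsid)), A2 = rep_len(a2, length(rsid)),
             FRQ = rep_len(frq, length(rsid)), BETA = z / 10, SE = 0.1,
             Z = z, P = 2 * pnorm(-abs(z)), N = n,
             R2 = rep_len(r2, length(rsid)), MONOMORPHIC = FALSE,
             stringsAsFactors = FALSE)
}

fake_ld <- function(rsid, gamma) {
  dimnames(gamma) <- list(rsid, rsid)
  list(variants = rsid, gamma = gamma, sigma2 = diag(gamma))
}

test_that("summary filter is the identity when all records pass", {
  s <- fake_stats(paste0("rs", 1:5), rnorm(5), frq = 0.3, r2 = 0.9)
  expect_equal(nrow(filter_summary(s)), 5)
  expect_equal(nrow(filter_summary(s, maf_min = 0, r2_min = 0)), 5)
})

test_that("summary filter removes low-frequency or low-quality records", {
  s <- fake_stats(paste0("rs", 1:8), rnorm(8))
  s$FRQ <- c(0.005, 0.3, 0.995, 0.2, 0.4, 0.25, 0.35, 0.45)  # 2 fail MAF
  s$R2 <- c(0.9, 0.3, 0.9, 0.9, 0.9, 0.9, 0.9, 0.9)          # 1 more fails R2
  out <- filter_summary(s, maf_min = 0.01, r2_min = 0.5)
  expect_equal(nrow(out), 5)
  expect_error(filter_summary(s, maf_min = 0.49, r2_min = 0.99), "pass")
})

test_that("a single-SNP model returns the signed per-variant z", {
  s <- fake_stats("rs1", 2.5)
  ld <- fake_ld("rs1", matrix(0.4, 1, 1))
  m <- make_model("g1", "t1", "rs1", 1.3, pos = 1000)
  res <- spredixcan_z(m, s, ld)
  expect_equal(res$z, 2.5, tolerance = 1e-12)
  m_neg <- make_model("g1", "t1", "rs1", -1.3, pos = 1000)
  expect_equal(spredixcan_z(m_neg, s, ld)$z, -2.5, tolerance = 1e-12)
})

test_that("all-null summary z gives a null gene z", {
  s <- fake_stats(paste0("rs", 1:3), c(0, 0, 0))
  ld <- fake_ld(paste0("rs", 1:3), diag(c(0.3, 0.4, 0.5)))
  m <- make_model("g1", "t1", paste0("rs", 1:3), c(0.5, -0.2, 0.1),
                  pos = 1:3 * 1000)
  res <- spredixcan_z(m, s, ld)
  expect_equal(res$z, 0)
  expect_equal(res$p, 1)
})

test_that("flipping the coded allele of a summary record leaves z_g unchanged", {
  set.seed(40)
  z <- rnorm(4)
  s <- fake_stats(paste0("rs", 1:4), z)
  gamma <- crossprod(matrix(rnorm(16), 4)) / 4 + diag(0.1, 4)
  ld <- fake_ld(paste0("rs", 1:4), gamma)
  m <- make_model("g1", "t1", paste0("rs", 1:4), rnorm(4), pos = 1:4 * 1000)
  base <- spredixcan_z(m, s, ld)$z
  s2 <- s
  s2$Z[2] <- -s2$Z[2]
  s2$A1[2] <- "A"; s2$A2[2] <- "G"
  s2$FRQ[2] <- 1 - s2$FRQ[2]
  expect_equal(spredixcan_z(m, s2, ld)$z, base, tolerance = 1e-12)
})

test_that("z_g is invariant to positive rescaling of the weights", {
  set.seed(41)
  s <- fake_stats(paste0("rs", 1:4), rnorm(4))
  gamma <- crossprod(matrix(rnorm(16), 4)) / 4 + diag(0.1, 4)
  ld <- fake_ld(paste0("rs", 1:4), gamma)
  w <- rnorm(4)
  m1 <- make_model("g1", "t1", paste0("rs", 1:4), w, pos = 1:4 * 1000)
  m7 <- make_model("g1", "t1", paste0("rs", 1:4), 7 * w, pos = 1:4 * 1000)
  expect_equal(spredixcan_z(m1, s, ld)$z, spredixcan_z(m7, s, ld)$z,
               tolerance = 1e-12)
})

test_that("weights on unusable variants make the gene untestable", {
  s <- fake_stats("rs1", 1.0)
  ld <- fake_ld("rs1", matrix(0.4, 1, 1))
  m <- make_model("g1", "t1", c("rs98", "rs99"), c(1, 1), pos = c(98, 99) * 1000)
  expect_error(spredixcan_z(m, s, ld), "untestable")
})

test_that("perfectly correlated tissues collapse to z-squared with one df", {
  rsid <- paste0("rs", 1:2)
  gamma <- matrix(c(0.4, 0.2, 0.2, 0.4), 2)
  ld <- fake_ld(rsid, gamma)
  w <- c(0.7, 0.3)
  models <- list(t1 = make_model("g1", "t1", rsid, w, pos = 1:2 * 1000),
                 t2 = make_model("g1", "t2", rsid, w, pos = 1:2 * 1000))
  z <- c(t1 = 2.2, t2 = 2.2)
  res <- summary_cross_tissue(z, models, ld)
  expect_equal(res$n_pcs, 1L)
  expect_equal(res$stat, 2.2^2, tolerance = 1e-8)
})

test_that("independent tissues give the sum of squared z with full df", {
  rsid <- paste0("rs", 1:2)
  ld <- fake_ld(rsid, diag(c(0.4, 0.5)))
  models <- list(t1 = make_model("g1", "t1", rsid, c(1, 0), pos = 1:2 * 1000),
                 t2 = make_model("g1", "t2", rsid, c(0, 1), pos = 1:2 * 1000))
  z <- c(t1 = 1.5, t2 = -0.7)
  res <- summary_cross_tissue(z, models, ld)
  expect_equal(res$n_pcs, 2L)
  expect_equal(res$stat, 1.5^2 + 0.7^2, tolerance = 1e-10)
})

test_that("the summary cross-tissue test is calibrated under the null", {
  pvals <- c()
  for (s in 1:10) {
    cfg <- simulation_config(n_studies = 1, n_per_study = 1000,
                             n_variants = 400, n_genes = 100, n_tissues = 4,
                             snps_per_gene = 4, weight_sparsity = 0.6,
                             cross_tissue_sharing = 0.5, n_causal_genes = 0,
                             seed = s)
    set <- simulate_study_set(cfg, seed = s, gwas = TRUE)
    stats <- set$summary[[1]]$stats
    ld <- set$summary[[1]]$ld
    sp <- spredixcan_scan(set$models, stats, ld)
    for (g in unique(sp$GENE)) {
      rows <- sp[sp$GENE == g, ]
      if (nrow(rows) < 2 || is.null(ld[[g]])) next
      z <- stats::setNames(rows$Z, rows$TISSUE)
      mg <- set$models[paste0(g, "@", rows$TISSUE)]
      names(mg) <- rows$TISSUE
      p <- tryCatch(summary_cross_tissue(z, mg, ld[[g]])$p,
                    error = function(e) NA_real_)
      pvals <- c(pvals, p)
    }
  }
  pvals <- pvals[!is.na(pvals)]
  expect_gte(length(pvals), 800)
  rate <- mean(pvals < 0.05)
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)
})
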