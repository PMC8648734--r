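test_that("zero thresholds keep every variant", {
  d <- make_dosage(matrix(rbinom(40, 2, 0.3), 8, 5))
  f <- filter_variants(d, maf_min = 0, r2_min = 0)
  expect_equal(dim(f$values), dim(d$values))
})

test_that("MAF filter keeps exactly the strict exceedances", {
  vals <- matrix(1, 4, 10)
  d <- make_dosage(vals, maf = seq(0.01, 0.10, by = 0.01), r2 = rep(1, 10))
  f <- filter_variants(d, maf_min = 0.05, r2_min = 0)
  expect_equal(ncol(f$values), 5)
  expect_equal(f$variant_meta$maf, seq(0.06, 0.10, by = 0.01))
})

test_that("joint filter matches a brute-force metadata scan", {
  cfg <- simulation_config(n_studies = 1, n_per_study = 300, n_variants = 100,
                           n_genes = 10, n_tissues = 2, maf_range = c(0.01, 0.5),
                           seed = 4)
  d <- simulate_genotypes(cfg)
  f <- filter_variants(d, maf_min = 0.05, r2_min = 0.5)
  brute <- sum(sapply(seq_len(nrow(d$variant_meta)), function(i) {
    d$variant_meta$maf[i] > 0.05 && d$variant_meta$r2[i] > 0.5
  }))
  expect_equal(ncol(f$values), brute)
})

test_that("removing everything is an error naming the thresholds", {
  d <- make_dosage(matrix(1, 4, 3), maf = rep(0.01, 3))
  expect_error(filter_variants(d, maf_min = 0.4, r2_min = 0.5), "0.4")
})

test_that("alt-effect entries match with zero flips", {
  d <- make_dosage(matrix(rbinom(30, 2, 0.4), 10, 3))
  m <- make_model("g1", "t1", d$variant_meta$rsid, c(0.5, -0.2, 0.1),
                  pos = d$variant_meta$pos)
  h <- harmonize_model(m, d$variant_meta)
  expect_equal(unname(h$report$counts["matched"]), 3L)
  expect_equal(unname(h$report$counts["flipped"]), 0L)
})

test_that("ref-effect entries contribute w * (2 - d)", {
  d <- make_dosage(matrix(c(0, 1, 2, 1), 4, 1))
  m <- make_model("g1", "t1", d$variant_meta$rsid, 1, effect_allele = "A",
                  pos = d$variant_meta$pos)
  gx <- impute_grex(d, list(`g1@t1` = m))
  expect_equal(unname(gx$values[, 1]), 2 - c(0, 1, 2, 1))
})

test_that("missing model SNPs reduce coverage and are dropped from the sum", {
  d <- make_dosage(matrix(rbinom(50, 2, 0.3), 10, 5))
  rsids <- c(d$variant_meta$rsid, "rs999001", "rs999002", "rs999003")
  m <- make_model("g1", "t1", rsids, rep(0.3, 8),
                  pos = c(d$variant_meta$pos, 91000, 92000, 93000))
  h <- harmonize_model(m, d$variant_meta)
  expect_equal(unname(h$report$counts["missing"]), 3L)
  gx <- impute_grex(d, list(`g1@t1` = m))
  expect_equal(gx$coverage$n_snps_used, 5L)
  expect_equal(gx$coverage$n_snps_in_model, 8L)
})

test_that("irreconcilable alleles are reported and excluded", {
  d <- make_dosage(matrix(rbinom(20, 2, 0.3), 10, 2))
  m <- make_model("g1", "t1", d$variant_meta$rsid, c(1, 1),
                  ref = c("A", "C"), alt = c("G", "T"),
                  effect_allele = c("G", "T"), pos = d$variant_meta$pos)
  h <- harmonize_model(m, d$variant_meta)
  expect_equal(unname(h$report$counts["allele_mismatch"]), 1L)
  expect_equal(unname(h$report$counts["matched"]), 1L)
  expect_true(all(c("matched", "allele_mismatch") %in% h$report$status$status))
})

test_that("a 3-SNP toy model reproduces hand-computed weighted sums", {
  vals <- matrix(c(0, 1, 2, 1,
                   2, 0, 1, 2,
                   1, 1, 0, 2), nrow = 4)
  d <- make_dosage(vals)
  w <- c(0.5, -0.2, 0.1)
  m <- make_model("g1", "t1", d$variant_meta$rsid, w, pos = d$variant_meta$pos)
  gx <- impute_grex(d, list(`g1@t1` = m))
  hand <- c(0.5 * 0 - 0.2 * 2 + 0.1 * 1,
            0.5 * 1 - 0.2 * 0 + 0.1 * 1,
            0.5 * 2 - 0.2 * 1 + 0.1 * 0,
            0.5 * 1 - 0.2 * 2 + 0.1 * 2)
  expect_equal(unname(gx$values[, 1]), hand)
})

test_that("a single-SNP alt-effect model with w = 1 reproduces the dosage column", {
  d <- make_dosage(matrix(rbinom(12, 2, 0.4), 12, 1))
  m <- make_model("g1", "t1", d$variant_meta$rsid, 1, pos = d$variant_meta$pos)
  gx <- impute_grex(d, list(`g1@t1` = m))
  expect_equal(unname(gx$values[, 1]), unname(d$values[, 1]))
})

test_that("imputation is linear in the weights", {
  set.seed(8)
  d <- make_dosage(matrix(rbinom(60, 2, 0.3), 12, 5))
  w <- rnorm(5)
  m1 <- make_model("g1", "t1", d$variant_meta$rsid, w, pos = d$variant_meta$pos)
  m3 <- make_model("g1", "t1", d$variant_meta$rsid, 3 * w, pos = d$variant_meta$pos)
  g1 <- impute_grex(d, list(`g1@t1` = m1))$values
  g3 <- impute_grex(d, list(`g1@t1` = m3))$values
  expect_equal(3 * g1, g3)
})

test_that("recoding a variant (swap alleles, d -> 2 - d) leaves GReX unchanged", {
  set.seed(9)
  d <- make_dosage(matrix(rbinom(36, 2, 0.4), 12, 3))
  w <- c(0.4, -0.3, 0.2)
  m <- make_model("g1", "t1", d$variant_meta$rsid, w, pos = d$variant_meta$pos)
  before <- impute_grex(d, list(`g1@t1` = m))$values
  # recode variant 2: swap ref/alt and complement the dosage
  d2 <- d
  d2$values[, 2] <- 2 - d2$values[, 2]
  d2$variant_meta$ref[2] <- "G"
  d2$variant_meta$alt[2] <- "A"
  after <- impute_grex(d2, list(`g1@t1` = m))$values
  expect_equal(before, after)
})

test_that("dropping a model SNP changes only its additive contribution", {
  set.seed(10)
  d <- make_dosage(matrix(rbinom(48, 2, 0.3), 12, 4))
  w <- c(0.4, -0.3, 0.2, 0.1)
  m <- make_model("g1", "t1", d$variant_meta$rsid, w, pos = d$variant_meta$pos)
  full <- impute_grex(d, list(`g1@t1` = m))$values[, 1]
  d_drop <- d
  keep <- c(1, 2, 4)
  d_drop$values <- d_drop$values[, keep]
  d_drop$variant_meta <- d_drop$variant_meta[keep, ]
  reduced <- impute_grex(d_drop, list(`g1@t1` = m))$values[, 1]
  expect_equal(unname(full - reduced), unname(0.2 * d$values[, 3]))
})

test_that("a model with zero usable variants is omitted with a warning", {
  d <- make_dosage(matrix(rbinom(20, 2, 0.3), 10, 2))
  m <- make_model("g9", "t1", c("rs555001", "rs555002"), c(1, 1),
                  pos = c(77000, 78000))
  expect_warning(gx <- impute_grex(d, list(`g9@t1` = m)), "zero usable")
  expect_equal(ncol(gx$values), 0)
})
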