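# Shared builders for small in-code fixtures.

# A dosage_matrix from a plain matrix (columns = variants).
make_dosage <- function(values, maf = NULL, r2 = NULL, chrom = "1",
                        pos = NULL, ref = "A", alt = "G", rsid = NULL) {
  values <- as.matrix(values)
  m <- ncol(values)
  if (is.null(rsid)) rsid <- sprintf("rs%06d", seq_len(m))
  if (is.null(pos)) pos <- seq_len(m) * 1000L
  alt_freq <- colMeans(values) / 2
  if (is.null(maf)) maf <- pmin(alt_freq, 1 - alt_freq)
  if (is.null(r2)) r2 <- rep(1, m)
  colnames(values) <- rsid
  ids <- sprintf("ind_%05d", seq_len(nrow(values)))
  rownames(values) <- ids
  structure(list(
    values = values,
    variant_meta = data.frame(rsid = rsid, chrom = rep_len(chrom, m),
                              pos = pos, ref = rep_len(ref, m),
                              alt = rep_len(alt, m), maf = maf,
                              alt_freq = alt_freq, r2 = r2,
                              stringsAsFactors = FALSE),
    sample_ids = ids
  ), class = "dosage_matrix")
}

# A weight_model from parallel vectors.
make_model <- function(gene, tissue, rsid, weight, effect_allele = "G",
                       ref = "A", alt = "G", chrom = "1", pos = NULL,
                       gene_tss = 1000L) {
  k <- length(rsid)
  if (is.null(pos)) pos <- match(rsid, sprintf("rs%06d", 1:10000)) * 1000L
  structure(list(
    gene = gene, gene_chrom = chrom, gene_tss = gene_tss, tissue = tissue,
    entries = data.frame(rsid = rsid, chrom = rep_len(chrom, k), pos = pos,
                         ref = rep_len(ref, k), alt = rep_len(alt, k),
                         effect_allele = rep_len(effect_allele, k),
                         weight = weight, stringsAsFactors = FALSE)
  ), class = "weight_model")
}

# Minimal covariate table (null covariates) for association fixtures.
make_covariates <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(IID = sprintf("ind_%05d", seq_len(n)),
             SEX = rbinom(n, 1, 0.5),
             AGE = runif(n, 60, 95),
             PC1 = rnorm(n), PC2 = rnorm(n),
             stringsAsFactors = FALSE)
}

# Independent penalized log-likelihood for the grid oracle: written from the
# definition, no code shared with fit_firth.
oracle_pll <- function(b, X, y) {
  eta <- drop(X %*% b)
  p <- 1 / (1 + exp(-eta))
  l <- sum(y * eta - log(1 + exp(eta)))
  W <- diag(p * (1 - p), nrow(X))
  info <- t(X) %*% W %*% X
  l + 0.5 * determinant(info, logarithm = TRUE)$modulus[1]
}

# Two-stage dense grid maximization of the penalized likelihood over
# (intercept, slope); resolution 1e-3 after refinement.
oracle_grid_max <- function(X, y, lim = 5) {
  coarse <- seq(-lim, lim, by = 0.05)
  best <- c(0, 0); best_v <- -Inf
  for (b0 in coarse) for (b1 in coarse) {
    v <- oracle_pll(c(b0, b1), X, y)
    if (v > best_v) { best_v <- v; best <- c(b0, b1) }
  }
  fine0 <- seq(best[1] - 0.06, best[1] + 0.06, by = 0.001)
  fine1 <- seq(best[2] - 0.06, best[2] + 0.06, by = 0.001)
  for (b0 in fine0) for (b1 in fine1) {
    v <- oracle_pll(c(b0, b1), X, y)
    if (v > best_v) { best_v <- v; best <- c(b0, b1) }
  }
  best
}
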