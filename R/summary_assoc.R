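#' Filter GWAS summary statistics by frequency and imputation quality
#'
#' Removes variants with MAF below `maf_min` or imputation R-squared below
#' `r2_min` — the standard cleaning applied to published summary statistics
#' before summary-level expression imputation.
#'
#' @param stats Summary-statistics data.frame with columns `FRQ` (effect
#'   allele frequency) and `R2`.
#' @param maf_min Minimum minor-allele frequency.
#' @param r2_min Minimum imputation quality.
#' @return The filtered data.frame.
#' @export
filter_summary <- function(stats, maf_min = 0.01, r2_min = 0.5) {
  maf <- pmin(stats$FRQ, 1 - stats$FRQ)
  keep <- maf >= maf_min & stats$R2 >= r2_min
  if (!any(keep)) {
    stop("no summary records pass MAF >= ", maf_min, " and R2 >= ", r2_min)
  }
  out <- stats[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summary-statistic gene-level association (S-PrediXcan statistic)
#'
#' Infers the GReX-trait association z-score for one gene-by-tissue weight
#' model from per-variant GWAS summary statistics and an LD reference:
#' \deqn{z_g = \sum_l w_l \frac{\sigma_l}{\sigma_g} z_l, \qquad
#'   \sigma_g^2 = \sum_l \sum_m w_l w_m \Gamma_{lm}}
#' where \eqn{\Gamma} is the dosage covariance of the model variants in the
#' reference and \eqn{\sigma_l^2} its diagonal. Model entries whose effect
#' allele is the summary A2 (other) allele have their summary z sign-flipped
#' before combination. Only variants present in both the summary table and
#' the LD reference enter the sums.
#'
#' @param model A `weight_model`.
#' @param stats Summary data.frame (columns SNP, A1, A2, Z at minimum).
#' @param ld LD reference list for this gene: `variants`, `gamma`, `sigma2`
#'   (as produced by [compute_gwas_summary()]).
#' @param tol Numerical floor for \eqn{\sigma_g^2}.
#' @return List with `gene`, `tissue`, `z`, `p`, `n_snps_used`, `sigma_g`.
#' @export
spredixcan_z <- function(model, stats, ld, tol = 1e-12) {
  e <- model$entries
  idx <- match(e$rsid, stats$SNP)
  usable <- !is.na(idx) & e$rsid %in% ld$variants
  if (!any(usable)) {
    stop("untestable gene ", model$gene, ": no model variant has both summary ",
         "statistics and LD reference data")
  }
  e <- e[usable, , drop = FALSE]
  idx <- idx[usable]
  z_l <- stats$Z[idx]
  a1 <- stats$A1[idx]; a2 <- stats$A2[idx]
  flip <- e$effect_allele == a2
  bad <- !(e$effect_allele == a1 | flip)
  if (any(bad)) {
    e <- e[!bad, , drop = FALSE]; z_l <- z_l[!bad]; flip <- flip[!bad]
    if (nrow(e) == 0) stop("untestable gene ", model$gene, ": allele mismatch")
  }
  z_l <- ifelse(flip, -z_l, z_l)

  li <- match(e$rsid, ld$variants)
  gamma <- ld$gamma[li, li, drop = FALSE]
  sigma_l <- sqrt(ld$sigma2[li])
  w <- e$weight
  sigma_g2 <- drop(t(w) %*% gamma %*% w)
  if (sigma_g2 <= tol) {
    stop("untestable gene ", model$gene, ": predicted expression variance ~ 0")
  }
  sigma_g <- sqrt(sigma_g2)
  z_g <- sum(w * sigma_l / sigma_g * z_l)
  list(gene = model$gene, tissue = model$tissue, z = z_g,
       p = 2 * stats::pnorm(-abs(z_g)), n_snps_used = nrow(e),
       sigma_g = sigma_g)
}

#' Summary-level association scan over all models
#'
#' @param models Named list of `weight_model`s.
#' @param stats Summary-statistics data.frame.
#' @param ld Per-gene LD reference list.
#' @param study Study label recorded in the output.
#' @return data.frame GENE, TISSUE, STUDY, Z, P, N_SNPS_USED, SIGMA_G;
#'   untestable models are skipped.
#' @export
spredixcan_scan <- function(models, stats, ld, study = "study_01") {
  rows <- lapply(names(models), function(key) {
    m <- models[[key]]
    if (is.null(ld[[m$gene]])) return(NULL)
    r <- tryCatch(spredixcan_z(m, stats, ld[[m$gene]]), error = function(e) NULL)
    if (is.null(r)) return(NULL)
    data.frame(GENE = r$gene, TISSUE = r$tissue, STUDY = study, Z = r$z,
               P = r$p, N_SNPS_USED = r$n_snps_used, SIGMA_G = r$sigma_g,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  rownames(out) <- NULL
  out
}

#' Summary-level cross-tissue combination
#'
#' Combines one gene's per-tissue summary z-scores, accounting for the
#' correlation of predicted expression across tissues implied by the weight
#' models and LD reference (\eqn{\mathrm{Cov}(t,s) = w_t' \Gamma w_s}). The
#' tissue correlation matrix is eigendecomposed, components whose condition
#' number (largest eigenvalue over own) exceeds `cond_limit` are discarded to
#' stabilize the inversion, and the quadratic statistic of the rotated z
#' vector is referred to chi-square with degrees of freedom equal to the
#' retained components (the large-reference-panel limit of an F-test).
#'
#' @param z_by_tissue Named numeric vector of per-tissue z-scores for one
#'   gene.
#' @param models_for_gene Named list of the gene's `weight_model`s (one per
#'   tissue named in `z_by_tissue`).
#' @param ld LD reference list entry for the gene.
#' @param cond_limit Condition-number cutoff for component truncation.
#' @return List with `stat`, `n_pcs` (df), `p`, `n_tissues`.
#' @export
summary_cross_tissue <- function(z_by_tissue, models_for_gene, ld,
                                 cond_limit = 30) {
  tissues <- names(z_by_tissue)
  if (length(tissues) < 2) stop("need >= 2 tissues with defined z-scores")
  vars <- ld$variants
  W <- sapply(tissues, function(t) {
    m <- models_for_gene[[t]]
    w <- numeric(length(vars))
    i <- match(m$entries$rsid, vars)
    ok <- !is.na(i)
    w[i[ok]] <- m$entries$weight[ok]
    w
  })
  S <- t(W) %*% ld$gamma %*% W
  d <- sqrt(diag(S))
  if (any(d <= 0)) stop("tissue with zero predicted-expression variance")
  C <- S / tcrossprod(d)
  eig <- eigen(C, symmetric = TRUE)
  lam <- eig$values
  keep <- lam > 0 & (lam[1] / lam) <= cond_limit
  if (!any(keep)) stop("tissue correlation matrix numerically degenerate")
  Q <- eig$vectors[, keep, drop = FALSE]
  rot <- drop(crossprod(Q, z_by_tissue))
  stat <- sum(rot^2 / lam[keep])
  df <- sum(keep)
  list(stat = stat, n_pcs = df,
       p = stats::pchisq(stat, df = df, lower.tail = FALSE),
       n_tissues = length(tissues))
}
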