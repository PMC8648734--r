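#' Storey's estimate of the true-positive proportion
#'
#' Estimates the proportion of null hypotheses
#' \eqn{\hat{\pi}_0(\lambda) = \#\{p > \lambda\} / \{m(1-\lambda)\}}
#' over a grid of tuning values. In `"smoother"` mode (the recommended
#' default) a cubic smoothing spline is fit to \eqn{\hat{\pi}_0(\lambda)}
#' and evaluated at the largest lambda; `"fixed"` mode uses
#' \eqn{\lambda = 0.5}. The true-positive rate is
#' \eqn{\pi_1 = 1 - \hat{\pi}_0}, clamped to \[0, 1\].
#'
#' @param pvals Numeric p-values in \[0, 1\] (a warning is issued below 100
#'   tests, where the estimate is unstable).
#' @param lambda_grid Tuning grid, default `seq(0.05, 0.95, by = 0.05)`.
#' @param mode `"smoother"` or `"fixed"`.
#' @return List with `pi0_hat`, `pi1`, `lambda_grid`, `n_tests`.
#' @export
storey_pi1 <- function(pvals, lambda_grid = seq(0.05, 0.95, by = 0.05),
                       mode = c("smoother", "fixed")) {
  mode <- match.arg(mode)
  if (length(pvals) == 0) stop("invalid input: empty p-value vector")
  if (any(!is.finite(pvals)) || any(pvals < 0) || any(pvals > 1)) {
    stop("invalid input: p-values must lie in [0, 1]")
  }
  if (length(pvals) < 100) {
    warning("fewer than 100 p-values; pi1 estimate may be unstable")
  }
  m <- length(pvals)
  if (mode == "fixed") {
    pi0 <- sum(pvals > 0.5) / (m * 0.5)
  } else {
    pi0_l <- vapply(lambda_grid, function(l) sum(pvals > l) / (m * (1 - l)),
                    numeric(1))
    fit <- stats::smooth.spline(lambda_grid, pi0_l, df = 3)
    pi0 <- stats::predict(fit, x = max(lambda_grid))$y
  }
  pi0 <- min(max(pi0, 0), 1)
  list(pi0_hat = pi0, pi1 = 1 - pi0, lambda_grid = lambda_grid,
       n_tests = m)
}

#' Median-based Mendelian randomization
#'
#' Per-instrument causal effects are Wald ratios
#' \eqn{r_l = \beta^{out}_l / \beta^{exp}_l}; the causal estimate is their
#' simple median or their inverse-variance-weighted median (weights
#' \eqn{(\beta^{exp}_l)^2 / (se^{out}_l)^2}, the first-order precision of the
#' ratio). The median is consistent when fewer than half the instruments are
#' invalid (pleiotropic). The standard error comes from a parametric
#' bootstrap resampling each instrument's effect estimates from their stated
#' normals, and \eqn{p = 2\Phi(-|estimate/se|)}.
#'
#' @param beta_exposure,se_exposure Instrument-exposure effects and SEs.
#' @param beta_outcome,se_outcome Instrument-outcome effects and SEs.
#' @param weighted Use the weighted median (default simple).
#' @param n_boot Bootstrap replicates.
#' @param seed Integer seed for the bootstrap (mandatory).
#' @return List with `estimate`, `se`, `p`, `n_instruments`, `method`,
#'   `n_boot`, `seed`.
#' @export
mr_median <- function(beta_exposure, se_exposure, beta_outcome, se_outcome,
                      weighted = FALSE, n_boot = 1000, seed) {
  k <- length(beta_exposure)
  if (k < 3) stop("insufficient instruments: median-based MR needs >= 3")
  stopifnot(length(se_exposure) == k, length(beta_outcome) == k,
            length(se_outcome) == k)
  if (any(beta_exposure == 0)) {
    stop("zero exposure effect for instrument ", which(beta_exposure == 0)[1],
         "; Wald ratio undefined")
  }
  if (missing(seed)) stop("seed is required for the bootstrap")

  point <- function(bx, by) {
    r <- by / bx
    if (!weighted) return(stats::median(r))
    weighted_median(r, (bx / se_outcome)^2)
  }
  est <- point(beta_exposure, beta_outcome)
  se <- NA_real_
  if (n_boot >= 2) {
    set.seed(as.integer(seed))
    boot <- replicate(n_boot, {
      bx <- stats::rnorm(k, beta_exposure, se_exposure)
      by <- stats::rnorm(k, beta_outcome, se_outcome)
      bx[bx == 0] <- .Machine$double.eps
      point(bx, by)
    })
    se <- stats::sd(boot)
  }
  list(estimate = est, se = se,
       p = if (is.na(se)) NA_real_ else 2 * stats::pnorm(-abs(est / se)),
       n_instruments = k,
       method = if (weighted) "weighted_median" else "simple_median",
       n_boot = n_boot, seed = as.integer(seed))
}

# Weighted median with linear interpolation at cumulative weight 1/2.
weighted_median <- function(x, w) {
  o <- order(x)
  x <- x[o]; w <- w[o] / sum(w)
  cw <- cumsum(w) - w / 2
  below <- max(which(cw < 0.5), 1)
  if (cw[below] >= 0.5) return(x[1])
  if (below == length(x)) return(x[length(x)])
  x[below] + (x[below + 1] - x[below]) * (0.5 - cw[below]) /
    (cw[below + 1] - cw[below])
}

#' Heritability enrichment ratio
#'
#' Enrichment of a SNP category is the proportion of trait heritability the
#' category explains divided by the proportion of SNPs it contains. When the
#' standard error of the heritability proportion is supplied, the enrichment
#' SE is `se_h2 / prop_snps` and a normal-approximation p-value against
#' enrichment = 1 is reported.
#'
#' @param prop_h2 Proportion of heritability in the category.
#' @param prop_snps Proportion of SNPs in the category (> 0).
#' @param se_h2 Optional SE of `prop_h2`.
#' @param percent Set `TRUE` when inputs are percentages; the ratio is
#'   unit-invariant, so results are identical either way.
#' @return List with `prop_h2`, `prop_snps`, `enrichment`, `se_enrichment`,
#'   `p`.
#' @export
enrichment_ratio <- function(prop_h2, prop_snps, se_h2 = NULL,
                             percent = FALSE) {
  if (percent) {
    prop_h2 <- prop_h2 / 100
    prop_snps <- prop_snps / 100
    if (!is.null(se_h2)) se_h2 <- se_h2 / 100
  }
  if (prop_snps == 0) stop("prop_snps must be > 0")
  stopifnot(prop_h2 >= 0, prop_h2 <= 1, prop_snps > 0, prop_snps <= 1)
  enr <- prop_h2 / prop_snps
  se_enr <- p <- NULL
  if (!is.null(se_h2)) {
    se_enr <- se_h2 / prop_snps
    p <- 2 * stats::pnorm(-abs((enr - 1) / se_enr))
  }
  list(prop_h2 = prop_h2, prop_snps = prop_snps, enrichment = enr,
       se_enrichment = se_enr, p = p)
}

#' Concordance between two association result sets
#'
#' Aligns two result tables by (gene, tissue), reports the squared Pearson
#' correlation of their log-transformed p-values, applies
#' Benjamini-Hochberg within each method, and counts the tests significant
#' in exactly one method versus both — the standard view for comparing an
#' individual-level and a summary-level pipeline.
#'
#' @param results_a,results_b data.frames with columns GENE, TISSUE, P.
#' @param fdr FDR level for per-method significance.
#' @return List with `r2_logp`, `n_only_a`, `n_only_b`, `n_common`,
#'   `n_shared_tests`.
#' @export
method_concordance <- function(results_a, results_b, fdr = 0.05) {
  key_a <- paste(results_a$GENE, results_a$TISSUE, sep = "@")
  key_b <- paste(results_b$GENE, results_b$TISSUE, sep = "@")
  shared <- intersect(key_a, key_b)
  if (length(shared) == 0) stop("no shared (gene, tissue) keys to compare")
  pa <- results_a$P[match(shared, key_a)]
  pb <- results_b$P[match(shared, key_b)]
  r2 <- stats::cor(log(pa), log(pb))^2
  sig_a <- shared[bh_adjust(pa, fdr)$significant]
  sig_b <- shared[bh_adjust(pb, fdr)$significant]
  list(r2_logp = r2,
       n_only_a = length(setdiff(sig_a, sig_b)),
       n_only_b = length(setdiff(sig_b, sig_a)),
       n_common = length(intersect(sig_a, sig_b)),
       n_shared_tests = length(shared))
}

#' Per-tissue true-positive-rate report
#'
#' Summarizes Storey pi1 estimates across tissues, with an optional
#' brain/non-brain annotation — a descriptive report of which tissue models
#' carry signal, not a formal test.
#'
#' @param pvals_by_tissue Named list of per-tissue p-value vectors.
#' @param brain_tissues Optional character vector of brain tissue labels.
#' @param ... Passed to [storey_pi1()].
#' @return data.frame tissue, pi1, n_tests, brain.
#' @export
pi1_by_tissue <- function(pvals_by_tissue, brain_tissues = character(), ...) {
  rows <- lapply(names(pvals_by_tissue), function(t) {
    r <- storey_pi1(pvals_by_tissue[[t]], ...)
    data.frame(tissue = t, pi1 = r$pi1, n_tests = r$n_tests,
               brain = t %in% brain_tissues, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
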