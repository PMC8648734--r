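#' Sample-size-weighted z-score meta-analysis
#'
#' Combines per-study signed z-scores with the square-root-of-N weighting
#' used by sample-size-based GWAS meta-analysis (the METAL scheme):
#' \deqn{Z = \frac{\sum_i \sqrt{N_i}\, z_i}{\sqrt{\sum_i N_i}}}
#' which is standard normal under the null. An alternative N-proportional
#' weighting \eqn{\sum_i N_i z_i / \sqrt{\sum_i N_i^2}} is available behind
#' the `weighting` flag; see the README for why square-root-of-N is the
#' default.
#'
#' @param z Numeric vector of per-study signed z-scores.
#' @param n Numeric vector of per-study sample sizes (all >= 1).
#' @param weighting `"sqrt_n"` (default) or `"n"`.
#' @return List with `z_combined`, `p` (two-sided), `n_total`, `n_studies`.
#' @export
combine_z <- function(z, n, weighting = c("sqrt_n", "n")) {
  weighting <- match.arg(weighting)
  if (length(z) != length(n) || length(z) < 1) {
    stop("z and n must be equal-length, non-empty vectors")
  }
  if (any(!is.finite(z))) stop("invalid input: non-finite z-score")
  if (any(n <= 0)) stop("invalid input: sample sizes must be positive")
  zc <- if (weighting == "sqrt_n") {
    sum(sqrt(n) * z) / sqrt(sum(n))
  } else {
    sum(n * z) / sqrt(sum(n^2))
  }
  list(z_combined = zc, p = z_to_p(zc), n_total = sum(n),
       n_studies = length(z))
}

#' Two-sided p-value from a z-score
#'
#' \eqn{p = 2\Phi(-|z|)} under the standard normal null.
#'
#' @param z Finite z-score (vectorized).
#' @return Two-sided p-value(s).
#' @export
z_to_p <- function(z) {
  if (any(!is.finite(z))) stop("z must be finite")
  2 * stats::pnorm(-abs(z))
}

#' Meta-analyze association tables across studies
#'
#' Groups per-study association rows by gene and tissue (or scope) and
#' combines their signed z-scores with [combine_z()].
#'
#' @param assoc data.frame with columns GENE, Z, N, STUDY and either TISSUE
#'   or SCOPE (the grouping label).
#' @param weighting Passed to [combine_z()].
#' @return data.frame GENE, TISSUE, Z, P, N, N_STUDIES.
#' @export
meta_analyze <- function(assoc, weighting = c("sqrt_n", "n")) {
  weighting <- match.arg(weighting)
  label <- if ("TISSUE" %in% names(assoc)) assoc$TISSUE else assoc$SCOPE
  key <- paste(assoc$GENE, label, sep = "@")
  rows <- lapply(split(seq_len(nrow(assoc)), key), function(i) {
    r <- combine_z(assoc$Z[i], assoc$N[i], weighting)
    data.frame(GENE = assoc$GENE[i[1]], TISSUE = label[i[1]],
               Z = r$z_combined, P = r$p, N = r$n_total,
               N_STUDIES = r$n_studies, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values over one pooled family of tests (single- and
#' cross-tissue results are corrected jointly, matching a study-wide FDR
#' control), with a significance flag at the chosen q.
#'
#' @param pvals Numeric vector of raw p-values in (0, 1\].
#' @param q FDR level for the significance flag.
#' @return data.frame with `p`, `p_adj`, `significant`, and attribute-free
#'   column `m` (family size).
#' @export
bh_adjust <- function(pvals, q = 0.05) {
  if (length(pvals) == 0) stop("invalid input: empty p-value vector")
  if (any(!is.finite(pvals)) || any(pvals <= 0) || any(pvals > 1)) {
    stop("invalid input: p-values must lie in (0, 1]")
  }
  adj <- stats::p.adjust(pvals, method = "BH")
  data.frame(p = pvals, p_adj = adj, significant = adj < q,
             m = length(pvals))
}

#' Annotate genes by proximity to known risk SNPs
#'
#' A gene is in a "known region" when its transcription start lies within
#' `window` base pairs (default 10 Mb) of any known risk SNP on the same
#' chromosome; otherwise it is flagged novel. Chromosome labels are
#' normalized (`chr1` and `1` compare equal) before matching.
#'
#' @param genes data.frame with columns `gene`, `chrom`, `tss` (1-based bp).
#' @param known_snps data.frame with columns `snp`, `chrom`, `pos`.
#' @param window Window half-width in bp.
#' @return data.frame gene, nearest_known_snp, distance, within_window,
#'   novel.
#' @export
annotate_known_loci <- function(genes, known_snps, window = 1e7) {
  gc <- normalize_chrom(genes$chrom)
  kc <- normalize_chrom(known_snps$chrom)
  rows <- lapply(seq_len(nrow(genes)), function(i) {
    same <- which(kc == gc[i])
    if (length(same) == 0) {
      return(data.frame(gene = genes$gene[i],
                        nearest_known_snp = NA_character_,
                        distance = NA_real_, within_window = FALSE,
                        novel = TRUE, stringsAsFactors = FALSE))
    }
    d <- abs(known_snps$pos[same] - genes$tss[i])
    j <- same[which.min(d)]
    data.frame(gene = genes$gene[i], nearest_known_snp = known_snps$snp[j],
               distance = min(d), within_window = min(d) <= window,
               novel = min(d) > window, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
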