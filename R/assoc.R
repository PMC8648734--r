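#' Single-tissue GReX association tests
#'
#' Fits a Firth-penalized logistic regression of case status on each
#' gene-by-tissue GReX column, adjusting for sex, standardized age and
#' genetic principal components, and reports the term-of-interest test. The
#' default p-value is the penalized likelihood-ratio test; the reduced
#' (covariates-only) model is shared across genes, so a scan over many genes
#' refits only the full model per column. Constant GReX columns are
#' untestable and excluded with a warning.
#'
#' @param grex A `grex_matrix` (or a plain numeric matrix with `GENE@TISSUE`
#'   column names).
#' @param phenotype Binary 0/1 case status vector.
#' @param covariates Covariate data.frame with columns `SEX`, `AGE`, and
#'   optionally `PC1..PCk`.
#' @param method `"penalized_lr"` (default) or `"wald"`.
#' @param study Study label recorded in the output.
#' @param conditioning Optional extra covariate column (numeric vector
#'   aligned with samples) plus `conditioning_label` describing it; used by
#'   [assoc_conditional()].
#' @param conditioning_label Description of the conditioning column.
#' @return data.frame with GENE, TISSUE, STUDY, BETA, SE, Z, P, N, N_CASES,
#'   METHOD, CONDITIONING — one row per testable column.
#' @export
assoc_single_tissue <- function(grex, phenotype, covariates,
                                method = c("penalized_lr", "wald"),
                                study = "study_01",
                                conditioning = NULL,
                                conditioning_label = NA_character_) {
  method <- match.arg(method)
  values <- if (inherits(grex, "grex_matrix")) grex$values else as.matrix(grex)
  y <- as.numeric(phenotype)
  stopifnot(nrow(values) == length(y))
  base <- covariate_design(covariates)
  if (!is.null(conditioning)) {
    stopifnot(length(conditioning) == length(y))
    base <- cbind(base, COND = as.numeric(conditioning))
  }
  rows <- vector("list", ncol(values))
  for (j in seq_len(ncol(values))) {
    g <- values[, j]
    key <- colnames(values)[j]
    if (stats::var(g) == 0) {
      warning("constant GReX column ", key, " is untestable; excluded")
      next
    }
    if (!is.null(conditioning)) {
      r <- suppressWarnings(stats::cor(g, conditioning))
      if (is.finite(r) && abs(r) > 0.999) {
        stop("conditioning column is collinear with GReX column ", key,
             " (|r| = ", round(abs(r), 4), ")")
      }
    }
    X <- cbind(base, GREX = g)
    fit <- tryCatch(fit_firth(X, y), error = function(e) NULL)
    if (is.null(fit) || !fit$converged) next
    term <- ncol(X)
    beta <- unname(fit$coefficients[term])
    if (method == "penalized_lr") {
      # null model: same design with the GReX coefficient constrained to 0
      reduced <- tryCatch(fit_firth(X, y, fixed = term), error = function(e) NULL)
      if (is.null(reduced) || !reduced$converged) next
      stat <- max(0, 2 * (fit$penalized_loglik - reduced$penalized_loglik))
      p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
      z <- if (beta == 0) 0 else sign(beta) * abs(stats::qnorm(p / 2))
    } else {
      z <- beta / fit$se[term]
      p <- 2 * stats::pnorm(-abs(z))
    }
    gt <- split_gene_tissue(key)
    rows[[j]] <- data.frame(
      GENE = gt[1], TISSUE = gt[2], STUDY = study,
      BETA = beta, SE = unname(fit$se[term]), Z = z, P = p,
      N = length(y), N_CASES = sum(y == 1),
      METHOD = method, CONDITIONING = conditioning_label,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out)) {
    out <- data.frame(GENE = character(), TISSUE = character(),
                      STUDY = character(), BETA = numeric(), SE = numeric(),
                      Z = numeric(), P = numeric(), N = integer(),
                      N_CASES = integer(), METHOD = character(),
                      CONDITIONING = character(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

split_gene_tissue <- function(key) {
  if (is.null(key) || is.na(key)) return(c(NA_character_, NA_character_))
  parts <- strsplit(key, "@", fixed = TRUE)[[1]]
  if (length(parts) == 2) parts else c(key, NA_character_)
}

#' Conditional GReX association
#'
#' Re-tests GReX association after adding one conditioning covariate — the
#' dosage of a known risk SNP, or the GReX of an index gene — to isolate
#' signal independent of the known locus. Identical to
#' [assoc_single_tissue()] with one added covariate; the output records what
#' was adjusted for. A conditioning column nearly collinear with the tested
#' GReX (|r| > 0.999) is an error.
#'
#' @inheritParams assoc_single_tissue
#' @param conditioning Numeric vector (SNP dosage or index-gene GReX) aligned
#'   with samples.
#' @param conditioning_label Description recorded in the CONDITIONING column.
#' @return Same layout as [assoc_single_tissue()].
#' @export
assoc_conditional <- function(grex, phenotype, covariates, conditioning,
                              conditioning_label = "conditioned",
                              method = c("penalized_lr", "wald"),
                              study = "study_01") {
  assoc_single_tissue(grex, phenotype, covariates, method = method,
                      study = study, conditioning = conditioning,
                      conditioning_label = conditioning_label)
}

#' Choose a tag SNP for an index risk variant
#'
#' When the index risk SNP itself is unavailable in a target dataset, the
#' variant in strongest linkage disequilibrium with it (squared Pearson
#' correlation of dosages in a reference panel) is used as a proxy, provided
#' r-squared exceeds `r2_min`. Ties are broken toward the variant nearest the
#' index position, then the lowest position.
#'
#' @param index_rsid rsid of the index risk SNP (must be in the reference).
#' @param dosage Reference `dosage_matrix` (panel role).
#' @param candidates Optional rsids available in the target set; defaults to
#'   all reference variants.
#' @param r2_min LD threshold; no tag chosen at or below it.
#' @return List with `index_snp`, `chosen` (rsid or `NA`), `r2`.
#' @export
select_tag_snp <- function(index_rsid, dosage, candidates = NULL, r2_min = 0.6) {
  meta <- dosage$variant_meta
  if (!index_rsid %in% meta$rsid) {
    stop("index SNP ", index_rsid, " not found in the reference panel")
  }
  if (is.null(candidates)) candidates <- meta$rsid
  candidates <- intersect(candidates, meta$rsid)
  d_index <- dosage$values[, index_rsid]
  index_pos <- meta$pos[match(index_rsid, meta$rsid)]
  r2 <- vapply(candidates, function(v) {
    r <- suppressWarnings(stats::cor(d_index, dosage$values[, v]))
    if (is.na(r)) 0 else r^2
  }, numeric(1))
  pos <- meta$pos[match(candidates, meta$rsid)]
  ord <- order(-r2, abs(pos - index_pos), pos)
  best <- ord[1]
  if (r2[best] > r2_min) {
    list(index_snp = index_rsid, chosen = candidates[best], r2 = unname(r2[best]))
  } else {
    list(index_snp = index_rsid, chosen = NA_character_, r2 = unname(r2[best]))
  }
}
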