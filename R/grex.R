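#' Filter variants by MAF and imputation quality
#'
#' Retains exactly the variants with MAF strictly above `maf_min` and
#' imputation R-squared strictly above `r2_min` — the usual inclusion rule
#' for imputed genotype panels ahead of expression imputation.
#'
#' @param dosage A `dosage_matrix`.
#' @param maf_min Minimum minor-allele frequency (exclusive), in \[0, 0.5\].
#' @param r2_min Minimum imputation R-squared (exclusive), in \[0, 1\].
#' @return The filtered `dosage_matrix`.
#' @export
filter_variants <- function(dosage, maf_min = 0.05, r2_min = 0.5) {
  stopifnot(maf_min >= 0, maf_min <= 0.5, r2_min >= 0, r2_min <= 1)
  keep <- dosage$variant_meta$maf > maf_min & dosage$variant_meta$r2 > r2_min
  if (!any(keep)) {
    stop("no variants pass maf > ", maf_min, " and r2 > ", r2_min)
  }
  dosage$values <- dosage$values[, keep, drop = FALSE]
  dosage$variant_meta <- dosage$variant_meta[keep, , drop = FALSE]
  rownames(dosage$variant_meta) <- NULL
  dosage
}

#' Harmonize a weight model against a dosage variant set
#'
#' Matches each model entry to the dosage metadata, primarily by
#' (chromosome, position, allele pair) and falling back to rsid. An entry is
#' `matched` when its effect allele equals the dosage alt allele, `flipped`
#' when the effect allele equals ref (its dosage is later used as `2 - d`),
#' `missing` when the variant is absent from the dosage set, and
#' `allele_mismatch` when the variant is found but the allele pair is
#' irreconcilable. Missing and mismatched entries are dropped from the
#' prediction sum; the report is never an error.
#'
#' @param model A `weight_model`.
#' @param variant_meta The `variant_meta` data.frame of a `dosage_matrix`.
#' @return List with `model` (entries reduced to usable ones, with a
#'   `flipped` logical column) and `report` (per-entry `status` plus counts).
#' @export
harmonize_model <- function(model, variant_meta) {
  e <- model$entries
  n <- nrow(e)
  status <- character(n)
  flipped <- logical(n)
  pos_key <- paste(normalize_chrom(variant_meta$chrom), variant_meta$pos)
  for (i in seq_len(n)) {
    j <- NA_integer_
    if (!is.na(e$pos[i])) {
      hit <- which(pos_key == paste(normalize_chrom(e$chrom[i]), e$pos[i]))
      if (length(hit)) j <- hit[1]
    }
    if (is.na(j) && !is.na(e$rsid[i])) {
      hit <- which(variant_meta$rsid == e$rsid[i])
      if (length(hit)) j <- hit[1]
    }
    if (is.na(j)) {
      status[i] <- "missing"
      next
    }
    ref <- variant_meta$ref[j]; alt <- variant_meta$alt[j]
    pair_ok <- setequal(c(e$ref[i], e$alt[i]), c(ref, alt)) ||
      (is.na(e$ref[i]) && e$effect_allele[i] %in% c(ref, alt))
    if (!pair_ok || !(e$effect_allele[i] %in% c(ref, alt))) {
      status[i] <- "allele_mismatch"
      next
    }
    if (e$effect_allele[i] == alt) {
      status[i] <- "matched"
    } else {
      status[i] <- "flipped"
      flipped[i] <- TRUE
    }
    e$rsid[i] <- variant_meta$rsid[j]
  }
  usable <- status %in% c("matched", "flipped")
  out <- model
  out$entries <- cbind(e[usable, , drop = FALSE],
                       flipped = flipped[usable])
  rownames(out$entries) <- NULL
  out$n_snps_in_model <- n
  report <- list(
    status = data.frame(rsid = e$rsid, status = status, stringsAsFactors = FALSE),
    counts = c(matched = sum(status == "matched"),
               flipped = sum(status == "flipped"),
               missing = sum(status == "missing"),
               allele_mismatch = sum(status == "allele_mismatch"))
  )
  list(model = out, report = report)
}

normalize_chrom <- function(x) sub("^chr", "", as.character(x), ignore.case = TRUE)

#' Impute genetically regulated expression
#'
#' For each gene-by-tissue weight model, predicted expression is the weighted
#' sum of effect-allele dosages over the model's variants present in the
#' dosage set:
#' \deqn{\mathrm{GReX}_{ig} = \sum_k w_{kg} d'_{ik}}
#' where \eqn{d' = d} for entries whose effect allele is the alt allele and
#' \eqn{d' = 2 - d} for flipped entries. Missing model SNPs contribute zero
#' (the PrediXcan convention); per-model coverage is reported so low-coverage
#' genes can be filtered. Models with no usable entry are omitted with a
#' warning.
#'
#' @param dosage A `dosage_matrix`.
#' @param models Named list of `weight_model`s (harmonization is applied
#'   internally against the dosage metadata).
#' @param warn_empty Warn when a model has zero matched entries.
#' @return A `grex_matrix`: `values` (individuals x models, columns named
#'   `GENE@TISSUE`) and `coverage` (gene, tissue, n_snps_used,
#'   n_snps_in_model).
#' @export
impute_grex <- function(dosage, models, warn_empty = TRUE) {
  n <- nrow(dosage$values)
  cols <- list()
  cov_rows <- list()
  for (key in names(models)) {
    h <- harmonize_model(models[[key]], dosage$variant_meta)
    e <- h$model$entries
    n_model <- h$model$n_snps_in_model
    if (nrow(e) == 0) {
      if (n_model > 0 && warn_empty) {
        warning("model ", key, " has zero usable variants; column omitted")
      }
      next
    }
    D <- dosage$values[, e$rsid, drop = FALSE]
    w <- ifelse(e$flipped, -e$weight, e$weight)
    const <- 2 * sum(e$weight[e$flipped])
    cols[[key]] <- drop(D %*% w) + const
    cov_rows[[key]] <- data.frame(
      gene = models[[key]]$gene, tissue = models[[key]]$tissue,
      n_snps_used = nrow(e), n_snps_in_model = n_model,
      stringsAsFactors = FALSE
    )
  }
  if (length(cols) == 0) {
    values <- matrix(numeric(0), nrow = n, ncol = 0,
                     dimnames = list(dosage$sample_ids, NULL))
    coverage <- data.frame(gene = character(), tissue = character(),
                           n_snps_used = integer(), n_snps_in_model = integer())
  } else {
    values <- do.call(cbind, cols)
    rownames(values) <- dosage$sample_ids
    coverage <- do.call(rbind, cov_rows)
    rownames(coverage) <- NULL
  }
  structure(list(values = values, coverage = coverage), class = "grex_matrix")
}

#' @export
print.grex_matrix <- function(x, ...) {
  cat(sprintf("GReX matrix: %d individuals x %d gene-tissue models\n",
              nrow(x$values), ncol(x$values)))
  if (nrow(x$coverage)) {
    cat(sprintf("  genes: %d, tissues: %d, mean coverage: %.2f\n",
                length(unique(x$coverage$gene)),
                length(unique(x$coverage$tissue)),
                mean(x$coverage$n_snps_used / x$coverage$n_snps_in_model)))
  }
  invisible(x)
}
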