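#' Write dosages as VCF v4.2 with a DS FORMAT field
#'
#' One record per variant, 1-based positions, per-sample alt-allele dosage in
#' the DS field (GT is written as `./.` since hard calls are not retained).
#'
#' @param dosage A `dosage_matrix`.
#' @param path Output file path.
#' @export
write_dosage_vcf <- function(dosage, path) {
  meta <- dosage$variant_meta
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Alt allele dosage\">",
    "##INFO=<ID=R2,Number=1,Type=Float,Description=\"Imputation quality\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", dosage$sample_ids), collapse = "\t")
  )
  body <- vapply(seq_len(nrow(meta)), function(j) {
    ds <- sprintf("./.:%g", dosage$values[, j])
    paste(c(meta$chrom[j], meta$pos[j], meta$rsid[j], meta$ref[j],
            meta$alt[j], ".", "PASS", sprintf("R2=%g", meta$r2[j]),
            "GT:DS", ds), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
}

#' Read a dosage matrix from a VCF with DS (or GT) genotypes
#'
#' Uses the `vcfR` parser when available; DS is preferred, with a GT-to-dosage
#' fallback counting alt alleles.
#'
#' @param path VCF file path.
#' @return A `dosage_matrix` (MAF computed from the dosages; R2 taken from
#'   the INFO field when present, else 1).
#' @export
read_dosage_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("read_dosage_vcf requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  ds <- tryCatch(vcfR::extract.gt(v, element = "DS", as.numeric = TRUE),
                 error = function(e) NULL)
  if (is.null(ds) || all(is.na(ds))) {
    gt <- vcfR::extract.gt(v, element = "GT")
    ds <- apply(gt, c(1, 2), function(g) {
      if (is.na(g)) return(NA_real_)
      sum(as.integer(strsplit(g, "[/|]")[[1]]) > 0)
    })
  }
  values <- t(ds)
  r2 <- suppressWarnings(as.numeric(sub(".*R2=([0-9.eE+-]+).*", "\\1", fix$INFO)))
  r2[is.na(r2)] <- 1
  alt_freq <- colMeans(values) / 2
  meta <- data.frame(
    rsid = fix$ID, chrom = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT,
    maf = pmin(alt_freq, 1 - alt_freq), alt_freq = alt_freq, r2 = r2,
    stringsAsFactors = FALSE
  )
  structure(list(values = values, variant_meta = meta,
                 sample_ids = rownames(values)), class = "dosage_matrix")
}

#' Write phenotype and covariates as TSV
#'
#' Columns: IID, STATUS, SEX, AGE, PC1..PCk.
#' @param phenotype 0/1 vector.
#' @param covariates Covariate data.frame (IID, SEX, AGE, PCs).
#' @param path Output path.
#' @export
write_phenotype_tsv <- function(phenotype, covariates, path) {
  out <- cbind(covariates[, "IID", drop = FALSE], STATUS = phenotype,
               covariates[, setdiff(names(covariates), "IID"), drop = FALSE])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a phenotype/covariate TSV
#' @param path File path.
#' @return List with `phenotype` and `covariates`.
#' @export
read_phenotype_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  list(phenotype = d$STATUS,
       covariates = d[, setdiff(names(d), "STATUS"), drop = FALSE])
}

#' Write weight models as a flat TSV
#'
#' Long format mirroring the relational weight-database schema: one row per
#' (gene, tissue, variant) with the effect allele and weight, plus the gene
#' position columns used for novelty annotation.
#'
#' @param models Named list of `weight_model`s.
#' @param path Output path.
#' @export
write_weights_tsv <- function(models, path) {
  rows <- lapply(models, function(m) {
    if (nrow(m$entries) == 0) return(NULL)
    data.frame(gene = m$gene, tissue = m$tissue, gene_chrom = m$gene_chrom,
               gene_tss = m$gene_tss, rsid = m$entries$rsid,
               chrom = m$entries$chrom, pos = m$entries$pos,
               ref_allele = m$entries$ref, eff_allele = m$entries$effect_allele,
               weight = m$entries$weight, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read weight models from the flat TSV written by [write_weights_tsv()]
#' @param path File path.
#' @return Named list of `weight_model`s keyed `GENE@TISSUE`.
#' @export
read_weights_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  keys <- unique(paste0(d$gene, "@", d$tissue))
  models <- lapply(keys, function(k) {
    gt <- strsplit(k, "@", fixed = TRUE)[[1]]
    e <- d[d$gene == gt[1] & d$tissue == gt[2], , drop = FALSE]
    structure(list(
      gene = gt[1], gene_chrom = as.character(e$gene_chrom[1]),
      gene_tss = e$gene_tss[1], tissue = gt[2],
      entries = data.frame(rsid = e$rsid, chrom = as.character(e$chrom),
                           pos = e$pos, ref = e$ref_allele,
                           alt = ifelse(e$eff_allele == e$ref_allele, NA, e$eff_allele),
                           effect_allele = e$eff_allele, weight = e$weight,
                           stringsAsFactors = FALSE)
    ), class = "weight_model")
  })
  names(models) <- keys
  models
}

#' Write GWAS summary statistics as TSV
#' @param stats Summary data.frame from [compute_gwas_summary()].
#' @param path Output path.
#' @export
write_summary_tsv <- function(stats, path) {
  utils::write.table(stats, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a GWAS summary-statistics TSV
#' @param path File path.
#' @return data.frame.
#' @export
read_summary_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write a per-gene LD covariance reference as TSV
#'
#' Long format with columns GENE, RSID1, RSID2, VALUE (upper triangle
#' including the diagonal).
#'
#' @param ld Per-gene LD list from [compute_gwas_summary()].
#' @param path Output path.
#' @export
write_ld_tsv <- function(ld, path) {
  rows <- lapply(names(ld), function(g) {
    v <- ld[[g]]$variants
    m <- ld[[g]]$gamma
    idx <- which(upper.tri(m, diag = TRUE), arr.ind = TRUE)
    data.frame(GENE = g, RSID1 = v[idx[, 1]], RSID2 = v[idx[, 2]],
               VALUE = m[idx], stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Read a per-gene LD covariance TSV
#' @param path File path.
#' @return Per-gene list with `variants`, `gamma`, `sigma2`.
#' @export
read_ld_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  out <- lapply(split(d, d$GENE), function(g) {
    v <- unique(c(g$RSID1, g$RSID2))
    m <- matrix(0, length(v), length(v), dimnames = list(v, v))
    for (i in seq_len(nrow(g))) {
      m[g$RSID1[i], g$RSID2[i]] <- g$VALUE[i]
      m[g$RSID2[i], g$RSID1[i]] <- g$VALUE[i]
    }
    list(variants = v, gamma = m, sigma2 = diag(m))
  })
  out
}

#' Write a GReX matrix as TSV (rows = individuals, columns = GENE@TISSUE)
#' @param grex A `grex_matrix`.
#' @param path Output path (coverage is written alongside as
#'   `<path>.coverage.tsv`).
#' @export
write_grex_tsv <- function(grex, path) {
  out <- data.frame(IID = rownames(grex$values), grex$values,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(grex$coverage, paste0(path, ".coverage.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
}
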