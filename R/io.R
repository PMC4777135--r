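#' Read a genotype dosage TSV
#'
#' Dialect: header `id<TAB>locus...`, one row per individual, dosage values
#' 0/1/2 or `NA`.
#'
#' @param path file path.
#' @return dosage matrix with sample/locus dimnames.
#' @export
read_genotypes_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
  if (names(df)[1] != "id") stop(path, ": first column must be 'id'")
  ids <- df$id
  if (anyDuplicated(ids)) stop(path, ": duplicate id '",
                               ids[duplicated(ids)][1], "'")
  m <- as.matrix(df[, -1, drop = FALSE])
  suppressWarnings(storage <- matrix(as.numeric(m), nrow(m),
                                     dimnames = list(ids, colnames(m))))
  bad <- which((!is.na(m) & m != "NA" & is.na(storage)) |
                 (!is.na(storage) & !storage %in% c(0, 1, 2)), arr.ind = TRUE)
  if (nrow(bad))
    stop(path, ": unknown genotype code '", m[bad[1, , drop = FALSE]],
         "' at row ", bad[1, 1], " (id '", ids[bad[1, 1]], "'), locus '",
         colnames(m)[bad[1, 2]], "'")
  check_dosages(storage)
  storage
}

#' Write a genotype dosage TSV
#' @param g dosage matrix.
#' @param path file path.
#' @export
write_genotypes_tsv <- function(g, path) {
  df <- data.frame(id = rownames(g), g, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read biallelic SNP dosages from a VCF
#'
#' Parses GT fields into alternative-allele counts. Multi-allelic records
#' are skipped (their count is reported as an attribute); missing GT becomes
#' `NA`.
#'
#' @param path VCF file (may be bgzipped).
#' @return dosage matrix with attribute `n_skipped_multiallelic`.
#' @export
read_genotypes_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  alt <- vcfR::getALT(v)
  biallelic <- !is.na(alt) & !grepl(",", alt)
  n_skipped <- sum(!biallelic)
  if (!any(biallelic)) stop(path, ": no biallelic SNP records")
  gt <- vcfR::extract.gt(v[biallelic, ], element = "GT")
  count_alt <- function(x) {
    x[x %in% c(".", "./.", ".|.")] <- NA
    alleles <- strsplit(gsub("\\|", "/", x), "/", fixed = FALSE)
    vapply(alleles, function(a) {
      if (length(a) == 0 || anyNA(a) || any(a == "."))
        return(NA_real_)
      sum(a == "1")
    }, 0)
  }
  dos <- apply(gt, 2, count_alt)
  if (is.null(dim(dos))) dos <- matrix(dos, nrow = 1, dimnames = list(rownames(gt), names(dos)))
  m <- t(dos)
  dimnames(m) <- list(colnames(gt), rownames(gt))
  check_dosages(m)
  attr(m, "n_skipped_multiallelic") <- n_skipped
  m
}

#' Read / write a pedigree CSV (`id,dam,sire`; empty field = unknown parent)
#' @param path file path.
#' @return pedigree data.frame.
#' @export
read_pedigree_csv <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  normalize_pedigree(df)
}

#' @rdname read_pedigree_csv
#' @param ped pedigree data.frame.
#' @export
write_pedigree_csv <- function(ped, path) {
  out <- ped
  out$dam[is.na(out$dam)] <- ""
  out$sire[is.na(out$sire)] <- ""
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a phenotype CSV (`id,family,block,<trait>...`)
#' @param path file path.
#' @return data.frame with character id/family/block and numeric traits.
#' @export
read_phenotypes_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "family", "block")
  if (!all(need %in% names(df)))
    stop(path, ": phenotype file needs columns id, family, block")
  for (col in need) {
    df[[col]] <- as.character(df[[col]])
    blank <- is.na(df[[col]]) | df[[col]] == ""
    if (any(blank))
      stop(path, ": empty '", col, "' label at row ", which(blank)[1])
  }
  if (anyDuplicated(df$id))
    stop(path, ": duplicate id '", df$id[duplicated(df$id)][1], "'")
  traits <- setdiff(names(df), need)
  if (!length(traits)) stop(path, ": no trait columns")
  for (tr in traits) df[[tr]] <- as.numeric(df[[tr]])
  df
}

#' @rdname read_phenotypes_csv
#' @param pheno phenotype data.frame.
#' @export
write_phenotypes_csv <- function(pheno, path) {
  utils::write.csv(pheno, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a relationship kernel as square TSV with id headers
#' @param path file path.
#' @param label kernel label recorded on read.
#' @return a `rel_kernel`.
#' @export
read_kernel_tsv <- function(path, label = "kernel") {
  df <- utils::read.delim(path, check.names = FALSE)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- ids
  if (!identical(ids, colnames(m)))
    stop(path, ": row and column ids differ")
  rel_kernel(m, label)
}

#' @rdname read_kernel_tsv
#' @param k a `rel_kernel`.
#' @export
write_kernel_tsv <- function(k, path) {
  df <- data.frame(id = rownames(k), unclass(k), check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
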