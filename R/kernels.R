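#' Relationship kernel objects
#'
#' A relationship kernel is a labelled symmetric matrix giving the covariance
#' structure of one random genetic term: the pedigree numerator relationship
#' matrix `A`, the realized genomic additive (`G_add`) and dominance
#' (`G_dom`, `G_dom_geno`) matrices, or Hadamard epistatic products
#' (`AxA`, `DxD`, `AxD`).
#'
#' @param mat symmetric numeric matrix with sample ids as dimnames.
#' @param label kernel label, e.g. `"A"`, `"G_add"`, `"AxA"`.
#' @param epsilon diagonal stabilization already applied (0 if none).
#' @return an object of class `rel_kernel` (a matrix with `label` and
#'   `epsilon` attributes).
#' @export
rel_kernel <- function(mat, label, epsilon = 0) {
  if (!is.matrix(mat) || nrow(mat) != ncol(mat))
    stop("kernel must be a square matrix")
  ids <- rownames(mat)
  if (is.null(ids) || is.null(colnames(mat)))
    stop("kernel matrix must carry sample ids as dimnames")
  if (anyDuplicated(ids)) stop("duplicate sample ids in kernel")
  if (!identical(ids, colnames(mat))) stop("row and column ids differ")
  asym <- max(abs(mat - t(mat)))
  if (asym > 1e-10) stop("kernel not symmetric (max asymmetry ", signif(asym, 3), ")")
  mat <- (mat + t(mat)) / 2
  structure(mat, label = label, epsilon = epsilon, class = c("rel_kernel", "matrix"))
}

#' @export
print.rel_kernel <- function(x, ...) {
  cat(sprintf("<rel_kernel '%s'> %d x %d individuals", attr(x, "label"),
              nrow(x), ncol(x)))
  eps <- attr(x, "epsilon")
  if (!is.null(eps) && eps > 0) cat(sprintf(", stabilized (epsilon = %g)", eps))
  cat("\n  diag: mean", signif(mean(diag(x)), 4),
      " off-diag: mean", signif(mean(x[upper.tri(x)]), 4), "\n")
  invisible(x)
}

kernel_label <- function(k) attr(k, "label")

#' Allele frequencies from a dosage matrix
#'
#' Computes the per-locus frequency of the counted (alternative) allele from
#' observed dosages, excluding missing entries from the denominator.
#' Monomorphic loci (frequency 0 or 1, or entirely missing) are dropped.
#'
#' @param g dosage matrix (individuals x loci, entries 0/1/2 or `NA`) with
#'   locus ids as column names.
#' @return list with `p` (named frequency vector over retained loci),
#'   `retained` (column indices kept) and `dropped` (locus ids removed).
#' @export
allele_frequencies <- function(g) {
  check_dosages(g)
  n_obs <- colSums(!is.na(g))
  all_missing <- n_obs == 0L
  p <- colSums(g, na.rm = TRUE) / (2 * pmax(n_obs, 1L))
  mono <- !all_missing & (p <= 0 | p >= 1)
  drop <- all_missing | mono
  if (any(all_missing))
    warning(sum(all_missing), " loci dropped: all genotypes missing")
  if (all(drop)) stop("no polymorphic loci retained")
  list(p = p[!drop], retained = unname(which(!drop)),
       dropped = colnames(g)[drop])
}

check_dosages <- function(g) {
  if (!is.matrix(g) || nrow(g) == 0L || ncol(g) == 0L)
    stop("genotype matrix must be a non-empty matrix")
  if (is.null(rownames(g)) || is.null(colnames(g)))
    stop("genotype matrix must have sample and locus ids as dimnames")
  if (anyDuplicated(rownames(g))) stop("duplicate sample ids")
  if (anyDuplicated(colnames(g))) stop("duplicate locus ids")
  vals <- g[!is.na(g)]
  if (length(vals) && !all(vals %in% c(0, 1, 2)))
    stop("dosages must be 0, 1, 2 or NA")
  invisible(TRUE)
}

# Mean-impute missing dosages with 2p (the HWE expectation), so that centered
# columns stay zero-mean under the supplied frequencies.
impute_dosages <- function(g, p) {
  miss <- is.na(g)
  if (any(miss)) {
    fill <- matrix(rep(2 * p, each = nrow(g)), nrow = nrow(g))
    g[miss] <- fill[miss]
  }
  g
}

align_frequencies <- function(g, freq) {
  if (is.list(freq)) {
    g <- g[, freq$retained, drop = FALSE]
    p <- freq$p
  } else {
    p <- freq
    if (length(p) != ncol(g))
      stop("frequency vector length does not match locus count")
    keep <- p > 0 & p < 1
    g <- g[, keep, drop = FALSE]
    p <- p[keep]
  }
  if (!length(p)) stop("no polymorphic loci retained")
  list(g = g, p = as.numeric(p))
}

#' Genomic additive relationship matrix (VanRaden)
#'
#' G_add = ZZ' / (2 * sum p_i (1 - p_i)), with Z = M - P the dosage matrix
#' centered by twice the allele frequency at each locus. Missing dosages are
#' mean-imputed with 2p before centering.
#'
#' @param g dosage matrix (individuals x loci).
#' @param freq the result of [allele_frequencies()], or a numeric vector of
#'   per-locus frequencies (e.g. founder frequencies from a simulation).
#' @return a `rel_kernel` labelled `"G_add"`.
#' @export
additive_kernel <- function(g, freq = allele_frequencies(g)) {
  al <- align_frequencies(g, freq)
  p <- al$p
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0) stop("zero denominator: no polymorphic loci")
  Z <- impute_dosages(al$g, p)
  Z <- sweep(Z, 2L, 2 * p, `-`)
  rel_kernel(tcrossprod(Z) / denom, "G_add")
}

#' Genomic dominance relationship matrix
#'
#' Classical parameterization (Vitezica): W codes -2q^2 / 2pq / -2p^2 for the
#' reference homozygote / heterozygote / alternative homozygote, and
#' G_dom = WW' / sum_i (2 p_i q_i)^2. The genotypic alternative (Su) codes the
#' heterozygote indicator centered by 2pq, with denominator
#' sum_i 2 p_i q_i (1 - 2 p_i q_i).
#'
#' @inheritParams additive_kernel
#' @param parameterization `"classical"` or `"genotypic"`.
#' @return a `rel_kernel` labelled `"G_dom"` or `"G_dom_geno"`.
#' @export
dominance_kernel <- function(g, freq = allele_frequencies(g),
                             parameterization = c("classical", "genotypic")) {
  parameterization <- match.arg(parameterization)
  al <- align_frequencies(g, freq)
  M <- al$g
  p <- al$p
  q <- 1 - p
  # missing entries take the zero-mean code (the HWE expectation of either
  # coding is 0), the dominance analogue of mean imputation
  code_by_class <- function(w0, w1, w2) {
    W <- matrix(0, nrow(M), ncol(M), dimnames = dimnames(M))
    for (cls in 0:2) {
      idx <- which(!is.na(M) & M == cls)
      if (length(idx)) {
        wcol <- switch(cls + 1L, w0, w1, w2)
        W[idx] <- wcol[(idx - 1L) %/% nrow(M) + 1L]
      }
    }
    W
  }
  if (parameterization == "classical") {
    denom <- sum((2 * p * q)^2)
    if (denom <= 0) stop("zero denominator for dominance kernel")
    W <- code_by_class(-2 * p^2, 2 * p * q, -2 * q^2)
    label <- "G_dom"
  } else {
    denom <- sum(2 * p * q * (1 - 2 * p * q))
    if (denom <= 0) stop("zero denominator for dominance kernel")
    W <- code_by_class(-2 * p * q, 1 - 2 * p * q, -2 * p * q)
    label <- "G_dom_geno"
  }
  rel_kernel(tcrossprod(W) / denom, label)
}

#' Hadamard (entrywise) product of relationship kernels
#'
#' Epistatic covariance structures are built as Hadamard products of the
#' additive and dominance kernels: `G_add # G_add` (AxA), `G_dom # G_dom`
#' (DxD) and `G_add # G_dom` (AxD).
#'
#' @param k1,k2 `rel_kernel` objects over the same individuals, same order.
#' @param label optional label; derived from the operands when `NULL`.
#' @return a `rel_kernel`.
#' @export
hadamard <- function(k1, k2, label = NULL) {
  if (!identical(rownames(k1), rownames(k2)))
    stop("kernels cover different individuals (or different order)")
  if (is.null(label)) {
    short <- function(k) switch(kernel_label(k),
                                G_add = "A", A = "A",
                                G_dom = "D", G_dom_geno = "D",
                                kernel_label(k))
    label <- paste0(short(k1), "x", short(k2))
  }
  rel_kernel(unclass(k1) * unclass(k2), label)
}

#' Stabilize a kernel towards the identity
#'
#' K* = (1 - epsilon) K + epsilon I, used to make near-singular genomic
#' kernels safely positive definite for the mixed-model equations.
#'
#' @param k a `rel_kernel`.
#' @param epsilon blending weight in \[0, 1\] (default 0.01).
#' @return the stabilized `rel_kernel`; its `epsilon` attribute records the
#'   blend.
#' @export
stabilize <- function(k, epsilon = 0.01) {
  if (epsilon < 0 || epsilon > 1) stop("epsilon must be in [0, 1]")
  m <- (1 - epsilon) * unclass(k)
  diag(m) <- diag(m) + epsilon
  out <- rel_kernel(m, kernel_label(k), epsilon = epsilon)
  if (epsilon > 0) {
    lmin <- min(eigen(unclass(out), symmetric = TRUE, only.values = TRUE)$values)
    if (lmin <= 0)
      stop("kernel still not positive definite at epsilon = ", epsilon,
           "; increase epsilon")
  }
  out
}

#' Within- and among-family relationship summaries
#'
#' Collects the off-diagonal kernel entries for pairs within the same family
#' and pairs across families, with means, SDs and histogram bin counts —
#' the diagnostic used to visualise how far assumed half-sib families stray
#' from the expected 0.25 mean relationship.
#'
#' @param k a `rel_kernel`.
#' @param family named vector or factor mapping each sample id to a family.
#' @param bin_width histogram bin width (default 0.05).
#' @return list with `within` and `among` components (each: `values`, `mean`,
#'   `sd`, `histogram` data.frame) plus `n_singleton_families`.
#' @export
relationship_summaries <- function(k, family, bin_width = 0.05) {
  ids <- rownames(k)
  fam <- family[ids]
  if (anyNA(fam)) stop("family map does not cover all samples in the kernel")
  fam <- as.character(fam)
  n <- length(ids)
  same <- outer(fam, fam, `==`)
  ut <- upper.tri(k)
  within <- unclass(k)[ut & same]
  among <- unclass(k)[ut & !same]
  tab <- table(fam)
  summarise <- function(v) {
    if (!length(v))
      return(list(values = numeric(0), mean = NA_real_, sd = NA_real_,
                  histogram = data.frame(mid = numeric(0), count = integer(0))))
    br <- seq(floor(min(v) / bin_width) * bin_width,
              ceiling(max(v) / bin_width) * bin_width + bin_width, by = bin_width)
    h <- hist(v, breaks = br, plot = FALSE)
    list(values = v, mean = mean(v), sd = stats::sd(v),
         histogram = data.frame(mid = h$mids, count = h$counts))
  }
  out <- list(within = summarise(within), among = summarise(among),
              n_singleton_families = sum(tab == 1L))
  if (!length(within)) warning("only singleton families: within-family collection empty")
  out
}
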