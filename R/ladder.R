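#' Build the genomic kernel set for the model ladder
#'
#' From a dosage matrix (and optionally supplied allele frequencies) builds
#' G_add, G_dom and the Hadamard epistatic kernels AxA, DxD, AxD.
#'
#' @param genotypes dosage matrix (individuals x loci).
#' @param freq frequencies as in [additive_kernel()]; defaults to observed.
#' @param dominance_parameterization `"classical"` or `"genotypic"`.
#' @param epsilon stabilization applied to every genomic kernel (0 disables).
#' @return named list: `G_add`, `G_dom`, `AxA`, `DxD`, `AxD`.
#' @export
genomic_kernels <- function(genotypes, freq = allele_frequencies(genotypes),
                            dominance_parameterization = "classical",
                            epsilon = 0) {
  Ga <- additive_kernel(genotypes, freq)
  Gd <- dominance_kernel(genotypes, freq, dominance_parameterization)
  ks <- list(G_add = Ga, G_dom = Gd,
             AxA = hadamard(Ga, Ga), DxD = hadamard(Gd, Gd),
             AxD = hadamard(Ga, Gd))
  if (epsilon > 0) ks <- lapply(ks, stabilize, epsilon = epsilon)
  ks
}

#' Model definitions of the ABLUP/GBLUP ladder
#'
#' ABLUP uses the pedigree A-matrix for the additive term; GBLUP-A
#' substitutes G_add; GBLUP-AD adds the dominance kernel; GBLUP-ADE adds the
#' three epistatic kernels; GBLUP-AE keeps additive + AxA only. All models
#' carry random replication and replication x family terms.
#'
#' @param A pedigree `rel_kernel`.
#' @param G list from [genomic_kernels()].
#' @param models subset of the ladder to define.
#' @return named list of model definitions (`kernels`, `factors`).
#' @export
ladder_models <- function(A, G, models = c("ABLUP", "GBLUP-A", "GBLUP-AD",
                                           "GBLUP-ADE", "GBLUP-AE")) {
  defs <- list(
    "ABLUP" = list(kernels = list(additive = A)),
    "GBLUP-A" = list(kernels = list(additive = G$G_add)),
    "GBLUP-AD" = list(kernels = list(additive = G$G_add, dominance = G$G_dom)),
    "GBLUP-ADE" = list(kernels = list(additive = G$G_add, dominance = G$G_dom,
                                      add_x_add = G$AxA, dom_x_dom = G$DxD,
                                      add_x_dom = G$AxD)),
    "GBLUP-AE" = list(kernels = list(additive = G$G_add, add_x_add = G$AxA)))
  unknown <- setdiff(models, names(defs))
  if (length(unknown)) stop("unknown model(s): ", paste(unknown, collapse = ", "))
  defs <- defs[models]
  lapply(defs, function(d) {
    d$factors <- c(replication = "block", rep_x_family = ".rep_family")
    d
  })
}

add_rep_family <- function(pheno) {
  if (!all(c("block", "family") %in% names(pheno)))
    stop("phenotypes need 'block' and 'family' columns")
  pheno$.rep_family <- paste(pheno$block, pheno$family, sep = ":")
  pheno
}

#' Fit the full model ladder
#'
#' @param pheno phenotype data.frame (`id`, `family`, `block`, trait).
#' @param trait trait column name.
#' @param A pedigree `rel_kernel` (assumed half-sib pedigree).
#' @param G genomic kernels from [genomic_kernels()].
#' @param models which ladder models to fit.
#' @param transform passed to [reml_fit()].
#' @param ... further arguments to [reml_fit()].
#' @return named list of `reml_fit` objects.
#' @export
model_ladder <- function(pheno, trait, A, G,
                         models = c("ABLUP", "GBLUP-A", "GBLUP-AD",
                                    "GBLUP-ADE", "GBLUP-AE"),
                         transform = "none", ...) {
  pheno <- add_rep_family(pheno)
  defs <- ladder_models(A, G, models)
  lapply(defs, function(d)
    reml_fit(pheno, trait, kernels = d$kernels, factors = d$factors,
             transform = transform, ...))
}

#' Ladder comparison table
#'
#' One row per model: logL, AIC, additive variance, h2 and its SE.
#'
#' @param fits named list of `reml_fit` objects.
#' @return data.frame.
#' @export
ladder_summary <- function(fits) {
  do.call(rbind, lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    h2 <- tryCatch(heritability(f), error = function(e) c(h2 = NA, se = NA))
    est <- stats::setNames(f$varcomp$estimate, f$varcomp$term)
    data.frame(model = nm, logL = f$logL, AIC = f$AIC,
               sigma2_additive = est[["additive"]],
               h2 = h2[["h2"]], h2_se = h2[["se"]],
               converged = f$converged, row.names = NULL)
  }))
}
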