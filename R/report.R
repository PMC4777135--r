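#' Top-k rank persistence between two breeding-value rankings
#'
#' How many of the top `top_k` individuals under ranking `a` remain in the
#' top `top_k` under ranking `b` — the re-ranking diagnostic contrasting
#' pedigree-based with genomic evaluations. Ties are broken by ascending id.
#'
#' @param ebv_a,ebv_b named numeric vectors over the same ids.
#' @param top_k size of the elite set.
#' @return list: `overlap` (count in both top sets), `table` (id, rank_a,
#'   rank_b for the union of the two top sets).
#' @export
rank_comparison <- function(ebv_a, ebv_b, top_k = 50) {
  if (top_k <= 0) stop("top_k must be positive")
  ids <- names(ebv_a)
  if (is.null(ids) || !setequal(ids, names(ebv_b)))
    stop("ebv vectors must be named over the same ids")
  if (top_k > length(ids)) stop("top_k exceeds the number of individuals")
  rank_of <- function(v) {
    ord <- order(-v[ids], ids)  # best first, ties by ascending id
    stats::setNames(seq_along(ord), ids[ord])
  }
  ra <- rank_of(ebv_a)[ids]
  rb <- rank_of(ebv_b)[ids]
  top_a <- ids[ra <= top_k]
  top_b <- ids[rb <= top_k]
  union_ids <- union(top_a, top_b)
  tab <- data.frame(id = union_ids, rank_a = unname(ra[union_ids]),
                    rank_b = unname(rb[union_ids]), stringsAsFactors = FALSE)
  tab <- tab[order(tab$rank_a), , drop = FALSE]
  rownames(tab) <- NULL
  list(overlap = length(intersect(top_a, top_b)), table = tab)
}

#' Paired comparison of prediction standard errors between two fits
#'
#' Pairs the additive-effect SEPs of two fits on the same individuals and
#' reports the fraction of individuals whose SEP is smaller under the second
#' fit (points below the 45-degree line in the classic scatter).
#'
#' @param fit_a,fit_b `reml_fit` objects on identical individuals.
#' @param term random term to compare (default `"additive"`).
#' @return list: `table` (id, sep_a, sep_b), `fraction_below` (share with
#'   sep_b < sep_a).
#' @export
sep_comparison <- function(fit_a, fit_b, term = "additive") {
  a <- blups(fit_a, term)
  b <- blups(fit_b, term)
  # the pedigree fit also predicts founders; compare on the shared set
  common <- intersect(a$id, b$id)
  if (!length(common)) stop("fits cover different individuals")
  sa <- stats::setNames(a$sep, a$id)[common]
  sb <- stats::setNames(b$sep, b$id)[common]
  list(table = data.frame(id = common, sep_a = unname(sa), sep_b = unname(sb),
                          stringsAsFactors = FALSE),
       fraction_below = mean(sb < sa))
}

#' Run the full simulate -> kernels -> ladder -> cross-validation pipeline
#'
#' Orchestrates the whole analysis on a configuration and writes every
#' artifact (genotypes, pedigrees, phenotypes, kernels, variance components,
#' heritabilities, BLUPs with SEPs, CV correlations, consistency matrices,
#' rank/SEP comparisons) plus a JSON manifest under `out_dir`. Reruns with
#' the same config are byte-identical.
#'
#' @param config list with elements: `sim` (a [sim_config()]) or paths
#'   `genotypes`/`phenotypes`/`pedigree`; `trait` (default `"trait"`);
#'   `transform`; `models`; `cv` (list: `schemes`, `k`, `reps`);
#'   `dominance_parameterization`; `epsilon`; `seed`.
#' @param out_dir output directory (created).
#' @return invisibly, a list with the fits, CV results and file manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- utils::modifyList(
    list(trait = "trait", transform = "none",
         models = c("ABLUP", "GBLUP-A", "GBLUP-AD", "GBLUP-ADE", "GBLUP-AE"),
         cv = list(schemes = c("random", "block", "family"), k = 10, reps = 5),
         dominance_parameterization = "classical", epsilon = 0, seed = 1L),
    config)
  fp <- function(...) file.path(out_dir, ...)
  written <- character(0)
  note <- function(p) { written <<- c(written, basename(p)); p }

  if (!is.null(cfg$sim)) {
    sim <- simulate_op_dataset(cfg$sim)
    genotypes <- sim$genotypes
    pheno <- sim$phenotypes
    ped <- sim$assumed_pedigree
    freq <- sim$founder_p
    write_genotypes_tsv(genotypes, note(fp("genotypes.tsv")))
    write_pedigree_csv(ped, note(fp("assumed_pedigree.csv")))
    write_pedigree_csv(sim$truth$true_pedigree, note(fp("true_pedigree.csv")))
    write_phenotypes_csv(pheno, note(fp("phenotypes.csv")))
    yaml::write_yaml(unclass(cfg$sim), note(fp("sim_config.yaml")))
  } else if (!is.null(cfg$genotypes) && !is.null(cfg$phenotypes)) {
    genotypes <- if (grepl("\\.vcf(\\.gz)?$", cfg$genotypes))
      read_genotypes_vcf(cfg$genotypes) else read_genotypes_tsv(cfg$genotypes)
    pheno <- read_phenotypes_csv(cfg$phenotypes)
    ped <- if (!is.null(cfg$pedigree)) read_pedigree_csv(cfg$pedigree)
           else assumed_op_pedigree(pheno$id, pheno$family)
    freq <- allele_frequencies(genotypes)
  } else stop("config must provide either 'sim' or 'genotypes' + 'phenotypes'")

  A <- numerator_relationship(ped)
  G <- genomic_kernels(genotypes, freq,
                       dominance_parameterization = cfg$dominance_parameterization,
                       epsilon = cfg$epsilon)
  write_kernel_tsv(A, note(fp("kernel_A.tsv")))
  for (nm in names(G)) write_kernel_tsv(G[[nm]], note(fp(paste0("kernel_", nm, ".tsv"))))

  fam_map <- stats::setNames(pheno$family, pheno$id)
  rs <- relationship_summaries(G$G_add, fam_map)
  utils::write.csv(data.frame(
    group = c("within", "among"),
    mean = c(rs$within$mean, rs$among$mean),
    sd = c(rs$within$sd, rs$among$sd)),
    note(fp("relationship_summary.csv")), row.names = FALSE)

  fits <- model_ladder(pheno, cfg$trait, A, G, models = cfg$models,
                       transform = cfg$transform)
  lad <- ladder_summary(fits)
  utils::write.csv(lad, note(fp("model_ladder.csv")), row.names = FALSE)
  for (nm in names(fits)) {
    f <- fits[[nm]]
    tag <- gsub("[^A-Za-z0-9]+", "_", nm)
    vc <- f$varcomp
    vc$percent <- variance_proportions(f)
    utils::write.csv(vc, note(fp(sprintf("varcomp_%s.csv", tag))), row.names = FALSE)
    utils::write.csv(blups(f, "additive"),
                     note(fp(sprintf("blups_%s.csv", tag))), row.names = FALSE)
    diag_json <- list(model = nm, logL = f$logL, AIC = f$AIC,
                      converged = f$converged,
                      iterations = if (is.null(f$trace)) 0L else nrow(f$trace))
    ed <- tryCatch(sampling_correlation_diagnostic(f), error = function(e) NULL)
    if (!is.null(ed)) {
      diag_json$eigenvalues <- ed$eigenvalues
      diag_json$cumulative <- ed$cumulative
    }
    jsonlite::write_json(diag_json, note(fp(sprintf("diagnostics_%s.json", tag))),
                         auto_unbox = TRUE, digits = NA)
  }

  if ("ABLUP" %in% names(fits) && "GBLUP-A" %in% names(fits)) {
    sc <- sep_comparison(fits[["ABLUP"]], fits[["GBLUP-A"]])
    utils::write.csv(sc$table, note(fp("sep_ablup_vs_gblupa.csv")), row.names = FALSE)
    ra <- blups(fits[["ABLUP"]], "additive")
    last <- utils::tail(intersect(c("GBLUP-AE", "GBLUP-ADE", "GBLUP-A"),
                                  names(fits)), 1)
    rb <- blups(fits[[last]], "additive")
    common <- intersect(ra$id, rb$id)  # rank genotyped trees, not A-only founders
    rc <- rank_comparison(stats::setNames(ra$blup, ra$id)[common],
                          stats::setNames(rb$blup, rb$id)[common],
                          top_k = min(50, length(common)))
    utils::write.csv(rc$table, note(fp("rank_top50.csv")), row.names = FALSE)
  }

  cv_out <- list()
  cv_models <- intersect(cfg$models, c("ABLUP", "GBLUP-A", "GBLUP-AD", "GBLUP-ADE"))
  defs <- ladder_models(A, G, cv_models)
  for (scheme in cfg$cv$schemes) {
    plan <- make_folds(pheno$id, families = fam_map,
                       blocks = stats::setNames(pheno$block, pheno$id),
                       scheme = scheme, k = cfg$cv$k, reps = cfg$cv$reps,
                       seed = cfg$seed)
    res <- lapply(cv_models, function(m)
      cross_validate(plan, defs[[m]], pheno, cfg$trait, cfg$transform,
                     full_fit = fits[[m]]))
    names(res) <- cv_models
    cm <- consistency_matrix(res)
    utils::write.csv(cm$table, note(fp(sprintf("cv_%s.csv", scheme))),
                     row.names = FALSE)
    cv_out[[scheme]] <- cm
  }

  manifest <- list(package = "opgblup",
                   version = as.character(utils::packageVersion("opgblup")),
                   seed = cfg$seed, trait = cfg$trait,
                   transform = cfg$transform,
                   models = names(fits), cv_schemes = cfg$cv$schemes,
                   files = sort(unique(written)))
  jsonlite::write_json(manifest, fp("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(list(fits = fits, cv = cv_out, manifest = manifest,
                 out_dir = out_dir))
}
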