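#' Restricted cross-validation folding plans
#'
#' Builds the three folding schemes used to probe genomic prediction in OP
#' trials: `random` (ids shuffled into k near-equal folds), `family` (whole
#' families assigned to folds, so no family straddles training and
#' validation) and `block` (leave one whole block out as validation, with the
#' remaining blocks' individuals partitioned into k training folds).
#'
#' @param ids individual ids.
#' @param families named vector id -> family (required for `family` scheme).
#' @param blocks named vector id -> block (required for `block` scheme).
#' @param scheme `"random"`, `"family"` or `"block"`.
#' @param k fold count (default 10).
#' @param reps replications (default 5).
#' @param seed master seed; per-replication seeds are derived from it.
#' @return a `folding_plan`: for random/family, per replication a data.frame
#'   (id, fold); for block, per replication a list of rounds, each with
#'   `validation_block`, `validation` ids and a data.frame (id, fold) over
#'   the training ids.
#' @export
make_folds <- function(ids, families = NULL, blocks = NULL,
                       scheme = c("random", "family", "block"),
                       k = 10, reps = 5, seed = 1L) {
  scheme <- match.arg(scheme)
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("ids must be unique")
  chop <- function(x, k) { # shuffle into k near-equal folds (sizes differ <= 1)
    x <- sample(x)
    split(x, rep_len(seq_len(k), length(x))[order(seq_along(x))])
  }
  assignment <- vector("list", reps)
  for (r in seq_len(reps)) {
    set.seed(seed + 7919L * r)
    if (scheme == "random") {
      folds <- chop(ids, k)
      assignment[[r]] <- data.frame(
        id = unlist(folds, use.names = FALSE),
        fold = rep(seq_len(k), lengths(folds)), stringsAsFactors = FALSE)
    } else if (scheme == "family") {
      fam <- families[ids]
      if (anyNA(fam)) stop("families must cover all ids")
      ufam <- unique(as.character(fam))
      if (k > length(ufam)) stop("k exceeds the number of families")
      ffolds <- chop(ufam, k)
      fold_of_fam <- stats::setNames(rep(seq_len(k), lengths(ffolds)),
                                     unlist(ffolds, use.names = FALSE))
      assignment[[r]] <- data.frame(id = ids,
                                    fold = unname(fold_of_fam[as.character(fam)]),
                                    stringsAsFactors = FALSE)
    } else {
      bl <- blocks[ids]
      if (anyNA(bl)) stop("blocks must cover all ids")
      ubl <- unique(as.character(bl))
      if (length(ubl) < 2) stop("block scheme needs at least 2 blocks")
      rounds <- lapply(ubl, function(b) {
        val <- ids[bl == b]
        train <- ids[bl != b]
        tfolds <- chop(train, k)
        list(validation_block = b, validation = val,
             training = data.frame(id = unlist(tfolds, use.names = FALSE),
                                   fold = rep(seq_len(k), lengths(tfolds)),
                                   stringsAsFactors = FALSE))
      })
      assignment[[r]] <- rounds
    }
  }
  structure(list(scheme = scheme, k = k, reps = reps, seed = seed,
                 ids = ids, assignment = assignment),
            class = "folding_plan")
}

#' @export
print.folding_plan <- function(x, ...) {
  cat(sprintf("<folding_plan> scheme=%s k=%d reps=%d over %d individuals\n",
              x$scheme, x$k, x$reps, length(x$ids)))
  invisible(x)
}

# refit (or resolve at fixed variances) on training ids only and return the
# additive BLUPs for every id in the additive kernel
predict_additive <- function(pheno, trait, def, transform, train_ids,
                             full_fit, reestimate) {
  sub <- pheno[pheno$id %in% train_ids, , drop = FALSE]
  fit <- if (reestimate)
    reml_fit(sub, trait, kernels = def$kernels, factors = def$factors,
             transform = transform)
  else {
    fv <- stats::setNames(full_fit$varcomp$estimate, full_fit$varcomp$term)
    reml_fit(sub, trait, kernels = def$kernels, factors = def$factors,
             transform = transform, fix_variances = fv)
  }
  b <- blups(fit, "additive")
  stats::setNames(b$blup, b$id)
}

#' Cross-validated predicted breeding values
#'
#' For each replication and fold, the model is resolved on training
#' individuals only: validation phenotypes are withheld but validation
#' individuals keep their rows/columns in the genomic kernels, so marker
#' relationships propagate information across the training/validation split
#' (the pedigree model can propagate only through pedigree links — under
#' family folding its validation predictions collapse to the model mean).
#' Variance components are re-used from the full-data fit by default.
#'
#' @param plan a [make_folds()] plan.
#' @param def one model definition from [ladder_models()].
#' @param pheno phenotype data.frame (already containing the design columns
#'   the definition's factors name, see [model_ladder()] internals; plain
#'   `id/family/block` tables are augmented automatically).
#' @param trait trait column.
#' @param transform trait transform.
#' @param full_fit optional pre-computed full-data `reml_fit` of this model
#'   (computed when omitted); its variance components are re-used and its
#'   BLUPs serve as the EBV reference.
#' @param reestimate re-run REML on every training fold instead of re-using
#'   the full-data variance components.
#' @param block_mode `"kfold"` trains k models per validation block (each
#'   omitting one training fold) and averages the predictions;
#'   `"loo"` trains a single model on all remaining blocks.
#' @return list: `pbv` data.frame (rep, id, pbv), `ebv` named vector from
#'   the full fit, `full_fit`, `plan`.
#' @export
cross_validate <- function(plan, def, pheno, trait, transform = "none",
                           full_fit = NULL, reestimate = FALSE,
                           block_mode = c("kfold", "loo")) {
  block_mode <- match.arg(block_mode)
  if (!".rep_family" %in% names(pheno) &&
      any(unname(def$factors) == ".rep_family"))
    pheno <- add_rep_family(pheno)
  pheno$id <- as.character(pheno$id)
  if (is.null(full_fit))
    full_fit <- reml_fit(pheno, trait, kernels = def$kernels,
                         factors = def$factors, transform = transform)
  eb <- blups(full_fit, "additive")
  ebv <- stats::setNames(eb$blup, eb$id)
  out <- vector("list", plan$reps)
  for (r in seq_len(plan$reps)) {
    asg <- plan$assignment[[r]]
    if (plan$scheme %in% c("random", "family")) {
      folds <- split(asg$id, asg$fold)
      pbv <- lapply(folds, function(val) {
        # degenerate one-fold plan: nothing is withheld, PBV = full-data EBV
        train <- if (plan$k == 1L) plan$ids else setdiff(plan$ids, val)
        pred <- predict_additive(pheno, trait, def, transform, train,
                                 full_fit, reestimate)
        pred[val]
      })
      pbv <- unlist(unname(pbv))
    } else {
      acc <- list()
      for (round in asg) {
        val <- round$validation
        preds <- if (block_mode == "loo") {
          p1 <- predict_additive(pheno, trait, def, transform,
                                 round$training$id, full_fit, reestimate)
          matrix(p1[val], ncol = 1)
        } else {
          sapply(seq_len(plan$k), function(j) {
            train <- round$training$id[round$training$fold != j]
            predict_additive(pheno, trait, def, transform, train,
                             full_fit, reestimate)[val]
          })
        }
        acc[[round$validation_block]] <- stats::setNames(rowMeans(preds), val)
      }
      pbv <- unlist(unname(acc))
    }
    out[[r]] <- data.frame(rep = r, id = names(pbv), pbv = unname(pbv),
                           stringsAsFactors = FALSE)
  }
  list(pbv = do.call(rbind, out), ebv = ebv, full_fit = full_fit, plan = plan)
}

#' Prediction accuracy: Pearson correlation of EBV and PBV
#'
#' Returns `NA` (not zero) when either vector is degenerate, e.g. when
#' pedigree-based predictions for unlinked validation families collapse to
#' the model mean.
#'
#' @param ebv,pbv named vectors aligned by id (intersection used).
#' @return Pearson correlation or `NA_real_`.
#' @export
accuracy <- function(ebv, pbv) {
  common <- intersect(names(ebv), names(pbv))
  if (length(common) < 2) return(NA_real_)
  a <- ebv[common]; b <- pbv[common]
  if (stats::sd(a) < 1e-12 || stats::sd(b) < 1e-12) return(NA_real_)
  stats::cor(a, b)
}

#' Standard error of the mean of replicate correlations
#'
#' SE = sd(correlations) / sqrt(n), with n the number of replicates.
#'
#' @param correlations numeric vector of per-replication correlations.
#' @return SEM.
#' @export
sem <- function(correlations) {
  correlations <- correlations[!is.na(correlations)]
  if (length(correlations) < 2) return(NA_real_)
  stats::sd(correlations) / sqrt(length(correlations))
}

#' Accuracy/consistency matrix across models
#'
#' For every pair (EBV model l, PBV model m) computes the per-replication
#' Pearson correlation between the full-data EBVs of model l and the
#' cross-validated PBVs of model m, then the mean and SEM over replications.
#' Diagonals are within-model prediction accuracies; off-diagonals are
#' cross-model consistencies.
#'
#' @param cv_results named list (by model) of [cross_validate()] results,
#'   all from the same folding scheme.
#' @return list with `table` (long data.frame: ebv_model, pbv_model, mean_r,
#'   sem, n_reps) and `matrix` (mean correlations, EBV models in columns).
#' @export
consistency_matrix <- function(cv_results) {
  models <- names(cv_results)
  rows <- list()
  for (m in models) {
    pbv_tab <- cv_results[[m]]$pbv
    for (l in models) {
      ebv <- cv_results[[l]]$ebv
      rs <- vapply(split(pbv_tab, pbv_tab$rep), function(d)
        accuracy(ebv, stats::setNames(d$pbv, d$id)), 0)
      rows[[paste(l, m)]] <- data.frame(
        ebv_model = l, pbv_model = m,
        mean_r = if (all(is.na(rs))) NA_real_ else mean(rs, na.rm = TRUE),
        sem = sem(rs), n_reps = sum(!is.na(rs)), stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  mat <- matrix(NA_real_, length(models), length(models),
                dimnames = list(pbv = models, ebv = models))
  for (i in seq_len(nrow(tab)))
    mat[tab$pbv_model[i], tab$ebv_model[i]] <- tab$mean_r[i]
  list(table = tab, matrix = mat)
}
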