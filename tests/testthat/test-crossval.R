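make_ids <- function(n_fam = 12, per_fam = 6, n_blocks = 6) {
  ids <- sprintf("F%02d_%d", rep(seq_len(n_fam), each = per_fam),
                 seq_len(per_fam))
  fam <- setNames(rep(sprintf("F%02d", seq_len(n_fam)), each = per_fam), ids)
  blk <- setNames(rep_len(sprintf("B%d", seq_len(n_blocks)), length(ids)), ids)
  list(ids = ids, fam = fam, blk = blk)
}

test_that("folding plans satisfy their defining partition properties", {
  x <- make_ids()
  # random: exact partition, near-equal sizes, deterministic under seed
  p1 <- make_folds(x$ids, scheme = "random", k = 10, reps = 3, seed = 4)
  p2 <- make_folds(x$ids, scheme = "random", k = 10, reps = 3, seed = 4)
  expect_identical(p1$assignment, p2$assignment)
  for (r in 1:3) {
    a <- p1$assignment[[r]]
    expect_setequal(a$id, x$ids)
    expect_false(anyDuplicated(a$id) > 0)
    expect_lte(diff(range(table(a$fold))), 1)
  }
  # family: no family straddles folds, checked exhaustively
  pf <- make_folds(x$ids, families = x$fam, scheme = "family", k = 4, reps = 3,
                   seed = 4)
  for (r in 1:3) {
    a <- pf$assignment[[r]]
    expect_setequal(a$id, x$ids)
    folds_per_family <- tapply(a$fold, x$fam[a$id], function(v) length(unique(v)))
    expect_true(all(folds_per_family == 1))
  }
  expect_error(make_folds(x$ids, families = x$fam, scheme = "family", k = 99),
               "exceeds")
  # block: validation is exactly one whole block per round
  pb <- make_folds(x$ids, blocks = x$blk, scheme = "block", k = 5, reps = 2,
                   seed = 4)
  for (r in 1:2) {
    rounds <- pb$assignment[[r]]
    expect_length(rounds, length(unique(x$blk)))
    for (rd in rounds) {
      expect_setequal(rd$validation, x$ids[x$blk == rd$validation_block])
      expect_setequal(c(rd$validation, rd$training$id), x$ids)
    }
  }
  one_block <- setNames(rep("B1", length(x$ids)), x$ids)
  expect_error(make_folds(x$ids, blocks = one_block, scheme = "block"),
               "at least 2 blocks")
})

test_that("accuracy and SEM follow the correlation formulas", {
  e <- setNames(c(1, 2, 3, 4), letters[1:4])
  expect_equal(accuracy(e, e), 1)
  expect_true(is.na(accuracy(e, setNames(rep(1, 4), letters[1:4]))))
  rs <- c(0.70, 0.72, 0.74, 0.76, 0.78)
  expect_equal(mean(rs), 0.74)
  expect_equal(sem(rs), sd(rs) / sqrt(5))
  expect_equal(sem(rs), 0.01414, tolerance = 1e-3)
  expect_true(is.na(sem(0.5)))
})

test_that("SEM shrinks as 1/sqrt(reps) on synthetic replication sets", {
  set.seed(6)
  r5 <- replicate(200, sem(rnorm(5, 0.7, 0.05)))
  r20 <- replicate(200, sem(rnorm(20, 0.7, 0.05)))
  expect_equal(mean(r5) / mean(r20), sqrt(20 / 5), tolerance = 0.15)
})

test_that("degenerate one-fold cross-validation returns the full-data EBVs", {
  cfg <- small_op_config(seed = 41, n_families = 10, offspring = 5, n_loci = 100)
  d <- simulate_op_dataset(cfg)
  G <- genomic_kernels(d$genotypes, d$founder_p)
  A <- numerator_relationship(d$assumed_pedigree)
  def <- ladder_models(A, G, "GBLUP-A")[["GBLUP-A"]]
  plan <- make_folds(d$phenotypes$id, scheme = "random", k = 1, reps = 1,
                     seed = 1)
  cv <- cross_validate(plan, def, d$phenotypes, "trait")
  pbv <- setNames(cv$pbv$pbv, cv$pbv$id)
  expect_equal(pbv[names(cv$ebv)], cv$ebv, tolerance = 1e-8)
})

test_that("ABLUP predictions collapse to the model mean under family folding", {
  cfg <- small_op_config(seed = 43, n_families = 12, offspring = 5, n_loci = 120)
  d <- simulate_op_dataset(cfg)
  G <- genomic_kernels(d$genotypes, d$founder_p)
  A <- numerator_relationship(d$assumed_pedigree)
  fam <- setNames(d$phenotypes$family, d$phenotypes$id)
  plan <- make_folds(d$phenotypes$id, families = fam, scheme = "family",
                     k = 4, reps = 1, seed = 2)
  defs <- ladder_models(A, G, c("ABLUP", "GBLUP-A"))
  cv_a <- cross_validate(plan, defs[["ABLUP"]], d$phenotypes, "trait")
  # validation families share no pedigree links with training: additive BLUP
  # deviations are exactly zero (PBV equals the model mean)
  expect_true(all(abs(cv_a$pbv$pbv) < 1e-8))
  expect_true(is.na(accuracy(cv_a$ebv, setNames(cv_a$pbv$pbv, cv_a$pbv$id))))
  # the genomic model propagates information across families
  cv_g <- cross_validate(plan, defs[["GBLUP-A"]], d$phenotypes, "trait")
  r <- accuracy(cv_g$ebv, setNames(cv_g$pbv$pbv, cv_g$pbv$id))
  expect_false(is.na(r))
  expect_gt(r, 0)
})

test_that("the consistency matrix has model-by-model shape with accuracies on the diagonal", {
  cfg <- small_op_config(seed = 47, n_families = 10, offspring = 5, n_loci = 100)
  d <- simulate_op_dataset(cfg)
  G <- genomic_kernels(d$genotypes, d$founder_p)
  A <- numerator_relationship(d$assumed_pedigree)
  defs <- ladder_models(A, G, c("GBLUP-A", "GBLUP-AD"))
  plan <- make_folds(d$phenotypes$id, scheme = "random", k = 5, reps = 2,
                     seed = 3)
  res <- lapply(defs, function(df) cross_validate(plan, df, d$phenotypes, "trait"))
  cm <- consistency_matrix(res)
  expect_equal(dim(cm$matrix), c(2, 2))
  expect_equal(nrow(cm$table), 4)
  expect_true(all(cm$table$mean_r >= -1 & cm$table$mean_r <= 1, na.rm = TRUE))
  expect_true(all(cm$table$sem >= 0, na.rm = TRUE))
  # dominance truth is zero: the two models agree, off-diagonals track diagonals
  expect_equal(cm$matrix["GBLUP-A", "GBLUP-AD"], cm$matrix["GBLUP-A", "GBLUP-A"],
               tolerance = 0.05)
})

test_that("block folding predicts every individual once per replication in both modes", {
  cfg <- small_op_config(seed = 53, n_families = 8, offspring = 6, n_loci = 80)
  d <- simulate_op_dataset(cfg)
  G <- genomic_kernels(d$genotypes, d$founder_p)
  A <- numerator_relationship(d$assumed_pedigree)
  def <- ladder_models(A, G, "GBLUP-A")[["GBLUP-A"]]
  blk <- setNames(d$phenotypes$block, d$phenotypes$id)
  plan <- make_folds(d$phenotypes$id, blocks = blk, scheme = "block", k = 3,
                     reps = 1, seed = 5)
  cv_k <- cross_validate(plan, def, d$phenotypes, "trait", block_mode = "kfold")
  cv_l <- cross_validate(plan, def, d$phenotypes, "trait", block_mode = "loo")
  for (cv in list(cv_k, cv_l)) {
    expect_setequal(cv$pbv$id, d$phenotypes$id)
    expect_false(anyDuplicated(cv$pbv$id) > 0)
  }
  r_k <- accuracy(cv_k$ebv, setNames(cv_k$pbv$pbv, cv_k$pbv$id))
  r_l <- accuracy(cv_l$ebv, setNames(cv_l$pbv$pbv, cv_l$pbv$id))
  expect_gt(r_k, 0.3)
  expect_gt(r_l, 0.3)
})
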