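test_that("REML matches the balanced one-way ANOVA closed form at interior solutions", {
  set.seed(42)
  for (case in list(c(s = 25, n = 8, vf = 4, ve = 8),
                    c(s = 40, n = 5, vf = 2, ve = 3))) {
    s <- case[["s"]]; n <- case[["n"]]
    fam <- rep(sprintf("F%02d", seq_len(s)), each = n)
    y <- 10 + rnorm(s, 0, sqrt(case[["vf"]]))[as.integer(factor(fam))] +
      rnorm(s * n, 0, sqrt(case[["ve"]]))
    ph <- data.frame(id = sprintf("i%04d", seq_along(y)), fam = fam, trait = y)
    fit <- reml_fit(ph, "trait", factors = c(family = "fam"))
    ms <- anova(lm(y ~ fam))
    msb <- ms$`Mean Sq`[1]; msw <- ms$`Mean Sq`[2]
    est <- setNames(fit$varcomp$estimate, fit$varcomp$term)
    expect_true(fit$converged)
    expect_equal(unname(est["family"]), (msb - msw) / n, tolerance = 1e-5)
    expect_equal(unname(est["residual"]), msw, tolerance = 1e-5)
  }
})

test_that("GBLUP solutions equal ridge-regression marker effects at a fixed variance ratio", {
  set.seed(7)
  for (r in 1:4) {
    n <- sample(8:14, 1); m <- sample(15:25, 1)
    g <- random_genotypes(n, m)
    fr <- allele_frequencies(g)
    G <- additive_kernel(g, fr)
    y <- rnorm(n, 50, 3)
    ph <- data.frame(id = rownames(g), trait = y)
    sa <- runif(1, 0.5, 3); se <- runif(1, 1, 4)
    fit <- reml_fit(ph, "trait", kernels = list(additive = G),
                    fix_variances = c(additive = sa, residual = se))
    ebv <- setNames(blups(fit, "additive")$blup, blups(fit, "additive")$id)
    # independent ridge oracle
    p <- fr$p
    cden <- 2 * sum(p * (1 - p))
    Z <- sweep(g[, fr$retained, drop = FALSE], 2, 2 * p, "-")
    V <- sa * tcrossprod(Z) / cden + se * diag(n)
    Vi <- solve(V)
    X <- matrix(1, n, 1)
    beta <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
    lam <- cden * se / sa
    ahat <- solve(crossprod(Z) + lam * diag(ncol(Z)),
                  crossprod(Z, y - X %*% beta))
    expect_equal(unname(ebv[rownames(g)]), unname(drop(Z %*% ahat)),
                 tolerance = 1e-8)
  }
})

test_that("constant response drives all non-residual components to the lower bound", {
  set.seed(3)
  g <- random_genotypes(20, 30)
  G <- additive_kernel(g)
  ph <- data.frame(id = rownames(g), fam = rep(c("A", "B"), 10),
                   trait = rep(5, 20))
  expect_error(reml_fit(ph, "trait", kernels = list(additive = G)),
               NA)  # must not crash on zero variance...
  # ...with a tiny perturbation the additive component pins to the bound
  ph$trait <- 5 + rnorm(20, 0, 1)
  ph$trait <- ph$trait - ave(ph$trait, ph$fam)  # no structure left
  fit <- reml_fit(ph, "trait", kernels = list(additive = G))
  est <- setNames(fit$varcomp$estimate, fit$varcomp$term)
  expect_lt(est[["additive"]] / est[["residual"]], 0.2)
})

test_that("likelihood never decreases across iterations and nesting holds", {
  cfg <- small_op_config(seed = 13, n_families = 25, offspring = 6, n_loci = 150)
  d <- simulate_op_dataset(cfg)
  G <- genomic_kernels(d$genotypes, d$founder_p)
  ph <- d$phenotypes
  A <- numerator_relationship(d$assumed_pedigree)
  fits <- model_ladder(ph, "trait", A, G,
                       models = c("GBLUP-A", "GBLUP-AD", "GBLUP-ADE"))
  for (f in fits) expect_true(all(diff(f$trace$logL) >= -1e-8))
  # nesting, up to the convergence tolerance of both fits
  expect_gte(fits[["GBLUP-AD"]]$logL, fits[["GBLUP-A"]]$logL - 1e-4)
  expect_gte(fits[["GBLUP-ADE"]]$logL, fits[["GBLUP-AD"]]$logL - 1e-4)
})

test_that("heritability and variance proportions follow their definitions", {
  # desk arithmetic on a printed-style component vector
  comp <- c(replication = 561.4, rep_x_family = 2624.8, additive = 2178.9,
            residual = 6581.7)
  expect_equal(round(heritability_from_components(comp), 3), 0.249)
  expect_equal(round(unname(variance_proportions(comp)["additive"]), 2), 18.24)
  expect_equal(sum(variance_proportions(comp)), 100)
  expect_equal(heritability_from_components(c(additive = 0, residual = 2)), 0)
  # from a fitted object: denominator excludes design terms, percent includes them
  # 8 offspring over 6 blocks: some family-block cells hold 2 trees, so the
  # rep x family component is identified and SEs are estimable
  cfg <- small_op_config(seed = 17, n_families = 20, offspring = 8, n_loci = 120)
  d <- simulate_op_dataset(cfg)
  G <- additive_kernel(d$genotypes, d$founder_p)
  ph <- d$phenotypes; ph$.rep_family <- paste(ph$block, ph$family, sep = ":")
  fit <- reml_fit(ph, "trait", kernels = list(additive = G),
                  factors = c(replication = "block", rep_x_family = ".rep_family"))
  est <- setNames(fit$varcomp$estimate, fit$varcomp$term)
  h2 <- heritability(fit)
  expect_equal(unname(h2["h2"]), unname(est["additive"] /
                                          (est["additive"] + est["residual"])))
  expect_false(is.na(h2["se"]))
  expect_equal(sum(variance_proportions(fit)), 100)
})

test_that("AIC is -2 logL + 2 parameters", {
  f1 <- list(logL = -100, AIC = -2 * -100 + 2 * 4)
  expect_equal(f1$AIC, 208)
  cfg <- small_op_config(seed = 19, n_families = 15, offspring = 5, n_loci = 80)
  d <- simulate_op_dataset(cfg)
  G <- additive_kernel(d$genotypes, d$founder_p)
  fit <- reml_fit(d$phenotypes, "trait", kernels = list(additive = G),
                  factors = c(replication = "block"))
  expect_equal(aic(fit), -2 * fit$logL + 2 * 3)
})

test_that("the eigen-diagnostic matches closed forms and flags boundary parameters", {
  V <- matrix(c(1, 0.6 * sqrt(2), 0.6 * sqrt(2), 2), 2,
              dimnames = list(c("a", "b"), c("a", "b")))
  ed <- sampling_correlation_diagnostic(V)
  expect_equal(ed$eigenvalues, c(1.6, 0.4))
  expect_equal(diag(ed$F), c(a = 1, b = 1))
  expect_equal(ed$cumulative, c(0.8, 1))
  # diagonal V: orthogonal reference line
  ed2 <- sampling_correlation_diagnostic(diag(c(2, 3, 4)))
  expect_equal(ed2$eigenvalues, c(1, 1, 1))
  expect_equal(ed2$cumulative, c(1, 2, 3) / 3)
  # boundary parameter excluded with a warning
  V3 <- diag(c(1, 0, 2))
  dimnames(V3) <- list(c("a", "b", "c"), c("a", "b", "c"))
  expect_warning(ed3 <- sampling_correlation_diagnostic(V3), "boundary")
  expect_length(ed3$eigenvalues, 2)
})

test_that("SEPs are non-negative and bounded by the prior SD for phenotyped individuals", {
  cfg <- small_op_config(seed = 23, n_families = 20, offspring = 6, n_loci = 150)
  d <- simulate_op_dataset(cfg)
  G <- additive_kernel(d$genotypes, d$founder_p)
  ph <- d$phenotypes; ph$.rep_family <- paste(ph$block, ph$family, sep = ":")
  fit <- reml_fit(ph, "trait", kernels = list(additive = G),
                  factors = c(replication = "block", rep_x_family = ".rep_family"))
  b <- blups(fit, "additive")
  est <- setNames(fit$varcomp$estimate, fit$varcomp$term)
  prior_sd <- sqrt(est[["additive"]] * diag(unclass(G))[b$id])
  expect_true(all(b$sep >= 0))
  expect_true(all(b$sep <= prior_sd + 1e-8))
})

test_that("log transform is applied and validated", {
  ph <- data.frame(id = c("a", "b", "c"), trait = c(1, -2, 3))
  expect_error(reml_fit(ph, "trait", transform = "log"), "positive")
  set.seed(1)
  g <- random_genotypes(30, 50)
  G <- additive_kernel(g)
  ph2 <- data.frame(id = rownames(g), trait = exp(rnorm(30, 1, 0.3)))
  f_log <- reml_fit(ph2, "trait", kernels = list(additive = G), transform = "log")
  ph3 <- ph2; ph3$trait <- log(ph3$trait)
  f_man <- reml_fit(ph3, "trait", kernels = list(additive = G))
  expect_equal(f_log$logL, f_man$logL)
})
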