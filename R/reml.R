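#' Multi-kernel REML for the open-pollinated mixed model
#'
#' Fits y = X beta + sum_t u_t + e by restricted maximum likelihood, where
#' each random term u_t is either a genetic effect with covariance
#' sigma^2_t K_t (K_t a [rel_kernel()]) or a design effect (replication,
#' replication x family) with identity covariance over its levels. The fixed
#' part is the overall mean. Estimation is average-information (AI) REML with
#' a few initial EM steps for stability and step-halving whenever a step
#' would decrease the restricted likelihood.
#'
#' @param pheno data.frame with columns `id` and the trait, plus any design
#'   factor columns named in `factors`.
#' @param trait name of the trait column.
#' @param kernels named list of `rel_kernel` objects; names are the term
#'   names (e.g. `additive`, `dominance`, `add_x_add`). Every phenotyped id
#'   must appear in every kernel; kernel ids absent from the phenotypes are
#'   still predicted (their BLUPs are driven by the covariance structure).
#' @param factors named character vector mapping design term names to factor
#'   columns of `pheno`, e.g. `c(replication = "block")`.
#' @param transform `"none"` or `"log"` (natural log of the trait).
#' @param init optional named vector of starting variance components
#'   (including `residual`); default splits the phenotypic variance equally.
#' @param fix_variances optional named vector (including `residual`): skip
#'   estimation and solve BLUPs/likelihood at these values.
#' @param max_iter,tol iteration cap and convergence tolerance on both the
#'   log-likelihood change and the maximum relative parameter change.
#' @param n_em number of initial EM iterations before switching to AI.
#' @param verbose print the iteration trace.
#' @return an object of class `reml_fit`: `varcomp` (term, estimate, SE,
#'   and `bound` flag), `vcov` (asymptotic covariance of the estimates),
#'   `logL`, `AIC`, `converged`, `trace`, `blups` (per random term: id,
#'   blup, sep), `n`, and bookkeeping needed for prediction.
#' @export
reml_fit <- function(pheno, trait, kernels = list(), factors = character(),
                     transform = c("none", "log"), init = NULL,
                     fix_variances = NULL, max_iter = 200, tol = 1e-6,
                     n_em = 3, verbose = FALSE) {
  transform <- match.arg(transform)
  if (!trait %in% names(pheno)) stop("trait column '", trait, "' not found")
  keep <- !is.na(pheno[[trait]])
  if (!any(keep)) stop("no non-missing phenotypes for trait '", trait, "'")
  pheno <- pheno[keep, , drop = FALSE]
  ids <- as.character(pheno$id)
  if (anyDuplicated(ids)) stop("duplicate phenotyped ids")
  y <- pheno[[trait]]
  if (transform == "log") {
    if (any(y <= 0)) stop("log transform requires strictly positive trait values")
    y <- log(y)
  }
  n <- length(y)
  X <- matrix(1, n, 1, dimnames = list(ids, "mu"))

  terms <- build_terms(kernels, factors, pheno, ids)
  tn <- c(names(terms), "residual")
  nt <- length(tn)
  vy <- max(stats::var(y), .Machine$double.eps) # constant y still yields a PD V
  bound <- 1e-6 * vy

  if (!is.null(fix_variances)) {
    theta <- fix_variances[tn]
    if (anyNA(theta)) stop("fix_variances must name every term: ",
                           paste(tn, collapse = ", "))
    st <- reml_state(y, X, terms, as.numeric(theta))
    return(finalize_fit(st, theta = stats::setNames(as.numeric(theta), tn),
                        terms = terms, kernels = kernels, ids = ids, y = y,
                        trait = trait, transform = transform,
                        vcov = NULL, converged = TRUE, trace = NULL,
                        bound = bound, fixed = TRUE))
  }

  theta <- if (is.null(init)) rep(vy / nt, nt) else {
    th <- init[tn]
    if (anyNA(th)) stop("init must name every term")
    as.numeric(th)
  }
  theta <- pmax(theta, bound)
  names(theta) <- tn

  trace <- data.frame(iter = integer(0), logL = numeric(0), step = character(0))
  st <- reml_state(y, X, terms, theta)
  converged <- FALSE
  vcov <- NULL
  q_em <- c(vapply(terms, function(t) t$q, 0), n)
  em_step <- function(theta, sc) pmax(theta + theta^2 * (sc$ypcpy - sc$trPC) / q_em, bound)
  ai_step <- function(theta, sc, damp) {
    # damped (Levenberg-Marquardt) AI step; damping rescues steps along
    # ill-informed directions of collinear kernels. Parameters pinned at the
    # lower bound whose gradient points outward stay pinned (active set).
    pinned <- theta <= bound * (1 + 1e-8) & sc$score < 0
    free <- which(!pinned)
    if (!length(free)) return(theta)
    A <- sc$AI[free, free, drop = FALSE]
    A <- A + damp * mean(diag(A)) * diag(length(free))
    step <- tryCatch(solve(A, sc$score[free]), error = function(e) NULL)
    if (is.null(step)) return(NULL)
    out <- theta
    out[free] <- theta[free] + step
    pmax(out, bound)
  }
  for (iter in seq_len(max_iter)) {
    sc <- reml_scores(st, terms)
    kind <- if (iter <= n_em) "EM" else "AI"
    halvings <- 0L
    if (kind == "EM") {
      theta_new <- em_step(theta, sc)
      st_new <- reml_state(y, X, terms, theta_new)
    } else {
      st_new <- NULL
      for (damp in c(0, 1e-6, 1e-4, 1e-2, 1, 1e2)) {
        cand <- ai_step(theta, sc, damp)
        if (is.null(cand)) next
        st_cand <- reml_state(y, X, terms, cand)
        # one halving before escalating the damping
        if (st_cand$logL < st$logL - 1e-10) {
          cand <- (cand + theta) / 2
          st_cand <- reml_state(y, X, terms, cand)
          halvings <- halvings + 1L
        }
        if (st_cand$logL >= st$logL - 1e-10) {
          theta_new <- cand
          st_new <- st_cand
          break
        }
      }
      if (is.null(st_new)) { # no damped AI step improves: monotone EM step
        theta_new <- em_step(theta, sc)
        st_new <- reml_state(y, X, terms, theta_new)
        kind <- "EM-fallback"
      }
    }
    dlogL <- st_new$logL - st$logL
    pinned <- theta_new <= bound * (1 + 1e-8)
    drel <- max(c(0, (abs(theta_new - theta) /
                        pmax(abs(theta), bound))[!pinned]))
    step_lab <- if (halvings) sprintf("%s/halved x%d", kind, halvings) else kind
    trace <- rbind(trace, data.frame(iter = iter, logL = st_new$logL,
                                     step = step_lab))
    theta <- theta_new
    st <- st_new
    if (verbose)
      cat(sprintf("it %3d logL %.6f  [%s] %s\n", iter, st$logL,
                  paste(signif(theta, 4), collapse = " "), step_lab))
    if (iter > n_em && abs(dlogL) < tol && drel < tol) {
      converged <- TRUE
      break
    }
  }
  sc <- reml_scores(st, terms)
  at_bound <- theta <= bound * (1 + 1e-8)
  free <- which(!at_bound)
  vcov <- matrix(NA_real_, nt, nt, dimnames = list(tn, tn))
  if (length(free)) {
    vinv <- tryCatch(solve(sc$AI[free, free, drop = FALSE]),
                     error = function(e) NULL)
    if (!is.null(vinv)) vcov[free, free] <- vinv
  }
  finalize_fit(st, theta = theta, terms = terms, kernels = kernels, ids = ids,
               y = y, trait = trait, transform = transform, vcov = vcov,
               converged = converged, trace = trace, bound = bound,
               fixed = FALSE)
}

# ---- internal machinery -----------------------------------------------------

build_terms <- function(kernels, factors, pheno, ids) {
  terms <- list()
  if (length(kernels)) {
    if (is.null(names(kernels)) || any(names(kernels) == ""))
      stop("kernels must be a named list")
    for (nm in names(kernels)) {
      K <- kernels[[nm]]
      if (!inherits(K, "rel_kernel")) stop("kernel '", nm, "' is not a rel_kernel")
      missing_ids <- setdiff(ids, rownames(K))
      if (length(missing_ids))
        stop("kernel '", nm, "' misses phenotyped ids: ",
             paste(utils::head(missing_ids, 5), collapse = ", "))
      terms[[nm]] <- list(type = "kernel",
                          C = unclass(K)[ids, ids, drop = FALSE],
                          q = length(ids))
    }
  }
  if (length(factors)) {
    if (is.null(names(factors)) || any(names(factors) == ""))
      stop("factors must be a named character vector")
    for (nm in names(factors)) {
      col <- factors[[nm]]
      if (!col %in% names(pheno)) stop("factor column '", col, "' not found")
      f <- factor(as.character(pheno[[col]]))
      if (anyNA(f) || any(levels(f) == ""))
        stop("design factor '", col, "' has missing or empty levels")
      terms[[nm]] <- list(type = "factor", f = f, q = nlevels(f))
    }
  }
  if (anyDuplicated(names(terms))) stop("duplicate random term names")
  terms
}

# C_t %*% v for one term without forming Z K Z' for factor terms
term_mult <- function(term, v) {
  if (term$type == "kernel") term$C %*% v
  else {
    s <- rowsum(v, term$f)             # level sums
    s[as.integer(term$f), , drop = FALSE]
  }
}

# V = sum theta_t C_t + theta_e I and the projections needed everywhere
reml_state <- function(y, X, terms, theta) {
  n <- length(y)
  nt <- length(terms)
  V <- diag(theta[nt + 1L], n)
  for (t in seq_len(nt)) {
    term <- terms[[t]]
    if (term$type == "kernel") V <- V + theta[t] * term$C
    else {
      same <- outer(as.integer(term$f), as.integer(term$f), `==`)
      V <- V + theta[t] * same
    }
  }
  ch <- tryCatch(chol(V), error = function(e)
    stop("covariance matrix not positive definite; stabilize() the kernels"))
  Vi <- chol2inv(ch)
  ViX <- Vi %*% X
  XtViX <- crossprod(X, ViX)
  XtViX_inv <- solve(XtViX)
  Viy <- Vi %*% y
  Py <- Viy - ViX %*% (XtViX_inv %*% crossprod(ViX, y))
  logdetV <- 2 * sum(log(diag(ch)))
  logL <- -0.5 * (logdetV + determinant(XtViX, logarithm = TRUE)$modulus[1] +
                    sum(y * Py))
  list(y = y, X = X, Vi = Vi, ViX = ViX, XtViX_inv = XtViX_inv, Py = Py,
       logL = logL, n = n)
}

reml_scores <- function(st, terms) {
  nt <- length(terms) + 1L
  n <- st$n
  trPC <- ypcpy <- numeric(nt)
  W <- matrix(0, n, nt)   # C_t Py
  PW <- matrix(0, n, nt)
  proj <- function(v) st$Vi %*% v - st$ViX %*% (st$XtViX_inv %*% crossprod(st$ViX, v))
  corr_tr <- function(CViX) sum(st$XtViX_inv * crossprod(st$ViX, CViX))
  for (t in seq_len(nt)) {
    if (t < nt) {
      term <- terms[[t]]
      if (term$type == "kernel") {
        trVC <- sum(st$Vi * term$C)  # tr(Vi C): both symmetric
        CViX <- term$C %*% st$ViX
      } else {
        B <- rowsum(st$Vi, term$f)   # q x n level sums of Vi rows
        trVC <- sum(rowsum(t(B), term$f)[cbind(seq_len(term$q), seq_len(term$q))])
        CViX <- term_mult(term, st$ViX)
      }
      w <- term_mult(term, st$Py)
    } else {
      trVC <- sum(diag(st$Vi))
      CViX <- st$ViX
      w <- st$Py
    }
    trPC[t] <- trVC - corr_tr(CViX)
    W[, t] <- w
    PW[, t] <- proj(w)
    ypcpy[t] <- sum(st$Py * w)
  }
  AI <- 0.5 * crossprod(W, PW)
  AI <- (AI + t(AI)) / 2
  score <- -0.5 * (trPC - ypcpy)
  list(trPC = trPC, ypcpy = ypcpy, AI = AI, score = score)
}

# BLUPs u_hat_t = theta_t K_t[, obs] Py with prediction error variance
# PEV = theta K - theta^2 K[,obs] P K[obs,]; SEP = sqrt(diag PEV)
solve_blups <- function(st, terms, kernels, theta, ids) {
  P <- st$Vi - st$ViX %*% st$XtViX_inv %*% t(st$ViX)
  out <- list()
  nt <- length(terms)
  for (t in seq_len(nt)) {
    nm <- names(terms)[t]
    term <- terms[[t]]
    th <- theta[t]
    if (term$type == "kernel") {
      Kfull <- unclass(kernels[[nm]])
      Kco <- Kfull[, ids, drop = FALSE]
      u <- th * drop(Kco %*% st$Py)
      KP <- Kco %*% P
      pev <- th * diag(Kfull) - th^2 * rowSums(KP * Kco)
      out[[nm]] <- data.frame(id = rownames(Kfull), blup = u,
                              sep = sqrt(pmax(pev, 0)), row.names = NULL,
                              stringsAsFactors = FALSE)
    } else {
      u <- th * drop(rowsum(st$Py, term$f))
      ZtPZ <- rowsum(t(rowsum(P, term$f)), term$f)
      pev <- th - th^2 * diag(ZtPZ)
      out[[nm]] <- data.frame(id = levels(term$f), blup = u,
                              sep = sqrt(pmax(pev, 0)), row.names = NULL,
                              stringsAsFactors = FALSE)
    }
  }
  out
}

finalize_fit <- function(st, theta, terms, kernels, ids, y, trait, transform,
                         vcov, converged, trace, bound, fixed) {
  tn <- names(theta)
  se <- if (is.null(vcov)) rep(NA_real_, length(tn)) else sqrt(pmax(diag(vcov), 0))
  at_bound <- theta <= bound * (1 + 1e-8)
  se[at_bound] <- NA_real_   # bound-pinned components: SE not estimable
  k_params <- length(tn)
  fit <- list(
    varcomp = data.frame(term = tn, estimate = as.numeric(theta),
                         se = as.numeric(se), bound = at_bound,
                         row.names = NULL, stringsAsFactors = FALSE),
    vcov = vcov, logL = st$logL,
    AIC = -2 * st$logL + 2 * k_params,
    n_params = k_params, converged = converged, trace = trace,
    blups = solve_blups(st, terms, kernels, theta, ids),
    n = st$n, ids = ids, trait = trait, transform = transform,
    term_types = vapply(terms, function(t) t$type, ""),
    fixed_variances = fixed, Py = st$Py,
    mu = drop(st$XtViX_inv %*% crossprod(st$ViX, y)))
  class(fit) <- "reml_fit"
  fit
}

#' @export
print.reml_fit <- function(x, ...) {
  cat(sprintf("REML fit: trait '%s'%s, n = %d, %s\n", x$trait,
              if (x$transform == "log") " (log)" else "", x$n,
              if (x$fixed_variances) "fixed variances"
              else if (x$converged) "converged" else "NOT converged"))
  vc <- x$varcomp
  vc$pct <- sprintf("%.2f", variance_proportions(x))
  print(vc, digits = 4)
  cat(sprintf("logL = %.4f  AIC = %.4f\n", x$logL, x$AIC))
  h2 <- tryCatch(heritability(x), error = function(e) NULL)
  if (!is.null(h2))
    cat(sprintf("h2 = %.3f (SE %.3f)\n", h2[["h2"]], h2[["se"]]))
  invisible(x)
}

#' Narrow-sense heritability from a fitted model
#'
#' h2 = sigma^2_a / sigma^2_p, where the phenotypic variance is the sum of
#' the residual and all *genetic* variance components (additive, dominance,
#' epistatic); design variances (replication, replication x family) are
#' excluded from the denominator. The SE comes from the delta method on the
#' asymptotic covariance of the variance-component estimates.
#'
#' @param fit a `reml_fit`.
#' @param additive name of the additive term (default `"additive"`).
#' @return named vector `c(h2, se)`.
#' @export
heritability <- function(fit, additive = "additive") {
  vc <- fit$varcomp
  if (!additive %in% vc$term) stop("no term '", additive, "' in the fit")
  genetic <- vc$term[vc$term == "residual" |
                       (vc$term %in% names(fit$term_types)[fit$term_types == "kernel"])]
  est <- stats::setNames(vc$estimate, vc$term)
  denom <- sum(est[genetic])
  if (denom <= 0) stop("zero phenotypic variance denominator")
  h2 <- est[[additive]] / denom
  se <- NA_real_
  if (!is.null(fit$vcov)) {
    g <- stats::setNames(numeric(nrow(vc)), vc$term)
    g[genetic] <- -est[[additive]] / denom^2
    g[additive] <- (denom - est[[additive]]) / denom^2
    V <- fit$vcov
    ok <- !is.na(diag(V))
    if (any(ok)) se <- sqrt(drop(t(g[ok]) %*% V[ok, ok] %*% g[ok]))
  }
  c(h2 = unname(h2), se = unname(se))
}

#' Heritability from printed variance components
#'
#' Desk-scale arithmetic: h2 from a named vector of variance components
#' (must include `additive` and `residual`; design components, if present,
#' are excluded from the denominator).
#'
#' @param components named numeric vector of variance components.
#' @param design_terms names treated as design (excluded) components.
#' @return h2 as a number.
#' @export
heritability_from_components <- function(components,
                                         design_terms = c("replication", "rep_x_family")) {
  keep <- setdiff(names(components), design_terms)
  if (!"additive" %in% keep) stop("components must include 'additive'")
  components[["additive"]] / sum(components[keep])
}

#' Variance components as percentages of the total
#'
#' Each component (including replication and replication x family) divided
#' by the sum of all components, times 100.
#'
#' @param fit a `reml_fit`, or a named numeric vector of components.
#' @return named vector of percentages summing to 100.
#' @export
variance_proportions <- function(fit) {
  est <- if (inherits(fit, "reml_fit"))
    stats::setNames(fit$varcomp$estimate, fit$varcomp$term)
  else fit
  100 * est / sum(est)
}

#' Eigen-diagnostic of the sampling correlation of variance estimates
#'
#' F = L^{-1/2} V L^{-1/2}, where V is the asymptotic covariance matrix of
#' the variance-component estimates and L its diagonal. Eigenvalues of F are
#' returned sorted descending, with the cumulative proportion sequence; for
#' perfectly independent estimates all eigenvalues are 1 and the cumulative
#' curve is the straight diagonal.
#'
#' @param fit a `reml_fit` (or a covariance matrix directly).
#' @return list with `F`, `eigenvalues`, `cumulative` and `excluded`
#'   (boundary parameters dropped from V).
#' @export
sampling_correlation_diagnostic <- function(fit) {
  V <- if (inherits(fit, "reml_fit")) fit$vcov else fit
  if (is.null(V)) stop("no asymptotic covariance matrix available")
  d <- diag(V)
  bad <- is.na(d) | d <= 0
  if (any(bad)) {
    warning("excluding boundary parameter(s) with non-positive sampling variance: ",
            paste(rownames(V)[bad], collapse = ", "))
    V <- V[!bad, !bad, drop = FALSE]
    d <- diag(V)
  }
  if (!nrow(V)) stop("no free parameters left for the diagnostic")
  Fm <- V / sqrt(outer(d, d))
  ev <- sort(eigen((Fm + t(Fm)) / 2, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  list(F = Fm, eigenvalues = ev, cumulative = cumsum(ev) / length(ev),
       excluded = names(bad)[bad])
}

#' Fitted-model AIC
#'
#' AIC = -2 logL + 2 t with t the number of variance parameters. Comparable
#' only between fits from this implementation (the REML likelihood constant
#' differs between software).
#'
#' @param fit a `reml_fit`.
#' @return numeric AIC.
#' @export
aic <- function(fit) fit$AIC

#' BLUP table for one random term
#'
#' @param fit a `reml_fit`.
#' @param term term name (default `"additive"`, the estimated breeding
#'   values).
#' @return data.frame (id, blup, sep).
#' @export
blups <- function(fit, term = "additive") {
  if (!term %in% names(fit$blups)) stop("no BLUPs for term '", term, "'")
  fit$blups[[term]]
}
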