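#' Configuration for the synthetic open-pollinated family generator
#'
#' Defaults emulate the study conditions of a single-site white-spruce OP
#' trial: 214 families of 8 offspring in a randomized complete block design
#' with 6 blocks, a dense biallelic SNP panel, and variance targets on the
#' scale of a 22-yr height trait with a large additive-by-additive component.
#' The half-sib assumption is deliberately contaminated: each offspring may
#' be a self of the dam or share its sire with the previous sibling
#' (creating full-sibs) at configurable rates.
#'
#' @param n_parents number of founder dams.
#' @param n_families number of OP families (<= n_parents).
#' @param offspring_per_family offspring sampled per family.
#' @param n_blocks replications (blocks) in the RCB design.
#' @param n_loci biallelic SNP count.
#' @param maf_range interval in (0, 0.5] for founder minor-allele frequencies.
#' @param pollen_pool_size candidate sires per family (fresh unrelated trees).
#' @param selfing_rate probability an offspring is a self of the dam.
#' @param repeated_sire_rate probability an offspring reuses the previous
#'   sibling's sire (creating full-sibs).
#' @param variance_targets named vector of variances for `additive`,
#'   `dominance`, `add_x_add`, `replication`, `rep_x_family`, `residual`.
#' @param n_dominance_loci loci carrying a heterozygote (dominance) effect.
#' @param n_epistatic_pairs random locus pairs carrying an
#'   additive-by-additive effect.
#' @param trait_mean intercept of the simulated trait.
#' @param seed integer seed; all outputs are reproducible given the config.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_parents = 214, n_families = 214,
                       offspring_per_family = 8, n_blocks = 6,
                       n_loci = 7338, maf_range = c(0.05, 0.5),
                       pollen_pool_size = 20,
                       selfing_rate = 0.05, repeated_sire_rate = 0.10,
                       variance_targets = c(additive = 1160, dominance = 12,
                                            add_x_add = 1335, replication = 555,
                                            rep_x_family = 2614, residual = 6163),
                       n_dominance_loci = 300, n_epistatic_pairs = 1000,
                       trait_mean = 100, seed = 1L) {
  cfg <- list(n_parents = n_parents, n_families = n_families,
              offspring_per_family = offspring_per_family, n_blocks = n_blocks,
              n_loci = n_loci, maf_range = maf_range,
              pollen_pool_size = pollen_pool_size,
              selfing_rate = selfing_rate,
              repeated_sire_rate = repeated_sire_rate,
              variance_targets = variance_targets,
              n_dominance_loci = n_dominance_loci,
              n_epistatic_pairs = n_epistatic_pairs,
              trait_mean = trait_mean, seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot_config <- function(ok, msg) if (!ok) stop("invalid simulation config: ", msg)
  stopifnot_config(cfg$n_loci >= 1, "n_loci must be >= 1")
  stopifnot_config(cfg$n_parents >= 1, "n_parents must be >= 1")
  stopifnot_config(cfg$n_families >= 1 && cfg$n_families <= cfg$n_parents,
                   "need 1 <= n_families <= n_parents")
  stopifnot_config(cfg$offspring_per_family >= 1, "offspring_per_family must be >= 1")
  stopifnot_config(cfg$n_blocks >= 1, "n_blocks must be >= 1")
  mr <- cfg$maf_range
  stopifnot_config(length(mr) == 2 && mr[1] > 0 && mr[2] <= 0.5 && mr[1] <= mr[2],
                   "maf_range must lie within (0, 0.5]")
  rates <- c(cfg$selfing_rate, cfg$repeated_sire_rate)
  stopifnot_config(all(rates >= 0 & rates <= 1), "rates must be probabilities")
  need <- c("additive", "dominance", "add_x_add", "replication",
            "rep_x_family", "residual")
  vt <- cfg$variance_targets
  stopifnot_config(all(need %in% names(vt)), paste("variance_targets needs",
                                                   paste(need, collapse = ", ")))
  stopifnot_config(all(vt >= 0), "variance targets must be >= 0")
  stopifnot_config(cfg$pollen_pool_size >= 1 || cfg$selfing_rate >= 1,
                   "pollen_pool_size must be >= 1 unless selfing_rate is 1")
  invisible(cfg)
}

#' Simulate founder dams under Hardy-Weinberg equilibrium
#'
#' Draws a founder allele frequency per locus uniformly from `maf_range`,
#' then founder dosages as Binomial(2, p) per individual and locus.
#'
#' @param config a [sim_config()].
#' @return list with `genotypes` (dams x loci dosage matrix) and `p`
#'   (true founder frequencies, named by locus).
#' @export
simulate_founders <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  loci <- sprintf("L%05d", seq_len(config$n_loci))
  p <- stats::runif(config$n_loci, config$maf_range[1], config$maf_range[2])
  names(p) <- loci
  dams <- sprintf("DAM%03d", seq_len(config$n_parents))
  g <- matrix(stats::rbinom(config$n_parents * config$n_loci, 2L,
                            rep(p, each = config$n_parents)),
              nrow = config$n_parents, dimnames = list(dams, loci))
  list(genotypes = g, p = p)
}

# one gamete per locus from each parent: homozygotes transmit their allele,
# heterozygotes a fair coin
draw_gametes <- function(parent_dosages) {
  het <- parent_dosages == 1L
  gam <- parent_dosages / 2L
  gam[het] <- stats::rbinom(sum(het), 1L, 0.5)
  as.integer(gam)
}

#' Simulate open-pollinated progeny with hidden relatedness
#'
#' Each family has a fixed founder dam. Each offspring's sire is the dam
#' itself with probability `selfing_rate` (a self), the previous sibling's
#' sire with probability `repeated_sire_rate` (creating full-sibs), and
#' otherwise a fresh sire from the family's pollen pool (drawn without
#' replacement, so uncontaminated families are strict maternal half-sib
#' groups). Gametes segregate independently across loci (no linkage).
#'
#' @param founders result of [simulate_founders()].
#' @param config the same [sim_config()].
#' @return list with `genotypes` (offspring x loci), `truth` (a list holding
#'   `true_pedigree` with actual sires, and placeholders filled by
#'   [simulate_phenotypes()]), and `assumed_pedigree` (dam known, sire
#'   unknown).
#' @export
simulate_op_progeny <- function(founders, config) {
  validate_sim_config(config)
  if (config$pollen_pool_size < 1 && config$selfing_rate < 1)
    stop("invalid simulation config: pollen_pool_size must be >= 1 unless selfing_rate is 1")
  set.seed(config$seed + 1L)
  n_off <- config$offspring_per_family
  fam_dams <- rownames(founders$genotypes)[seq_len(config$n_families)]
  p <- founders$p
  n_loci <- length(p)
  n_total <- config$n_families * n_off
  G <- matrix(0L, n_total, n_loci)
  ped <- vector("list", config$n_families)
  sire_store <- new.env(parent = emptyenv())
  row <- 0L
  ids <- character(n_total)
  fams <- character(n_total)
  for (f in seq_len(config$n_families)) {
    dam_id <- fam_dams[f]
    dam_g <- founders$genotypes[dam_id, ]
    fam_id <- sprintf("FAM%03d", f)
    # fresh sires: unrelated HWE trees private to the family, drawn without
    # replacement so distinct offspring get distinct fathers
    n_pool <- max(config$pollen_pool_size, 1L)
    pool_ids <- sprintf("%s_SIRE%02d", fam_id, seq_len(n_pool))
    pool_g <- matrix(stats::rbinom(n_pool * n_loci, 2L, rep(p, each = n_pool)),
                     nrow = n_pool, dimnames = list(pool_ids, names(p)))
    pool_left <- sample(n_pool)
    prev_sire <- NULL
    sires <- character(n_off)
    for (k in seq_len(n_off)) {
      u <- stats::runif(2)
      if (u[1] < config$selfing_rate) {
        sire_id <- dam_id; sire_g <- dam_g
      } else if (!is.null(prev_sire) && u[2] < config$repeated_sire_rate) {
        sire_id <- prev_sire; sire_g <- get(prev_sire, envir = sire_store)
      } else {
        if (!length(pool_left)) pool_left <- sample(n_pool)  # pool exhausted: recycle
        take <- pool_left[1]; pool_left <- pool_left[-1]
        sire_id <- pool_ids[take]; sire_g <- pool_g[take, ]
        assign(sire_id, sire_g, envir = sire_store)
      }
      prev_sire <- if (sire_id == dam_id) prev_sire else sire_id
      if (sire_id != dam_id) assign(sire_id, sire_g, envir = sire_store)
      row <- row + 1L
      G[row, ] <- draw_gametes(dam_g) + draw_gametes(sire_g)
      ids[row] <- sprintf("%s_%02d", fam_id, k)
      fams[row] <- fam_id
      sires[k] <- sire_id
    }
    ped[[f]] <- data.frame(id = ids[(row - n_off + 1L):row], dam = dam_id,
                           sire = sires, stringsAsFactors = FALSE)
  }
  dimnames(G) <- list(ids, names(p))
  offspring_ped <- do.call(rbind, ped)
  founders_in_ped <- unique(c(offspring_ped$dam, offspring_ped$sire))
  founders_in_ped <- setdiff(founders_in_ped, offspring_ped$id)
  true_ped <- rbind(
    data.frame(id = sort(founders_in_ped), dam = NA_character_,
               sire = NA_character_, stringsAsFactors = FALSE),
    offspring_ped)
  truth <- list(true_pedigree = true_ped, family = stats::setNames(fams, ids),
                founder_p = p)
  list(genotypes = G, truth = truth,
       assumed_pedigree = assumed_op_pedigree(ids, fams,
                                              dam_ids = offspring_ped$dam))
}

scale_to_var <- function(x, target) {
  v <- stats::var(x)
  if (target == 0 || v == 0) return(rep(0, length(x)))
  (x - mean(x)) * sqrt(target / v) # exact realized variance, zero mean
}

#' Simulate phenotypes under the OP trial variance structure
#'
#' True breeding values come from additive locus effects on centered dosages,
#' dominance deviations from heterozygote effects on a locus subset, and
#' additive-by-additive values from products of centered dosages on random
#' locus pairs; each genetic term is empirically rescaled so its realized
#' variance equals the target exactly. Replication (block), replication x
#' family and residual effects are independent zero-mean normals at their
#' targets. Families are spread round-robin over blocks.
#'
#' @param progeny result of [simulate_op_progeny()].
#' @param config the same [sim_config()].
#' @return list with `phenotypes` (data.frame id, family, block, trait) and
#'   `truth` (true pedigree, per-individual true genetic values, realized
#'   variances).
#' @export
simulate_phenotypes <- function(progeny, config) {
  validate_sim_config(config)
  set.seed(config$seed + 2L)
  G <- progeny$genotypes
  p <- progeny$truth$founder_p
  n <- nrow(G)
  vt <- config$variance_targets
  Z <- sweep(G, 2L, 2 * p, `-`)

  a <- stats::rnorm(ncol(Z))
  tbv <- scale_to_var(drop(Z %*% a), vt[["additive"]])

  n_dom <- min(config$n_dominance_loci, ncol(G))
  dom_loci <- sample(ncol(G), n_dom)
  H <- (G[, dom_loci, drop = FALSE] == 1L) * 1
  H <- sweep(H, 2L, 2 * p[dom_loci] * (1 - p[dom_loci]), `-`)
  tdd <- scale_to_var(drop(H %*% stats::rnorm(n_dom)), vt[["dominance"]])

  n_pairs <- config$n_epistatic_pairs
  pair_i <- sample(ncol(Z), n_pairs, replace = TRUE)
  pair_j <- sample(ncol(Z), n_pairs, replace = TRUE)
  swap <- pair_i == pair_j
  pair_j[swap] <- (pair_j[swap] %% ncol(Z)) + 1L
  E <- Z[, pair_i, drop = FALSE] * Z[, pair_j, drop = FALSE]
  tee <- scale_to_var(drop(E %*% stats::rnorm(n_pairs)), vt[["add_x_add"]])

  fam <- progeny$truth$family[rownames(G)]
  block <- integer(n)
  for (f in unique(fam)) {
    idx <- which(fam == f)
    block[idx] <- ((sample(config$n_blocks, 1L) + seq_along(idx) - 2L) %%
                     config$n_blocks) + 1L
  }
  block <- sprintf("B%d", block)
  rep_eff <- stats::rnorm(config$n_blocks, 0, sqrt(vt[["replication"]]))
  names(rep_eff) <- sprintf("B%d", seq_len(config$n_blocks))
  rf <- interaction(block, fam, drop = TRUE)
  rf_eff <- stats::rnorm(nlevels(rf), 0, sqrt(vt[["rep_x_family"]]))
  resid <- stats::rnorm(n, 0, sqrt(vt[["residual"]]))

  y <- config$trait_mean + tbv + tdd + tee + rep_eff[block] +
    rf_eff[as.integer(rf)] + resid
  pheno <- data.frame(id = rownames(G), family = unname(fam), block = block,
                      trait = unname(y), stringsAsFactors = FALSE)
  truth <- progeny$truth
  truth$true_breeding_value <- stats::setNames(tbv, rownames(G))
  truth$true_dominance_deviation <- stats::setNames(tdd, rownames(G))
  truth$true_epistatic_value <- stats::setNames(tee, rownames(G))
  truth$realized_variances <- c(additive = stats::var(tbv),
                                dominance = stats::var(tdd),
                                add_x_add = stats::var(tee),
                                replication = stats::var(unname(rep_eff[block])),
                                rep_x_family = stats::var(rf_eff[as.integer(rf)]),
                                residual = stats::var(resid))
  list(phenotypes = pheno, truth = truth)
}

#' Full synthetic OP-family dataset
#'
#' Convenience wrapper chaining [simulate_founders()],
#' [simulate_op_progeny()] and [simulate_phenotypes()].
#'
#' @param config a [sim_config()].
#' @return list: `genotypes`, `phenotypes`, `assumed_pedigree`, `truth`,
#'   `founder_p`, `config`.
#' @export
simulate_op_dataset <- function(config = sim_config()) {
  founders <- simulate_founders(config)
  progeny <- simulate_op_progeny(founders, config)
  ph <- simulate_phenotypes(progeny, config)
  list(genotypes = progeny$genotypes, phenotypes = ph$phenotypes,
       assumed_pedigree = progeny$assumed_pedigree, truth = ph$truth,
       founder_p = founders$p, config = config)
}
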