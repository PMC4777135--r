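# Independent oracles used across the suite.

# Recursive kinship (coancestry) on an ordered pedigree; A = 2 * kinship.
# Deliberately independent of the tabular method in the package.
kinship_bruteforce <- function(ped) {
  ids <- ped$id
  pos <- setNames(seq_along(ids), ids)
  dam <- ped$dam
  sire <- ped$sire
  kin <- function(i, j) {
    if (i == 0L || j == 0L) return(0)
    if (i == j) {
      d <- if (is.na(dam[i])) 0L else pos[[dam[i]]]
      s <- if (is.na(sire[i])) 0L else pos[[sire[i]]]
      return(0.5 + 0.5 * kin(d, s))
    }
    if (i < j) { tmp <- i; i <- j; j <- tmp }  # recurse on the later individual
    d <- if (is.na(dam[i])) 0L else pos[[dam[i]]]
    s <- if (is.na(sire[i])) 0L else pos[[sire[i]]]
    0.5 * (kin(d, j) + kin(s, j))
  }
  n <- length(ids)
  K <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) for (j in seq_len(i)) K[i, j] <- K[j, i] <- kin(i, j)
  K
}

# Random ordered pedigree: founders plus offspring drawing each parent from
# earlier individuals (or unknown).
random_pedigree <- function(n_founders = 4, n_offspring = 8,
                            p_unknown = 0.3) {
  ids <- sprintf("P%02d", seq_len(n_founders + n_offspring))
  dam <- sire <- rep(NA_character_, n_founders + n_offspring)
  for (i in seq_len(n_offspring)) {
    row <- n_founders + i
    pool <- ids[seq_len(row - 1L)]
    if (runif(1) > p_unknown) dam[row] <- sample(pool, 1)
    if (runif(1) > p_unknown) sire[row] <- sample(pool, 1)
  }
  data.frame(id = ids, dam = dam, sire = sire, stringsAsFactors = FALSE)
}

# Small random genotype matrix with ids.
random_genotypes <- function(n, m, maf = c(0.1, 0.5)) {
  p <- runif(m, maf[1], maf[2])
  g <- matrix(rbinom(n * m, 2, rep(p, each = n)), n,
              dimnames = list(sprintf("i%03d", seq_len(n)),
                              sprintf("L%03d", seq_len(m))))
  g
}

# Small contaminated OP dataset used by several tests.
small_op_config <- function(seed, n_families = 40, offspring = 6,
                            n_loci = 300, selfing = 0, repeated = 0,
                            targets = c(additive = 2, dominance = 0,
                                        add_x_add = 0, replication = 0.5,
                                        rep_x_family = 1, residual = 5)) {
  sim_config(n_parents = n_families, n_families = n_families,
             offspring_per_family = offspring, n_blocks = 6,
             n_loci = n_loci, pollen_pool_size = max(offspring, 8),
             selfing_rate = selfing, repeated_sire_rate = repeated,
             variance_targets = targets, n_dominance_loci = min(50, n_loci),
             n_epistatic_pairs = 100, seed = seed)
}

toy_freq <- function(p) list(p = p, retained = seq_along(p),
                             dropped = character(0))

add_rf <- function(ph) {
  ph$.rep_family <- paste(ph$block, ph$family, sep = ":")
  ph
}
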