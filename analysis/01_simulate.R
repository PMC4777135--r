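#!/usr/bin/env Rscript
# Step 1 -- generate a synthetic open-pollinated progeny trial.
#
# The generator emulates a single-site OP family test: founder dams in
# Hardy-Weinberg equilibrium, families assumed half-sib but contaminated with
# selfs and full-sibs at the configured rates, a randomized complete block
# design, and a height-scale trait carrying additive, (small) dominance and
# large additive-by-additive variance on top of replication, rep-x-family
# and residual noise. Sizes are scaled to roughly half the motivating trial
# so every downstream step runs in minutes on a laptop.

suppressPackageStartupMessages(library(opgblup))

out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config(
  n_parents = 120, n_families = 120, offspring_per_family = 8,
  n_blocks = 6, n_loci = 1500, maf_range = c(0.05, 0.5),
  pollen_pool_size = 20, selfing_rate = 0.05, repeated_sire_rate = 0.10,
  variance_targets = c(additive = 1160, dominance = 12, add_x_add = 1335,
                       replication = 555, rep_x_family = 2614,
                       residual = 6163),
  n_dominance_loci = 300, n_epistatic_pairs = 1000, seed = 20160119)

d <- simulate_op_dataset(cfg)

write_genotypes_tsv(d$genotypes, file.path(out, "genotypes.tsv"))
write_phenotypes_csv(d$phenotypes, file.path(out, "phenotypes.csv"))
write_pedigree_csv(d$assumed_pedigree, file.path(out, "assumed_pedigree.csv"))
write_pedigree_csv(d$truth$true_pedigree, file.path(out, "true_pedigree.csv"))
yaml::write_yaml(unclass(cfg), file.path(out, "sim_config.yaml"))
utils::write.csv(
  data.frame(id = names(d$truth$true_breeding_value),
             tbv = unname(d$truth$true_breeding_value),
             dominance = unname(d$truth$true_dominance_deviation),
             epistatic = unname(d$truth$true_epistatic_value)),
  file.path(out, "true_genetic_values.csv"), row.names = FALSE)

rv <- d$truth$realized_variances
cat("Simulated", nrow(d$genotypes), "offspring in", cfg$n_families,
    "OP families on", cfg$n_loci, "loci.\n")
cat("Realized variances (genetic terms rescaled to their targets):\n")
print(round(rv, 2))
tp <- d$truth$true_pedigree
off <- tp[!is.na(tp$dam), ]
cat(sprintf("Hidden relatedness: %.1f%% selfs, %.1f%% repeated-sire offspring\n",
            100 * mean(off$sire == off$dam),
            100 * mean(duplicated(paste(off$dam, off$sire)) & off$sire != off$dam)))
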