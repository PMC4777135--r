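#!/usr/bin/env Rscript
# Step 2 -- relationship matrices.
#
# Builds the pedigree numerator relationship matrix A from the *assumed*
# half-sib pedigree, and the realized genomic kernels from the markers:
# G_add (VanRaden), G_dom (Vitezica coding) and the Hadamard epistatic
# products AxA, DxD, AxD. Exports the within/among-family relationship
# distributions -- the diagnostic that shows how far assumed half-sib
# families stray from the expected 0.25.

suppressPackageStartupMessages(library(opgblup))

data_dir <- "results/data"
out <- "results/kernels"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

genotypes <- read_genotypes_tsv(file.path(data_dir, "genotypes.tsv"))
pheno <- read_phenotypes_csv(file.path(data_dir, "phenotypes.csv"))
ped <- read_pedigree_csv(file.path(data_dir, "assumed_pedigree.csv"))

A <- numerator_relationship(ped)
G <- genomic_kernels(genotypes)  # observed-sample allele frequencies

write_kernel_tsv(A, file.path(out, "A.tsv"))
for (nm in names(G)) write_kernel_tsv(G[[nm]], file.path(out, paste0(nm, ".tsv")))

fam <- setNames(pheno$family, pheno$id)
rs <- relationship_summaries(G$G_add, fam, bin_width = 0.05)
utils::write.csv(rbind(
  data.frame(group = "within", rs$within$histogram),
  data.frame(group = "among", rs$among$histogram)),
  file.path(out, "relationship_histograms.csv"), row.names = FALSE)

cat(sprintf("Within-family G_add: mean %.3f (sd %.3f) over %d pairs\n",
            rs$within$mean, rs$within$sd, length(rs$within$values)))
cat(sprintf("Among-family  G_add: mean %.3f (sd %.3f) over %d pairs\n",
            rs$among$mean, rs$among$sd, length(rs$among$values)))
cat("Contamination pushes the within-family mean above the half-sib 0.25;\n")
cat("the among-family mean stays at 0 (unrelated dams and pollen pools).\n")

# correlation between the additive and additive-by-additive kernels (the
# "tug-of-war" diagnostic for epistatic variance partitioning)
ut <- upper.tri(G$G_add)
cat(sprintf("cor(G_add, AxA) off-diagonals: r = %.3f\n",
            cor(unclass(G$G_add)[ut], unclass(G$AxA)[ut])))
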