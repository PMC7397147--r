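#!/usr/bin/env Rscript
# Suggest PCR primers for confirmed SNP-bearing markers: conserved pairs
# bracketing the SNP (sequence in both sexes, heterozygous in the
# heterogametic one) and allele-specific pairs whose 3' ends sit on the
# Y alleles (amplify the Y haplotype only).

suppressPackageStartupMessages(library(sexmarkr))

catalog <- read_fasta("results/simdata/catalog.fa")
calls <- read.delim("results/calls_validated.tsv")
class(calls) <- c("marker_calls", "data.frame")
confirmed <- calls[calls$status == "CONFIRMED" & !is.na(calls$snp_col), ]

# SNP metadata (column and alleles) from the simulation's truth files
truth_geno <- read_genotype_matrix("results/simdata/genotypes.tsv")
panel <- read_sex_map("results/simdata/sex_map.tsv")
records <- read_sumstats("results/simdata/populations.sumstats.tsv", panel)
rec <- records[match(confirmed$locus_id, records$locus_id), ]
# X allele: the allele near-fixed in the homogametic sex; Y: the other
fx <- ifelse(rec$n_F > 0, rec$p_count_F / (2 * rec$n_F), NA)
snp_meta <- data.frame(
  locus_id = rec$locus_id, col = rec$col,
  x_allele = ifelse(fx >= 0.5, rec$p_nuc, rec$q_nuc),
  y_allele = ifelse(fx >= 0.5, rec$q_nuc, rec$p_nuc))

cons <- design_primers(confirmed, catalog, snp_meta, type = "conserved")
as_ <- design_primers(confirmed, catalog, snp_meta,
                      type = "allele_specific")
message(sprintf("conserved pairs: %d markers; allele-specific pairs: %d markers",
                length(unique(cons$locus_id)),
                length(unique(as_$locus_id))))
primers <- rbind(cons, as_)
write.table(primers, "results/primers.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message("wrote results/primers.tsv")
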