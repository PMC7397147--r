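#!/usr/bin/env Rscript
# Screen the catalog for sex-linked markers with the three criteria
# (allele-frequency difference, heterozygosity contrast, sex-limited
# occurrence), reading the Stacks-dialect files written by 01_simulate.R,
# and write the united candidate list.

suppressPackageStartupMessages(library(sexmarkr))

panel <- read_sex_map("results/simdata/sex_map.tsv")
records <- read_sumstats("results/simdata/populations.sumstats.tsv", panel)
occupancy <- read_matches("results/simdata/matches.tsv", panel)

scr <- screen_all(records, occupancy, panel)
cts <- scr$counts
message(sprintf("allele-frequency screen: %d SNPs on %d tags",
                cts$n_snps_freq, cts$n_tags_freq))
message(sprintf("heterozygosity screen:   %d SNPs on %d tags (%d shared)",
                cts$n_snps_het, cts$n_tags_het, cts$n_tags_freq_het_overlap))
message(sprintf("sex-limited tags:        %d male-limited, %d female-limited",
                cts$n_male_limited, cts$n_female_limited))
message(sprintf("united candidates:       %d (%d conflicts excluded)",
                cts$n_candidates, cts$n_conflict))

write.table(as.data.frame(scr$calls), "results/candidates.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(data.frame(statistic = names(cts), value = unlist(cts)),
            "results/screen_counts.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message("wrote results/candidates.tsv and results/screen_counts.tsv")
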