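#!/usr/bin/env Rscript
# Validate the screened candidates with the false-positive cascade:
# opposite-sex raw-read search for sex-limited tags, genome-alignment
# filters against the homogametic-sex assembly, and duplicate collapse.
# Writes the confirmed marker list and the stage-by-stage ledger.

suppressPackageStartupMessages(library(sexmarkr))

panel <- read_sex_map("results/simdata/sex_map.tsv")
records <- read_sumstats("results/simdata/populations.sumstats.tsv", panel)
catalog <- read_fasta("results/simdata/catalog.fa")
genome <- read_fasta("results/simdata/homogametic_genome.fa")

calls <- read.delim("results/candidates.tsv")
class(calls) <- c("marker_calls", "data.frame")

read_files <- list.files("results/simdata/reads", full.names = TRUE)
sample_of <- sub("\\.fq$", "", basename(read_files))
pool <- function(sex) {
  files <- read_files[panel$sex[sample_of] == sex]
  unlist(lapply(files, read_fastq), use.names = FALSE)
}
reads <- list(M = pool("M"), F = pool("F"))

val <- run_validation(calls, catalog, reads, genome, records)
message("validation ledger:")
print(as.data.frame(val$ledger))
message(sprintf("confirmed markers: %d (%d sex-limited, %d SNP)",
                nrow(val$confirmed), sum(is.na(val$confirmed$snp_col)),
                sum(!is.na(val$confirmed$snp_col))))

write.table(as.data.frame(val$calls), "results/calls_validated.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(as.data.frame(val$ledger), "results/ledger.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
message("wrote results/calls_validated.tsv and results/ledger.tsv")
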