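#!/usr/bin/env Rscript
# Assign confirmed markers to the candidate sex-chromosome assembly (top
# alignment at e <= 1e-20) and annotate the mapped markers against a small
# local gene database built for the demonstration.

suppressPackageStartupMessages(library(sexmarkr))

catalog <- read_fasta("results/simdata/catalog.fa")
contigs <- read_fasta("results/simdata/hemi_contigs.fa")
calls <- read.delim("results/calls_validated.tsv")
class(calls) <- c("marker_calls", "data.frame")
confirmed <- calls[calls$status == "CONFIRMED", ]

asg <- assign_to_chromosome(confirmed, catalog, contigs)
message(sprintf("mapped %d of %d confirmed markers (%.1f%%)",
                asg$n_mapped, asg$n_confirmed, 100 * asg$mapped_fraction))
write.table(asg$assignments, "results/assignments.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

# annotation demonstration: a synthetic "gene" database in which one mapped
# marker has a diverged (~80% identity) copy of a gene segment.
# (A seed distinct from the simulation's: reusing the master seed would
# replay the RNG stream that generated the catalog tags themselves.)
set.seed(8847L)
mapped_ids <- asg$assignments$locus_id[asg$assignments$mapped]
if (length(mapped_ids)) {
  bases <- c("A", "C", "G", "T")
  gene <- paste(sample(bases, 3000, replace = TRUE), collapse = "")
  seg <- catalog[[as.character(mapped_ids[1])]]
  for (p in sample(nchar(seg), round(0.2 * nchar(seg)))) {
    substr(seg, p, p) <- sample(setdiff(bases, substr(seg, p, p)), 1)
  }
  db <- c(synthetic_gene = paste0(substr(gene, 1, 1200), seg,
                                  substr(gene, 1201, 3000)))
  ann <- annotate_markers(confirmed[confirmed$locus_id %in% mapped_ids, ],
                          catalog, db)
  print(ann)
  write.table(ann, "results/annotation.tsv", sep = "\t", quote = FALSE,
              row.names = FALSE)
}
message("wrote results/assignments.tsv and results/annotation.tsv")
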