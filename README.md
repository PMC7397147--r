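# sexmarkr

Sex-linked marker discovery, validation and chromosome assignment for
GBS/RAD-seq catalogs.

Many amphibians and fishes have young, homomorphic sex chromosomes, so
neither karyotypes nor reference genomes reveal which chromosome determines
sex or whether the system is XY (male heterogametic) or ZW (female
heterogametic). Given a catalog built from a sexed panel (e.g. 21 males and
19 females), `sexmarkr` finds the loci that betray the sex-limited
chromosome, confirms them, and maps them onto a candidate assembly:

1. **Screen** every SNP and tag with three criteria, each evaluated for both
   XY and ZW: an allele near-fixed in the homogametic sex (frequency
   ≥ 0.95) with a between-sex frequency difference ≥ 0.45; all genotyped
   homogametic-sex individuals homozygous with ≥ half of the heterogametic
   sex heterozygous; and tags present in ≥ half of one sex but absent from
   the other.
2. **Validate** candidates with a false-positive cascade: exact search of
   sex-limited tags in the opposite sex's raw reads, a multi-hit
   (≥ 2 hits, ≥ 99% identity) filter against the homogametic-sex genome, an
   allele-consistency filter for SNP tags (significant alignment, e ≤ 1e-20,
   whose genome base matches the homogametic-fixed allele), and duplicate
   collapse at ≥ 95% identity with transitive grouping. Every stage is
   recorded in a conservation-checked ledger.
3. **Assign** confirmed markers to candidate sex-chromosome contigs by top
   alignment at e ≤ 1e-20 and report the mapped fraction; optionally
   annotate mapped markers against a local sequence database.
4. **Design primers**: allele-specific pairs whose 3′-terminal bases sit on
   Y-specific SNPs (male-only amplification) and conserved pairs bracketing
   a SNP (sequence-based sexing).

A synthetic-data module (`simulate_panel()`) generates sexed GBS panels
with known ground truth in every input format the pipeline consumes
(Stacks-dialect `populations.sumstats.tsv`, `matches.tsv`, catalog FASTA,
per-sample FASTQ, genome and contig FASTA, sex map), and
`simulate_cascade_fixture()` builds staged validation scenarios with
prescribed outcomes.

## Worked example

The staged scenario below constructs 141 candidates — 56 male-limited tags
(24 of them planted into female reads as contaminants, 4 repeated in the
female genome, 3 near-identical pairs), 10 female-limited contaminants, and
75 candidate SNP tags (48 embedded consistently in the female genome, four
duplicate pairs among them) — then runs the cascade and the assignment:

```r
library(sexmarkr)

fx  <- simulate_cascade_fixture(seed = 1)
val <- run_validation(fx$calls, fx$catalog, fx$reads_by_sex, fx$genome)
as.data.frame(val$ledger)
#>                stage  branch n_in n_retained n_removed
#> 1 opposite_sex_reads limited   66         32        34
#> 2    genome_multihit limited   32         28         4
#> 3 duplicate_collapse limited   28         25         3
#> 4 genome_consistency     snp   75         48        27
#> 5 duplicate_collapse     snp   48         44         4

nrow(val$confirmed)
#> [1] 69

asg <- assign_to_chromosome(val$confirmed, fx$catalog, fx$contigs)
c(asg$n_mapped, round(100 * asg$mapped_fraction, 1))
#> [1] 55.0 79.7
```

Reading the ledger: of 66 sex-limited candidates, the opposite-sex read
filter removes the 34 contaminants (56 male-limited shrink to 32; all 10
female-limited die); the multi-hit genome filter removes the 4 repeated
tags; duplicate collapse keeps one representative per near-identical pair.
The SNP branch retains the 48 genome-consistent tags and collapses the four
duplicate pairs. The 25 + 44 = 69 survivors are the confirmed sex-linked
markers, of which 55 (79.7%) map onto the candidate chromosome contigs.

A full simulated survey lives in `analysis/`: numbered scripts simulate a
21M/19F panel (`01_simulate.R`), screen it from the on-disk Stacks-dialect
files (`02_screen.R`), validate (`03_validate.R`), assign and annotate
(`04_assign.R`), design primers (`05_primers.R`) and write the accounting
report (`06_report.R`), each leaving its tables under `results/`.

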