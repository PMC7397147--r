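---
title: "Discovering and validating sex-linked markers in GBS catalogs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering and validating sex-linked markers in GBS catalogs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

In many amphibians and fishes the sex chromosomes are young and homomorphic:
no karyotype or reference genome will tell you which chromosome determines
sex, or whether the species is male-heterogametic (XY) or
female-heterogametic (ZW). Reduced-representation sequencing (GBS/RAD-seq)
of a panel of phenotypically sexed individuals offers a shortcut: loci
residing on the sex-limited chromosome (Y or W) leave characteristic
footprints in the catalog of assembled tags, and a handful of such markers
is enough to establish the heterogametic system, anchor a candidate
chromosome, and design diagnostic PCR assays.

`sexmarkr` implements that workflow end to end for Stacks-style catalogs: a
panel of $n_M$ males and $n_F$ females (the surveys this package emulates
used 21 and 19), per-SNP summary statistics split by sex, per-sample
tag-match tables, and consensus tag sequences of roughly 224 bp.

## The three screening criteria

Written for the XY case; the ZW case exchanges the sexes throughout, and
every function evaluates both forms.

**Allele-frequency contrast.** A gametologous SNP has one allele fixed on
the X and a divergent allele on the Y. Females (XX) then carry the X allele
at frequency 1; males (XY) at frequency 1/2. Allowing for genotyping error
and X–Y recombination, a SNP is flagged when some allele has frequency
$\ge 0.95$ in females and the between-sex frequency difference is
$\ge 0.45$. Frequencies are computed over genotyped individuals only,
matching how Stacks reports them.

**Heterozygosity contrast.** At the same kind of locus every female is
homozygous while males are heterozygous (X and Y copies assembled into one
tag). A SNP is flagged when all genotyped females are homozygous and at
least half of the genotyped males are heterozygous.

**Sex-limited occurrence.** A tag hemizygous on the Y assembles in males
only. A tag is flagged when it is matched in zero females and in at least
half of the males. "At least half" is the literal fraction: 10 of 21 males
fails, 11 of 21 passes.

### Why "all females homozygous" is the default

The homozygosity fraction for the homogametic sex
(`hom_female_fraction_min`) defaults to 1 rather than 0.5. The permissive
half-the-females reading admits ordinary autosomal SNPs at a substantial
rate: for a locus with heterozygosity $h$, the chance that at least half of
21 males are heterozygous *and* at least half of 19 females homozygous is
about 25% at $h = 0.5$, and averages several percent over a neutral
site-frequency spectrum. A screen with that false-positive rate would flag
thousands of loci in a catalog of half a million polymorphic tags, which is
not what such surveys report; requiring all genotyped females to be
homozygous brings the chance rate to $(1-h)^{n_F} \approx 10^{-6}$ at
$h = 0.5$ while costing little recall, because missing genotypes are
already excluded from the denominator. The threshold is exposed, so the
permissive reading is `screen_config(hom_female_fraction_min = 0.5)`.

A SNP whose configuration passes both the XY and the ZW form of a screen
(possible under extreme missingness) is flagged ambiguous and not called.
Loci flagged XY by one approach and ZW by another are retained with a
conflict flag but excluded from the candidate union. All threshold
comparisons are inclusive and applied with a $10^{-9}$ tolerance so that
count ratios such as $38/40 - 20/40 \ge 0.45$ behave as the arithmetic
intends rather than as floating-point representation dictates.

## The validation cascade

Screening alone over-calls, so candidates pass a false-positive cascade
whose every stage records its accounting in a ledger
(`n_in = n_retained + n_removed`, stages chained within each branch):

1. **Opposite-sex reads** (sex-limited tags). A truly hemizygous tag cannot
   occur in reads of the homogametic sex; any candidate with one or more
   exact matches in the opposite sex's raw reads is removed. Both strands
   are searched by default — reads derive from either strand — with
   `read_search_revcomp = FALSE` available to reproduce a plain
   forward-strand grep.
2. **Multi-hit genome filter** (sex-limited tags). A candidate with two or
   more hits at $\ge 99\%$ identity in the homogametic-sex genome assembly
   is a repeated sequence, not a Y resident. A coverage requirement (90% of
   the tag) keeps short spurious repeats from triggering the rule.
3. **Genome consistency** (SNP tags). A candidate SNP tag must align
   significantly (e-value $\le 10^{-20}$) to the homogametic-sex genome
   *and* the aligned genome base at the SNP column must equal the allele
   fixed in the homogametic sex. Minus-strand hits are checked with
   complemented alleles.
4. **Duplicate collapse** (both branches). Tags aligning at $\ge 95\%$
   identity over $\ge 90\%$ of the shorter sequence are grouped by
   transitive closure (union–find) and one representative is kept: the
   longest sequence, ties broken by lowest locus id. Pure lowest-id is
   demonstrably not what published surveys did (longer assemblies win), so
   the tie-break is configurable. The operation is idempotent.

Survivors are *confirmed* markers. Confirmed markers are then assigned to a
candidate sex-chromosome assembly by their top alignment (lowest e-value,
ties by bit score then subject id) at e-value $\le 10^{-20}$, and the
mapped fraction — mapped over confirmed — summarizes how much of the signal
the candidate chromosome explains. Annotation against a user-supplied local
FASTA reports the best hit per marker and subject with query cover,
identity, e-value and 1-based subject coordinates; no network access is
ever used.

## The built-in aligner

All alignment steps use one primitive: exact k-mer seeding (word size 11),
per-diagonal ungapped extension to the optimal-scoring segment (+1 match,
−2 mismatch, Kadane's maximum-subarray on the diagonal), and
Karlin–Altschul e-values with standard ungapped nucleotide parameters
($\lambda = 1.28$, $K = 0.46$), the search space being query length times
total database length. Both strands are searched; minus-strand hits are
normalized so subject start $\le$ end with a strand flag. Tag coordinates
are 0-based columns within the tag (the Stacks convention); alignment
coordinates are 1-based inclusive (the BLAST convention).

The e-values are meant to order hits correctly and gate them at the
$10^{-20}$ threshold, not to reproduce NCBI BLAST bit-for-bit; on 224-bp
tags an exact match of ~49 bp already clears $10^{-20}$ against a
desk-scale database. Gapped alignment is out of scope — the cascade's
questions (is this tag present? repeated? carrying which allele at one
column?) are ungapped questions at these scales. Externally produced
12-column tabular alignments can be ingested instead via
`read_blast_tab()`. In the test suite the aligner is checked against a
Smith–Waterman oracle (`Biostrings::pairwiseAlignment` with prohibitive gap
penalties) on sequences up to 500 bp.

## The synthetic panel generator

`simulate_panel()` draws a panel with known ground truth in every format
the pipeline consumes. Under XY (ZW mirrors):

* *Sex-linked SNP loci*: the X allele is fixed in females; males are X/Y
  heterozygotes with probability $1 - r$, where $r$ is the
  marker–sex-locus recombination fraction (default 0).
* *Hemizygous tags*: present in every male, absent from every female, and
  embedded in the Y-contig FASTA but not the female genome.
* *Autosomal SNP loci*: minor-allele frequency drawn from the folded
  neutral site-frequency spectrum over the panel's $2N$ chromosomes
  ($P(i) \propto 1/i + 1/(2N-i)$), genotypes under Hardy–Weinberg,
  independent of sex. The neutral SFS concentrates mass on rare variants,
  as de novo GBS catalogs do; a uniform spectrum would overweight
  intermediate frequencies.
* *Genotyping error*: with probability $e$ the called genotype is replaced
  by one of the other two genotypes uniformly — crude, but analytically
  tractable, so tests can check observed heterozygosity against a binomial
  oracle.
* *Missingness*: each genotype and each tag match is masked independently
  with the stated probability.
* *Raw reads*: unmutated copies of each sample's tag alleles at constant
  Q40. Read-level sequencing error is deliberately absent because the
  read-filter stage is exact-match; a planted-contaminant operation
  (`plant_contaminant()`) creates known false positives instead.

A single master seed drives everything; identical seeds give byte-identical
output files. Default sizes emulate the surveyed design (21 males, 19
females, 224-bp tags) at desk scale: 20 sex-linked SNP loci, 10 hemizygous
tags, 100 autosomal SNP loci and 30 monomorphic tags — enough loci to
measure recall and false-positive rates while keeping a full simulation
under a second.

What the generator does *not* emulate: restriction-site positioning and
allele dropout, linkage between loci, read-quality variation, indels, and
paralogy beyond the explicit duplicate constructions. Passing tests
therefore demonstrate the pipeline's arithmetic and decision rules, not
robustness to every artifact of real GBS data.

`simulate_cascade_fixture()` complements the generator: it constructs a
candidate set whose cascade outcome is fixed by construction (planted
contaminants, repeated genome inserts, near-identical pairs, consistent and
inconsistent embeddings), which is how the test suite and the acceptance
script exercise the bookkeeping at the published scale
(56 → 32 → 28 → 25 sex-limited; 75 → 48 → 44 SNP; 69 confirmed; 55 of 69
mapped, 79.7%).

## Primer suggestion

Two designs, both with 0-based SNP columns on the marker and the Wallace
rule ($2(A{+}T) + 4(G{+}C)$ °C) for melting temperature — adequate for
suggestion-level output; nearest-neighbor thermodynamics is out of scope.

* *Allele-specific*: each primer's 3′-terminal base is the Y allele at a
  Y-specific column (forward on the plus strand ending on the SNP; reverse
  the reverse complement starting at the SNP), so extension fails on the X
  haplotype and only males amplify. With a single Y-specific SNP the
  reverse primer falls back to conserved sequence.
* *Conserved*: both primers avoid every SNP column and the product contains
  at least one SNP, so the amplicon sequences heterozygous in males and
  homozygous in females.

Defaults: primer length 17–25 bases, product 100–300 bp. The reported
product length is the physical amplicon — forward primer 5′ end through
reverse primer 5′ end inclusive — which is always at least the sum of the
primer lengths.

## Problem sizes and runtime choices

The bundled analysis scripts and tests run the full pipeline on the
40-sample desk-scale panel above (~160 loci, ~13,000 reads), the staged
cascade scenario at its published sizes (141 candidates), screening-oracle
enumeration over all genotype-count configurations up to 4 males + 4
females, label-swap symmetry over 100 small simulated panels, and
recall/false-positive measurement over 20 seeds at genotyping error 0.02
and missingness 0.1. These sizes keep any single step within seconds while
leaving every decision rule exercised at its boundaries.

## Known limitations

* The sumstats reader is pinned to the Stacks 2.41 column layout with the
  sexes as populations `M`/`F`; pooled-population output requires the
  per-sample genotype-matrix companion the generator always writes.
* The aligner is ungapped; a marker whose genome copy contains an indel
  inside the aligned region will be filtered as inconsistent rather than
  realigned.
* The consistency rule operationalizes "consistent with the catalog
  record" as X-allele agreement at the SNP column of a significant hit;
  other readings (e.g. requiring the best hit, or excluding multi-hit SNP
  tags) are stricter and can be composed from the exposed primitives.
* Mean reads per sample is reported as the floor of the integer division,
  matching how such totals are customarily printed.
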