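#' Parameters for the synthetic GBS panel generator
#'
#' Defaults mirror the study design the package targets: a wild-caught panel
#' of 21 males and 19 females genotyped at GBS tags trimmed to 224 bp, with a
#' male-heterogametic (XY) system. Locus counts are desk-scale: enough
#' autosomal background to measure false-positive rates, enough sex-linked
#' loci to measure recall.
#'
#' @param n_males,n_females Panel sizes per sex.
#' @param n_autosomal_snp_loci Autosomal loci carrying one biallelic SNP.
#' @param n_sexlinked_snp_loci Gametologous loci: one allele fixed on the
#'   homogametic chromosome (X under XY), the other restricted to the
#'   heterogametic chromosome (Y) and transmitted to the heterogametic sex
#'   with probability `1 - recombination_fraction`.
#' @param n_hemizygous_tags Tags residing only on the heterogametic
#'   chromosome (Y under XY): present in heterogametic-sex samples, absent
#'   from the homogametic sex.
#' @param n_autosomal_tags Monomorphic autosomal tags (background catalog).
#' @param system `"XY"`, `"ZW"` or `"NONE"` (no sex-linked loci).
#' @param genotyping_error_rate Per-genotype probability that the called
#'   genotype is replaced by one of the other two genotypes, uniformly.
#' @param missing_rate Per-genotype (and per tag-match) missingness
#'   probability.
#' @param recombination_fraction Recombination fraction between each
#'   sex-linked marker and the sex-determining locus, in `[0, 0.5]`.
#' @param tag_length Tag length in bases (default 224).
#' @param reads_per_present_tag Raw reads emitted per present tag per sample.
#' @param seed Master seed; all randomness derives from it.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(n_males = 21L, n_females = 19L,
                       n_autosomal_snp_loci = 100L,
                       n_sexlinked_snp_loci = 20L,
                       n_hemizygous_tags = 10L,
                       n_autosomal_tags = 30L,
                       system = c("XY", "ZW", "NONE"),
                       genotyping_error_rate = 0,
                       missing_rate = 0,
                       recombination_fraction = 0,
                       tag_length = 224L,
                       reads_per_present_tag = 2L,
                       seed = 1L) {
  system <- match.arg(system)
  p <- list(n_males = as.integer(n_males), n_females = as.integer(n_females),
            n_autosomal_snp_loci = as.integer(n_autosomal_snp_loci),
            n_sexlinked_snp_loci = as.integer(n_sexlinked_snp_loci),
            n_hemizygous_tags = as.integer(n_hemizygous_tags),
            n_autosomal_tags = as.integer(n_autosomal_tags),
            system = system,
            genotyping_error_rate = genotyping_error_rate,
            missing_rate = missing_rate,
            recombination_fraction = recombination_fraction,
            tag_length = as.integer(tag_length),
            reads_per_present_tag = as.integer(reads_per_present_tag),
            seed = as.integer(seed))
  probs <- c(p$genotyping_error_rate, p$missing_rate)
  if (any(probs < 0 | probs > 1))
    stopf("error and missing rates must lie in [0, 1]")
  if (p$recombination_fraction < 0 || p$recombination_fraction > 0.5)
    stopf("recombination_fraction must lie in [0, 0.5]")
  counts <- unlist(p[c("n_males", "n_females", "n_autosomal_snp_loci",
                       "n_sexlinked_snp_loci", "n_hemizygous_tags",
                       "n_autosomal_tags", "reads_per_present_tag")])
  if (any(counts < 0)) stopf("counts must be non-negative")
  if (p$tag_length < 50L) stopf("tag_length must be at least 50")
  if (p$n_males < 1L || p$n_females < 1L)
    stopf("need at least one sample of each sex: per-sex frequencies are undefined otherwise")
  if (p$system == "NONE") {
    p$n_sexlinked_snp_loci <- 0L
    p$n_hemizygous_tags <- 0L
  }
  structure(p, class = "sim_params")
}

# which sex carries the hemizygous chromosome
het_sex <- function(system) if (system == "ZW") "F" else "M"
hom_sex <- function(system) if (system == "ZW") "M" else "F"

#' Simulate a sexed GBS panel with known ground truth
#'
#' Generates a full dataset bundle in the formats the pipeline consumes:
#' per-SNP records, per-sample genotypes, tag occupancy, catalog consensus
#' sequences, per-sample raw reads, a homogametic-sex genome, contigs of the
#' heterogametic chromosome, and a sex map — plus a truth table naming each
#' locus's category.
#'
#' Under XY (ZW mirrors with the sexes swapped): sex-linked SNP loci are
#' fixed for the X allele in females and heterozygous X/Y in males with
#' probability `1 - recombination_fraction`; hemizygous tags occur in males
#' only and sit on the Y contigs, absent from the female genome; autosomal
#' loci draw a minor-allele frequency from the folded neutral site-frequency
#' spectrum over the panel's chromosomes and genotypes under Hardy–Weinberg
#' independently of sex. Genotyping error then replaces each
#' called genotype with one of the other two uniformly at the stated rate,
#' and missingness masks genotypes and tag matches independently.
#'
#' @param params A [sim_params()].
#' @return A list of class `sim_panel` with elements `panel`, `truth`,
#'   `genotypes`, `snp_records`, `occupancy`, `catalog`, `snp_meta`
#'   (per SNP locus: `col`, `x_allele`, `y_allele`), `reads` (named list,
#'   sample id to read vector), `homogametic_genome`, `hemi_contigs`,
#'   `planted`, and `params`. Identical seeds give identical bundles.
#' @export
simulate_panel <- function(params) {
  stopifnot(is(params, "sim_params"))
  with_seed(params$seed, simulate_panel_impl(params))
}

simulate_panel_impl <- function(p) {
  males <- sprintf("M%02d", seq_len(p$n_males))
  females <- sprintf("F%02d", seq_len(p$n_females))
  panel <- sexed_panel(c(males, females),
                       c(rep("M", p$n_males), rep("F", p$n_females)))
  hsex <- het_sex(p$system)
  het_samples <- panel_samples(panel, if (p$system == "NONE") "M" else hsex)
  hom_samples <- setdiff(panel$sample_ids, het_samples)

  n_total <- p$n_sexlinked_snp_loci + p$n_autosomal_snp_loci +
    p$n_hemizygous_tags + p$n_autosomal_tags
  ids <- seq_len(n_total)
  cat_sl <- ids[seq_len(p$n_sexlinked_snp_loci)]
  cat_au <- ids[p$n_sexlinked_snp_loci + seq_len(p$n_autosomal_snp_loci)]
  cat_hemi <- ids[p$n_sexlinked_snp_loci + p$n_autosomal_snp_loci +
                    seq_len(p$n_hemizygous_tags)]
  cat_plain <- setdiff(ids, c(cat_sl, cat_au, cat_hemi))

  truth <- data.frame(
    locus_id = ids,
    category = c(rep("SEXLINKED_SNP", length(cat_sl)),
                 rep("AUTOSOMAL", length(cat_au)),
                 rep("HEMIZYGOUS_TAG", length(cat_hemi)),
                 rep("AUTOSOMAL", length(cat_plain))),
    system = ifelse(ids %in% c(cat_sl, cat_hemi), p$system, "NONE"))

  catalog <- setNames(vapply(ids, function(i) random_dna(p$tag_length), ""),
                      as.character(ids))

  # SNP metadata: column within tag and the two alleles; the catalog
  # consensus carries the homogametic-chromosome (X/Z) allele
  snp_ids <- c(cat_sl, cat_au)
  snp_meta <- data.frame(locus_id = integer(), col = integer(),
                         x_allele = character(), y_allele = character())
  if (length(snp_ids)) {
    cols <- sample(10:(p$tag_length - 11L), length(snp_ids), replace = TRUE)
    x_al <- substr(catalog[as.character(snp_ids)], cols + 1L, cols + 1L)
    y_al <- vapply(x_al, function(a) sample(setdiff(DNA_BASES, a), 1L), "")
    snp_meta <- data.frame(locus_id = snp_ids, col = cols,
                           x_allele = unname(x_al), y_allele = unname(y_al))
  }

  # true genotypes, one row per (locus, sample)
  geno <- vector("list", length(snp_ids))
  for (k in seq_along(snp_ids)) {
    lid <- snp_ids[k]
    meta <- snp_meta[k, ]
    gg <- character(length(panel$sample_ids))
    names(gg) <- panel$sample_ids
    if (lid %in% cat_sl) {
      gg[hom_samples] <- strrep(meta$x_allele, 2L)
      carries_y <- runif(length(het_samples)) >= p$recombination_fraction
      gg[het_samples] <- ifelse(
        carries_y,
        paste0(pmin(meta$x_allele, meta$y_allele),
               pmax(meta$x_allele, meta$y_allele)),
        strrep(meta$x_allele, 2L))
    } else {
      # minor-allele frequency from the folded neutral SFS over the panel's
      # 2N chromosomes; the consensus carries the major allele
      two_n <- 2L * length(panel$sample_ids)
      i <- seq_len(floor(two_n / 2))
      w <- 1 / i + ifelse(i < two_n - i, 1 / (two_n - i), 0)
      maf <- sample(i, 1L, prob = w) / two_n
      n_alt <- rbinom(length(panel$sample_ids), 2L, maf)
      gg[] <- c(strrep(meta$x_allele, 2L),
                paste0(pmin(meta$x_allele, meta$y_allele),
                       pmax(meta$x_allele, meta$y_allele)),
                strrep(meta$y_allele, 2L))[n_alt + 1L]
    }
    geno[[k]] <- data.frame(locus_id = lid, col = meta$col,
                            sample_id = panel$sample_ids,
                            genotype = unname(gg))
  }
  genotypes <- if (length(geno)) do.call(rbind, geno) else
    data.frame(locus_id = integer(), col = integer(),
               sample_id = character(), genotype = character())

  # genotyping error: replace by one of the other two genotypes uniformly
  if (nrow(genotypes) && p$genotyping_error_rate > 0) {
    flip <- runif(nrow(genotypes)) < p$genotyping_error_rate
    if (any(flip)) {
      al <- snp_meta[match(genotypes$locus_id, snp_meta$locus_id), ]
      g3 <- cbind(strrep(al$x_allele, 2L),
                  paste0(pmin(al$x_allele, al$y_allele),
                         pmax(al$x_allele, al$y_allele)),
                  strrep(al$y_allele, 2L))
      for (i in which(flip)) {
        others <- setdiff(g3[i, ], genotypes$genotype[i])
        genotypes$genotype[i] <- sample(others, 1L)
      }
    }
  }
  if (nrow(genotypes) && p$missing_rate > 0)
    genotypes <- genotypes[runif(nrow(genotypes)) >= p$missing_rate, ,
                           drop = FALSE]

  # tag occupancy: autosomal and SNP tags in everyone, hemizygous tags in the
  # heterogametic sex only; tag-level missingness applied independently
  occ_loci <- c(rep(c(cat_sl, cat_au, cat_plain),
                    each = length(panel$sample_ids)),
                rep(cat_hemi, each = length(het_samples)))
  occ_samp <- c(rep(panel$sample_ids, length(c(cat_sl, cat_au, cat_plain))),
                rep(het_samples, length(cat_hemi)))
  if (p$missing_rate > 0) {
    keep <- runif(length(occ_loci)) >= p$missing_rate
    occ_loci <- occ_loci[keep]; occ_samp <- occ_samp[keep]
  }
  occupancy <- tag_occupancy(occ_loci, occ_samp, panel)

  # raw reads: unmutated copies of the sample's tag alleles
  variant_seq <- function(lid, allele) {
    meta <- snp_meta[snp_meta$locus_id == lid, ]
    s <- catalog[[as.character(lid)]]
    substr(s, meta$col + 1L, meta$col + 1L) <- allele
    s
  }
  reads <- setNames(vector("list", length(panel$sample_ids)),
                    panel$sample_ids)
  occ_by_sample <- split(occupancy$locus_id, occupancy$sample_id)
  geno_by_sample <- split(genotypes[, c("locus_id", "genotype")],
                          genotypes$sample_id)
  for (sm in panel$sample_ids) {
    present <- occ_by_sample[[sm]] %||% integer()
    gs <- geno_by_sample[[sm]]
    out <- character(0)
    for (lid in present) {
      alleles <- catalog[[as.character(lid)]]
      gi <- if (is.null(gs)) character(0) else
        gs$genotype[match(lid, gs$locus_id)]
      gi <- gi[!is.na(gi)]
      if (length(gi) == 1L && substr(gi, 1, 1) != substr(gi, 2, 2)) {
        alleles <- c(variant_seq(lid, substr(gi, 1, 1)),
                     variant_seq(lid, substr(gi, 2, 2)))
      } else if (length(gi) == 1L) {
        alleles <- variant_seq(lid, substr(gi, 1, 1))
      }
      rep_seq <- rep(alleles, length.out = p$reads_per_present_tag)
      out <- c(out, setNames(rep_seq,
                             sprintf("%s_tag%d_r%d", sm, lid,
                                     seq_along(rep_seq))))
    }
    reads[[sm]] <- out
  }

  flank <- function(s) paste0(random_dna(60L), s, random_dna(60L))
  hom_ids <- c(cat_sl, cat_au, cat_plain)
  homogametic_genome <- setNames(
    vapply(hom_ids, function(i) flank(catalog[[as.character(i)]]), ""),
    sprintf("contig_%d", hom_ids))
  hemi_inserts <- c(
    setNames(vapply(cat_hemi,
                    function(i) flank(catalog[[as.character(i)]]), ""),
             sprintf("hemicontig_%d", cat_hemi)),
    setNames(vapply(cat_sl, function(i) {
      meta <- snp_meta[snp_meta$locus_id == i, ]
      flank(variant_seq(i, meta$y_allele))
    }, ""), sprintf("hemicontig_sl_%d", cat_sl)))

  structure(list(panel = panel, truth = truth, genotypes = genotypes,
                 snp_records = snp_records_from_genotypes(genotypes, panel),
                 occupancy = occupancy, catalog = catalog,
                 snp_meta = snp_meta, reads = reads,
                 homogametic_genome = homogametic_genome,
                 hemi_contigs = hemi_inserts,
                 planted = character(0), params = p),
            class = "sim_panel")
}

#' @export
print.sim_panel <- function(x, ...) {
  cat(sprintf("sim_panel: %d samples, %d loci (%s system), seed %d\n",
              length(x$panel$sample_ids), nrow(x$truth),
              x$params$system, x$params$seed))
  invisible(x)
}

#' Plant a contaminant read to create a known false positive
#'
#' Inserts the exact consensus sequence of a tag (optionally its reverse
#' complement) as one read in the read set of the first sample of the target
#' sex. Used to exercise the opposite-sex read filter on known negatives.
#'
#' @param bundle A `sim_panel`.
#' @param tag_id Catalog locus id of the tag to plant.
#' @param target_sex `"M"` or `"F"`; defaults to the homogametic sex (the
#'   opposite sex for a hemizygous tag).
#' @param revcomp Plant the reverse complement instead of the forward
#'   sequence.
#' @return The modified bundle, with the planting recorded in `$planted`.
#' @export
plant_contaminant <- function(bundle, tag_id,
                              target_sex = NULL, revcomp = FALSE) {
  stopifnot(is(bundle, "sim_panel"))
  key <- as.character(tag_id)
  if (!key %in% names(bundle$catalog)) stopf("unknown tag_id: %s", key)
  target_sex <- target_sex %||% hom_sex(bundle$params$system)
  victim <- panel_samples(bundle$panel, target_sex)[1]
  seqv <- bundle$catalog[[key]]
  if (revcomp) seqv <- revcomp(seqv)
  nm <- sprintf("%s_planted_%s%s", victim, key, if (revcomp) "_rc" else "")
  bundle$reads[[victim]] <- c(bundle$reads[[victim]], setNames(seqv, nm))
  bundle$planted <- c(bundle$planted, key)
  bundle
}

# reads pooled by sex: list(M = character vector, F = character vector)
reads_by_sex <- function(bundle) {
  stopifnot(is(bundle, "sim_panel"))
  pool <- function(s) {
    ids <- panel_samples(bundle$panel, s)
    unlist(bundle$reads[ids], use.names = TRUE) %||% character(0)
  }
  list(M = pool("M"), F = pool("F"))
}

#' Write a simulated bundle to disk in every pipeline input format
#'
#' Emits `populations.sumstats.tsv`, the per-sample genotype matrix
#' companion, `matches.tsv`, `catalog.fa`, one FASTQ per sample (Phred+33,
#' constant Q40), the homogametic-sex genome FASTA, the
#' heterogametic-chromosome contig FASTA, the sex map, and the truth table.
#'
#' @param bundle A `sim_panel`.
#' @param dir Output directory (created if needed).
#' @return Named list of written paths, invisibly.
#' @export
write_panel_files <- function(bundle, dir) {
  stopifnot(is(bundle, "sim_panel"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    sumstats = file.path(dir, "populations.sumstats.tsv"),
    genotype_matrix = file.path(dir, "genotypes.tsv"),
    matches = file.path(dir, "matches.tsv"),
    catalog = file.path(dir, "catalog.fa"),
    genome = file.path(dir, "homogametic_genome.fa"),
    hemi_contigs = file.path(dir, "hemi_contigs.fa"),
    sex_map = file.path(dir, "sex_map.tsv"),
    truth = file.path(dir, "truth.tsv"))
  write_sumstats(bundle$snp_records, paths$sumstats)
  write_genotype_matrix(bundle$genotypes, paths$genotype_matrix)
  write_matches(bundle$occupancy, paths$matches)
  write_fasta(bundle$catalog, paths$catalog)
  write_fasta(bundle$homogametic_genome, paths$genome)
  write_fasta(bundle$hemi_contigs, paths$hemi_contigs)
  write_sex_map(bundle$panel, paths$sex_map)
  write.table(bundle$truth, paths$truth, sep = "\t", quote = FALSE,
              row.names = FALSE)
  read_dir <- file.path(dir, "reads")
  dir.create(read_dir, showWarnings = FALSE)
  paths$reads <- vapply(names(bundle$reads), function(sm) {
    f <- file.path(read_dir, paste0(sm, ".fq"))
    write_fastq(bundle$reads[[sm]], f)
    f
  }, "")
  invisible(paths)
}
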