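#' Construct a validation scenario with prescribed stage outcomes
#'
#' Builds a synthetic candidate set plus the reads, genome and contigs that
#' drive the false-positive cascade to chosen stage-by-stage outcomes, for
#' testing the cascade's bookkeeping end to end. All sequences are random;
#' the scenario is shaped entirely by which tags are planted into
#' opposite-sex reads, duplicated in the homogametic genome, near-duplicated
#' in the catalog, embedded consistently or inconsistently, and copied onto
#' the candidate-chromosome contigs.
#'
#' Defaults reproduce a male-heterogametic survey in which 56 male-limited
#' tags shrink to 32 after the opposite-sex read filter (24 planted
#' contaminants), to 28 after the multi-hit genome filter (4 repeated
#' inserts), and to 25 after duplicate collapse (three near-identical
#' pairs); 10 female-limited tags are all contaminants; and 75 candidate SNP
#' tags shrink to 48 after the genome-consistency filter and to 44 after
#' collapsing four duplicate pairs. 55 of the 69 survivors are embedded in
#' the candidate-chromosome contigs.
#'
#' @param n_male_limited,n_planted,n_multihit Male-limited candidate count,
#'   how many are planted into female reads, how many are duplicated in the
#'   genome.
#' @param limited_dup_pairs List of id pairs that are near-identical; within
#'   each pair the member listed in `longer_members` (if any) carries extra
#'   sequence and is therefore the retained representative, otherwise the
#'   lower id is retained.
#' @param longer_members Ids given a longer sequence than their duplicate
#'   partner.
#' @param n_female_limited Female-limited candidates, all planted into male
#'   reads.
#' @param n_snp,n_snp_unaligned,n_snp_inconsistent SNP-tag candidate count,
#'   how many are absent from the genome, how many are embedded with the
#'   wrong (heterogametic) allele at the SNP column.
#' @param snp_dup_pairs List of id pairs of near-identical SNP tags, all
#'   embedded consistently.
#' @param n_freq_tags,n_overlap_tags SNP tags flagged by the
#'   allele-frequency screen and the overlap with the heterozygosity screen
#'   (the remainder are heterozygosity-only).
#' @param n_mapped How many cascade survivors to embed in the
#'   candidate-chromosome contigs.
#' @param tag_length Tag length in bases.
#' @param seed Master seed.
#' @return A list with `calls` (a `marker_calls` data frame), `catalog`,
#'   `reads_by_sex`, `genome`, `contigs`, `snp_meta`, and the id sets used
#'   in construction.
#' @export
simulate_cascade_fixture <- function(
    n_male_limited = 56L, n_planted = 24L, n_multihit = 4L,
    limited_dup_pairs = list(c(863235L, 871854L), c(871860L, 882819L),
                             c(869195L, 883421L)),
    longer_members = 883421L,
    n_female_limited = 10L,
    n_snp = 75L, n_snp_unaligned = 20L, n_snp_inconsistent = 7L,
    snp_dup_pairs = list(c(24363L, 43213L), c(52538L, 307750L),
                         c(63643L, 199967L), c(85771L, 228137L)),
    n_freq_tags = 18L, n_overlap_tags = 8L,
    n_mapped = 55L, tag_length = 224L, seed = 1L) {
  with_seed(seed, {
    dup_lim_ids <- unlist(limited_dup_pairs)
    n_other_lim <- n_male_limited - n_planted - n_multihit -
      length(dup_lim_ids)
    if (n_other_lim < 0)
      stopf("male-limited subsets exceed n_male_limited")
    planted_ids <- 820000L + seq_len(n_planted)
    multihit_ids <- 810000L + seq_len(n_multihit)
    other_lim_ids <- 830000L + seq_len(n_other_lim)
    male_lim_ids <- c(dup_lim_ids, multihit_ids, planted_ids, other_lim_ids)
    female_lim_ids <- 840000L + seq_len(n_female_limited)

    dup_snp_ids <- unlist(snp_dup_pairs)
    n_aligned <- n_snp - n_snp_unaligned - n_snp_inconsistent
    n_other_aligned <- n_aligned - length(dup_snp_ids)
    if (n_other_aligned < 0) stopf("SNP duplicate pairs exceed aligned set")
    aligned_ids <- c(dup_snp_ids, 100000L + seq_len(n_other_aligned))
    unaligned_ids <- 110000L + seq_len(n_snp_unaligned)
    inconsistent_ids <- 120000L + seq_len(n_snp_inconsistent)
    snp_ids <- c(aligned_ids, unaligned_ids, inconsistent_ids)

    all_ids <- c(male_lim_ids, female_lim_ids, snp_ids)
    if (anyDuplicated(all_ids)) stopf("fixture ids collide")

    catalog <- setNames(
      vapply(all_ids, function(i) random_dna(tag_length), ""),
      as.character(all_ids))
    # near-identical partners: one substitution away from the first member;
    # members listed in longer_members additionally carry a 30-base tail
    mutate_at <- function(s, pos) {
      old <- substr(s, pos, pos)
      substr(s, pos, pos) <- sample(setdiff(DNA_BASES, old), 1L)
      s
    }
    for (pair in c(limited_dup_pairs, snp_dup_pairs)) {
      a <- as.character(pair[1]); b <- as.character(pair[2])
      catalog[[b]] <- mutate_at(catalog[[a]], 5L)
      for (m in intersect(pair, longer_members))
        catalog[[as.character(m)]] <-
          paste0(catalog[[as.character(m)]], random_dna(30L))
    }

    snp_col <- 50L
    x_allele <- substr(catalog[as.character(snp_ids)], snp_col + 1L,
                       snp_col + 1L)
    y_allele <- vapply(x_allele,
                       function(a) sample(setdiff(DNA_BASES, a), 1L), "")
    snp_meta <- data.frame(locus_id = snp_ids, col = snp_col,
                           x_allele = unname(x_allele),
                           y_allele = unname(y_allele))

    # candidate calls: sex-limited tags plus SNP tags with screen approaches
    # split as n_freq_tags FREQ (n_overlap_tags of them also HET), rest HET
    approaches <- c(rep("FREQ", n_freq_tags - n_overlap_tags),
                    rep("FREQ+HET", n_overlap_tags),
                    rep("HET", n_snp - n_freq_tags))
    calls <- rbind(
      data.frame(locus_id = snp_ids, snp_col = snp_col, system = "XY",
                 approaches = approaches),
      data.frame(locus_id = male_lim_ids, snp_col = NA_integer_,
                 system = "XY", approaches = "LIMITED"),
      data.frame(locus_id = female_lim_ids, snp_col = NA_integer_,
                 system = "ZW", approaches = "LIMITED"))
    calls$status <- "PUTATIVE"
    calls$removal_reason <- NA_character_
    calls$conflict <- FALSE
    calls <- calls[order(calls$locus_id), , drop = FALSE]
    rownames(calls) <- NULL
    class(calls) <- c("marker_calls", "data.frame")

    # reads: planted contaminants verbatim, plus random background
    reads_F <- c(unname(catalog[as.character(planted_ids)]),
                 vapply(1:20, function(i) random_dna(tag_length), ""))
    reads_M <- c(unname(catalog[as.character(female_lim_ids)]),
                 vapply(1:20, function(i) random_dna(tag_length), ""))

    # homogametic genome: consistent SNP inserts (consensus carries the
    # homogametic allele), inconsistent inserts with the Y allele at the SNP
    # column, and two high-identity copies of each multi-hit limited tag
    flank <- function(s) paste0(random_dna(60L), s, random_dna(60L))
    with_y_allele <- function(id) {
      s <- catalog[[as.character(id)]]
      ya <- snp_meta$y_allele[snp_meta$locus_id == id]
      substr(s, snp_col + 1L, snp_col + 1L) <- ya
      s
    }
    genome <- c(
      setNames(vapply(aligned_ids,
                      function(i) flank(catalog[[as.character(i)]]), ""),
               sprintf("g_cons_%d", aligned_ids)),
      setNames(vapply(inconsistent_ids,
                      function(i) flank(with_y_allele(i)), ""),
               sprintf("g_incons_%d", inconsistent_ids)),
      setNames(vapply(multihit_ids,
                      function(i) flank(catalog[[as.character(i)]]), ""),
               sprintf("g_rep1_%d", multihit_ids)),
      setNames(vapply(multihit_ids,
                      function(i) flank(mutate_at(catalog[[as.character(i)]],
                                                  9L)), ""),
               sprintf("g_rep2_%d", multihit_ids)))

    # expected cascade survivors, from the construction
    lim_losers <- vapply(limited_dup_pairs, function(p) {
      longer <- intersect(p, longer_members)
      if (length(longer)) setdiff(p, longer)[1] else max(p)
    }, 0L)
    snp_losers <- vapply(snp_dup_pairs, max, 0L)
    surviving <- sort(c(
      setdiff(male_lim_ids, c(planted_ids, multihit_ids, lim_losers)),
      setdiff(aligned_ids, snp_losers)))
    mapped_ids <- head(surviving, n_mapped)
    contigs <- setNames(
      vapply(mapped_ids, function(i) flank(catalog[[as.character(i)]]), ""),
      sprintf("sexchrom_%d", mapped_ids))

    list(calls = calls, catalog = catalog,
         reads_by_sex = list(M = reads_M, F = reads_F),
         genome = genome, contigs = contigs, snp_meta = snp_meta,
         planted_ids = planted_ids, multihit_ids = multihit_ids,
         surviving_ids = surviving, mapped_ids = mapped_ids)
  })
}
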