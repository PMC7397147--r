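#' Screening thresholds
#'
#' Thresholds for the three sex-linkage screens, stated for the XY form; the
#' ZW form mirrors them with the sexes exchanged.
#'
#' * allele-frequency screen: some allele has frequency at least
#'   `homogametic_freq_min` in the homogametic sex and the between-sex
#'   frequency difference is at least `freq_diff_min`;
#' * heterozygosity screen: at least `hom_female_fraction_min` of genotyped
#'   females are homozygous and at least `het_male_fraction_min` of genotyped
#'   males are heterozygous;
#' * sex-limited screen: the tag is absent from every female and present in
#'   at least `presence_fraction_min` of the males.
#'
#' "At least half" is the literal fraction: 10/21 fails, 11/21 passes.
#' Frequencies and fractions are always over genotyped individuals.
#'
#' The homozygosity requirement defaults to all genotyped individuals of the
#' homogametic sex (`hom_female_fraction_min = 1`): an X-linked SNP whose Y
#' allele is absent from females leaves every female homozygous, and a
#' half-the-females rule admits common autosomal SNPs at a rate of several
#' percent under any realistic allele-frequency spectrum (at a
#' heterozygosity of 0.5, roughly a quarter of such loci pass by chance in a
#' 21M/19F panel). Set it to 0.5 for the permissive reading; genotyping
#' error tolerance is better handled by excluding missing genotypes from the
#' denominator, which this screen already does.
#'
#' @param homogametic_freq_min Minimum near-fixed allele frequency in the
#'   homogametic sex (default 0.95).
#' @param freq_diff_min Minimum absolute between-sex frequency difference
#'   (default 0.45).
#' @param het_male_fraction_min,hom_female_fraction_min Heterozygosity-screen
#'   fractions (defaults 0.5 and 1; named for the XY form).
#' @param presence_fraction_min Sex-limited presence fraction (default 0.5).
#' @param min_genotyped_per_sex Minimum genotyped individuals per sex for a
#'   SNP to be evaluable (default 1).
#' @return A list of class `screen_config`.
#' @export
screen_config <- function(homogametic_freq_min = 0.95,
                          freq_diff_min = 0.45,
                          het_male_fraction_min = 0.5,
                          hom_female_fraction_min = 1,
                          presence_fraction_min = 0.5,
                          min_genotyped_per_sex = 1L) {
  cfg <- list(homogametic_freq_min = homogametic_freq_min,
              freq_diff_min = freq_diff_min,
              het_male_fraction_min = het_male_fraction_min,
              hom_female_fraction_min = hom_female_fraction_min,
              presence_fraction_min = presence_fraction_min,
              min_genotyped_per_sex = as.integer(min_genotyped_per_sex))
  th <- unlist(cfg[1:5])
  if (any(th < 0 | th > 1)) stopf("screen thresholds must lie in [0, 1]")
  structure(cfg, class = "screen_config")
}

# allele frequencies of p and q in one sex for every record row
sex_freqs <- function(records, sex) {
  p <- snp_freq(records, sex)
  cbind(p = p, q = 1 - p)
}

# inclusive threshold comparison robust to floating-point representation of
# count ratios (e.g. 38/40 - 20/40 must satisfy >= 0.45)
geq <- function(x, y) x >= y - 1e-9

#' Allele-frequency screen for sex-linked SNPs
#'
#' A SNP is called XY-linked when some allele is near-fixed in females
#' (frequency >= `homogametic_freq_min`) while the between-sex frequency
#' difference for that allele is >= `freq_diff_min` — the pattern of an
#' X-fixed allele with a divergent Y allele carried by males. ZW is the
#' mirror (near-fixed in males). Both thresholds are inclusive. A SNP whose
#' configuration passes both the XY and ZW forms is flagged ambiguous and
#' not called. SNPs with fewer than `min_genotyped_per_sex` genotyped
#' individuals in either sex are skipped (reported, not an error).
#'
#' @param records A `snp_records` table.
#' @param cfg A [screen_config()].
#' @return A data frame with one row per evaluated SNP: `locus_id`, `col`,
#'   `system` (`"XY"`, `"ZW"`, or `NA` for no call), `ambiguous`, `skipped`.
#' @export
screen_allele_freq <- function(records, cfg = screen_config()) {
  out <- data.frame(locus_id = records$locus_id, col = records$col,
                    system = NA_character_, ambiguous = FALSE,
                    skipped = FALSE)
  if (!nrow(records)) return(out)
  skip <- records$n_M < cfg$min_genotyped_per_sex |
    records$n_F < cfg$min_genotyped_per_sex
  fM <- sex_freqs(records, "M"); fF <- sex_freqs(records, "F")
  passes <- function(f_hom, f_het) {
    (geq(f_hom[, "p"], cfg$homogametic_freq_min) &
       geq(abs(f_hom[, "p"] - f_het[, "p"]), cfg$freq_diff_min)) |
      (geq(f_hom[, "q"], cfg$homogametic_freq_min) &
         geq(abs(f_hom[, "q"] - f_het[, "q"]), cfg$freq_diff_min))
  }
  xy <- passes(fF, fM) & !skip
  zw <- passes(fM, fF) & !skip
  out$system[xy & !zw] <- "XY"
  out$system[zw & !xy] <- "ZW"
  out$ambiguous <- xy & zw
  out$skipped <- skip
  out
}

#' Heterozygosity screen for sex-linked SNPs
#'
#' XY form: at least `hom_female_fraction_min` of genotyped females are
#' homozygous and at least `het_male_fraction_min` of genotyped males are
#' heterozygous — males carrying divergent X and Y copies appear
#' heterozygous while females are homozygous. ZW mirrors. Fractions are over
#' genotyped individuals of that sex; a configuration passing both forms is
#' flagged ambiguous and not called.
#'
#' @inheritParams screen_allele_freq
#' @return Same shape as [screen_allele_freq()].
#' @export
screen_heterozygosity <- function(records, cfg = screen_config()) {
  out <- data.frame(locus_id = records$locus_id, col = records$col,
                    system = NA_character_, ambiguous = FALSE,
                    skipped = FALSE)
  if (!nrow(records)) return(out)
  skip <- records$n_M < cfg$min_genotyped_per_sex |
    records$n_F < cfg$min_genotyped_per_sex
  hom_frac <- function(s) ifelse(records[[paste0("n_", s)]] > 0,
                                 records[[paste0("n_hom_", s)]] /
                                   records[[paste0("n_", s)]], NA_real_)
  het_frac <- function(s) ifelse(records[[paste0("n_", s)]] > 0,
                                 records[[paste0("n_het_", s)]] /
                                   records[[paste0("n_", s)]], NA_real_)
  xy <- geq(hom_frac("F"), cfg$hom_female_fraction_min) &
    geq(het_frac("M"), cfg$het_male_fraction_min) & !skip
  zw <- geq(hom_frac("M"), cfg$hom_female_fraction_min) &
    geq(het_frac("F"), cfg$het_male_fraction_min) & !skip
  xy[is.na(xy)] <- FALSE; zw[is.na(zw)] <- FALSE
  out$system[xy & !zw] <- "XY"
  out$system[zw & !xy] <- "ZW"
  out$ambiguous <- xy & zw
  out$skipped <- skip
  out
}

#' Sex-limited tag screen
#'
#' A tag is male-limited (XY evidence) when matched in zero females and in at
#' least `presence_fraction_min` of the males; female-limited (ZW evidence)
#' mirrors. The fraction is over all panel members of that sex.
#'
#' @param occ A `tag_occupancy`.
#' @param panel A [sexed_panel()].
#' @param cfg A [screen_config()].
#' @return Data frame with columns `locus_id`, `system` for flagged tags.
#' @export
screen_sex_limited <- function(occ, panel, cfg = screen_config()) {
  counts <- occupancy_by_sex(occ, panel)
  nM <- sum(panel$sex == "M"); nF <- sum(panel$sex == "F")
  male_lim <- counts$n_F == 0L &
    geq(counts$n_M / nM, cfg$presence_fraction_min) & counts$n_M > 0L
  female_lim <- counts$n_M == 0L &
    geq(counts$n_F / nF, cfg$presence_fraction_min) & counts$n_F > 0L
  data.frame(locus_id = c(counts$locus_id[male_lim],
                          counts$locus_id[female_lim]),
             system = c(rep("XY", sum(male_lim)),
                        rep("ZW", sum(female_lim))))
}

#' Unite the three screens into one candidate list
#'
#' Produces one candidate marker per distinct locus. SNP calls on the same
#' locus merge their approaches (a locus flagged by both SNP screens carries
#' approaches `FREQ+HET`); a locus flagged under XY by one approach and ZW by
#' another is kept with a conflict flag but excluded from the candidate
#' union. Per-approach counts, tag-level counts and overlaps are recorded as
#' ledger stage detail.
#'
#' @param freq_calls,het_calls Outputs of [screen_allele_freq()] and
#'   [screen_heterozygosity()].
#' @param limited_calls Output of [screen_sex_limited()].
#' @return A list with `calls` (a `marker_calls` data frame: `locus_id`,
#'   `snp_col`, `system`, `approaches`, `status`, `removal_reason`,
#'   `conflict`) and `counts` (the screening tallies: SNPs and tags per
#'   approach, tag overlap between the SNP screens, limited tags per system,
#'   and the distinct-candidate union size).
#' @export
unite_candidates <- function(freq_calls, het_calls, limited_calls) {
  f <- freq_calls[!is.na(freq_calls$system), , drop = FALSE]
  h <- het_calls[!is.na(het_calls$system), , drop = FALSE]
  l <- limited_calls

  snp <- rbind(
    if (nrow(f)) data.frame(locus_id = f$locus_id, snp_col = f$col,
                            system = f$system, approach = "FREQ"),
    if (nrow(h)) data.frame(locus_id = h$locus_id, snp_col = h$col,
                            system = h$system, approach = "HET"))
  snp <- snp %||% data.frame(locus_id = integer(), snp_col = integer(),
                             system = character(), approach = character())

  # merge per locus: approaches united, first flagged column kept
  per_locus <- function(d) {
    apps <- paste(sort(unique(d$approach)), collapse = "+")
    sys <- unique(d$system)
    data.frame(locus_id = d$locus_id[1], snp_col = min(d$snp_col),
               system = if (length(sys) == 1L) sys else NA_character_,
               approaches = apps,
               conflict = length(sys) > 1L)
  }
  snp_merged <- if (nrow(snp))
    do.call(rbind, lapply(split(snp, snp$locus_id), per_locus)) else
      data.frame(locus_id = integer(), snp_col = integer(),
                 system = character(), approaches = character(),
                 conflict = logical())

  lim_merged <- if (nrow(l))
    data.frame(locus_id = l$locus_id, snp_col = NA_integer_,
               system = l$system, approaches = "LIMITED",
               conflict = FALSE) else
      data.frame(locus_id = integer(), snp_col = integer(),
                 system = character(), approaches = character(),
                 conflict = logical())

  # a locus both SNP-flagged and sex-limited-flagged merges too
  both <- intersect(snp_merged$locus_id, lim_merged$locus_id)
  if (length(both)) {
    for (id in both) {
      i <- which(snp_merged$locus_id == id)
      j <- which(lim_merged$locus_id == id)
      sys <- unique(c(snp_merged$system[i], lim_merged$system[j]))
      sys <- sys[!is.na(sys)]
      snp_merged$approaches[i] <-
        paste(sort(unique(c(strsplit(snp_merged$approaches[i], "+",
                                     fixed = TRUE)[[1]], "LIMITED"))),
              collapse = "+")
      snp_merged$conflict[i] <- snp_merged$conflict[i] || length(sys) > 1L
      snp_merged$system[i] <- if (length(sys) == 1L) sys else NA_character_
    }
    lim_merged <- lim_merged[!lim_merged$locus_id %in% both, , drop = FALSE]
  }

  calls <- rbind(snp_merged, lim_merged)
  calls <- calls[order(calls$locus_id), , drop = FALSE]
  calls$status <- ifelse(calls$conflict, "REMOVED", "PUTATIVE")
  calls$removal_reason <- ifelse(calls$conflict, "SYSTEM_CONFLICT",
                                 NA_character_)
  calls <- calls[, c("locus_id", "snp_col", "system", "approaches",
                     "status", "removal_reason", "conflict")]
  rownames(calls) <- NULL
  class(calls) <- c("marker_calls", "data.frame")

  counts <- list(
    n_snps_freq = nrow(f), n_tags_freq = length(unique(f$locus_id)),
    n_snps_het = nrow(h), n_tags_het = length(unique(h$locus_id)),
    n_tags_freq_het_overlap = length(intersect(unique(f$locus_id),
                                               unique(h$locus_id))),
    n_male_limited = sum(l$system == "XY"),
    n_female_limited = sum(l$system == "ZW"),
    n_conflict = sum(calls$conflict),
    n_candidates = sum(!calls$conflict))
  list(calls = calls, counts = counts)
}

#' Run all three screens on a dataset
#'
#' Convenience wrapper: evaluates the allele-frequency, heterozygosity and
#' sex-limited screens and unites them into the candidate list.
#'
#' @param records A `snp_records` table.
#' @param occ A `tag_occupancy`.
#' @param panel A [sexed_panel()].
#' @param cfg A [screen_config()].
#' @return As [unite_candidates()].
#' @export
screen_all <- function(records, occ, panel, cfg = screen_config()) {
  unite_candidates(screen_allele_freq(records, cfg),
                   screen_heterozygosity(records, cfg),
                   screen_sex_limited(occ, panel, cfg))
}
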