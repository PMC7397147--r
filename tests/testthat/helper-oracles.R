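# Independent oracles used across tests; deliberately naive implementations.

# exact substring counting by regex scan, independent of Biostrings matching
naive_count <- function(tag, reads, revcomp = TRUE) {
  count_one <- function(pat) {
    sum(vapply(reads, function(r) {
      m <- gregexpr(pat, r, fixed = TRUE)[[1]]
      if (m[1] == -1L) 0L else length(m)
    }, 0L))
  }
  n <- count_one(tag)
  if (revcomp) {
    rc <- paste(rev(chartr("ACGT", "TGCA",
                           strsplit(tag, "")[[1]])), collapse = "")
    n <- n + count_one(rc)
  }
  n
}

# build a one-row snp_records table from per-sex genotype counts
# (counts of PP, PQ, QQ genotypes)
record_from_counts <- function(mPP, mPQ, mQQ, fPP, fPQ, fQQ,
                               locus_id = 1L, col = 0L,
                               p_nuc = "A", q_nuc = "C") {
  out <- data.frame(
    locus_id = locus_id, col = col, p_nuc = p_nuc, q_nuc = q_nuc,
    n_M = mPP + mPQ + mQQ, p_count_M = 2L * mPP + mPQ,
    n_hom_M = mPP + mQQ, n_het_M = mPQ,
    n_F = fPP + fPQ + fQQ, p_count_F = 2L * fPP + fPQ,
    n_hom_F = fPP + fQQ, n_het_F = fPQ)
  class(out) <- c("snp_records", "data.frame")
  out
}

# direct inequality evaluation of the allele-frequency screen
oracle_freq <- function(mPP, mPQ, mQQ, fPP, fPQ, fQQ, fmin = 0.95,
                        dmin = 0.45) {
  nM <- mPP + mPQ + mQQ; nF <- fPP + fPQ + fQQ
  if (nM == 0 || nF == 0) return(NA_character_)
  pM <- (2 * mPP + mPQ) / (2 * nM); pF <- (2 * fPP + fPQ) / (2 * nF)
  pass <- function(fhom, fhet)
    (fhom >= fmin && abs(fhom - fhet) >= dmin) ||
    ((1 - fhom) >= fmin && abs(fhom - fhet) >= dmin)
  xy <- pass(pF, pM); zw <- pass(pM, pF)
  if (xy && zw) return("AMBIG")
  if (xy) return("XY")
  if (zw) return("ZW")
  NA_character_
}

# direct inequality evaluation of the heterozygosity screen
oracle_het <- function(mPP, mPQ, mQQ, fPP, fPQ, fQQ, hom_min = 1,
                       het_min = 0.5) {
  nM <- mPP + mPQ + mQQ; nF <- fPP + fPQ + fQQ
  if (nM == 0 || nF == 0) return(NA_character_)
  xy <- (fPP + fQQ) / nF >= hom_min && mPQ / nM >= het_min
  zw <- (mPP + mQQ) / nM >= hom_min && fPQ / nF >= het_min
  if (xy && zw) return("AMBIG")
  if (xy) return("XY")
  if (zw) return("ZW")
  NA_character_
}

# Smith-Waterman oracle via Biostrings, forced ungapped (+1/-2 scoring)
sw_score <- function(query, subject) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                  baseOnly = TRUE)
  Biostrings::pairwiseAlignment(query, subject, type = "local",
                                substitutionMatrix = mat,
                                gapOpening = 1000, gapExtension = 1000,
                                scoreOnly = TRUE)
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutate_positions <- function(s, positions) {
  for (p in positions) {
    old <- substr(s, p, p)
    substr(s, p, p) <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
  }
  s
}

small_params <- function(...) {
  sim_params(n_males = 6L, n_females = 5L, n_autosomal_snp_loci = 15L,
             n_sexlinked_snp_loci = 6L, n_hemizygous_tags = 4L,
             n_autosomal_tags = 5L, ...)
}
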