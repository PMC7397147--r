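#' Validation thresholds for the false-positive cascade
#'
#' @param genome_evalue_max Significance threshold for genome alignments of
#'   SNP-bearing tags (default 1e-20).
#' @param multihit_identity_min,multihit_min_hits,multihit_cover_min A
#'   sex-limited tag is discarded when it has at least `multihit_min_hits`
#'   genome hits at identity >= `multihit_identity_min` percent covering at
#'   least `multihit_cover_min` of the tag — a tag repeated in the
#'   homogametic genome cannot be hemizygous. The coverage requirement
#'   guards against spurious short repeats.
#' @param dup_identity_min,dup_cover_min Two tags are duplicates when they
#'   align at identity >= `dup_identity_min` percent over at least
#'   `dup_cover_min` of the shorter tag.
#' @param dup_tie_break Duplicate-group representative: the longest sequence
#'   with ties broken by lowest locus id (`"longest_then_lowest"`), or the
#'   lowest id outright.
#' @param read_search_revcomp Search both strands in the opposite-sex read
#'   filter (set `FALSE` for a literal forward-strand grep).
#' @return A list of class `validate_config`.
#' @export
validate_config <- function(genome_evalue_max = 1e-20,
                            multihit_identity_min = 99,
                            multihit_min_hits = 2L,
                            multihit_cover_min = 0.9,
                            dup_identity_min = 95,
                            dup_cover_min = 0.9,
                            dup_tie_break = c("longest_then_lowest",
                                              "lowest_id"),
                            read_search_revcomp = TRUE) {
  if (genome_evalue_max <= 0) stopf("genome_evalue_max must be positive")
  if (multihit_identity_min < 0 || multihit_identity_min > 100 ||
      dup_identity_min < 0 || dup_identity_min > 100)
    stopf("identity thresholds are percentages in [0, 100]")
  if (dup_cover_min < 0 || dup_cover_min > 1 ||
      multihit_cover_min < 0 || multihit_cover_min > 1)
    stopf("coverage thresholds lie in [0, 1]")
  structure(list(genome_evalue_max = genome_evalue_max,
                 multihit_identity_min = multihit_identity_min,
                 multihit_min_hits = as.integer(multihit_min_hits),
                 multihit_cover_min = multihit_cover_min,
                 dup_identity_min = dup_identity_min,
                 dup_cover_min = dup_cover_min,
                 dup_tie_break = match.arg(dup_tie_break),
                 read_search_revcomp = read_search_revcomp),
            class = "validate_config")
}

#' Stage-by-stage accounting ledger
#'
#' A ledger is an ordered list of stage records, each conserving its input:
#' `n_in = n_retained + n_removed`, and within a branch each stage's `n_in`
#' equals the previous stage's `n_retained`. `ledger_stage()` builds one
#' record; `ledger_check()` verifies conservation and chaining and errors on
#' violation; `as.data.frame()` tabulates the counts.
#'
#' @param stage Stage name.
#' @param branch Cascade branch the stage belongs to (e.g. `"limited"`,
#'   `"snp"`).
#' @param in_ids Locus ids entering the stage.
#' @param retained_ids Locus ids retained.
#' @param removed Data frame with `locus_id`, `reason`, `detail` for removed
#'   loci.
#' @return `ledger_stage()` returns a one-stage `ledger` list.
#' @export
ledger_stage <- function(stage, branch, in_ids, retained_ids, removed) {
  if (is.null(removed) || !nrow(removed))
    removed <- data.frame(locus_id = integer(), reason = character(),
                          detail = character())
  rec <- list(stage = stage, branch = branch,
              n_in = length(in_ids), n_retained = length(retained_ids),
              n_removed = nrow(removed), removed = removed)
  if (rec$n_in != rec$n_retained + rec$n_removed)
    stopf("ledger conservation violated at stage '%s': %d in != %d + %d",
          stage, rec$n_in, rec$n_retained, rec$n_removed)
  if (length(setdiff(removed$locus_id, in_ids)))
    stopf("stage '%s' removed loci that never entered it", stage)
  structure(list(rec), class = "ledger")
}

#' @rdname ledger_stage
#' @param ... Ledgers to concatenate, in stage order.
#' @export
ledger_concat <- function(...) {
  parts <- list(...)
  parts <- parts[!vapply(parts, is.null, TRUE)]
  structure(do.call(c, lapply(parts, unclass)), class = "ledger")
}

#' @rdname ledger_stage
#' @param ledger A `ledger`.
#' @export
ledger_check <- function(ledger) {
  stopifnot(is(ledger, "ledger"))
  prev <- list()
  for (rec in ledger) {
    if (rec$n_in != rec$n_retained + rec$n_removed)
      stopf("ledger conservation violated at stage '%s'", rec$stage)
    if (!is.null(prev[[rec$branch]]) && rec$n_in != prev[[rec$branch]])
      stopf("ledger chaining violated at stage '%s': n_in %d != previous n_retained %d",
            rec$stage, rec$n_in, prev[[rec$branch]])
    prev[[rec$branch]] <- rec$n_retained
  }
  invisible(TRUE)
}

#' @export
as.data.frame.ledger <- function(x, ...) {
  do.call(rbind, lapply(x, function(r)
    data.frame(stage = r$stage, branch = r$branch, n_in = r$n_in,
               n_retained = r$n_retained, n_removed = r$n_removed)))
}

#' @export
print.ledger <- function(x, ...) {
  print(as.data.frame(x))
  invisible(x)
}

# mark calls removed/confirmed; helper shared by the filters
apply_removals <- function(calls, removed) {
  if (nrow(removed)) {
    i <- match(removed$locus_id, calls$locus_id)
    calls$status[i] <- "REMOVED"
    calls$removal_reason[i] <- removed$reason
  }
  calls
}

#' Opposite-sex read filter for sex-limited tags
#'
#' A truly hemizygous tag cannot occur in reads of the homogametic sex; any
#' sex-limited candidate with one or more exact matches in the opposite
#' sex's raw reads is discarded as a false positive.
#'
#' @param calls A `marker_calls` data frame of sex-limited candidates.
#' @param catalog Named character vector of catalog consensus sequences
#'   (names are locus ids).
#' @param reads_by_sex List with elements `M` and `F`, each a character
#'   vector of read sequences.
#' @param cfg A [validate_config()].
#' @return List with `retained` (calls), `removed` (data frame) and `stage`
#'   (a one-stage ledger).
#' @export
filter_opposite_sex_reads <- function(calls, catalog, reads_by_sex,
                                      cfg = validate_config()) {
  ids <- as.character(calls$locus_id)
  missing_seq <- setdiff(ids, names(catalog))
  if (length(missing_seq))
    stopf("no catalog sequence for loci: %s",
          paste(head(missing_seq, 5), collapse = ", "))
  counts <- setNames(integer(nrow(calls)), ids)
  for (sys in unique(calls$system)) {
    opp <- if (sys == "XY") "F" else "M"
    sel <- calls$system == sys
    counts[sel] <- find_in_reads(catalog[ids[sel]],
                                 reads_by_sex[[opp]] %||% character(0),
                                 search_revcomp = cfg$read_search_revcomp)
  }
  hit <- counts >= 1L
  removed <- data.frame(locus_id = calls$locus_id[hit],
                        reason = rep("OPPOSITE_SEX_READS", sum(hit)),
                        detail = sprintf("%d read matches", counts[hit]))
  list(retained = calls[!hit, , drop = FALSE], removed = removed,
       stage = ledger_stage("opposite_sex_reads", "limited",
                            calls$locus_id, calls$locus_id[!hit], removed))
}

#' Multi-hit genome filter for sex-limited tags
#'
#' A candidate hemizygous tag with multiple high-identity hits in the
#' homogametic-sex genome is a repeated sequence, not a
#' heterogametic-chromosome resident, and is discarded. Single-hit and
#' no-hit tags are retained.
#'
#' @inheritParams filter_opposite_sex_reads
#' @param genome Named character vector: homogametic-sex genome contigs.
#' @export
filter_genome_limited <- function(calls, catalog, genome,
                                  cfg = validate_config()) {
  if (!length(genome)) stopf("empty genome database")
  removed <- data.frame(locus_id = integer(), reason = character(),
                        detail = character())
  if (nrow(calls)) {
    seqs <- catalog[as.character(calls$locus_id)]
    hits <- align_local(seqs, genome)
    n_multi <- vapply(seq_len(nrow(calls)), function(i) {
      h <- hits[hits$query_id == as.character(calls$locus_id[i]) &
                  hits$percent_identity >= cfg$multihit_identity_min &
                  hits$query_cover >= cfg$multihit_cover_min, , drop = FALSE]
      nrow(h)
    }, 0L)
    bad <- n_multi >= cfg$multihit_min_hits
    removed <- data.frame(
      locus_id = calls$locus_id[bad],
      reason = rep("MULTIPLE_GENOME_HITS", sum(bad)),
      detail = sprintf("%d hits >= %.0f%% identity", n_multi[bad],
                       cfg$multihit_identity_min))
  } else bad <- logical(0)
  list(retained = calls[!bad, , drop = FALSE], removed = removed,
       stage = ledger_stage("genome_multihit", "limited",
                            calls$locus_id, calls$locus_id[!bad], removed))
}

# genome base aligned to query position p1 (1-based) under an ungapped hit
genome_base_at <- function(hit, p1, genome) {
  if (p1 < hit$q_start || p1 > hit$q_end) return(NA_character_)
  if (hit$strand == "+") {
    pos <- hit$subject_start + (p1 - hit$q_start)
    substr(genome[[hit$subject_id]], pos, pos)
  } else {
    pos <- hit$subject_start + (hit$q_end - p1)
    complement_base(substr(genome[[hit$subject_id]], pos, pos))
  }
}

#' Genome-consistency filter for SNP-bearing candidate tags
#'
#' A candidate sex-linked SNP tag is retained only when it aligns
#' significantly (e-value at or below `genome_evalue_max`) to the
#' homogametic-sex genome and the aligned genome base at the SNP column
#' equals the allele fixed in the homogametic sex (the X allele under XY) —
#' the genome of the homogametic sex must carry that allele if the catalog
#' record is real.
#'
#' @inheritParams filter_genome_limited
#' @param records A `snp_records` table; the homogametic-fixed allele is the
#'   majority allele of the homogametic sex. Falls back to the catalog
#'   consensus base at the SNP column for loci without a record.
#' @export
filter_genome_snp <- function(calls, catalog, genome, records = NULL,
                              cfg = validate_config()) {
  if (!length(genome)) stopf("empty genome database")
  removed <- data.frame(locus_id = integer(), reason = character(),
                        detail = character())
  keep <- logical(nrow(calls))
  if (nrow(calls)) {
    seqs <- catalog[as.character(calls$locus_id)]
    if (anyNA(seqs)) stopf("missing catalog sequence for SNP candidates")
    hits <- align_local(seqs, genome, max_evalue = cfg$genome_evalue_max)
    why <- character(nrow(calls))
    for (i in seq_len(nrow(calls))) {
      id <- as.character(calls$locus_id[i])
      h <- hits[hits$query_id == id, , drop = FALSE]
      if (!nrow(h)) { why[i] <- "no significant genome hit"; next }
      expected <- expected_hom_allele(calls$locus_id[i], calls$snp_col[i],
                                      calls$system[i], records, catalog)
      p1 <- calls$snp_col[i] + 1L
      bases <- vapply(seq_len(nrow(h)),
                      function(j) genome_base_at(h[j, ], p1, genome) %||%
                        NA_character_, "")
      if (any(!is.na(bases) & bases == expected)) keep[i] <- TRUE
      else why[i] <- sprintf("genome base %s != %s at SNP column",
                             paste(unique(bases[!is.na(bases)]),
                                   collapse = "/"), expected)
    }
    removed <- data.frame(locus_id = calls$locus_id[!keep],
                          reason = rep("GENOME_INCONSISTENT", sum(!keep)),
                          detail = why[!keep])
  }
  list(retained = calls[keep, , drop = FALSE], removed = removed,
       stage = ledger_stage("genome_consistency", "snp",
                            calls$locus_id, calls$locus_id[keep], removed))
}

# the allele fixed in the homogametic sex: majority allele of that sex from
# the SNP records, else the catalog consensus base at the column
expected_hom_allele <- function(locus_id, snp_col, system, records, catalog) {
  if (!is.null(records)) {
    r <- records[records$locus_id == locus_id & records$col == snp_col, ,
                 drop = FALSE]
    if (nrow(r) == 1L) {
      s <- if (identical(system, "ZW")) "M" else "F"
      fp <- snp_freq(r, s)
      if (!is.na(fp)) return(if (fp >= 0.5) r$p_nuc else r$q_nuc)
    }
  }
  substr(catalog[[as.character(locus_id)]], snp_col + 1L, snp_col + 1L)
}

#' Collapse near-identical candidate tags
#'
#' Groups candidate tags whose sequences align at identity >=
#' `dup_identity_min` percent over at least `dup_cover_min` of the shorter
#' sequence (transitively closed), and keeps one representative per group —
#' the longest sequence, ties broken by lowest locus id. Idempotent.
#'
#' @inheritParams filter_opposite_sex_reads
#' @param branch Ledger branch label.
#' @export
collapse_duplicates <- function(calls, catalog, cfg = validate_config(),
                                branch = "dedup") {
  removed <- data.frame(locus_id = integer(), reason = character(),
                        detail = character())
  keep_ids <- calls$locus_id
  if (nrow(calls) > 1L) {
    ids <- as.character(calls$locus_id)
    seqs <- catalog[ids]
    hits <- align_local(seqs, seqs)
    lens <- setNames(nchar(seqs), ids)
    dup <- hits[hits$query_id != hits$subject_id &
                  hits$percent_identity >= cfg$dup_identity_min &
                  hits$alignment_length >=
                    cfg$dup_cover_min * pmin(lens[hits$query_id],
                                             lens[hits$subject_id]), ,
                drop = FALSE]
    # union-find over duplicate pairs
    parent <- seq_along(ids)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (k in seq_len(nrow(dup))) {
      a <- find(match(dup$query_id[k], ids))
      b <- find(match(dup$subject_id[k], ids))
      if (a != b) parent[b] <- a
    }
    root <- vapply(seq_along(ids), find, 0L)
    groups <- split(ids, root)
    rem <- list()
    for (g in groups) {
      if (length(g) == 1L) next
      ord <- if (cfg$dup_tie_break == "longest_then_lowest")
        order(-lens[g], as.integer(g)) else order(as.integer(g))
      rep_id <- g[ord[1]]
      losers <- setdiff(g, rep_id)
      keep_ids <- setdiff(keep_ids, as.integer(losers))
      rem[[length(rem) + 1L]] <- data.frame(
        locus_id = as.integer(losers), reason = "DUPLICATE",
        detail = sprintf("duplicate of %s", rep_id))
    }
    if (length(rem)) removed <- do.call(rbind, rem)
  }
  retained <- calls[calls$locus_id %in% keep_ids, , drop = FALSE]
  list(retained = retained, removed = removed,
       stage = ledger_stage("duplicate_collapse", branch,
                            calls$locus_id, retained$locus_id, removed))
}

#' Run the full false-positive cascade
#'
#' Composes the validation stages in pipeline order. Sex-limited candidates:
#' opposite-sex read filter, then the multi-hit genome filter, then
#' duplicate collapse. SNP candidates: genome-consistency filter, then
#' duplicate collapse. Survivors are confirmed; the ledger records every
#' stage and conserves counts.
#'
#' @param calls A `marker_calls` data frame (the united candidates).
#' @param catalog Named character vector of catalog sequences.
#' @param reads_by_sex List with read sequences per sex (`M`, `F`).
#' @param genome Homogametic-sex genome, named character vector.
#' @param records Optional `snp_records` for the consistency check.
#' @param cfg A [validate_config()].
#' @return List with `calls` (statuses updated), `confirmed` (the confirmed
#'   subset), and `ledger`.
#' @export
run_validation <- function(calls, catalog, reads_by_sex, genome,
                           records = NULL, cfg = validate_config()) {
  active <- calls[calls$status == "PUTATIVE", , drop = FALSE]
  lim <- active[is.na(active$snp_col), , drop = FALSE]
  snp <- active[!is.na(active$snp_col), , drop = FALSE]

  s1 <- filter_opposite_sex_reads(lim, catalog, reads_by_sex, cfg)
  s2 <- filter_genome_limited(s1$retained, catalog, genome, cfg)
  s3 <- collapse_duplicates(s2$retained, catalog, cfg, branch = "limited")

  s4 <- filter_genome_snp(snp, catalog, genome, records, cfg)
  s5 <- collapse_duplicates(s4$retained, catalog, cfg, branch = "snp")

  ledger <- ledger_concat(s1$stage, s2$stage, s3$stage, s4$stage, s5$stage)
  ledger_check(ledger)

  for (s in list(s1, s2, s3, s4, s5)) calls <- apply_removals(calls, s$removed)
  confirmed_ids <- c(s3$retained$locus_id, s5$retained$locus_id)
  calls$status[calls$locus_id %in% confirmed_ids &
                 calls$status == "PUTATIVE"] <- "CONFIRMED"
  list(calls = calls,
       confirmed = calls[calls$status == "CONFIRMED", , drop = FALSE],
       ledger = ledger)
}
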