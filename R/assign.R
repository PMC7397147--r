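#' Assignment and annotation thresholds
#'
#' @param evalue_max Top hits onto the candidate sex-chromosome assembly are
#'   retained at e-value <= this (default 1e-20).
#' @param annotation_evalue_max Significance threshold for annotation hits
#'   against a local sequence database (default 1e-5).
#' @return A list of class `assign_config`.
#' @export
assign_config <- function(evalue_max = 1e-20, annotation_evalue_max = 1e-5) {
  if (evalue_max <= 0 || annotation_evalue_max <= 0)
    stopf("e-value thresholds must be positive")
  structure(list(evalue_max = evalue_max,
                 annotation_evalue_max = annotation_evalue_max),
            class = "assign_config")
}

# best hit per query: lowest e-value, ties by higher bit score then
# lexicographically lowest subject id
top_hit_per_query <- function(hits) {
  if (!nrow(hits)) return(hits)
  ord <- order(hits$query_id, hits$e_value, -hits$bit_score,
               hits$subject_id)
  h <- hits[ord, , drop = FALSE]
  h[!duplicated(h$query_id), , drop = FALSE]
}

#' Assign confirmed markers to a candidate sex-chromosome assembly
#'
#' Aligns each confirmed marker against the assembly contigs and keeps its
#' top hit (lowest e-value; ties broken by higher bit score, then lowest
#' subject id) when the e-value is at or below `evalue_max`. The mapped
#' fraction — mapped markers over confirmed markers — summarizes how much of
#' the confirmed set the candidate chromosome explains.
#'
#' @param confirmed A `marker_calls` data frame of confirmed markers.
#' @param catalog Named character vector of catalog sequences.
#' @param contigs Named character vector: candidate sex-chromosome assembly.
#' @param cfg An [assign_config()].
#' @param hits Optional pre-computed alignment-hit data frame (e.g. from
#'   [read_blast_tab()]); when supplied the built-in aligner is skipped.
#' @return List with `assignments` (one row per confirmed marker: its top
#'   hit columns or NA, plus `mapped`), `n_mapped`, `n_confirmed`, and
#'   `mapped_fraction` (NA when no markers are confirmed).
#' @export
assign_to_chromosome <- function(confirmed, catalog, contigs,
                                 cfg = assign_config(), hits = NULL) {
  if (!length(contigs)) stopf("empty contig database")
  n_conf <- nrow(confirmed)
  if (n_conf == 0L)
    return(list(assignments = data.frame(), n_mapped = 0L,
                n_confirmed = 0L, mapped_fraction = NA_real_))
  ids <- as.character(confirmed$locus_id)
  if (is.null(hits))
    hits <- align_local(catalog[ids], contigs, max_evalue = 10)
  top <- top_hit_per_query(hits[hits$e_value <= cfg$evalue_max, ,
                                drop = FALSE])
  i <- match(ids, top$query_id)
  assignments <- data.frame(
    locus_id = confirmed$locus_id,
    mapped = !is.na(i),
    contig = top$subject_id[i],
    percent_identity = top$percent_identity[i],
    alignment_length = top$alignment_length[i],
    query_cover = top$query_cover[i],
    subject_start = top$subject_start[i],
    subject_end = top$subject_end[i],
    e_value = top$e_value[i],
    bit_score = top$bit_score[i])
  n_mapped <- sum(assignments$mapped)
  list(assignments = assignments, n_mapped = n_mapped,
       n_confirmed = n_conf, mapped_fraction = n_mapped / n_conf)
}

#' Annotate mapped markers against a local sequence database
#'
#' Aligns marker sequences against a user-supplied annotation FASTA (for
#' example, locally saved gene records) and reports the best hit per marker
#' per database subject at e-value <= `annotation_evalue_max`: query cover,
#' identity, e-value and 1-based subject coordinates.
#'
#' @param calls A `marker_calls` data frame (typically the mapped markers).
#' @param catalog Named character vector of catalog sequences.
#' @param annotation_db Named character vector of database sequences.
#' @param cfg An [assign_config()].
#' @return Data frame with one row per (marker, subject) best hit: locus id,
#'   marker length, subject id, `query_cover`, `e_value`,
#'   `percent_identity`, `subject_start`, `subject_end`.
#' @export
annotate_markers <- function(calls, catalog, annotation_db,
                             cfg = assign_config()) {
  empty <- data.frame(locus_id = integer(), length = integer(),
                      subject_id = character(), query_cover = numeric(),
                      e_value = numeric(), percent_identity = numeric(),
                      subject_start = integer(), subject_end = integer())
  if (!nrow(calls) || !length(annotation_db)) return(empty)
  ids <- as.character(calls$locus_id)
  hits <- align_local(catalog[ids], annotation_db,
                      max_evalue = cfg$annotation_evalue_max)
  if (!nrow(hits)) return(empty)
  key <- paste(hits$query_id, hits$subject_id)
  ord <- order(key, hits$e_value, -hits$bit_score)
  h <- hits[ord, , drop = FALSE]
  h <- h[!duplicated(key[ord]), , drop = FALSE]
  data.frame(locus_id = as.integer(h$query_id),
             length = nchar(catalog[h$query_id]),
             subject_id = h$subject_id,
             query_cover = h$query_cover,
             e_value = h$e_value,
             percent_identity = h$percent_identity,
             subject_start = h$subject_start,
             subject_end = h$subject_end,
             row.names = NULL)
}
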