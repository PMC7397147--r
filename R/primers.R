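# Wallace-rule melting temperature: 2(A+T) + 4(G+C) degrees C
wallace_tm <- function(primer) {
  b <- strsplit(toupper(primer), "", fixed = TRUE)[[1]]
  2 * sum(b %in% c("A", "T")) + 4 * sum(b %in% c("G", "C"))
}

empty_primer_df <- function() {
  data.frame(forward = character(), reverse = character(),
             design_type = character(), product_length = integer(),
             fwd_start = integer(), rev_end = integer(),
             tm_forward = numeric(), tm_reverse = numeric())
}

primer_pair_row <- function(forward, reverse, design_type, fwd_start,
                            rev_end) {
  data.frame(forward = forward, reverse = reverse,
             design_type = design_type,
             product_length = rev_end - fwd_start + 1L,
             fwd_start = fwd_start, rev_end = rev_end,
             tm_forward = wallace_tm(forward),
             tm_reverse = wallace_tm(reverse))
}

#' Design allele-specific primer pairs for a sex-linked marker
#'
#' Allele-specific primers restrict amplification to the
#' heterogametic-chromosome (Y) haplotype: each primer's 3'-terminal base is
#' the Y allele at a Y-specific SNP, so extension fails on the X haplotype.
#' The forward primer lies on the plus strand ending 3' on one Y-specific
#' column; the reverse primer is the reverse complement of the marker
#' starting at a second, downstream Y-specific column, its 3' base the
#' complement of that column's Y allele. With a single Y-specific SNP the
#' forward primer is allele-specific and the reverse primer is placed in
#' sequence conserved between the haplotypes.
#'
#' All positions are 0-based columns within the marker; products are
#' reported as 1-based spans. Melting temperatures use the Wallace rule,
#' 2(A+T) + 4(G+C).
#'
#' @param marker_seq Marker (tag) sequence, X haplotype as assembled.
#' @param y_snp_cols 0-based columns of Y-specific SNPs (at least one).
#' @param y_alleles Y allele at each column, parallel to `y_snp_cols`.
#' @param primer_length_range Allowed primer lengths (default 17-25).
#' @param product_length_range Allowed product sizes in bases
#'   (default 100-300).
#' @param tm_range Acceptable Wallace Tm per primer (default 40-70).
#' @return Data frame of candidate pairs: `forward`, `reverse`,
#'   `design_type`, `product_length`, marker-coordinate anchors and per
#'   primer Tm. Errors when no Y-specific SNP is given.
#' @export
design_allele_specific <- function(marker_seq, y_snp_cols, y_alleles,
                                   primer_length_range = c(17L, 25L),
                                   product_length_range = c(100L, 300L),
                                   tm_range = c(40, 70)) {
  if (!length(y_snp_cols)) stopf("no Y-specific SNP columns supplied")
  if (length(y_alleles) != length(y_snp_cols))
    stopf("y_alleles must parallel y_snp_cols")
  n <- nchar(marker_seq)
  ord <- order(y_snp_cols)
  y_snp_cols <- y_snp_cols[ord]; y_alleles <- y_alleles[ord]
  y_seq <- marker_seq
  for (k in seq_along(y_snp_cols))
    substr(y_seq, y_snp_cols[k] + 1L, y_snp_cols[k] + 1L) <- y_alleles[k]

  lens <- seq(primer_length_range[1], primer_length_range[2])
  pairs <- list()

  fwd_at <- function(col) {
    p3 <- col + 1L  # 1-based 3' anchor
    for (L in lens) {
      if (p3 - L + 1L < 1L) next
      pr <- substr(y_seq, p3 - L + 1L, p3)
      tm <- wallace_tm(pr)
      if (tm >= tm_range[1] && tm <= tm_range[2])
        return(list(seq = pr, start = p3 - L + 1L, end = p3))
    }
    NULL
  }
  rev_at <- function(col) {
    a <- col + 1L  # footprint starts at the SNP; primer 3' base pairs here
    for (L in lens) {
      if (a + L - 1L > n) next
      pr <- revcomp(substr(y_seq, a, a + L - 1L))
      tm <- wallace_tm(pr)
      if (tm >= tm_range[1] && tm <= tm_range[2])
        return(list(seq = pr, start = a, end = a + L - 1L))
    }
    NULL
  }

  if (length(y_snp_cols) >= 2L) {
    combos <- utils::combn(seq_along(y_snp_cols), 2L)
    for (k in seq_len(ncol(combos))) {
      f <- fwd_at(y_snp_cols[combos[1, k]])
      r <- rev_at(y_snp_cols[combos[2, k]])
      if (is.null(f) || is.null(r)) next
      plen <- r$end - f$start + 1L
      if (plen < product_length_range[1] || plen > product_length_range[2])
        next
      if (r$start <= f$end) next  # primers must not overlap
      pairs[[length(pairs) + 1L]] <-
        primer_pair_row(f$seq, r$seq, "ALLELE_SPECIFIC", f$start, r$end)
    }
  }
  if (!length(pairs)) {
    # single usable Y-SNP: allele-specific forward, conserved reverse
    for (ci in seq_along(y_snp_cols)) {
      f <- fwd_at(y_snp_cols[ci])
      if (is.null(f)) next
      for (from in seq(f$end + 1L, n)) {
        r <- conserved_window(y_seq, y_snp_cols, lens, tm_range,
                              from = from, n = n, reverse = TRUE)
        if (is.null(r)) break
        plen <- r$end - f$start + 1L
        if (plen > product_length_range[2]) break
        if (plen >= product_length_range[1]) {
          pairs[[length(pairs) + 1L]] <-
            primer_pair_row(f$seq, r$seq, "ALLELE_SPECIFIC", f$start, r$end)
          break
        }
      }
      if (length(pairs)) break
    }
  }
  if (!length(pairs)) return(empty_primer_df())
  do.call(rbind, pairs)
}

# first primer window in [from, n] avoiding all SNP columns and meeting Tm;
# reverse = TRUE returns the reverse complement primer for that window
conserved_window <- function(seqv, snp_cols, lens, tm_range, from, n,
                             reverse = FALSE) {
  snp_pos <- snp_cols + 1L
  for (a in seq(max(1L, from), n)) {
    for (L in lens) {
      b <- a + L - 1L
      if (b > n) next
      if (any(snp_pos >= a & snp_pos <= b)) next
      pr <- substr(seqv, a, b)
      if (reverse) pr <- revcomp(pr)
      tm <- wallace_tm(pr)
      if (tm >= tm_range[1] && tm <= tm_range[2])
        return(list(seq = pr, start = a, end = b))
    }
  }
  NULL
}

#' Design conserved primer pairs flanking a sex-linked SNP
#'
#' Both primers sit in sequence shared by the X and Y haplotypes (no SNP
#' column inside either primer), so the pair amplifies in both sexes; the
#' product contains at least one SNP column, so sequencing the amplicon
#' reveals heterozygosity in the heterogametic sex.
#'
#' @inheritParams design_allele_specific
#' @param snp_cols 0-based columns of all SNPs on the marker.
#' @return Data frame as in [design_allele_specific()] with `design_type`
#'   `"CONSERVED"`; zero rows when no valid pair exists.
#' @export
design_conserved <- function(marker_seq, snp_cols,
                             primer_length_range = c(17L, 25L),
                             product_length_range = c(100L, 300L),
                             tm_range = c(40, 70)) {
  if (!length(snp_cols)) stopf("no SNP columns supplied")
  n <- nchar(marker_seq)
  lens <- seq(primer_length_range[1], primer_length_range[2])
  snp_pos <- sort(snp_cols) + 1L
  pairs <- list()
  f <- conserved_window(marker_seq, snp_cols, lens, tm_range, from = 1L,
                        n = min(n, snp_pos[1] - 1L))
  if (!is.null(f) && f$end < snp_pos[1]) {
    for (a in seq(snp_pos[length(snp_pos)] + 1L, n)) {
      r <- conserved_window(marker_seq, snp_cols, lens, tm_range,
                            from = a, n = n, reverse = TRUE)
      if (is.null(r)) break
      plen <- r$end - f$start + 1L
      if (plen >= product_length_range[1] &&
          plen <= product_length_range[2] &&
          any(snp_pos > f$end & snp_pos < r$start)) {
        pairs[[length(pairs) + 1L]] <-
          primer_pair_row(f$seq, r$seq, "CONSERVED", f$start, r$end)
        break
      }
      if (plen > product_length_range[2]) break
    }
  }
  if (!length(pairs)) return(empty_primer_df())
  do.call(rbind, pairs)
}

#' Suggest primers for a set of confirmed markers
#'
#' For SNP-bearing markers, designs conserved pairs (and allele-specific
#' pairs when Y alleles are supplied); returns a long table across markers.
#'
#' @param confirmed A `marker_calls` data frame.
#' @param catalog Named character vector of catalog sequences.
#' @param snp_meta Data frame with `locus_id`, `col`, `x_allele`, `y_allele`
#'   describing SNP columns per marker.
#' @param type `"allele_specific"` or `"conserved"`.
#' @param ... Passed to the designers.
#' @return Data frame of primer pairs with a `locus_id` column.
#' @export
design_primers <- function(confirmed, catalog, snp_meta,
                           type = c("conserved", "allele_specific"), ...) {
  type <- match.arg(type)
  out <- list()
  for (i in seq_len(nrow(confirmed))) {
    id <- confirmed$locus_id[i]
    meta <- snp_meta[snp_meta$locus_id == id, , drop = FALSE]
    if (!nrow(meta)) next
    seqv <- catalog[[as.character(id)]]
    pp <- if (type == "allele_specific")
      design_allele_specific(seqv, meta$col, meta$y_allele, ...)
    else design_conserved(seqv, meta$col, ...)
    if (nrow(pp)) out[[length(out) + 1L]] <- cbind(locus_id = id, pp)
  }
  if (!length(out)) return(data.frame())
  do.call(rbind, out)
}
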