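# Karlin-Altschul parameters for +1/-2 nucleotide scoring (ungapped);
# e-values on synthetic data need ordering correctness, not NCBI bit-exactness
KA_LAMBDA <- 1.28
KA_K <- 0.46
MATCH_SCORE <- 1L
MISMATCH_SCORE <- -2L

#' Count exact occurrences of tag sequences in raw reads
#'
#' Exact substring search of each tag in a pool of reads, the computational
#' form of grepping candidate tags in the opposite sex's read files. By
#' default both strands are searched (reads may derive from either strand);
#' `search_revcomp = FALSE` restricts to the forward strand, reproducing a
#' plain grep.
#'
#' @param tag_seqs Named character vector of tag sequences.
#' @param reads Character vector of read sequences.
#' @param search_revcomp Also search the reverse complement of each tag.
#' @return Named integer vector of occurrence counts, one per tag.
#' @export
find_in_reads <- function(tag_seqs, reads, search_revcomp = TRUE) {
  if (!length(tag_seqs)) return(setNames(integer(0), character(0)))
  out <- setNames(integer(length(tag_seqs)), names(tag_seqs))
  if (!length(reads)) return(out)
  subject <- Biostrings::DNAStringSet(toupper(reads))
  for (i in seq_along(tag_seqs)) {
    pat <- Biostrings::DNAString(tag_seqs[[i]])
    n <- sum(Biostrings::vcountPattern(pat, subject, fixed = TRUE))
    if (search_revcomp)
      n <- n + sum(Biostrings::vcountPattern(
        Biostrings::reverseComplement(pat), subject, fixed = TRUE))
    out[i] <- n
  }
  out
}

#' @rdname find_in_reads
#' @param paths FASTA/FASTQ file paths (`.fq`/`.fastq` parsed as FASTQ).
#' @export
find_in_read_files <- function(tag_seqs, paths, search_revcomp = TRUE) {
  reads <- unlist(lapply(paths, function(p) {
    if (!file.exists(p)) stopf("read file not found: %s", p)
    if (grepl("\\.(fq|fastq)(\\.gz)?$", p)) read_fastq(p) else read_fasta(p)
  }))
  find_in_reads(tag_seqs, reads, search_revcomp = search_revcomp)
}

empty_hits <- function() {
  data.frame(query_id = character(), subject_id = character(),
             percent_identity = numeric(), alignment_length = integer(),
             query_cover = numeric(), q_start = integer(), q_end = integer(),
             subject_start = integer(), subject_end = integer(),
             strand = character(), e_value = numeric(),
             bit_score = numeric())
}

# best-scoring segment on one diagonal: Kadane's max subarray over
# +1 match / -2 mismatch, returning (start, end, score, matches)
best_segment <- function(is_match) {
  sc <- ifelse(is_match, MATCH_SCORE, MISMATCH_SCORE)
  best <- 0; best_a <- 0L; best_b <- -1L
  cur <- 0; cur_a <- 1L
  for (i in seq_along(sc)) {
    if (cur <= 0) { cur <- 0; cur_a <- i }
    cur <- cur + sc[i]
    if (cur > best) { best <- cur; best_a <- cur_a; best_b <- i }
  }
  if (best_b < best_a) return(NULL)
  list(a = best_a, b = best_b, score = best,
       matches = sum(is_match[best_a:best_b]))
}

# k-mer index over a set of subjects: environment mapping each word to
# encoded (subject, position) values
build_kmer_index <- function(subjects, word_size) {
  env <- new.env(hash = TRUE, parent = emptyenv())
  OFF <- 2^32
  for (si in seq_along(subjects)) {
    s <- subjects[[si]]
    n <- nchar(s)
    if (n < word_size) next
    starts <- seq_len(n - word_size + 1L)
    words <- substring(s, starts, starts + word_size - 1L)
    keep <- !grepl("N", words, fixed = TRUE)
    codes <- si * OFF + starts
    tab <- split(codes[keep], words[keep])
    for (w in names(tab)) {
      prev <- env[[w]]
      env[[w]] <- if (is.null(prev)) tab[[w]] else c(prev, tab[[w]])
    }
  }
  env
}

align_one_strand <- function(qseq, qid, qlen_orig, strand, index, subjects,
                             subject_names, db_len, word_size, min_score) {
  qn <- nchar(qseq)
  if (qn < word_size) return(NULL)
  OFF <- 2^32
  starts <- seq_len(qn - word_size + 1L)
  words <- substring(qseq, starts, starts + word_size - 1L)
  hit_codes <- lapply(seq_along(words), function(i) {
    v <- index[[words[i]]]
    if (is.null(v)) NULL else v - starts[i]  # subject*OFF + (spos - qpos)
  })
  diags <- unique(unlist(hit_codes))
  if (!length(diags)) return(NULL)
  qchars <- strsplit(qseq, "", fixed = TRUE)[[1]]
  rows <- list()
  for (dc in diags) {
    si <- floor(dc / OFF + 0.5)  # diag offset may be negative within subject
    d <- dc - si * OFF
    slen <- nchar(subjects[[si]])
    q_from <- max(1L, 1L - d)
    q_to <- min(qn, slen - d)
    if (q_to - q_from + 1L < word_size) next
    sseg <- strsplit(substr(subjects[[si]], q_from + d, q_to + d), "",
                     fixed = TRUE)[[1]]
    seg <- best_segment(qchars[q_from:q_to] == sseg)
    if (is.null(seg) || seg$score < min_score) next
    qa <- q_from + seg$a - 1L; qb <- q_from + seg$b - 1L
    len <- qb - qa + 1L
    bit <- (KA_LAMBDA * seg$score - log(KA_K)) / log(2)
    ev <- qlen_orig * db_len * 2^(-bit)
    # map reverse-strand query coordinates back to the original query
    if (strand == "-") {
      qa_o <- qlen_orig - qb + 1L; qb_o <- qlen_orig - qa + 1L
    } else {
      qa_o <- qa; qb_o <- qb
    }
    rows[[length(rows) + 1L]] <- data.frame(
      query_id = qid, subject_id = subject_names[si],
      percent_identity = 100 * seg$matches / len,
      alignment_length = len,
      query_cover = len / qlen_orig,
      q_start = qa_o, q_end = qb_o,
      subject_start = qa + d, subject_end = qb + d,
      strand = strand, e_value = ev, bit_score = bit)
  }
  if (length(rows)) do.call(rbind, rows) else NULL
}

#' Local alignment of queries against a sequence database
#'
#' A seeded ungapped local aligner: exact k-mer seeding (default word size
#' 11), per-diagonal ungapped extension to the optimal-scoring segment
#' (+1 match / -2 mismatch), and Karlin–Altschul e-values with standard
#' ungapped nucleotide parameters. The effective search space is query
#' length times total database length. Both strands are searched; hits on
#' the minus strand carry `strand == "-"` with subject coordinates
#' normalized so `subject_start <= subject_end` (1-based inclusive).
#'
#' @param queries Named character vector of query sequences (non-empty).
#' @param subjects Named character vector of database sequences (non-empty).
#' @param max_evalue Report hits with e-value at or below this (default 10).
#' @param word_size Seed length in bases.
#' @param both_strands Search the reverse complement of each query too.
#' @return A data frame of alignment hits, sorted by ascending e-value then
#'   descending bit score: `query_id`, `subject_id`, `percent_identity`,
#'   `alignment_length`, `query_cover`, `q_start`, `q_end`, `subject_start`,
#'   `subject_end`, `strand`, `e_value`, `bit_score`.
#' @export
align_local <- function(queries, subjects, max_evalue = 10,
                        word_size = 11L, both_strands = TRUE) {
  if (!length(queries) || any(!nzchar(queries)))
    stopf("empty query set or empty query sequence")
  if (!length(subjects)) stopf("empty subject database")
  if (is.null(names(queries)))
    names(queries) <- sprintf("query_%d", seq_along(queries))
  if (is.null(names(subjects)))
    names(subjects) <- sprintf("subject_%d", seq_along(subjects))
  queries <- toupper(queries); subjects <- toupper(subjects)
  db_len <- sum(nchar(subjects))
  index <- build_kmer_index(subjects, word_size)
  min_score <- word_size  # a bare seed is the weakest reportable segment
  out <- list()
  for (qi in seq_along(queries)) {
    qid <- names(queries)[qi]
    qseq <- queries[[qi]]
    qlen <- nchar(qseq)
    h <- align_one_strand(qseq, qid, qlen, "+", index, subjects,
                          names(subjects), db_len, word_size, min_score)
    if (both_strands) {
      h <- rbind(h, align_one_strand(revcomp(qseq), qid, qlen, "-", index,
                                     subjects, names(subjects), db_len,
                                     word_size, min_score))
    }
    if (!is.null(h)) out[[length(out) + 1L]] <- h
  }
  hits <- if (length(out)) do.call(rbind, out) else empty_hits()
  hits <- hits[hits$e_value <= max_evalue, , drop = FALSE]
  hits <- unique(hits)
  hits <- hits[order(hits$e_value, -hits$bit_score, hits$query_id,
                     hits$subject_id), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Read and write 12-column tabular alignment files
#'
#' The 12-column tabular dialect (query id, subject id, percent identity,
#' alignment length, mismatches, gap opens, query start/end, subject
#' start/end, e-value, bit score). On reading, minus-strand hits (subject
#' start greater than end) are normalized to `subject_start <= subject_end`
#' with `strand == "-"`. `query_cover` requires query lengths; pass them via
#' `query_lengths` or it is `NA`.
#'
#' @param path File path.
#' @param query_lengths Optional named vector of query lengths.
#' @return `read_blast_tab()` returns an alignment-hit data frame as in
#'   [align_local()].
#' @export
read_blast_tab <- function(path, query_lengths = NULL) {
  if (!file.exists(path)) stopf("alignment table not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) return(empty_hits())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 12L))
    stopf("malformed tabular alignment row (expected 12 columns) at line %d",
          which(lengths(parts) != 12L)[1])
  m <- do.call(rbind, parts)
  sstart <- as.integer(m[, 9]); send <- as.integer(m[, 10])
  minus <- sstart > send
  qlen <- if (is.null(query_lengths)) NA_real_ else
    as.numeric(query_lengths[m[, 1]])
  len <- as.integer(m[, 4])
  out <- data.frame(
    query_id = m[, 1], subject_id = m[, 2],
    percent_identity = as.numeric(m[, 3]),
    alignment_length = len,
    query_cover = len / qlen,
    q_start = as.integer(m[, 7]), q_end = as.integer(m[, 8]),
    subject_start = ifelse(minus, send, sstart),
    subject_end = ifelse(minus, sstart, send),
    strand = ifelse(minus, "-", "+"),
    e_value = as.numeric(m[, 11]), bit_score = as.numeric(m[, 12]))
  if (anyNA(out$e_value) || anyNA(out$subject_start))
    stopf("malformed numeric field in %s", path)
  out
}

#' @rdname read_blast_tab
#' @param hits An alignment-hit data frame.
#' @export
write_blast_tab <- function(hits, path) {
  minus <- hits$strand == "-"
  tab <- data.frame(
    hits$query_id, hits$subject_id,
    sprintf("%.3f", hits$percent_identity), hits$alignment_length,
    as.integer(round(hits$alignment_length *
                       (1 - hits$percent_identity / 100))),
    0L, hits$q_start, hits$q_end,
    ifelse(minus, hits$subject_end, hits$subject_start),
    ifelse(minus, hits$subject_start, hits$subject_end),
    format(hits$e_value, digits = 3, scientific = TRUE),
    sprintf("%.1f", hits$bit_score))
  write.table(tab, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
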