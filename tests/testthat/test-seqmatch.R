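test_that("read search counts exact occurrences on both strands", {
  withr::with_seed(101, {
    tag <- random_dna_str(60)
    reads <- c(random_dna_str(100), paste0(random_dna_str(20), tag,
                                           random_dna_str(20)),
               random_dna_str(100))
    rc <- paste(rev(chartr("ACGT", "TGCA", strsplit(tag, "")[[1]])),
                collapse = "")
    counts <- find_in_reads(c(t1 = tag), reads)
    expect_equal(unname(counts), 1L)
    expect_equal(unname(find_in_reads(c(t2 = random_dna_str(60)), reads)), 0L)
    # reverse complement only
    reads_rc <- c(reads[1], paste0("AC", rc, "GT"))
    expect_equal(unname(find_in_reads(c(t1 = tag), reads_rc,
                                      search_revcomp = FALSE)), 0L)
    expect_equal(unname(find_in_reads(c(t1 = tag), reads_rc,
                                      search_revcomp = TRUE)), 1L)
  })
})

test_that("read search equals a naive regex scan on random fixtures", {
  withr::with_seed(102, {
    for (k in 1:5) {
      tags <- setNames(vapply(1:4, function(i) random_dna_str(30), ""),
                       sprintf("t%d", 1:4))
      reads <- vapply(1:30, function(i) random_dna_str(80), "")
      # embed some tags, sometimes twice in one read
      reads[1] <- paste0(tags[1], reads[1])
      reads[2] <- paste0(tags[2], tags[2])
      got <- find_in_reads(tags, reads)
      want <- vapply(tags, naive_count, 0L, reads = reads)
      expect_equal(unname(got), unname(want))
    }
  })
})

test_that("read-file search parses FASTA and FASTQ and names missing files", {
  withr::with_seed(103, {
    tag <- c(t1 = random_dna_str(40))
    d <- withr::local_tempdir()
    write_fastq(c(r1 = paste0("AA", tag, "CC")), file.path(d, "a.fq"))
    write_fasta(c(r2 = random_dna_str(80)), file.path(d, "b.fa"))
    got <- find_in_read_files(tag, file.path(d, c("a.fq", "b.fa")))
    expect_equal(unname(got), 1L)
    expect_error(find_in_read_files(tag, file.path(d, "absent.fq")),
                 "absent.fq")
  })
})

test_that("a perfect substring query yields one full-identity hit", {
  withr::with_seed(110, {
    genome <- c(chr1 = random_dna_str(3000))
    q <- substr(genome[[1]], 501, 724)
    hits <- align_local(c(tag = q), genome)
    best <- hits[1, ]
    expect_equal(best$percent_identity, 100)
    expect_equal(best$query_cover, 1.0)
    expect_equal(best$alignment_length, 224L)
    expect_equal(best$subject_start, 501L)
    expect_equal(best$subject_end, 724L)
    expect_lt(best$e_value, 1e-20)
  })
})

test_that("random queries find no significant hit in an unrelated database", {
  withr::with_seed(111, {
    genome <- c(chr1 = random_dna_str(5000))
    for (k in 1:5) {
      hits <- align_local(c(q = random_dna_str(224)), genome)
      expect_equal(nrow(hits[hits$e_value <= 1e-20, ]), 0L)
    }
  })
})

test_that("identical subjects yield hits of equal bit score", {
  withr::with_seed(112, {
    s <- random_dna_str(400)
    q <- substr(s, 100, 250)
    hits <- align_local(c(q = q), c(a = s, b = s))
    sig <- hits[hits$percent_identity == 100, ]
    expect_equal(nrow(sig), 2L)
    expect_equal(sig$bit_score[1], sig$bit_score[2])
    expect_setequal(sig$subject_id, c("a", "b"))
  })
})

test_that("reverse-complement queries are found with normalized coordinates", {
  withr::with_seed(113, {
    genome <- c(chr1 = random_dna_str(2000))
    fwd <- substr(genome[[1]], 301, 500)
    rc <- paste(rev(chartr("ACGT", "TGCA", strsplit(fwd, "")[[1]])),
                collapse = "")
    hits <- align_local(c(q = rc), genome)
    best <- hits[1, ]
    expect_equal(best$strand, "-")
    expect_equal(best$subject_start, 301L)
    expect_equal(best$subject_end, 500L)
    expect_lte(best$subject_start, best$subject_end)
  })
})

test_that("segment scores agree with a Smith-Waterman oracle", {
  withr::with_seed(114, {
    for (k in 1:8) {
      subject <- random_dna_str(500)
      core <- substr(subject, 101, 340)
      n_mut <- sample(0:8, 1)
      query <- if (n_mut > 0)
        mutate_positions(core, sample(20:220, n_mut)) else core
      hits <- align_local(c(q = query), c(s = subject),
                          both_strands = FALSE)
      expect_gt(nrow(hits), 0L)
      best <- hits[1, ]
      impl_score <- best$percent_identity / 100 * best$alignment_length *
        1 - (1 - best$percent_identity / 100) * best$alignment_length * 2
      expect_equal(round(impl_score), sw_score(query, subject))
    }
  })
})

test_that("aligner rejects degenerate input", {
  expect_error(align_local(character(0), c(s = "ACGT")), "empty query")
  expect_error(align_local(c(q = ""), c(s = "ACGT")), "empty query")
  expect_error(align_local(c(q = "ACGTACGTACGT"), character(0)),
               "empty subject")
})

test_that("tabular alignment files round-trip with strand normalization", {
  withr::with_seed(120, {
    genome <- c(chr1 = random_dna_str(1500))
    q1 <- substr(genome[[1]], 201, 380)
    rc <- paste(rev(chartr("ACGT", "TGCA", strsplit(q1, "")[[1]])),
                collapse = "")
    hits <- align_local(c(plus = q1, minus = rc), genome)
    f <- withr::local_tempfile(fileext = ".tsv")
    write_blast_tab(hits, f)
    back <- read_blast_tab(f, query_lengths = c(plus = 180, minus = 180))
    expect_equal(nrow(back), nrow(hits))
    expect_true(all(back$subject_start <= back$subject_end))
    i <- which(back$query_id == "minus")[1]
    expect_equal(back$strand[i], "-")
    expect_equal(back$subject_start[i], 201L)
    # empty file
    writeLines(character(0), f)
    expect_equal(nrow(read_blast_tab(f)), 0L)
    # wrong column count
    writeLines("a\tb\tc", f)
    expect_error(read_blast_tab(f), "12 columns")
  })
})
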