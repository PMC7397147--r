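make_limited_calls <- function(ids, system = "XY") {
  calls <- data.frame(locus_id = ids, snp_col = NA_integer_,
                      system = system, approaches = "LIMITED",
                      status = "PUTATIVE", removal_reason = NA_character_,
                      conflict = FALSE)
  class(calls) <- c("marker_calls", "data.frame")
  calls
}

test_that("opposite-sex read filter removes exactly the planted tags", {
  withr::with_seed(201, {
    catalog <- setNames(vapply(1:6, function(i) random_dna_str(120), ""),
                        as.character(1:6))
    calls <- make_limited_calls(1:6)
    reads_F <- c(catalog[["2"]],                      # verbatim
                 paste0("AATT", catalog[["5"]], "GG"),  # embedded
                 random_dna_str(200))
    out <- filter_opposite_sex_reads(calls, catalog,
                                     list(M = character(0), F = reads_F))
    expect_setequal(out$removed$locus_id, c(2L, 5L))
    expect_setequal(out$retained$locus_id, c(1L, 3L, 4L, 6L))
    expect_equal(out$stage[[1]]$n_in, 6L)
    # no reads at all: everything retained
    out2 <- filter_opposite_sex_reads(calls, catalog,
                                      list(M = character(0),
                                           F = character(0)))
    expect_equal(nrow(out2$retained), 6L)
    # every tag planted: everything removed
    out3 <- filter_opposite_sex_reads(calls, catalog,
                                      list(M = character(0),
                                           F = unname(catalog)))
    expect_equal(nrow(out3$retained), 0L)
    # female-limited candidates are searched in male reads
    callsZ <- make_limited_calls(1:2, system = "ZW")
    outZ <- filter_opposite_sex_reads(callsZ, catalog,
                                      list(M = catalog[["1"]],
                                           F = character(0)))
    expect_equal(outZ$removed$locus_id, 1L)
  })
})

test_that("multi-hit genome filter removes only repeated tags", {
  withr::with_seed(202, {
    catalog <- setNames(vapply(1:4, function(i) random_dna_str(150), ""),
                        as.character(1:4))
    flank <- function(s) paste0(random_dna_str(40), s, random_dna_str(40))
    genome <- c(g1 = flank(catalog[["1"]]),          # single perfect hit
                g2a = flank(catalog[["2"]]),         # two near-perfect hits
                g2b = flank(mutate_positions(catalog[["2"]], 10)),
                g4 = flank(mutate_positions(catalog[["4"]],
                                            seq(5, 145, by = 10))))
    calls <- make_limited_calls(1:4)
    out <- filter_genome_limited(calls, catalog, genome)
    # tag 2 repeated at >= 99% identity: removed; single (1), absent (3)
    # and low-identity (4) retained
    expect_equal(out$removed$locus_id, 2L)
    expect_setequal(out$retained$locus_id, c(1L, 3L, 4L))
  })
})

test_that("genome-consistency filter checks the homogametic allele", {
  withr::with_seed(203, {
    tags <- vapply(1:3, function(i) random_dna_str(150), "")
    col <- 60L
    x_al <- substr(tags, col + 1L, col + 1L)
    y_al <- vapply(x_al, function(a)
      sample(setdiff(c("A", "C", "G", "T"), a), 1), "")
    catalog <- setNames(tags, as.character(1:3))
    with_y <- tags[2]
    substr(with_y, col + 1L, col + 1L) <- y_al[2]
    flank <- function(s) paste0(random_dna_str(40), s, random_dna_str(40))
    genome <- c(gc = flank(tags[1]),   # consistent: consensus embedded
                gi = flank(with_y))    # inconsistent: Y allele at the column
    calls <- data.frame(locus_id = 1:3, snp_col = col, system = "XY",
                        approaches = "HET", status = "PUTATIVE",
                        removal_reason = NA_character_, conflict = FALSE)
    class(calls) <- c("marker_calls", "data.frame")
    out <- filter_genome_snp(calls, catalog, genome)
    expect_equal(out$retained$locus_id, 1L)
    expect_setequal(out$removed$locus_id, c(2L, 3L))
    reasons <- setNames(out$removed$detail, out$removed$locus_id)
    expect_match(reasons[["3"]], "no significant")
    expect_match(reasons[["2"]], "!=")
  })
})

test_that("minus-strand genome hits are checked with complemented alleles", {
  withr::with_seed(204, {
    tag <- random_dna_str(150)
    col <- 60L
    rc <- paste(rev(chartr("ACGT", "TGCA", strsplit(tag, "")[[1]])),
                collapse = "")
    genome <- c(g = paste0(random_dna_str(30), rc, random_dna_str(30)))
    calls <- data.frame(locus_id = 1L, snp_col = col, system = "XY",
                        approaches = "HET", status = "PUTATIVE",
                        removal_reason = NA_character_, conflict = FALSE)
    class(calls) <- c("marker_calls", "data.frame")
    out <- filter_genome_snp(calls, setNames(tag, "1"), genome)
    expect_equal(out$retained$locus_id, 1L)
  })
})

test_that("duplicate collapse groups transitively and picks the longest", {
  withr::with_seed(205, {
    a <- random_dna_str(224)
    b <- mutate_positions(a, sample(10:214, 8))   # ~96% identical to a
    cc <- mutate_positions(b, sample(10:214, 8))  # ~96% to b, ~93% to a
    solo <- random_dna_str(224)
    catalog <- c("10" = a, "20" = b, "30" = cc, "40" = solo)
    calls <- make_limited_calls(c(10L, 20L, 30L, 40L))
    out <- collapse_duplicates(calls, catalog)
    # transitive closure: {10, 20, 30} is one group; equal lengths, so the
    # lowest id represents it
    expect_setequal(out$retained$locus_id, c(10L, 40L))
    # longest member wins over lower id
    catalog2 <- catalog
    catalog2[["30"]] <- paste0(cc, random_dna_str(40))
    out2 <- collapse_duplicates(calls, catalog2)
    expect_setequal(out2$retained$locus_id, c(30L, 40L))
    # all distinct: identity operation
    cat3 <- setNames(vapply(1:4, function(i) random_dna_str(224), ""),
                     c("10", "20", "30", "40"))
    out3 <- collapse_duplicates(calls, cat3)
    expect_equal(nrow(out3$retained), 4L)
    # idempotence
    again <- collapse_duplicates(out$retained, catalog)
    expect_equal(again$retained$locus_id, out$retained$locus_id)
    expect_equal(nrow(again$removed), 0L)
  })
})

test_that("ledger stages conserve counts and chain across stages", {
  s1 <- ledger_stage("a", "x", 1:10, 1:7,
                     data.frame(locus_id = 8:10, reason = "r",
                                detail = ""))
  s2 <- ledger_stage("b", "x", 1:7, 1:7,
                     data.frame(locus_id = integer(), reason = character(),
                                detail = character()))
  expect_true(ledger_check(ledger_concat(s1, s2)))
  # conservation violation inside a stage
  expect_error(ledger_stage("bad", "x", 1:10, 1:5,
                            data.frame(locus_id = 8:10, reason = "r",
                                       detail = "")),
               "conservation")
  # chaining violation across stages
  s3 <- ledger_stage("c", "x", 1:6, 1:6,
                     data.frame(locus_id = integer(), reason = character(),
                                detail = character()))
  expect_error(ledger_check(ledger_concat(s1, s3)), "chaining")
})

test_that("the full cascade is deterministic and conserves every candidate", {
  fx <- simulate_cascade_fixture(n_male_limited = 12L, n_planted = 3L,
                                 n_multihit = 2L,
                                 limited_dup_pairs = list(c(501L, 502L)),
                                 longer_members = integer(0),
                                 n_female_limited = 2L,
                                 n_snp = 10L, n_snp_unaligned = 3L,
                                 n_snp_inconsistent = 2L,
                                 snp_dup_pairs = list(c(101L, 102L)),
                                 n_freq_tags = 4L, n_overlap_tags = 2L,
                                 n_mapped = 5L, seed = 77L)
  v1 <- run_validation(fx$calls, fx$catalog, fx$reads_by_sex, fx$genome)
  v2 <- run_validation(fx$calls, fx$catalog, fx$reads_by_sex, fx$genome)
  expect_identical(v1$confirmed, v2$confirmed)
  expect_true(ledger_check(v1$ledger))
  # every candidate is accounted for: confirmed + removed = putative in
  expect_equal(nrow(v1$confirmed) +
                 sum(v1$calls$status == "REMOVED"), nrow(fx$calls))
  # survivors equal the construction's arithmetic
  expect_setequal(v1$confirmed$locus_id, fx$surviving_ids)
  # planted contaminants are all removed with the read-filter reason
  st <- v1$calls[v1$calls$locus_id %in% fx$planted_ids, ]
  expect_true(all(st$status == "REMOVED"))
  expect_true(all(st$removal_reason == "OPPOSITE_SEX_READS"))
})

test_that("unplanted hemizygous tags survive an error-free cascade", {
  b <- simulate_panel(small_params(seed = 209L))
  res <- run_all(b)
  hemi <- b$truth$locus_id[b$truth$category == "HEMIZYGOUS_TAG"]
  conf <- res$validation$confirmed
  expect_true(all(hemi %in% conf$locus_id))
})
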