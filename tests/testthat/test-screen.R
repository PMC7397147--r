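test_that("allele-frequency screen matches its defining inequalities", {
  cfg <- screen_config()
  # canonical X-fixed / Y-divergent pattern: females 1.0, males 0.5
  r <- record_from_counts(0, 21, 0, 19, 0, 0)
  expect_equal(screen_allele_freq(r, cfg)$system, "XY")
  # flat frequencies: no call
  r <- record_from_counts(5, 10, 6, 5, 9, 5)
  expect_true(is.na(screen_allele_freq(r, cfg)$system))
  # boundary: female frequency exactly 0.95, difference exactly 0.45
  r <- record_from_counts(0, 20, 0, 18, 2, 0)  # F: p = 38/40 = 0.95, M: 0.5
  expect_equal(record_from_counts(0, 20, 0, 18, 2, 0)$p_count_F, 38L)
  expect_equal(screen_allele_freq(r, cfg)$system, "XY")
  # just under the difference threshold: no call
  r <- record_from_counts(4, 16, 1, 19, 0, 0)  # M: p = 24/42, diff 0.43
  expect_true(is.na(screen_allele_freq(r, cfg)$system))
})

test_that("heterozygosity screen matches its defining inequalities", {
  cfg <- screen_config()
  # ideal pattern: all females homozygous, all males heterozygous
  r <- record_from_counts(0, 21, 0, 19, 0, 0)
  expect_equal(screen_heterozygosity(r, cfg)$system, "XY")
  # everyone homozygous: no call
  r <- record_from_counts(21, 0, 0, 19, 0, 0)
  expect_true(is.na(screen_heterozygosity(r, cfg)$system))
  # permissive literal reading: 10/19 females homozygous, 11/21 males het
  loose <- screen_config(hom_female_fraction_min = 0.5)
  r <- record_from_counts(10, 11, 0, 10, 9, 0)
  expect_equal(screen_heterozygosity(r, loose)$system, "XY")
  # one heterozygous female blocks the strict default
  r <- record_from_counts(0, 21, 0, 18, 1, 0)
  expect_true(is.na(screen_heterozygosity(r, cfg)$system))
  expect_equal(screen_heterozygosity(r, loose)$system, "XY")
})

test_that("sex-limited screen applies the literal at-least-half rule", {
  panel <- sexed_panel(c(sprintf("m%d", 1:21), sprintf("f%d", 1:19)),
                       c(rep("M", 21), rep("F", 19)))
  males <- panel_samples(panel, "M")
  occ_n <- function(n_m) {
    tag_occupancy(c(rep(1L, n_m), rep(2L, 40)),
                  c(males[seq_len(n_m)], panel$sample_ids), panel)
  }
  # present in all males, absent in females
  out <- screen_sex_limited(occ_n(21L), panel)
  expect_equal(out$system[out$locus_id == 1L], "XY")
  # present everywhere: never flagged
  expect_false(2L %in% out$locus_id)
  # 10/21 males fails, 11/21 passes
  expect_false(1L %in% screen_sex_limited(occ_n(10L), panel)$locus_id)
  expect_true(1L %in% screen_sex_limited(occ_n(11L), panel)$locus_id)
})

test_that("screen decisions equal exhaustive oracle on tiny panels", {
  # all genotype-count configurations for 2 males and 2 females
  grid <- expand.grid(mPP = 0:2, mPQ = 0:2, mQQ = 0:2,
                      fPP = 0:2, fPQ = 0:2, fQQ = 0:2)
  grid <- grid[rowSums(grid[, 1:3]) <= 2 & rowSums(grid[, 4:6]) <= 2, ]
  for (i in seq_len(nrow(grid))) {
    g <- as.list(grid[i, ])
    r <- do.call(record_from_counts, g)
    want_f <- do.call(oracle_freq, g)
    got_f <- screen_allele_freq(r)
    got_f <- if (isTRUE(got_f$ambiguous)) "AMBIG" else got_f$system
    expect_identical(got_f, want_f)
    want_h <- do.call(oracle_het, g)
    got_h <- screen_heterozygosity(r)
    got_h <- if (isTRUE(got_h$ambiguous)) "AMBIG" else got_h$system
    expect_identical(got_h, want_h)
  }
})

test_that("screening is monotone in its thresholds", {
  b <- simulate_panel(small_params(genotyping_error_rate = 0.05, seed = 55L))
  n_calls <- function(cfg) {
    sum(!is.na(screen_allele_freq(b$snp_records, cfg)$system)) +
      sum(!is.na(screen_heterozygosity(b$snp_records, cfg)$system)) +
      nrow(screen_sex_limited(b$occupancy, b$panel, cfg))
  }
  base <- screen_config(hom_female_fraction_min = 0.5)
  for (raised in list(screen_config(homogametic_freq_min = 0.99,
                                    hom_female_fraction_min = 0.5),
                      screen_config(freq_diff_min = 0.49,
                                    hom_female_fraction_min = 0.5),
                      screen_config(het_male_fraction_min = 0.8,
                                    hom_female_fraction_min = 0.5),
                      screen_config(hom_female_fraction_min = 0.9),
                      screen_config(presence_fraction_min = 0.9,
                                    hom_female_fraction_min = 0.5))) {
    expect_lte(n_calls(raised), n_calls(base))
  }
})

test_that("uniting candidates merges approaches and counts overlaps", {
  # empty inputs
  empty <- unite_candidates(
    data.frame(locus_id = integer(), col = integer(),
               system = character()),
    data.frame(locus_id = integer(), col = integer(),
               system = character()),
    data.frame(locus_id = integer(), system = character()))
  expect_equal(nrow(empty$calls), 0L)
  expect_equal(empty$counts$n_candidates, 0L)

  f <- data.frame(locus_id = c(1L, 2L), col = c(5L, 9L), system = "XY")
  h <- data.frame(locus_id = c(2L, 3L), col = c(9L, 2L), system = "XY")
  l <- data.frame(locus_id = c(4L, 5L), system = c("XY", "ZW"))
  out <- unite_candidates(f, h, l)
  expect_equal(nrow(out$calls), 5L)
  expect_equal(out$calls$approaches[out$calls$locus_id == 2L], "FREQ+HET")
  expect_equal(out$counts$n_tags_freq_het_overlap, 1L)
  expect_equal(out$counts$n_candidates, 5L)

  # conflicting systems across approaches: retained, flagged, not counted
  f2 <- data.frame(locus_id = 1L, col = 0L, system = "XY")
  h2 <- data.frame(locus_id = 1L, col = 0L, system = "ZW")
  out2 <- unite_candidates(f2, h2, l[0, ])
  expect_true(out2$calls$conflict)
  expect_equal(out2$counts$n_candidates, 0L)

  # random inputs: union size equals the set-union oracle
  withr::with_seed(77, {
    for (k in 1:10) {
      ids_f <- sample(1:30, 8); ids_h <- sample(1:30, 8)
      ids_l <- sample(31:40, 4)
      f3 <- data.frame(locus_id = ids_f, col = 0L, system = "XY")
      h3 <- data.frame(locus_id = ids_h, col = 0L, system = "XY")
      l3 <- data.frame(locus_id = ids_l, system = "XY")
      out3 <- unite_candidates(f3, h3, l3)
      expect_equal(out3$counts$n_candidates,
                   length(union(union(ids_f, ids_h), ids_l)))
    }
  })
})

test_that("screening swaps XY and ZW when sex labels are swapped", {
  b <- simulate_panel(small_params(seed = 58L,
                                   genotyping_error_rate = 0.02))
  swapped <- swap_panel_sexes(b$panel)
  rec_orig <- b$snp_records
  rec_swap <- snp_records_from_genotypes(b$genotypes, swapped)
  for (screen in list(screen_allele_freq, screen_heterozygosity)) {
    a <- screen(rec_orig)
    z <- screen(rec_swap)
    flip <- function(s) ifelse(is.na(s), s,
                               ifelse(s == "XY", "ZW", "XY"))
    expect_identical(z$system, flip(a$system))
  }
  a <- screen_sex_limited(b$occupancy, b$panel)
  z <- screen_sex_limited(b$occupancy, swapped)
  expect_setequal(z$locus_id[z$system == "ZW"],
                  a$locus_id[a$system == "XY"])
  expect_setequal(z$locus_id[z$system == "XY"],
                  a$locus_id[a$system == "ZW"])
})
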