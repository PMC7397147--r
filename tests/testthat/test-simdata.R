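test_that("clean XY panels show the canonical gametologous pattern exactly", {
  b <- simulate_panel(sim_params(n_sexlinked_snp_loci = 10L,
                                 n_autosomal_snp_loci = 5L,
                                 n_hemizygous_tags = 3L,
                                 n_autosomal_tags = 3L, seed = 3L))
  sl <- b$truth$locus_id[b$truth$category == "SEXLINKED_SNP"]
  expect_length(sl, 10L)
  for (id in sl) {
    r <- b$snp_records[b$snp_records$locus_id == id, ]
    meta <- b$snp_meta[b$snp_meta$locus_id == id, ]
    # frequency of the X allele, whichever of p/q it is in the record
    fx_F <- if (r$p_nuc == meta$x_allele) r$p_count_F / (2 * r$n_F) else
      1 - r$p_count_F / (2 * r$n_F)
    fx_M <- if (r$p_nuc == meta$x_allele) r$p_count_M / (2 * r$n_M) else
      1 - r$p_count_M / (2 * r$n_M)
    expect_identical(fx_F, 1)
    expect_identical(fx_M, 0.5)
  }
  # hemizygous tags: in every male, in no female
  occ <- b$occupancy
  for (id in b$truth$locus_id[b$truth$category == "HEMIZYGOUS_TAG"]) {
    carriers <- occ$sample_id[occ$locus_id == id]
    expect_setequal(carriers, panel_samples(b$panel, "M"))
  }
})

test_that("the same seed reproduces byte-identical files", {
  p <- small_params(seed = 9L)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  f1 <- write_panel_files(simulate_panel(p), d1)
  f2 <- write_panel_files(simulate_panel(p), d2)
  for (k in seq_along(f1)) {
    a <- unlist(f1[k]); b <- unlist(f2[k])
    for (j in seq_along(a))
      expect_identical(readLines(a[j]), readLines(b[j]))
  }
  # and a different seed does not
  f3 <- write_panel_files(simulate_panel(small_params(seed = 10L)),
                          withr::local_tempdir())
  expect_false(identical(readLines(f1$catalog), readLines(f3$catalog)))
})

test_that("male heterozygosity under genotyping error matches the binomial model", {
  # error process: a true X/Y heterozygote is replaced by one of the two
  # homozygotes with probability e, so P(observed het) = 1 - e
  e <- 0.01
  b <- simulate_panel(sim_params(n_males = 21L, n_females = 19L,
                                 n_sexlinked_snp_loci = 60L,
                                 n_autosomal_snp_loci = 0L,
                                 n_hemizygous_tags = 0L,
                                 n_autosomal_tags = 0L,
                                 genotyping_error_rate = e, seed = 5L))
  r <- b$snp_records
  n_draws <- sum(r$n_M)
  obs_het <- sum(r$n_het_M) / n_draws
  p_het <- 1 - e
  se <- sqrt(p_het * (1 - p_het) / n_draws)
  expect_lt(abs(obs_het - p_het), 3 * se)
})

test_that("recombination moves Y alleles out of males at the stated rate", {
  rfrac <- 0.2
  b <- simulate_panel(sim_params(n_males = 40L, n_females = 5L,
                                 n_sexlinked_snp_loci = 50L,
                                 n_autosomal_snp_loci = 0L,
                                 n_hemizygous_tags = 0L,
                                 n_autosomal_tags = 0L,
                                 recombination_fraction = rfrac, seed = 6L))
  frac_het <- sum(b$snp_records$n_het_M) / sum(b$snp_records$n_M)
  se <- sqrt(rfrac * (1 - rfrac) / sum(b$snp_records$n_M))
  expect_lt(abs(frac_het - (1 - rfrac)), 4 * se)
})

test_that("ZW simulation mirrors XY with the sexes exchanged", {
  b <- simulate_panel(small_params(system = "ZW", seed = 12L))
  sl <- b$truth$locus_id[b$truth$category == "SEXLINKED_SNP"]
  r <- b$snp_records[b$snp_records$locus_id %in% sl, ]
  # homogametic sex is now male: males fixed, females heterozygous
  expect_true(all(r$n_het_M == 0))
  expect_true(all(r$n_het_F == r$n_F))
  for (id in b$truth$locus_id[b$truth$category == "HEMIZYGOUS_TAG"]) {
    carriers <- b$occupancy$sample_id[b$occupancy$locus_id == id]
    expect_setequal(carriers, panel_samples(b$panel, "F"))
  }
})

test_that("per-locus record invariants hold on simulated data", {
  b <- simulate_panel(small_params(genotyping_error_rate = 0.05,
                                   missing_rate = 0.2, seed = 13L))
  r <- b$snp_records
  expect_true(all(r$n_hom_M + r$n_het_M == r$n_M))
  expect_true(all(r$n_hom_F + r$n_het_F == r$n_F))
  expect_true(all(r$p_count_M <= 2 * r$n_M))
  expect_true(all(r$p_count_F <= 2 * r$n_F))
})

test_that("hemizygous tags live on the contigs and not in the genome", {
  b <- simulate_panel(small_params(seed = 21L))
  hemi <- b$truth$locus_id[b$truth$category == "HEMIZYGOUS_TAG"]
  genome <- paste(b$homogametic_genome, collapse = "|")
  contigs <- paste(b$hemi_contigs, collapse = "|")
  for (id in hemi) {
    s <- b$catalog[[as.character(id)]]
    expect_false(grepl(s, genome, fixed = TRUE))
    expect_true(grepl(s, contigs, fixed = TRUE))
  }
})

test_that("contaminant planting creates and controls read-filter hits", {
  b <- simulate_panel(small_params(seed = 30L))
  hemi <- as.character(b$truth$locus_id[b$truth$category == "HEMIZYGOUS_TAG"])
  tag <- hemi[1]
  # unplanted: no occurrences in female reads
  pool_F <- unlist(b$reads[panel_samples(b$panel, "F")])
  expect_equal(unname(find_in_reads(b$catalog[tag], pool_F)), 0L)
  # planted verbatim: found
  b1 <- plant_contaminant(b, tag)
  pool_F1 <- unlist(b1$reads[panel_samples(b1$panel, "F")])
  expect_gte(unname(find_in_reads(b$catalog[tag], pool_F1)), 1L)
  # planted reverse-complement only: found iff both strands searched
  b2 <- plant_contaminant(b, hemi[2], revcomp = TRUE)
  pool_F2 <- unlist(b2$reads[panel_samples(b2$panel, "F")])
  expect_equal(unname(find_in_reads(b$catalog[hemi[2]], pool_F2,
                                    search_revcomp = FALSE)), 0L)
  expect_gte(unname(find_in_reads(b$catalog[hemi[2]], pool_F2,
                                  search_revcomp = TRUE)), 1L)
  expect_error(plant_contaminant(b, 999999L), "unknown tag_id")
})

test_that("simulation rejects invalid parameters", {
  expect_error(sim_params(n_males = 0L), "each sex")
  expect_error(sim_params(missing_rate = 1.2), "\\[0, 1\\]")
  expect_error(sim_params(recombination_fraction = 0.7), "0.5")
  expect_error(sim_params(tag_length = 20L), "at least 50")
})
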