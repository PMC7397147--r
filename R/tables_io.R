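api_sumstats_cols <- c(
  "Locus ID", "Chr", "BP", "Col", "Pop ID", "P Nuc", "Q Nuc", "N", "P",
  "Obs Het", "Obs Hom", "Exp Het", "Exp Hom", "Pi", "Smoothed Pi",
  "Smoothed Pi P-value", "Fis", "Smoothed Fis", "Smoothed Fis P-value",
  "HWE P-value", "Private")

#' Build a per-SNP record table from per-sample genotypes
#'
#' The SNP record table is the package's central container for screening: one
#' row per (locus, column) with per-sex genotyped counts, counts of the P
#' allele, and homozygote/heterozygote counts. Coordinates follow the Stacks
#' convention: `col` is the 0-based position of the SNP within the tag.
#'
#' @param genotypes Data frame with columns `locus_id`, `col`, `sample_id`,
#'   `genotype` (two characters from ACGT, e.g. `"AG"`; missing genotypes are
#'   absent rows).
#' @param panel A [sexed_panel()].
#' @return A data frame of class `snp_records` with columns `locus_id`, `col`,
#'   `p_nuc`, `q_nuc` and, for each sex suffix `_M`/`_F`: `n` (genotyped),
#'   `p_count` (P-allele copies), `n_hom`, `n_het`.
#' @export
snp_records_from_genotypes <- function(genotypes, panel) {
  stopifnot(is(panel, "sexed_panel"))
  need <- c("locus_id", "col", "sample_id", "genotype")
  if (!all(need %in% names(genotypes)))
    stopf("genotype matrix must have columns: %s", paste(need, collapse = ", "))
  bad <- setdiff(unique(genotypes$sample_id), panel$sample_ids)
  if (length(bad))
    stopf("genotype matrix contains samples not in panel: %s",
          paste(head(bad, 5), collapse = ", "))
  if (nrow(genotypes) == 0) return(empty_snp_records())

  g <- genotypes
  g$sex <- unname(panel$sex[g$sample_id])
  g$a1 <- substr(g$genotype, 1, 1)
  g$a2 <- substr(g$genotype, 2, 2)
  key <- paste(g$locus_id, g$col, sep = ":")

  recs <- lapply(split(g, key), function(d) {
    alleles <- c(d$a1, d$a2)
    tab <- sort(table(alleles), decreasing = TRUE)
    nuc <- names(tab)
    if (length(nuc) > 2)
      stopf("locus %s col %s is not biallelic (%s)",
            d$locus_id[1], d$col[1], paste(nuc, collapse = "/"))
    p_nuc <- nuc[1]
    q_nuc <- if (length(nuc) == 2) nuc[2] else ""
    per_sex <- function(s) {
      ds <- d[d$sex == s, , drop = FALSE]
      het <- ds$a1 != ds$a2
      c(n = nrow(ds),
        p_count = sum(ds$a1 == p_nuc) + sum(ds$a2 == p_nuc),
        n_hom = sum(!het), n_het = sum(het))
    }
    m <- per_sex("M"); f <- per_sex("F")
    data.frame(locus_id = d$locus_id[1], col = d$col[1],
               p_nuc = p_nuc, q_nuc = q_nuc,
               n_M = m[["n"]], p_count_M = m[["p_count"]],
               n_hom_M = m[["n_hom"]], n_het_M = m[["n_het"]],
               n_F = f[["n"]], p_count_F = f[["p_count"]],
               n_hom_F = f[["n_hom"]], n_het_F = f[["n_het"]])
  })
  out <- do.call(rbind, recs)
  out <- out[order(out$locus_id, out$col), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("snp_records", "data.frame")
  validate_snp_records(out)
  out
}

empty_snp_records <- function() {
  out <- data.frame(locus_id = integer(), col = integer(),
                    p_nuc = character(), q_nuc = character(),
                    n_M = integer(), p_count_M = integer(),
                    n_hom_M = integer(), n_het_M = integer(),
                    n_F = integer(), p_count_F = integer(),
                    n_hom_F = integer(), n_het_F = integer())
  class(out) <- c("snp_records", "data.frame")
  out
}

validate_snp_records <- function(x) {
  for (s in c("M", "F")) {
    n <- x[[paste0("n_", s)]]
    ok_sum <- x[[paste0("n_hom_", s)]] + x[[paste0("n_het_", s)]] == n
    ok_cnt <- x[[paste0("p_count_", s)]] <= 2L * n
    if (!all(ok_sum))
      stopf("snp_records invariant violated: n_hom + n_het != n_genotyped (%s)", s)
    if (!all(ok_cnt))
      stopf("snp_records invariant violated: allele count exceeds 2n (%s)", s)
  }
  invisible(x)
}

# P-allele frequency over genotyped individuals of one sex; NA when none
snp_freq <- function(records, sex) {
  n <- records[[paste0("n_", sex)]]
  ifelse(n > 0, records[[paste0("p_count_", sex)]] / (2 * n), NA_real_)
}

#' Write and read a Stacks-style populations.sumstats.tsv
#'
#' The dialect is pinned to the Stacks 2.41 column layout (21 columns,
#' `#`-prefixed header) with the two sexes as the populations, labelled `M`
#' and `F`. Per-sex counts are reconstructed from the `N`, `P` and `Obs Het`
#' columns; a file whose `Pop ID` values are not `M`/`F` is rejected with a
#' pointer to the per-sample genotype-matrix companion
#' ([snp_records_from_genotypes()]), which covers pooled-population output.
#'
#' @param records A `snp_records` table.
#' @param path File path.
#' @return `read_sumstats()` returns a `snp_records` table.
#' @export
write_sumstats <- function(records, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# sexmarkr sumstats (Stacks 2.41 dialect)", con)
  writeLines(paste0("# ", paste(api_sumstats_cols, collapse = "\t")), con)
  if (nrow(records)) {
    rows <- lapply(c("M", "F"), function(s) {
      n <- records[[paste0("n_", s)]]
      p <- ifelse(n > 0, records[[paste0("p_count_", s)]] / (2 * n), 0)
      oh <- ifelse(n > 0, records[[paste0("n_het_", s)]] / n, 0)
      ohom <- ifelse(n > 0, records[[paste0("n_hom_", s)]] / n, 0)
      eh <- 2 * p * (1 - p)
      pi <- ifelse(n > 1, eh * (2 * n) / (2 * n - 1), 0)
      data.frame(records$locus_id, "un", records$col + 1L, records$col, s,
                 records$p_nuc,
                 ifelse(records$q_nuc == "", "-", records$q_nuc),
                 n, sprintf("%.5f", p), sprintf("%.5f", oh),
                 sprintf("%.5f", ohom), sprintf("%.5f", eh),
                 sprintf("%.5f", 1 - eh), sprintf("%.5f", pi),
                 0, 1, 0, 0, 1, 1, 0)
    })
    tab <- do.call(rbind, rows)
    ord <- order(tab[[1]], tab[[4]], tab[[5]])
    write.table(tab[ord, ], con, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_sumstats
#' @param panel A [sexed_panel()]; genotyped counts per sex may not exceed the
#'   panel's per-sex sizes.
#' @export
read_sumstats <- function(path, panel) {
  stopifnot(is(panel, "sexed_panel"))
  if (!file.exists(path)) stopf("sumstats file not found: %s", path)
  lines <- readLines(path)
  body <- which(!startsWith(lines, "#"))
  if (!length(body)) return(empty_snp_records())

  parts <- strsplit(lines[body], "\t", fixed = TRUE)
  nc <- lengths(parts)
  if (any(nc != length(api_sumstats_cols)))
    stopf("malformed sumstats row at line %d: expected %d columns, found %d",
          body[which(nc != length(api_sumstats_cols))[1]],
          length(api_sumstats_cols), nc[which(nc != length(api_sumstats_cols))[1]])
  m <- do.call(rbind, parts)
  pop <- m[, 5]
  if (!all(pop %in% c("M", "F")))
    stopf(paste("unknown population label '%s' at line %d: per-sex statistics",
                "need sexes as populations M/F, or use the genotype-matrix",
                "companion via snp_records_from_genotypes()"),
          pop[which(!pop %in% c("M", "F"))[1]],
          body[which(!pop %in% c("M", "F"))[1]])

  num <- function(j) {
    v <- suppressWarnings(as.numeric(m[, j]))
    if (anyNA(v))
      stopf("malformed sumstats row at line %d: non-numeric value in column %d",
            body[which(is.na(v))[1]], j)
    v
  }
  locus <- as.integer(num(1)); col <- as.integer(num(4))
  n <- as.integer(num(8)); p <- num(9); obs_het <- num(10)

  key <- paste(locus, col, sep = ":")
  ukey <- unique(key)
  rowsM <- which(pop == "M"); rowsF <- which(pop == "F")
  iM <- rowsM[match(ukey, key[rowsM])]
  iF <- rowsF[match(ukey, key[rowsF])]
  take <- function(i, what, default = 0L) {
    out <- what[i]
    out[is.na(i)] <- default
    out
  }
  n_M <- take(iM, n); n_F <- take(iF, n)
  if (any(n_M > sum(panel$sex == "M")) || any(n_F > sum(panel$sex == "F")))
    stopf("sumstats genotyped counts exceed panel size")
  het_M <- as.integer(round(take(iM, obs_het, 0) * n_M))
  het_F <- as.integer(round(take(iF, obs_het, 0) * n_F))
  first <- match(ukey, key)
  out <- data.frame(
    locus_id = locus[first], col = col[first],
    p_nuc = m[first, 6], q_nuc = ifelse(m[first, 7] == "-", "", m[first, 7]),
    n_M = n_M, p_count_M = as.integer(round(take(iM, p, 0) * 2 * n_M)),
    n_hom_M = n_M - het_M, n_het_M = het_M,
    n_F = n_F, p_count_F = as.integer(round(take(iF, p, 0) * 2 * n_F)),
    n_hom_F = n_F - het_F, n_het_F = het_F)
  out <- out[order(out$locus_id, out$col), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("snp_records", "data.frame")
  validate_snp_records(out)
  out
}

#' Write and read a per-sample genotype matrix (sumstats companion)
#'
#' Long-format TSV with columns `locus_id`, `col`, `sample_id`, `genotype`;
#' missing genotypes are absent rows.
#'
#' @param genotypes Data frame as in [snp_records_from_genotypes()].
#' @param path File path.
#' @export
write_genotype_matrix <- function(genotypes, path) {
  write.table(genotypes[, c("locus_id", "col", "sample_id", "genotype")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_genotype_matrix
#' @export
read_genotype_matrix <- function(path) {
  if (!file.exists(path)) stopf("genotype matrix not found: %s", path)
  read.delim(path, colClasses = c("integer", "integer", "character",
                                  "character"))
}

#' Tag occupancy: which samples carry which catalog tag
#'
#' `tag_occupancy()` builds the container from a long table of
#' (locus, sample) match events; presence means at least one match line.
#'
#' @param locus_id Integer vector of catalog locus ids.
#' @param sample_id Character vector of sample ids, parallel to `locus_id`.
#' @param panel A [sexed_panel()]; every sample must belong to it.
#' @return A data frame of class `tag_occupancy` with unique
#'   (`locus_id`, `sample_id`) rows.
#' @export
tag_occupancy <- function(locus_id, sample_id, panel) {
  stopifnot(is(panel, "sexed_panel"))
  bad <- setdiff(unique(sample_id), panel$sample_ids)
  if (length(bad))
    stopf("matches refer to samples not in panel: %s",
          paste(head(bad, 5), collapse = ", "))
  df <- unique(data.frame(locus_id = as.integer(locus_id),
                          sample_id = as.character(sample_id)))
  df <- df[order(df$locus_id, df$sample_id), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("tag_occupancy", "data.frame")
  df
}

# per-locus presence counts split by sex; returns data.frame
occupancy_by_sex <- function(occ, panel) {
  if (nrow(occ) == 0)
    return(data.frame(locus_id = integer(), n_M = integer(), n_F = integer()))
  sex <- unname(panel$sex[occ$sample_id])
  tab_m <- table(occ$locus_id[sex == "M"])
  tab_f <- table(occ$locus_id[sex == "F"])
  ids <- sort(unique(occ$locus_id))
  zero_na <- function(v) ifelse(is.na(v), 0L, v)
  data.frame(locus_id = ids,
             n_M = zero_na(as.integer(tab_m[as.character(ids)])),
             n_F = zero_na(as.integer(tab_f[as.character(ids)])))
}

#' Write and read a Stacks-style matches.tsv
#'
#' Pinned dialect: `#`-prefixed header, then columns catalog locus, sample id,
#' sample-side locus, haplotype, depth. Only presence (at least one row per
#' locus and sample) is used downstream.
#'
#' @param occ A `tag_occupancy`.
#' @param path File path (or several paths for `read_matches`, concatenated).
#' @param panel A [sexed_panel()].
#' @return `read_matches()` returns a `tag_occupancy`.
#' @export
write_matches <- function(occ, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# Catalog Locus\tSample\tSample Locus\tHaplotype\tDepth", con)
  if (nrow(occ))
    write.table(data.frame(occ$locus_id, occ$sample_id, occ$locus_id,
                           "consensus", 10L),
                con, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_matches
#' @export
read_matches <- function(path, panel) {
  rows <- lapply(path, function(p) {
    if (!file.exists(p)) stopf("matches file not found: %s", p)
    lines <- readLines(p)
    lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
    if (!length(lines))
      return(data.frame(locus_id = integer(), sample_id = character()))
    parts <- strsplit(lines, "\t", fixed = TRUE)
    if (any(lengths(parts) < 2))
      stopf("malformed matches row in %s", p)
    m <- do.call(rbind, parts)
    data.frame(locus_id = as.integer(m[, 1]), sample_id = m[, 2])
  })
  all <- do.call(rbind, rows)
  tag_occupancy(all$locus_id, all$sample_id, panel)
}

#' FASTA and FASTQ input/output
#'
#' Thin wrappers around Biostrings readers returning plain named character
#' vectors of upper-cased sequences. FASTQ qualities are parsed but unused
#' downstream (the read-search stage is exact-match). Duplicate sequence ids
#' are an error.
#'
#' @param path File path.
#' @return A named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stopf("FASTA not found: %s", path)
  x <- Biostrings::readBStringSet(path, format = "fasta")
  seqs <- toupper(as.character(x))
  names(seqs) <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(names(seqs)))
    stopf("duplicate sequence ids in %s: %s", path,
          paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  if (length(seqs) && any(grepl("[^ACGTN]", seqs)))
    stopf("non-ACGTN characters in %s", path)
  seqs
}

#' @rdname read_fasta
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stopf("FASTQ not found: %s", path)
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  seqs <- toupper(as.character(x))
  names(seqs) <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(names(seqs)))
    stopf("duplicate read ids in %s", path)
  seqs
}

#' @rdname read_fasta
#' @param seqs Named character vector of sequences.
#' @param width Line width for FASTA wrapping.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' @rdname read_fasta
#' @param quality Single quality character applied to every base
#'   (default `"I"`, Phred+33 Q40).
#' @export
write_fastq <- function(seqs, path, quality = "I") {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(c(paste0("@", names(seqs)[i]), seqs[[i]], "+",
                 strrep(quality, nchar(seqs[[i]]))), con)
  }
  invisible(path)
}

#' Catalog summary: polymorphic loci shared across 80% of samples
#'
#' A standard catalog health statistic used to choose assembly parameters:
#' the number of loci genotyped (tag matched) in at least 80% of samples that
#' carry at least one SNP, plus the distribution of SNPs per locus over those
#' wide-shared loci.
#'
#' @param records A `snp_records` table (may include zero rows for a
#'   monomorphic catalog).
#' @param occ A `tag_occupancy` covering all catalog loci.
#' @param panel A [sexed_panel()].
#' @param share_min Minimum fraction of samples a locus must be genotyped in
#'   (default 0.8).
#' @return A list with `n_polymorphic_r80` and `snps_per_locus` (a table over
#'   the shared loci, including a 0 bin for monomorphic ones).
#' @export
r80_summary <- function(records, occ, panel, share_min = 0.8) {
  n_samples <- length(panel$sample_ids)
  if (nrow(occ) == 0)
    return(list(n_polymorphic_r80 = 0L,
                snps_per_locus = table(integer())))
  cnt <- table(occ$locus_id)
  shared <- as.integer(names(cnt))[as.integer(cnt) / n_samples >= share_min]
  snp_per <- table(records$locus_id)
  nsnp <- as.integer(snp_per[as.character(shared)])
  nsnp[is.na(nsnp)] <- 0L
  list(n_polymorphic_r80 = sum(nsnp >= 1L),
       snps_per_locus = table(nsnp))
}
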