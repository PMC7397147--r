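#' Summarize a pipeline run as an accounting report
#'
#' Collates the screening tallies, the per-stage retention ledger, confirmed
#' totals by system, the mapped fraction onto the candidate sex chromosome,
#' and (when read counts are given) the mean reads per sample, reported as
#' the floor of the integer division as customarily printed.
#'
#' @param screen_counts The `counts` element of [unite_candidates()].
#' @param ledger A `ledger` from [run_validation()].
#' @param calls The status-updated `marker_calls`.
#' @param assignment Output of [assign_to_chromosome()] (optional).
#' @param total_reads,n_samples Optional read accounting inputs.
#' @return A list of class `pipeline_report` with elements `screening`,
#'   `stages` (data frame), `confirmed` (counts by system),
#'   `mapped` (`n_mapped`, `n_confirmed`, `mapped_fraction_pct`), and
#'   `reads` (`total_reads`, `n_samples`, `mean_reads_per_sample`).
#' @export
summarize_pipeline <- function(screen_counts, ledger, calls,
                               assignment = NULL, total_reads = NULL,
                               n_samples = NULL) {
  ledger_check(ledger)
  confirmed <- calls[calls$status == "CONFIRMED", , drop = FALSE]
  rep <- list(
    screening = screen_counts,
    stages = as.data.frame(ledger),
    confirmed = list(
      n_total = nrow(confirmed),
      n_xy = sum(confirmed$system == "XY", na.rm = TRUE),
      n_zw = sum(confirmed$system == "ZW", na.rm = TRUE),
      n_limited = sum(is.na(confirmed$snp_col)),
      n_snp = sum(!is.na(confirmed$snp_col))))
  if (!is.null(assignment))
    rep$mapped <- list(
      n_mapped = assignment$n_mapped,
      n_confirmed = assignment$n_confirmed,
      mapped_fraction_pct = if (is.na(assignment$mapped_fraction))
        NA_real_ else 100 * assignment$mapped_fraction)
  if (!is.null(total_reads) && !is.null(n_samples))
    rep$reads <- list(total_reads = total_reads, n_samples = n_samples,
                      mean_reads_per_sample = floor(total_reads / n_samples))
  class(rep) <- "pipeline_report"
  rep
}

#' @export
print.pipeline_report <- function(x, ...) {
  sc <- x$screening
  cat("Screening:\n")
  cat(sprintf("  allele-frequency screen: %d SNPs on %d tags\n",
              sc$n_snps_freq, sc$n_tags_freq))
  cat(sprintf("  heterozygosity screen:   %d SNPs on %d tags (%d tags shared)\n",
              sc$n_snps_het, sc$n_tags_het, sc$n_tags_freq_het_overlap))
  cat(sprintf("  sex-limited tags:        %d male-limited, %d female-limited\n",
              sc$n_male_limited, sc$n_female_limited))
  cat(sprintf("  distinct candidates:     %d (%d system conflicts excluded)\n",
              sc$n_candidates, sc$n_conflict))
  cat("Validation stages:\n")
  print(x$stages, row.names = FALSE)
  cat(sprintf("Confirmed: %d (%d XY, %d ZW; %d sex-limited, %d SNP)\n",
              x$confirmed$n_total, x$confirmed$n_xy, x$confirmed$n_zw,
              x$confirmed$n_limited, x$confirmed$n_snp))
  if (!is.null(x$mapped))
    cat(sprintf("Mapped to candidate chromosome: %d / %d (%.1f%%)\n",
                x$mapped$n_mapped, x$mapped$n_confirmed,
                x$mapped$mapped_fraction_pct))
  if (!is.null(x$reads))
    cat(sprintf("Reads: %s total over %d samples, mean %s per sample\n",
                format(x$reads$total_reads, big.mark = ","),
                x$reads$n_samples,
                format(x$reads$mean_reads_per_sample, big.mark = ",")))
  invisible(x)
}

#' Run the whole pipeline on a simulated or loaded dataset
#'
#' Screens, validates, assigns and reports in one call. Either pass a
#' `sim_panel` bundle, or the individual components a real dataset provides.
#'
#' @param bundle A `sim_panel` from [simulate_panel()].
#' @param screen_cfg,validate_cfg,assign_cfg Stage configurations.
#' @param contigs Candidate sex-chromosome contigs; defaults to the bundle's
#'   heterogametic-chromosome contigs.
#' @return A list with `screen`, `validation`, `assignment`, and `report`.
#' @export
run_all <- function(bundle, screen_cfg = screen_config(),
                    validate_cfg = validate_config(),
                    assign_cfg = assign_config(), contigs = NULL) {
  stopifnot(is(bundle, "sim_panel"))
  scr <- screen_all(bundle$snp_records, bundle$occupancy, bundle$panel,
                    screen_cfg)
  val <- run_validation(scr$calls, bundle$catalog, reads_by_sex(bundle),
                        bundle$homogametic_genome, bundle$snp_records,
                        validate_cfg)
  asg <- assign_to_chromosome(val$confirmed, bundle$catalog,
                              contigs %||% bundle$hemi_contigs, assign_cfg)
  rep <- summarize_pipeline(scr$counts, val$ledger, val$calls, asg)
  list(screen = scr, validation = val, assignment = asg, report = rep)
}
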