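#' Construct a sexed sample panel
#'
#' A sexed panel is the fixed frame for all per-sex statistics: an ordered set
#' of sample identifiers, each labelled `"M"` or `"F"`.
#'
#' @param sample_ids Character vector of unique sample identifiers.
#' @param sex Character vector the same length as `sample_ids`, each `"M"` or
#'   `"F"`. At least one sample of each sex is required, since per-sex allele
#'   frequencies are undefined otherwise.
#'
#' @return An object of class `sexed_panel`: a list with elements
#'   `sample_ids` and `sex` (a named character vector keyed by sample id).
#' @examples
#' sexed_panel(c("m1", "m2", "f1"), c("M", "M", "F"))
#' @export
sexed_panel <- function(sample_ids, sex) {
  sample_ids <- as.character(sample_ids)
  sex <- toupper(as.character(sex))
  if (length(sample_ids) != length(sex))
    stopf("sample_ids and sex must have equal length")
  if (anyDuplicated(sample_ids))
    stopf("duplicate sample ids: %s",
          paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (!all(sex %in% c("M", "F")))
    stopf("sex labels must be 'M' or 'F'")
  if (!any(sex == "M") || !any(sex == "F"))
    stopf("panel must contain at least one male and one female")
  structure(list(sample_ids = sample_ids,
                 sex = setNames(sex, sample_ids)),
            class = "sexed_panel")
}

#' @export
print.sexed_panel <- function(x, ...) {
  cat(sprintf("sexed_panel: %d samples (%d M, %d F)\n",
              length(x$sample_ids), sum(x$sex == "M"), sum(x$sex == "F")))
  invisible(x)
}

#' @rdname sexed_panel
#' @param panel A `sexed_panel`.
#' @param which `"M"` or `"F"`.
#' @return `panel_samples()` returns the ids of one sex, in panel order.
#' @export
panel_samples <- function(panel, which) {
  stopifnot(is(panel, "sexed_panel"), which %in% c("M", "F"))
  panel$sample_ids[panel$sex[panel$sample_ids] == which]
}

#' Swap the sex labels of a panel
#'
#' Relabels every male as female and vice versa. Used to express the XY/ZW
#' symmetry of the screening criteria: screening a relabelled panel must give
#' the same calls with the systems exchanged.
#'
#' @param panel A `sexed_panel`.
#' @return A `sexed_panel` with `M` and `F` exchanged.
#' @export
swap_panel_sexes <- function(panel) {
  stopifnot(is(panel, "sexed_panel"))
  sexed_panel(panel$sample_ids,
              ifelse(panel$sex[panel$sample_ids] == "M", "F", "M"))
}

#' Read and write a two-column sample-to-sex map
#'
#' The map is a headerless TSV with `sample_id<TAB>M|F`, one row per sample.
#'
#' @param path File path.
#' @return `read_sex_map()` returns a `sexed_panel`.
#' @export
read_sex_map <- function(path) {
  if (!file.exists(path)) stopf("sex map not found: %s", path)
  df <- read.delim(path, header = FALSE, colClasses = "character",
                   col.names = c("sample_id", "sex"))
  sexed_panel(df$sample_id, df$sex)
}

#' @rdname read_sex_map
#' @param panel A `sexed_panel` to write.
#' @export
write_sex_map <- function(panel, path) {
  stopifnot(is(panel, "sexed_panel"))
  df <- data.frame(sample_id = panel$sample_ids,
                   sex = unname(panel$sex[panel$sample_ids]))
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
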