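# Published chlorotype frequency tables for the dogwood collections, and
# reconstruction of per-sample datasets from the printed percentages.

#' Published chlorotype frequencies of the dogwood survey
#'
#' Per-group chlorotype percentages as printed in the published survey of
#' the Big-Bracted dogwood collections: the four-site panel over wild
#' Cornus florida accessions (n = 225), the C. florida cultivar/breeding
#' collection (n = 91), the C. kousa cultivar collection (n = 109) and the
#' other-Cornus species group (n = 32); and the extended twelve-site panel
#' over the two cultivar collections. \code{NA} marks chlorotypes absent
#' from a group. The wild C. florida four-site percentages sum to 96, not
#' 100, as printed.
#'
#' @param panel \code{"four_site"} or \code{"twelve_site"}.
#' @return Data frame of percentages with attribute \code{"group_sizes"}.
#' @export
chlorotype_survey_frequencies <- function(panel = c("twelve_site",
                                                    "four_site")) {
  panel <- match.arg(panel)
  if (panel == "four_site") {
    df <- data.frame(
      chlorotype = c("0001", "0011", "0101", "0111", "1100", "1101",
                     "1110", "1111"),
      wild_florida      = c(1, 17, 46, 24, 1, NA, 7, NA),
      florida_cultivars = c(NA, 1, 13, 82, NA, NA, 3, NA),
      kousa_cultivars   = c(NA, NA, NA, NA, NA, NA, 100, NA),
      other_cornus      = c(NA, NA, NA, 6, NA, 66, NA, 28),
      stringsAsFactors = FALSE)
    sizes <- c(wild_florida = 225L, florida_cultivars = 91L,
               kousa_cultivars = 109L, other_cornus = 32L)
  } else {
    df <- data.frame(
      chlorotype = c("001100111111", "010100111111", "010101111111",
                     "011100011111", "011100111101", "011100111111",
                     "111010111111", "111010000000", "111010000111",
                     "111011000000", "111011000001", "111011001010",
                     "111011010000", "111011010001", "111011110000",
                     "111011111111"),
      florida_cultivars = c(1, 12, 1, 1, 1, 80, 3,
                            NA, NA, NA, NA, NA, NA, NA, NA, NA),
      kousa_cultivars   = c(NA, NA, NA, NA, NA, NA, NA,
                            2, 1, 51, 19, 1, 13, 10, 2, 1),
      stringsAsFactors = FALSE)
    sizes <- c(florida_cultivars = 91L, kousa_cultivars = 109L)
  }
  attr(df, "group_sizes") <- sizes
  df
}

#' Reconstruct the per-sample survey dataset from printed percentages
#'
#' Converts the published percentage table back into a per-sample
#' \code{\link{grouped_dataset}} via
#' \code{\link{reconstruct_counts_from_percentages}} (round, then
#' largest-remainder correction where the printed column does not round
#' back to the group size).
#'
#' @param panel \code{"twelve_site"} (default; the two cultivar
#'   collections) or \code{"four_site"}.
#' @param groups Which group columns to reconstruct; defaults to every
#'   group present for the chosen panel.
#' @return A \code{\link{grouped_dataset}}; attribute
#'   \code{"count_corrected"} names groups where the largest-remainder
#'   correction fired.
#' @export
reconstruct_survey_dataset <- function(panel = c("twelve_site", "four_site"),
                                       groups = NULL) {
  panel <- match.arg(panel)
  freqs <- chlorotype_survey_frequencies(panel)
  sizes <- attr(freqs, "group_sizes")
  if (is.null(groups)) groups <- names(sizes)
  stopifnot(all(groups %in% names(sizes)))
  pan <- if (panel == "four_site") panel_4site() else panel_12site()
  rows <- list()
  corrected <- character(0)
  for (g in groups) {
    pct <- freqs[[g]]
    keep <- !is.na(pct)
    cnt <- reconstruct_counts_from_percentages(
      stats::setNames(pct[keep], freqs$chlorotype[keep]), sizes[[g]])
    if (isTRUE(attr(cnt, "corrected"))) corrected <- c(corrected, g)
    chl <- rep(names(cnt), cnt)
    rows[[g]] <- data.frame(
      sample_id = sprintf("%s_%04d", g, seq_along(chl)),
      group = g, chlorotype = chl, stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  out <- grouped_dataset(df$sample_id, df$group, df$chlorotype, panel = pan)
  attr(out, "count_corrected") <- corrected
  out
}
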