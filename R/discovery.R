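# Panel extension: polymorphic columns, informative restriction-site
# discovery (CAPS candidates) and greedy minimal-panel selection.

# Character matrix of an alignment (rows = samples, columns = positions).
alignment_matrix <- function(alignment) {
  widths <- unique(nchar(alignment))
  if (length(alignment) < 2L) stop("alignment needs at least 2 sequences")
  if (length(widths) != 1L) {
    stop("ragged alignment: sequence lengths ", paste(widths, collapse = ", "))
  }
  do.call(rbind, strsplit(toupper(alignment), ""))
}

#' Locate polymorphic alignment columns
#'
#' A column is polymorphic when at least two distinct non-gap symbols occur
#' in it; columns containing gaps are flagged as indel columns separately.
#'
#' @param alignment Named character vector of equal-length aligned sequences.
#' @return Data frame with \code{column} (0-based), \code{symbols}
#'   (non-gap symbols seen, collapsed), \code{indel} (gap present).
#' @export
find_polymorphic_columns <- function(alignment) {
  mat <- alignment_matrix(alignment)
  res <- lapply(seq_len(ncol(mat)), function(j) {
    col <- mat[, j]
    sym <- unique(col[col != "-"])
    if (length(sym) >= 2L) {
      data.frame(column = j - 1L,
                 symbols = paste(sort(sym), collapse = "/"),
                 indel = any(col == "-"), stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- data.frame(column = integer(0), symbols = character(0),
                      indel = logical(0))
  }
  out
}

#' Proportion of variable sites in an alignment
#'
#' @param alignment Named character vector of aligned sequences.
#' @return List with \code{pct} (100 x polymorphic columns / width) and
#'   \code{length} (alignment width, bp).
#' @export
variable_site_proportion <- function(alignment) {
  mat <- alignment_matrix(alignment)
  if (ncol(mat) == 0L) stop("empty alignment")
  poly <- find_polymorphic_columns(alignment)
  list(pct = 100 * nrow(poly) / ncol(mat), length = ncol(mat))
}

#' Discover informative restriction sites in aligned sequences
#'
#' For every catalog enzyme, each sequence's recognition-site hits (scanned
#' on the ungapped molecule) are projected onto alignment coordinates; an
#' alignment column becomes a candidate diagnostic site when site presence
#' there differs between at least one pair of samples. Sites already covered
#' by \code{exclude} are dropped: by exact (region, enzyme, column) when the
#' excluded panel carries coordinates, else by (region, enzyme).
#'
#' @param alignments Named list, region id -> named character vector of
#'   aligned sequences.
#' @param catalog Enzyme catalog (named list of \code{enzyme}).
#' @param exclude Optional \code{\link{chlorotype_panel}} of known sites.
#' @return Data frame with columns \code{region}, \code{enzyme},
#'   \code{column} (0-based motif start), \code{partition} (per-sample
#'   presence string over the region's samples: 1/0/? for present, absent,
#'   gapped), sorted by (region, enzyme, column).
#' @export
discover_informative_digests <- function(alignments,
                                         catalog = default_enzyme_catalog(),
                                         exclude = NULL) {
  stopifnot(length(catalog) > 0L)
  out <- list()
  for (reg in names(alignments)) {
    aln <- alignments[[reg]]
    mat <- alignment_matrix(aln)
    for (enz in catalog) {
      cols_per_sample <- lapply(aln, hit_columns, enzyme = enz)
      all_cols <- sort(unique(unlist(cols_per_sample)))
      for (cc in all_cols) {
        pres <- vapply(seq_along(aln), function(i) {
          foot <- seq.int(cc + 1L, length.out = nchar(enz$recognition))
          foot <- foot[foot <= ncol(mat)]
          if (any(mat[i, foot] == "-")) return(NA)
          cc %in% cols_per_sample[[i]]
        }, logical(1))
        if (any(pres %in% TRUE) && any(pres %in% FALSE)) {
          out[[length(out) + 1L]] <- data.frame(
            region = reg, enzyme = enz$name, column = cc,
            partition = paste(ifelse(is.na(pres), "?",
                                     ifelse(pres, "1", "0")), collapse = ""),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else {
    data.frame(region = character(0), enzyme = character(0),
               column = integer(0), partition = character(0))
  }
  if (!is.null(exclude) && nrow(res)) {
    ex <- as.data.frame(exclude)
    drop <- logical(nrow(res))
    for (i in seq_len(nrow(ex))) {
      same_re <- res$region == ex$region[i] & res$enzyme == ex$enzyme[i]
      if (is.na(ex$column[i])) {
        drop <- drop | same_re
      } else {
        drop <- drop | (same_re & res$column == ex$column[i])
      }
    }
    res <- res[!drop, , drop = FALSE]
  }
  res <- res[order(res$region, res$enzyme, res$column), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Select a minimal discriminating panel by greedy set cover
#'
#' Repeatedly adds the diagnostic site that splits the largest number of
#' still-unsplit sample pairs, until every pair distinguishable by the full
#' site set is split. Ties break deterministically by (region, enzyme,
#' column) lexicographic order. Gapped calls (\code{"?"}) split no pair.
#'
#' @param sites Data frame as returned by
#'   \code{\link{discover_informative_digests}} (needs a \code{partition}
#'   column; all partitions must have equal length).
#' @return A \code{\link{chlorotype_panel}} over the selected sites (empty
#'   panel when \code{sites} is empty).
#' @export
select_minimal_panel <- function(sites) {
  if (nrow(sites) == 0L) {
    return(chlorotype_panel(data.frame(region = character(0),
                                       enzyme = character(0),
                                       column = integer(0)),
                            name = "minimal"))
  }
  sites <- sites[order(sites$region, sites$enzyme, sites$column), ,
                 drop = FALSE]
  parts <- strsplit(sites$partition, "")
  n <- unique(lengths(parts))
  stopifnot(length(n) == 1L)
  pairs <- utils::combn(n, 2L)
  splits <- lapply(parts, function(p) {
    a <- p[pairs[1, ]]; b <- p[pairs[2, ]]
    a != b & a != "?" & b != "?"
  })
  target <- Reduce(`|`, splits)
  covered <- rep(FALSE, ncol(pairs))
  chosen <- integer(0)
  while (any(target & !covered)) {
    gain <- vapply(seq_along(splits), function(i) {
      if (i %in% chosen) -1L else sum(splits[[i]] & !covered)
    }, integer(1))
    best <- which.max(gain)  # first max = lexicographic tie-break
    if (gain[best] <= 0L) break
    chosen <- c(chosen, best)
    covered <- covered | splits[[best]]
  }
  chlorotype_panel(sites[chosen, c("region", "enzyme", "column")],
                   name = "minimal")
}
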