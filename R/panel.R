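# Chlorotype panels: diagnostic sites, digest calls, encoding, frequency
# tables and the digest-table interchange format.

#' Define a diagnostic site
#'
#' One panel position: a (region, enzyme) digest whose outcome at a specific
#' alignment coordinate is scored 0/1 per sample.
#'
#' @param region_id Region label.
#' @param enzyme Enzyme name (must exist in the catalog used for typing).
#' @param column 0-based alignment column of the recognition-motif start in
#'   the region's reference alignment; \code{NA} when typing from digest
#'   tables only.
#' @return One-row data frame with columns \code{region}, \code{enzyme},
#'   \code{column}.
#' @export
diagnostic_site <- function(region_id, enzyme, column = NA_integer_) {
  data.frame(region = region_id, enzyme = enzyme,
             column = as.integer(column), stringsAsFactors = FALSE)
}

#' Assemble an ordered chlorotype panel
#'
#' @param sites Data frame of diagnostic sites (rows in panel order), as
#'   built by \code{\link{diagnostic_site}} / \code{rbind}.
#' @param name Panel label.
#' @return Object of class \code{"chlorotype_panel"} (a data frame with a
#'   \code{panel_index} column and a \code{name} attribute).
#' @export
chlorotype_panel <- function(sites, name = "custom") {
  stopifnot(is.data.frame(sites),
            all(c("region", "enzyme") %in% names(sites)))
  if (is.null(sites$column)) sites$column <- NA_integer_
  sites <- sites[, c("region", "enzyme", "column")]
  sites$panel_index <- seq_len(nrow(sites)) - 1L
  key <- paste(sites$region, sites$enzyme, sites$column)
  if (anyDuplicated(key)) stop("duplicate diagnostic sites in panel")
  structure(sites, name = name, class = c("chlorotype_panel", "data.frame"))
}

#' The four-site chlorotype panel
#'
#' Site order: cpDNA01/AcuI, cpDNA02/TaqI, cpDNA02/Tsp45I, cpDNA03/SwaI.
#' The named four-site chlorotypes are H1 = 0101, H2 = 0011, H3 = 1110,
#' H4 = 0111.
#'
#' @return A \code{\link{chlorotype_panel}}.
#' @export
panel_4site <- function() {
  chlorotype_panel(rbind(
    diagnostic_site("cpDNA01", "AcuI"),
    diagnostic_site("cpDNA02", "TaqI"),
    diagnostic_site("cpDNA02", "Tsp45I"),
    diagnostic_site("cpDNA03", "SwaI")
  ), name = "4-site")
}

#' The extended twelve-site chlorotype panel
#'
#' The four original sites first, then the eight extension sites in order:
#' cpDNA01/Hpy188I, cpDNA01/MseI, cpDNA01/MspI, cpDNA01/TaqI,
#' cpDNA02/Hpy188I, cpDNA03/AluI, cpDNA03/ApoI, cpDNA03/MmeI.
#'
#' @return A \code{\link{chlorotype_panel}}.
#' @export
panel_12site <- function() {
  p4 <- as.data.frame(panel_4site())[, c("region", "enzyme", "column")]
  ext <- rbind(
    diagnostic_site("cpDNA01", "Hpy188I"),
    diagnostic_site("cpDNA01", "MseI"),
    diagnostic_site("cpDNA01", "MspI"),
    diagnostic_site("cpDNA01", "TaqI"),
    diagnostic_site("cpDNA02", "Hpy188I"),
    diagnostic_site("cpDNA03", "AluI"),
    diagnostic_site("cpDNA03", "ApoI"),
    diagnostic_site("cpDNA03", "MmeI")
  )
  chlorotype_panel(rbind(p4, ext), name = "12-site")
}

#' Named aliases of the four-site chlorotypes
#' @return Named character vector mapping string to alias.
#' @export
chlorotype_aliases <- function() {
  c("0101" = "H1", "0011" = "H2", "1110" = "H3", "0111" = "H4")
}

# ---- digest calls from sequences ------------------------------------------

# Hit columns of `enzyme` for one aligned sequence: scan the ungapped
# sequence (digestion happens on the molecule, not the alignment) and
# project each motif start to its alignment column.
hit_columns <- function(aligned_seq, enzyme, n_policy = "conservative") {
  um <- ungap_with_map(aligned_seq)
  hits <- scan_recognition_sites(um$ungapped, enzyme, n_policy)
  sort(unique(um$columns[hits$position + 1L]))
}

#' Call the digest state of one sample at one diagnostic site
#'
#' State \code{"1"} when the enzyme's recognition motif is present with its
#' start at the diagnostic alignment column; \code{"0"} when it is absent
#' there while the sample's remaining site set for that enzyme matches a
#' reference pattern; a novel lowercase symbol when the off-site pattern
#' matches no reference pattern (complex digestion product); \code{"?"} when
#' the motif footprint is gapped or undetermined in this sample.
#'
#' @param aligned_seq The sample's aligned region sequence (may contain "-").
#' @param site One-row diagnostic site (region, enzyme, column).
#' @param enzyme The \code{enzyme} object for the site.
#' @param reference_patterns List of reference off-site column sets for this
#'   (region, enzyme); \code{NULL} disables the novel-pattern check.
#' @param panel_columns All diagnostic columns of this (region, enzyme) in
#'   the active panel (excluded from the off-site pattern comparison).
#' @param novel_symbols Environment used to assign stable novel symbols in
#'   order of first appearance (\code{"a"}, \code{"b"}, ...).
#' @return Single character state.
#' @export
call_digest_state <- function(aligned_seq, site, enzyme,
                              reference_patterns = NULL,
                              panel_columns = site$column,
                              novel_symbols = NULL) {
  if (is.na(site$column)) {
    stop("diagnostic site ", site$region, "/", site$enzyme,
         " has no alignment column; sequence-based typing needs coordinates")
  }
  chars <- strsplit(aligned_seq, "")[[1]]
  foot <- seq.int(site$column + 1L, length.out = nchar(enzyme$recognition))
  foot <- foot[foot <= length(chars)]
  if (length(foot) < nchar(enzyme$recognition) ||
      any(chars[foot] %in% c("-", "N"))) {
    return("?")
  }
  cols <- hit_columns(aligned_seq, enzyme)
  present <- site$column %in% cols
  if (!is.null(reference_patterns)) {
    off <- setdiff(cols, panel_columns)
    known <- any(vapply(reference_patterns,
                        function(p) identical(sort(p), sort(off)), logical(1)))
    if (!known) {
      key <- paste(site$region, site$enzyme, paste(off, collapse = ","))
      return(novel_symbol_for(novel_symbols, key))
    }
  }
  if (present) "1" else "0"
}

# Stable alphabetic novel-pattern symbols per (region, enzyme, pattern),
# in order of first appearance.
novel_symbol_for <- function(env, key) {
  if (is.null(env)) return("a")
  if (!is.null(env$map[[key]])) return(env$map[[key]])
  sym <- letters[length(env$map) + 1L]
  if (length(env$map) >= 26L) sym <- "z"  # alphabet exhausted; lump
  env$map[[key]] <- sym
  sym
}

new_novel_symbol_env <- function() {
  e <- new.env(parent = emptyenv())
  e$map <- list()
  e
}

#' Type aligned region sequences into chlorotypes
#'
#' Applies \code{\link{call_digest_state}} over every sample and panel site.
#' Samples must share the column space of the reference alignments (the
#' reference may simply be the sample set itself).
#'
#' @param alignments Named list, region id -> named character vector of
#'   aligned sequences (one per sample; equal width within a region).
#' @param panel A \code{\link{chlorotype_panel}} with alignment columns set.
#' @param catalog Enzyme catalog (named list), default the shipped one.
#' @param reference_alignments Like \code{alignments}; defines the known
#'   off-site digestion patterns used to separate "0" from novel symbols.
#'   Defaults to \code{alignments}.
#' @return Named character vector of chlorotype strings (one per sample).
#' @export
type_sequences <- function(alignments, panel,
                           catalog = default_enzyme_catalog(),
                           reference_alignments = alignments) {
  samples <- Reduce(union, lapply(alignments, names))
  nse <- new_novel_symbol_env()
  # reference off-site patterns per (region, enzyme) used by the panel
  pe <- unique(as.data.frame(panel)[, c("region", "enzyme")])
  ref_patterns <- list()
  for (i in seq_len(nrow(pe))) {
    reg <- pe$region[i]; enz <- pe$enzyme[i]
    if (is.null(reference_alignments[[reg]])) next
    pcols <- panel$column[panel$region == reg & panel$enzyme == enz]
    pats <- lapply(reference_alignments[[reg]], function(s) {
      setdiff(hit_columns(s, catalog[[enz]]), pcols)
    })
    ref_patterns[[paste(reg, enz)]] <- unique(unname(pats))
  }
  out <- vapply(samples, function(sm) {
    states <- vapply(seq_len(nrow(panel)), function(i) {
      site <- panel[i, ]
      enz <- catalog[[site$enzyme]]
      if (is.null(enz)) stop("enzyme not in catalog: ", site$enzyme)
      aln <- alignments[[site$region]]
      if (is.null(aln) || !sm %in% names(aln)) return("?")
      pcols <- panel$column[panel$region == site$region &
                              panel$enzyme == site$enzyme]
      call_digest_state(aln[[sm]], site, enz,
                        reference_patterns = ref_patterns[[paste(site$region,
                                                                 site$enzyme)]],
                        panel_columns = pcols, novel_symbols = nse)
    }, character(1))
    paste(states, collapse = "")
  }, character(1))
  out
}

# ---- grouped datasets ------------------------------------------------------

#' Build a grouped chlorotype dataset
#'
#' @param sample_id,group,chlorotype Parallel vectors.
#' @param panel Optional \code{\link{chlorotype_panel}} attached as an
#'   attribute; chlorotype lengths must match its size when given.
#' @return Data frame of class \code{"grouped_dataset"} with the group levels
#'   (first-appearance order) in attribute \code{"groups"}.
#' @export
grouped_dataset <- function(sample_id, group, chlorotype, panel = NULL) {
  stopifnot(length(sample_id) == length(group),
            length(group) == length(chlorotype))
  lens <- unique(nchar(chlorotype))
  if (length(lens) > 1L) {
    stop("chlorotype strings have mixed lengths: ",
         paste(lens, collapse = ", "))
  }
  if (!is.null(panel) && length(lens) == 1L && lens != nrow(panel)) {
    stop("chlorotype length ", lens, " does not match panel size ",
         nrow(panel))
  }
  df <- data.frame(sample_id = as.character(sample_id),
                   group = as.character(group),
                   chlorotype = as.character(chlorotype),
                   stringsAsFactors = FALSE)
  structure(df, groups = unique(df$group), panel = panel,
            class = c("grouped_dataset", "data.frame"))
}

#' Drop samples with inconclusive calls
#'
#' Removes samples whose chlorotype contains \code{"?"}; the removed rows
#' are kept in attribute \code{"excluded"}.
#' @param dataset A \code{\link{grouped_dataset}}.
#' @return Filtered \code{grouped_dataset}.
#' @export
drop_inconclusive <- function(dataset) {
  bad <- grepl("?", dataset$chlorotype, fixed = TRUE)
  out <- grouped_dataset(dataset$sample_id[!bad], dataset$group[!bad],
                         dataset$chlorotype[!bad],
                         panel = attr(dataset, "panel"))
  attr(out, "excluded") <- as.data.frame(dataset)[bad, , drop = FALSE]
  out
}

#' Encode one sample's digest calls as a chlorotype string
#'
#' @param calls Data frame with columns \code{region}, \code{enzyme},
#'   \code{state} (one row per available call).
#' @param panel A \code{\link{chlorotype_panel}}.
#' @param sample_id Label used in error messages.
#' @return Chlorotype string in panel order; panel positions without a call
#'   become \code{"?"}.
#' @export
encode_chlorotype <- function(calls, panel, sample_id = "sample") {
  states <- vapply(seq_len(nrow(panel)), function(i) {
    hit <- calls$region == panel$region[i] & calls$enzyme == panel$enzyme[i]
    st <- unique(calls$state[hit])
    if (length(st) == 0L) return("?")
    if (length(st) > 1L) {
      stop("conflicting digest calls for ", sample_id, " at panel position ",
           i - 1L, " (", panel$region[i], "/", panel$enzyme[i], "): ",
           paste(st, collapse = " vs "))
    }
    st
  }, character(1))
  paste(states, collapse = "")
}

#' Per-group chlorotype frequency table
#'
#' Samples containing \code{"?"} are excluded from the percentages and
#' reported in attribute \code{"excluded"}. Percentages are over included
#' samples and sum to 100 per group up to rounding.
#'
#' @param dataset A \code{\link{grouped_dataset}}.
#' @param digits Rounding for the reported percentages (the published survey
#'   style uses integers); full precision is kept in \code{pct_exact}.
#' @return Data frame with columns \code{chlorotype}, \code{group},
#'   \code{count}, \code{pct}, \code{pct_exact}.
#' @export
tabulate_frequencies <- function(dataset, digits = 0) {
  kept <- drop_inconclusive(dataset)
  groups <- attr(dataset, "groups")
  out <- list()
  for (g in groups) {
    sub <- kept$chlorotype[kept$group == g]
    if (length(sub) == 0L) {
      stop("group '", g, "' has no resolved chlorotypes after exclusions")
    }
    tab <- table(sub)
    out[[g]] <- data.frame(chlorotype = names(tab), group = g,
                           count = as.integer(tab),
                           pct = round(100 * as.integer(tab) / length(sub),
                                       digits),
                           pct_exact = 100 * as.integer(tab) / length(sub),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res <- res[order(res$group, res$chlorotype), ]
  rownames(res) <- NULL
  attr(res, "excluded") <- attr(kept, "excluded")
  res
}

#' Cross-tabulate chlorotypes by group
#'
#' @param dataset A \code{\link{grouped_dataset}} (samples with \code{"?"}
#'   excluded first).
#' @return Integer matrix, chlorotypes x groups.
#' @export
contingency_table <- function(dataset) {
  kept <- drop_inconclusive(dataset)
  tab <- table(kept$chlorotype, factor(kept$group, levels = attr(dataset, "groups")))
  m <- matrix(as.integer(tab), nrow = nrow(tab),
              dimnames = dimnames(tab))
  m
}

# ---- digest-table interchange ---------------------------------------------

#' Write a per-sample digest-call table
#'
#' TSV layout: \code{sample_id}, \code{group}, then one column per panel
#' site named \code{<region>.<enzyme>} in panel order, each holding one
#' state symbol.
#'
#' @param dataset A \code{\link{grouped_dataset}} whose panel attribute is
#'   set (or pass \code{panel}).
#' @param path Output path.
#' @param panel Panel defining the column order.
#' @export
write_digest_table <- function(dataset, path, panel = attr(dataset, "panel")) {
  if (is.null(panel)) stop("a panel is required to name the digest columns")
  states <- do.call(rbind, strsplit(dataset$chlorotype, ""))
  colnames(states) <- paste(panel$region, panel$enzyme, sep = ".")
  df <- cbind(data.frame(sample_id = dataset$sample_id,
                         group = dataset$group, stringsAsFactors = FALSE),
              as.data.frame(states, stringsAsFactors = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-sample digest-call table
#'
#' Inverse of \code{\link{write_digest_table}}. When \code{panel} is given,
#' site columns are reordered to the panel order (they may be shuffled in
#' the file); otherwise the file's column order defines the panel.
#'
#' @param path TSV path.
#' @param panel Optional \code{\link{chlorotype_panel}}.
#' @return A \code{\link{grouped_dataset}}.
#' @export
read_digest_table <- function(path, panel = NULL) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character", check.names = FALSE,
                          comment.char = "")
  need <- c("sample_id", "group")
  if (!all(need %in% names(df))) {
    stop("digest table must have 'sample_id' and 'group' columns")
  }
  site_cols <- setdiff(names(df), need)
  if (length(site_cols) == 0L) stop("digest table has no site columns")
  parts <- strsplit(site_cols, ".", fixed = TRUE)
  if (any(lengths(parts) != 2L)) {
    stop("site column names must be <region>.<enzyme>, got: ",
         paste(site_cols[lengths(parts) != 2L], collapse = ", "))
  }
  file_panel <- chlorotype_panel(
    data.frame(region = vapply(parts, `[`, "", 1L),
               enzyme = vapply(parts, `[`, "", 2L),
               stringsAsFactors = FALSE),
    name = "file")
  if (is.null(panel)) {
    panel <- file_panel
    order_idx <- seq_along(site_cols)
  } else {
    want <- paste(panel$region, panel$enzyme, sep = ".")
    if (!setequal(want, site_cols) || length(want) != length(site_cols)) {
      stop("digest table columns do not match the panel: expected {",
           paste(want, collapse = ", "), "}")
    }
    order_idx <- match(want, site_cols)
  }
  alphabet <- c("0", "1", "?", letters)
  mat <- as.matrix(df[, site_cols, drop = FALSE])[, order_idx, drop = FALSE]
  bad <- which(!mat %in% alphabet)
  if (length(bad)) {
    rc <- arrayInd(bad[1], dim(mat))
    stop("unknown digest symbol '", mat[bad[1]], "' at row ", rc[1],
         ", column '", colnames(mat)[rc[2]], "'")
  }
  chl <- apply(mat, 1L, paste, collapse = "")
  grouped_dataset(df$sample_id, df$group, chl, panel = panel)
}
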