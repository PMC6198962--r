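# FASTA I/O, alignment projection helpers, and virtual amplicon extraction.

#' Read sequences from a FASTA file
#'
#' Reads plain or aligned FASTA (gap character \code{"-"}). Sequences are
#' uppercased; record order is preserved.
#'
#' @param path Path to a FASTA file.
#' @param strip_gaps Drop \code{"-"} characters (default keeps them, so that
#'   alignments read back unchanged).
#' @return Named character vector of sequences (names are record ids).
#' @export
read_sequences <- function(path, strip_gaps = FALSE) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("FASTA file is empty: ", path)
  seqs <- toupper(as.character(set))
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop("duplicate sequence id(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  names(seqs) <- ids
  if (strip_gaps) seqs <- gsub("-", "", seqs, fixed = TRUE)
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @param width Line wrap width.
#' @export
write_sequences <- function(seqs, path, width = 70L) {
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
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

# For one aligned sequence: 0-based alignment column of each ungapped base.
# Returns list(ungapped = string, columns = integer vector).
ungap_with_map <- function(aligned) {
  chars <- strsplit(aligned, "")[[1]]
  keep <- chars != "-"
  list(ungapped = paste(chars[keep], collapse = ""),
       columns = which(keep) - 1L)
}

#' Define an amplified region
#'
#' @param id Region label (e.g. \code{"cpDNA01"} for the trnQ-rps16 spacer).
#' @param forward_primer,reverse_primer Primer sequences, IUPAC allowed; the
#'   reverse primer is given 5'->3' on the bottom strand as usual.
#' @param expected_length_range Integer pair: plausible product size (bp).
#' @return Object of class \code{"region"}.
#' @export
region <- function(id, forward_primer, reverse_primer, expected_length_range) {
  stopifnot(nzchar(id), nzchar(forward_primer), nzchar(reverse_primer))
  expected_length_range <- as.integer(expected_length_range)
  if (length(expected_length_range) != 2L ||
      any(expected_length_range <= 0L) ||
      expected_length_range[1] > expected_length_range[2]) {
    stop("expected_length_range must be an ordered positive integer pair")
  }
  structure(list(id = id,
                 forward_primer = toupper(forward_primer),
                 reverse_primer = toupper(reverse_primer),
                 expected_length_range = expected_length_range),
            class = "region")
}

# Best primer match by sliding exhaustive scan: minimal IUPAC-aware mismatch
# count; ties broken towards the `side` end of the template. Returns
# list(position (0-based), mismatches) or NULL when above max_mismatch.
best_primer_match <- function(chars, primer, max_mismatch,
                              side = c("left", "right")) {
  side <- match.arg(side)
  m <- nchar(primer)
  L <- length(chars)
  if (L < m) return(NULL)
  pchars <- strsplit(primer, "")[[1]]
  mm <- integer(L - m + 1L)
  for (k in seq_len(m)) {
    mm <- mm + !iupac_match(pchars[k], chars[k:(L - m + k)])
  }
  best <- min(mm)
  if (best > max_mismatch) return(NULL)
  idx <- which(mm == best)
  pos <- if (side == "left") idx[1] else idx[length(idx)]
  list(position = pos - 1L, mismatches = best)
}

#' Extract a virtual PCR amplicon from a template
#'
#' Locates the forward primer and the reverse complement of the reverse
#' primer on the template (or its reverse complement) allowing up to
#' \code{max_mismatch} substitutions per primer, and returns the subsequence
#' spanning both primer footprints, oriented so the forward primer sits at
#' the 5' end. A template that is itself the amplicon is returned unchanged.
#'
#' @param template Gap-free DNA string.
#' @param region A \code{\link{region}} object.
#' @param max_mismatch Maximum substitutions tolerated per primer (default 1;
#'   indels are not modelled).
#' @param sample_id Optional label carried on the result.
#' @return Object of class \code{"amplicon"}: list with \code{sample_id},
#'   \code{region_id}, \code{sequence}, \code{strand} (strand of the template
#'   match) and \code{length_ok} (FALSE flags a product outside the region's
#'   expected size range; extraction still succeeds).
#' @export
extract_amplicon <- function(template, region, max_mismatch = 1L,
                             sample_id = NA_character_) {
  template <- toupper(template)
  if (grepl("-", template, fixed = TRUE)) {
    stop("template must be gap-free")
  }
  stopifnot(max_mismatch >= 0L)
  rc_rev <- revcomp_iupac(region$reverse_primer)

  try_strand <- function(seq, strand) {
    chars <- strsplit(seq, "")[[1]]
    f <- best_primer_match(chars, region$forward_primer, max_mismatch, "left")
    if (is.null(f)) return(NULL)
    r <- best_primer_match(chars, rc_rev, max_mismatch, "right")
    if (is.null(r)) return(NULL)
    end <- r$position + nchar(rc_rev)
    if (end <= f$position) return(NULL)
    list(sequence = substr(seq, f$position + 1L, end), strand = strand)
  }

  res <- try_strand(template, "+")
  if (is.null(res)) res <- try_strand(revcomp_iupac(template), "-")
  if (is.null(res)) {
    # rerun on + strand to name the missing primer
    chars <- strsplit(template, "")[[1]]
    f <- best_primer_match(chars, region$forward_primer, max_mismatch, "left")
    missing <- if (is.null(f)) region$forward_primer else region$reverse_primer
    stop("primer-not-found: primer '", missing, "' absent from template ",
         "of region ", region$id, " within ", max_mismatch, " mismatch(es)")
  }
  len <- nchar(res$sequence)
  rng <- region$expected_length_range
  structure(list(sample_id = sample_id, region_id = region$id,
                 sequence = res$sequence, strand = res$strand,
                 length_ok = len >= rng[1] && len <= rng[2]),
            class = "amplicon")
}

#' @export
print.amplicon <- function(x, ...) {
  cat(sprintf("<amplicon> %s/%s  %d bp  strand %s%s\n",
              x$sample_id, x$region_id, nchar(x$sequence), x$strand,
              if (x$length_ok) "" else "  [size outside expected range]"))
  invisible(x)
}
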