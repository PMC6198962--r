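# Restriction enzymes, IUPAC matching, site scanning, fragment prediction.
#
# Coordinates are 0-based, half-open, on the top strand of the scanned
# sequence throughout the package.

# IUPAC code -> the set of concrete bases it stands for.
IUPAC_EXPANSION <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Test whether a base satisfies an IUPAC motif character
#'
#' A template base matches a motif character when it belongs to the set of
#' bases the (possibly degenerate) IUPAC code stands for. An undetermined
#' template base \code{"N"} matches nothing under the default
#' \code{"conservative"} policy, so a miscalled base can never invent a
#' restriction site; under \code{"permissive"} it matches every motif
#' character.
#'
#' @param motif_char Single IUPAC character (A, C, G, T, R, Y, S, W, K, M, B,
#'   D, H, V, N).
#' @param base Single template base, one of A, C, G, T, N. Vectorised.
#' @param n_policy \code{"conservative"} (default) or \code{"permissive"}.
#' @return Logical vector, one element per \code{base}.
#' @export
iupac_match <- function(motif_char, base,
                        n_policy = c("conservative", "permissive")) {
  n_policy <- match.arg(n_policy)
  if (length(motif_char) != 1L || !motif_char %in% names(IUPAC_EXPANSION)) {
    stop("'", motif_char, "' is not an IUPAC nucleotide code")
  }
  bad <- !base %in% c("A", "C", "G", "T", "N")
  if (any(bad)) {
    stop("invalid template base(s): ", paste(unique(base[bad]), collapse = ", "))
  }
  out <- base %in% IUPAC_EXPANSION[[motif_char]]
  out[base == "N"] <- (n_policy == "permissive")
  out
}

#' Define a restriction enzyme
#'
#' @param name Short label, e.g. \code{"TaqI"}.
#' @param recognition Recognition motif as an IUPAC string (top strand).
#' @param cut_offset Cut position measured from the motif start on the top
#'   strand. May exceed the motif length for Type IIS enzymes that cut
#'   downstream of their recognition site (e.g. AcuI, MmeI).
#' @param palindromic Whether the motif equals its own reverse complement
#'   (computed from the motif when omitted). Non-palindromic enzymes are
#'   additionally scanned on the minus strand.
#' @return An object of class \code{"enzyme"}.
#' @export
restriction_enzyme <- function(name, recognition, cut_offset,
                               palindromic = NULL) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  recognition <- toupper(recognition)
  chars <- strsplit(recognition, "")[[1]]
  if (length(chars) == 0L || !all(chars %in% names(IUPAC_EXPANSION))) {
    stop("recognition motif of ", name,
         " must be a nonempty IUPAC string, got '", recognition, "'")
  }
  cut_offset <- as.integer(cut_offset)
  if (is.na(cut_offset) || cut_offset < 0L) {
    stop("cut_offset of ", name, " must be a non-negative integer")
  }
  if (is.null(palindromic)) {
    palindromic <- identical(recognition, revcomp_iupac(recognition))
  }
  structure(
    list(name = name, recognition = recognition, cut_offset = cut_offset,
         palindromic = isTRUE(palindromic)),
    class = "enzyme"
  )
}

#' @export
print.enzyme <- function(x, ...) {
  cat(sprintf("<enzyme> %s  %s  cut@%d  %s\n", x$name, x$recognition,
              x$cut_offset, if (x$palindromic) "palindromic" else "two-strand"))
  invisible(x)
}

# Reverse complement that preserves IUPAC degeneracy.
revcomp_iupac <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", D = "H", H = "D", V = "B",
            N = "N", "-" = "-")
  chars <- strsplit(toupper(x), "")[[1]]
  paste(rev(unname(comp[chars])), collapse = "")
}

#' Read an enzyme catalog from a YAML file
#'
#' The file holds a list of entries with fields \code{name},
#' \code{recognition}, \code{cut_offset} and optionally \code{palindromic}.
#'
#' @param path Path to the YAML catalog.
#' @return Named list of \code{enzyme} objects.
#' @export
read_enzyme_catalog <- function(path) {
  entries <- yaml::read_yaml(path)
  cat_list <- lapply(entries, function(e) {
    restriction_enzyme(e$name, e$recognition, e$cut_offset,
                       palindromic = e$palindromic)
  })
  names(cat_list) <- vapply(cat_list, `[[`, "", "name")
  if (anyDuplicated(names(cat_list))) {
    stop("duplicate enzyme names in catalog: ",
         paste(unique(names(cat_list)[duplicated(names(cat_list))]),
               collapse = ", "))
  }
  cat_list
}

#' The shipped ten-enzyme chlorotyping catalog
#'
#' Recognition motifs and cut offsets follow the public REBASE data for the
#' ten enzymes used on the three dogwood cpDNA non-coding regions: AcuI,
#' AluI, ApoI, Hpy188I, MmeI, MseI, MspI, SwaI, TaqI and Tsp45I. AcuI
#' (CTGAAG(16/14)) and MmeI (TCCRAC(20/18)) are Type IIS downstream cutters;
#' their chlorotype calls are driven by motif presence, with the distant cut
#' coordinate clamped to the sequence bounds during fragment prediction.
#'
#' @return Named list of \code{enzyme} objects.
#' @export
default_enzyme_catalog <- function() {
  path <- system.file("extdata", "enzymes.yaml", package = "chlorotypr",
                      mustWork = TRUE)
  read_enzyme_catalog(path)
}

#' Scan a sequence for restriction recognition sites
#'
#' Finds every position where the recognition motif matches on the top
#' strand and, for non-palindromic enzymes, every position where the reverse
#' complement of the motif matches (reported with strand \code{"-"}).
#'
#' @param sequence Gap-free DNA string over A, C, G, T, N.
#' @param enzyme An \code{enzyme} object.
#' @param n_policy Passed to \code{\link{iupac_match}}.
#' @return Data frame with columns \code{position} (0-based motif start),
#'   \code{strand} and \code{enzyme}, sorted by position.
#' @export
scan_recognition_sites <- function(sequence, enzyme,
                                   n_policy = c("conservative", "permissive")) {
  n_policy <- match.arg(n_policy)
  chars <- strsplit(toupper(sequence), "")[[1]]
  if (any(chars == "-")) stop("sequence must be gap-free; ungap it first")
  pos_plus <- motif_starts(chars, enzyme$recognition, n_policy)
  hits <- data.frame(position = pos_plus,
                     strand = rep("+", length(pos_plus)),
                     enzyme = rep(enzyme$name, length(pos_plus)),
                     stringsAsFactors = FALSE)
  if (!enzyme$palindromic) {
    pos_minus <- motif_starts(chars, revcomp_iupac(enzyme$recognition), n_policy)
    hits <- rbind(hits,
                  data.frame(position = pos_minus,
                             strand = rep("-", length(pos_minus)),
                             enzyme = rep(enzyme$name, length(pos_minus)),
                             stringsAsFactors = FALSE))
  }
  hits <- hits[order(hits$position, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

# 0-based start positions where `motif` matches the character vector `chars`.
motif_starts <- function(chars, motif, n_policy) {
  m <- nchar(motif)
  L <- length(chars)
  if (L < m) return(integer(0))
  mchars <- strsplit(motif, "")[[1]]
  ok <- rep(TRUE, L - m + 1L)
  for (k in seq_len(m)) {
    ok <- ok & iupac_match(mchars[k], chars[k:(L - m + k)], n_policy)
    if (!any(ok)) break
  }
  which(ok) - 1L
}

#' Predict restriction fragment lengths
#'
#' Cut coordinates are \code{site position + cut_offset}, clamped to the
#' sequence bounds; fragment lengths are the gaps between consecutive
#' distinct cut coordinates plus the two ends. Fragment lengths always sum
#' to the sequence length, and an uncut sequence yields one fragment.
#'
#' @inheritParams scan_recognition_sites
#' @return Sorted integer vector of fragment lengths (bp).
#' @export
digest_fragments <- function(sequence, enzyme,
                             n_policy = c("conservative", "permissive")) {
  L <- nchar(sequence)
  hits <- scan_recognition_sites(sequence, enzyme, n_policy)
  cuts <- pmin(pmax(hits$position + enzyme$cut_offset, 0L), L)
  cuts <- sort(unique(cuts))
  cuts <- cuts[cuts > 0L & cuts < L]
  frags <- diff(c(0L, cuts, L))
  sort(frags)
}
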