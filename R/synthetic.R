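# Seeded generators: sequence collections with controlled digest states,
# grouped sample collections at specified chlorotype frequencies, and the
# largest-remainder reconstructor for count tables printed as percentages.

#' Specify a synthetic chlorotyping study
#'
#' Defines haplotype classes (target chlorotype strings), the panel they are
#' scored on, the region lengths, and grouped collections drawn at given
#' chlorotype frequencies. Region lengths default to the alignment sizes of
#' the three dogwood cpDNA non-coding regions (1667, 986, 907 bp).
#'
#' @param haplotypes Data frame with columns \code{name}, \code{chlorotype}
#'   (binary strings of panel length).
#' @param groups Data frame with columns \code{label}, \code{size}, plus a
#'   list-column \code{freqs} of named frequency vectors over haplotype
#'   names (each summing to 1).
#' @param panel A \code{\link{chlorotype_panel}} (alignment columns are
#'   assigned by the generator).
#' @param regions Data frame with columns \code{id}, \code{length}.
#' @param missing_rate Probability of replacing a call by \code{"?"}.
#' @param primer_length Length of the synthetic primers flanking each
#'   region.
#' @param seed Integer seed; every generated byte is a deterministic
#'   function of the spec including this seed.
#' @return Object of class \code{"synthetic_spec"}.
#' @export
synthetic_spec <- function(haplotypes, groups = NULL, panel = panel_12site(),
                           regions = data.frame(
                             id = c("cpDNA01", "cpDNA02", "cpDNA03"),
                             length = c(1667L, 986L, 907L),
                             stringsAsFactors = FALSE),
                           missing_rate = 0, primer_length = 20L, seed = 1L) {
  stopifnot(is.data.frame(haplotypes),
            all(c("name", "chlorotype") %in% names(haplotypes)))
  if (any(nchar(haplotypes$chlorotype) != nrow(panel))) {
    stop("haplotype chlorotype length must equal panel size ", nrow(panel))
  }
  if (!all(unique(panel$region) %in% regions$id)) {
    stop("panel uses regions absent from the region table")
  }
  max_motif <- max(nchar(vapply(default_enzyme_catalog(), `[[`, "",
                                "recognition")))
  if (any(regions$length < max_motif + 2L * primer_length)) {
    stop("region lengths must be at least max motif + 2 x primer length")
  }
  if (!is.null(groups)) {
    stopifnot(all(c("label", "size", "freqs") %in% names(groups)))
    for (i in seq_len(nrow(groups))) {
      f <- groups$freqs[[i]]
      if (abs(sum(f) - 1) > 1e-8 || any(f < 0)) {
        stop("frequency vector of group '", groups$label[i],
             "' must be non-negative and sum to 1")
      }
      if (!all(names(f) %in% haplotypes$name)) {
        stop("group '", groups$label[i], "' references unknown haplotypes")
      }
    }
  }
  stopifnot(missing_rate >= 0, missing_rate <= 1)
  structure(list(haplotypes = haplotypes, groups = groups, panel = panel,
                 regions = regions, missing_rate = missing_rate,
                 primer_length = as.integer(primer_length),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# Deterministic concrete instantiation of an IUPAC motif (first base of each
# expansion, e.g. RAATTY -> AAATTC).
concretize_motif <- function(motif) {
  chars <- strsplit(motif, "")[[1]]
  paste(vapply(chars, function(ch) IUPAC_EXPANSION[[ch]][1], ""),
        collapse = "")
}

# Check a cut/uncut window pair in context: for every catalog enzyme the
# hit-position sets must be identical between the two variants, except the
# target enzyme, which must hit exactly at `offset` in the cut variant and
# nowhere new in the uncut one.
window_pair_ok <- function(ctx_cut, ctx_uncut, offset, target, catalog) {
  for (enz in catalog) {
    h1 <- scan_recognition_sites(ctx_cut, enz)$position
    h0 <- scan_recognition_sites(ctx_uncut, enz)$position
    if (enz$name == target) {
      if (!(offset %in% h1)) return(FALSE)
      if (!setequal(setdiff(h1, offset), h0)) return(FALSE)
    } else {
      if (!setequal(h1, h0)) return(FALSE)
    }
  }
  TRUE
}

#' Generate per-haplotype region sequences realising target chlorotypes
#'
#' Builds, for every region, a shared random background scrubbed so that the
#' only digest-relevant differences between haplotypes sit at the diagnostic
#' loci: each panel site gets a dedicated locus carrying the enzyme's
#' recognition motif when the haplotype's target symbol is "1" and a
#' single-substitution broken motif when it is "0". Candidate substitutions
#' are rejected (with local background resampling, bounded retries) whenever
#' they would create or destroy a recognition site of any other catalog
#' enzyme in the surrounding context. Synthetic primers are attached at both
#' ends so the sequences behave as complete amplicons.
#'
#' @param spec A \code{\link{synthetic_spec}}.
#' @param catalog Enzyme catalog used for placement and scrubbing.
#' @return List with \code{sequences} (region id -> named character vector,
#'   one sequence per haplotype), \code{panel} (the spec's panel with
#'   alignment columns filled in), and \code{regions} (named list of
#'   \code{\link{region}} objects with the synthetic primers).
#' @export
generate_haplotype_sequences <- function(spec,
                                         catalog = default_enzyme_catalog()) {
  set.seed(spec$seed)
  panel <- spec$panel
  if (!all(strsplit(paste(spec$haplotypes$chlorotype, collapse = ""),
                    "")[[1]] %in% c("0", "1"))) {
    stop("generated haplotypes must have binary target chlorotypes")
  }
  max_motif <- max(nchar(vapply(catalog, `[[`, "", "recognition")))
  flank <- max_motif - 1L
  pl <- spec$primer_length
  sequences <- list()
  region_defs <- list()
  panel$column <- NA_integer_
  hapmat <- do.call(rbind, strsplit(spec$haplotypes$chlorotype, ""))
  rownames(hapmat) <- spec$haplotypes$name

  for (ri in seq_len(nrow(spec$regions))) {
    reg_id <- spec$regions$id[ri]
    L <- spec$regions$length[ri]
    fwd <- paste(sample(c("A", "C", "G", "T"), pl, replace = TRUE),
                 collapse = "")
    rev_rc <- paste(sample(c("A", "C", "G", "T"), pl, replace = TRUE),
                    collapse = "")
    interior_len <- L - 2L * pl
    background <- sample(c("A", "C", "G", "T"), interior_len, replace = TRUE)
    site_idx <- which(panel$region == reg_id)
    loci <- integer(0)
    variants <- list()  # per site: list(cut = chars, uncut = chars, at = pos)
    if (length(site_idx)) {
      margin <- 2L * flank + 2L
      span <- interior_len - 2L * margin
      loci <- margin + round(span * (seq_along(site_idx) - 0.5) /
                               length(site_idx))
      for (s in seq_along(site_idx)) {
        enz <- catalog[[panel$enzyme[site_idx[s]]]]
        if (is.null(enz)) stop("enzyme not in catalog: ",
                               panel$enzyme[site_idx[s]])
        motif <- concretize_motif(enz$recognition)
        m <- nchar(motif)
        at <- loci[s]  # 0-based offset of the motif start in the interior
        placed <- FALSE
        for (attempt in 1:50) {
          ctx_range <- (at - flank + 1L):(at + m + flank)
          ctx <- background[ctx_range]
          ctx_cut <- ctx
          ctx_cut[flank + seq_len(m)] <- strsplit(motif, "")[[1]]
          # try every single-base substitution inside the motif
          done <- FALSE
          for (p in seq_len(m)) {
            for (b in setdiff(c("A", "C", "G", "T"),
                              ctx_cut[flank + p])) {
              ctx_uncut <- ctx_cut
              ctx_uncut[flank + p] <- b
              if (window_pair_ok(paste(ctx_cut, collapse = ""),
                                 paste(ctx_uncut, collapse = ""),
                                 flank, enz$name, catalog)) {
                variants[[as.character(site_idx[s])]] <-
                  list(cut = ctx_cut[flank + seq_len(m)],
                       uncut = ctx_uncut[flank + seq_len(m)], at = at)
                background[ctx_range] <- ctx_cut  # flanks now frozen
                done <- TRUE
                break
              }
            }
            if (done) break
          }
          if (done) { placed <- TRUE; break }
          # resample the flanks and retry
          background[(at - flank + 1L):at] <-
            sample(c("A", "C", "G", "T"), flank, replace = TRUE)
          background[(at + m + 1L):(at + m + flank)] <-
            sample(c("A", "C", "G", "T"), flank, replace = TRUE)
        }
        if (!placed) {
          stop("motif placement conflict for ", reg_id, "/", enz$name,
               " after bounded retries")
        }
        panel$column[site_idx[s]] <- pl + at
      }
    }
    # assemble per-haplotype sequences
    seqs <- vapply(rownames(hapmat), function(h) {
      interior <- background
      for (s in seq_along(site_idx)) {
        v <- variants[[as.character(site_idx[s])]]
        sym <- hapmat[h, site_idx[s]]
        win <- if (sym == "1") v$cut else v$uncut
        interior[(v$at + 1L):(v$at + length(win))] <- win
      }
      paste0(fwd, paste(interior, collapse = ""), rev_rc)
    }, character(1))
    sequences[[reg_id]] <- seqs
    region_defs[[reg_id]] <- region(
      reg_id, fwd, revcomp_iupac(rev_rc),
      expected_length_range = c(L - 50L, L + 50L))
  }
  # global consistency: per enzyme, haplotypes may differ only at that
  # enzyme's own diagnostic columns
  for (reg_id in names(sequences)) {
    for (enz in catalog) {
      cols <- lapply(sequences[[reg_id]], hit_columns, enzyme = enz)
      allowed <- panel$column[panel$region == reg_id &
                                panel$enzyme == enz$name]
      diffcols <- setdiff(Reduce(union, cols), Reduce(intersect, cols))
      if (!all(diffcols %in% allowed)) {
        stop("internal placement error: incidental ", enz$name,
             " polymorphism in ", reg_id, " at column(s) ",
             paste(setdiff(diffcols, allowed), collapse = ", "))
      }
    }
  }
  list(sequences = sequences, panel = panel, regions = region_defs)
}

#' Reconstruct integer counts from printed percentages
#'
#' counts = round(pct * n / 100); when the rounded counts do not sum to
#' \code{n}, a largest-remainder correction is applied (flagged in attribute
#' \code{"corrected"}). Order is preserved.
#'
#' @param pct Non-negative percentage vector (names kept).
#' @param n Group size.
#' @return Integer vector summing to \code{n}.
#' @export
reconstruct_counts_from_percentages <- function(pct, n) {
  if (any(pct < 0) || n <= 0) stop("percentages must be >= 0 and n > 0")
  q <- pct * n / 100
  counts <- round(q)
  corrected <- FALSE
  delta <- n - sum(counts)
  while (delta != 0) {
    corrected <- TRUE
    resid <- q - counts
    if (delta > 0) {
      i <- which.max(resid)
      counts[i] <- counts[i] + 1L
      delta <- delta - 1L
    } else {
      elig <- which(counts > 0)
      i <- elig[which.min(resid[elig])]
      counts[i] <- counts[i] - 1L
      delta <- delta + 1L
    }
  }
  counts <- stats::setNames(as.integer(counts), names(pct))
  attr(counts, "corrected") <- corrected
  counts
}

#' Generate a grouped sample collection from a synthetic spec
#'
#' In \code{"exact"} mode each group receives round-to-count numbers of each
#' haplotype (largest-remainder corrected); in \code{"multinomial"} mode
#' haplotypes are drawn independently at the given frequencies. Inconclusive
#' calls (\code{"?"}) are injected independently per panel position at the
#' spec's \code{missing_rate}. Fully reproducible given the spec (seed
#' included).
#'
#' @param spec A \code{\link{synthetic_spec}} with groups defined.
#' @param mode \code{"exact"} (default) or \code{"multinomial"}.
#' @return A \code{\link{grouped_dataset}} with the spec's panel attached
#'   and the source haplotype name per sample in column \code{haplotype}.
#' @export
generate_sample_collection <- function(spec, mode = c("exact", "multinomial")) {
  mode <- match.arg(mode)
  if (is.null(spec$groups)) stop("spec defines no groups")
  set.seed(spec$seed + 1L)
  chl <- stats::setNames(spec$haplotypes$chlorotype, spec$haplotypes$name)
  rows <- list()
  for (i in seq_len(nrow(spec$groups))) {
    lab <- spec$groups$label[i]
    size <- spec$groups$size[i]
    f <- spec$groups$freqs[[i]]
    haps <- if (mode == "exact") {
      cnt <- reconstruct_counts_from_percentages(100 * f, size)
      rep(names(f), cnt)
    } else {
      sample(names(f), size, replace = TRUE, prob = f)
    }
    rows[[i]] <- data.frame(
      sample_id = sprintf("%s_%04d", lab, seq_len(size)),
      group = lab, haplotype = haps, chlorotype = unname(chl[haps]),
      stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  if (spec$missing_rate > 0) {
    w <- nrow(spec$panel)
    mat <- do.call(rbind, strsplit(df$chlorotype, ""))
    mask <- matrix(stats::runif(nrow(mat) * w) < spec$missing_rate,
                   nrow(mat), w)
    mat[mask] <- "?"
    df$chlorotype <- apply(mat, 1L, paste, collapse = "")
  }
  out <- grouped_dataset(df$sample_id, df$group, df$chlorotype,
                         panel = spec$panel)
  out$haplotype <- df$haplotype
  out
}

#' Write a synthetic collection as per-region FASTA plus sample sheet
#'
#' Emits one multi-FASTA per region (a record per sample, carrying that
#' sample's haplotype sequence) and a TSV sample sheet, compatible with the
#' sequence-typing entry points.
#'
#' @param collection Result of \code{\link{generate_sample_collection}}
#'   (must retain the \code{haplotype} column).
#' @param haps Result of \code{\link{generate_haplotype_sequences}} from the
#'   same spec.
#' @param dir Output directory (created).
#' @return Invisible list of written paths.
#' @export
write_synthetic_fasta <- function(collection, haps, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  for (reg in names(haps$sequences)) {
    seqs <- haps$sequences[[reg]][collection$haplotype]
    names(seqs) <- collection$sample_id
    p <- file.path(dir, paste0(reg, ".fasta"))
    write_sequences(seqs, p)
    paths[[reg]] <- p
  }
  sheet <- file.path(dir, "samples.tsv")
  utils::write.table(as.data.frame(collection)[, c("sample_id", "group")],
                     sheet, sep = "\t", quote = FALSE, row.names = FALSE)
  paths$sample_sheet <- sheet
  invisible(paths)
}
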