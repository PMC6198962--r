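# Shared fixtures and independent mini-oracles used across test files.

# Independent IUPAC motif scanner built on base regex (used as an oracle for
# the package's character-wise scanner). Template N intentionally matches
# nothing, mirroring the conservative default.
oracle_motif_starts <- function(sequence, motif) {
  classes <- c(A = "A", C = "C", G = "G", T = "T", R = "[AG]", Y = "[CT]",
               S = "[CG]", W = "[AT]", K = "[GT]", M = "[AC]", B = "[CGT]",
               D = "[AGT]", H = "[ACT]", V = "[ACG]", N = "[ACGT]")
  pat <- paste(classes[strsplit(motif, "")[[1]]], collapse = "")
  m <- gregexpr(paste0("(?=", pat, ")"), sequence, perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m) - 1L
}

# Oracle for site scanning incl. minus strand of non-palindromic enzymes.
oracle_scan <- function(sequence, enzyme) {
  pos <- oracle_motif_starts(sequence, enzyme$recognition)
  if (!enzyme$palindromic) {
    pos <- sort(union(pos, oracle_motif_starts(
      sequence, chlorotypr:::revcomp_iupac(enzyme$recognition))))
  }
  pos
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Direct-summation AMOVA oracle: naive loops over all individual pairs,
# following the variance-component formulas step by step.
oracle_amova <- function(chlorotypes, group) {
  mat <- do.call(rbind, strsplit(chlorotypes, ""))
  N <- nrow(mat)
  d2 <- function(i, j) sum(mat[i, ] != mat[j, ])
  ssd_total <- 0
  for (i in seq_len(N - 1)) for (j in (i + 1):N) {
    ssd_total <- ssd_total + d2(i, j)
  }
  ssd_total <- ssd_total / N
  groups <- unique(group)
  wt <- numeric(length(groups))
  names(wt) <- groups
  for (g in groups) {
    idx <- which(group == g)
    s <- 0
    if (length(idx) > 1) {
      for (a in seq_len(length(idx) - 1)) for (b in (a + 1):length(idx)) {
        s <- s + d2(idx[a], idx[b])
      }
    }
    wt[g] <- s / length(idx)
  }
  ssd_within <- sum(wt)
  ssd_among <- ssd_total - ssd_within
  G <- length(groups)
  ng <- as.vector(table(factor(group, levels = groups)))
  ms_among <- ssd_among / (G - 1)
  ms_within <- ssd_within / (N - G)
  n0 <- (N - sum(ng^2) / N) / (G - 1)
  sigma2_within <- ms_within
  sigma2_among <- (ms_among - ms_within) / n0
  list(ssd_among = ssd_among, ssd_within = ssd_within,
       ssd_total = ssd_total,
       sigma2_among = sigma2_among, sigma2_within = sigma2_within,
       pct_among = 100 * max(sigma2_among, 0) /
         (max(sigma2_among, 0) + max(sigma2_within, 0)),
       contributions = 100 * wt / ssd_within)
}

# Random binary chlorotype strings.
random_chlorotypes <- function(n, width) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("0", "1"), width, replace = TRUE), collapse = "")
  }, character(1))
}

# All spanning trees of a complete graph on n nodes via Pruefer sequences;
# returns the minimal total weight (exhaustive MST oracle, n <= 7).
oracle_min_spanning_weight <- function(D) {
  n <- nrow(D)
  if (n == 2L) return(D[1, 2])
  seqs <- as.matrix(expand.grid(rep(list(seq_len(n)), n - 2L)))
  best <- Inf
  for (r in seq_len(nrow(seqs))) {
    prufer <- seqs[r, ]
    degree <- rep(1L, n)
    for (v in prufer) degree[v] <- degree[v] + 1L
    w <- 0
    pq <- prufer
    deg <- degree
    for (v in pq) {
      leaf <- which(deg == 1L)[1]
      w <- w + D[leaf, v]
      deg[leaf] <- deg[leaf] - 1L
      deg[v] <- deg[v] - 1L
    }
    last <- which(deg == 1L)
    w <- w + D[last[1], last[2]]
    best <- min(best, w)
  }
  best
}

# A small fixed 4-site study spec used by several files.
toy_4site_spec <- function(seed = 11L, groups = NULL) {
  synthetic_spec(
    data.frame(name = c("H1", "H2", "H3", "H4"),
               chlorotype = c("0101", "0011", "1110", "0111"),
               stringsAsFactors = FALSE),
    groups = groups, panel = panel_4site(),
    regions = data.frame(id = c("cpDNA01", "cpDNA02", "cpDNA03"),
                         length = c(400L, 300L, 300L),
                         stringsAsFactors = FALSE),
    seed = seed)
}
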