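# Population statistics on grouped chlorotype collections: Pearson
# chi-square, AMOVA with Monte-Carlo permutation, per-group within-variation
# contributions.

#' Pearson chi-square test on a chlorotype contingency table
#'
#' Plain Pearson X^2 (no continuity correction). Rows or columns with zero
#' marginal total are dropped with a warning (their expected counts are
#' zero); expected counts below 5 are reported with a warning but the table
#' is not collapsed.
#'
#' @param table Non-negative integer matrix, chlorotypes x groups.
#' @return List with \code{statistic}, \code{df}, \code{p_value},
#'   \code{expected}.
#' @export
pearson_chisq <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0)) stop("contingency table has negative cells")
  rz <- rowSums(table) == 0
  cz <- colSums(table) == 0
  if (any(rz) || any(cz)) {
    warning("dropping ", sum(rz), " zero-marginal row(s) and ", sum(cz),
            " zero-marginal column(s) (expected counts would be 0)")
    table <- table[!rz, !cz, drop = FALSE]
  }
  if (nrow(table) < 2L || ncol(table) < 2L) {
    stop("degenerate contingency table: need at least 2 rows and 2 columns ",
         "with positive marginals")
  }
  res <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  if (any(res$expected < 5)) {
    warning(sum(res$expected < 5), " cell(s) have expected count < 5; ",
            "the chi-square approximation may be rough")
  }
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p_value = res$p.value, expected = res$expected)
}

# Squared inter-individual distances for AMOVA. hamming: count of differing
# panel symbols (equals squared Euclidean distance on 0/1 site vectors;
# novel symbols differ from both 0 and 1). nei: -ln(matching fraction),
# taken as the squared distance.
squared_distance_matrix <- function(chlorotypes,
                                    distance = c("hamming", "nei")) {
  distance <- match.arg(distance)
  if (any(grepl("?", chlorotypes, fixed = TRUE))) {
    stop("chlorotypes contain '?'; drop inconclusive samples first")
  }
  mat <- do.call(rbind, strsplit(chlorotypes, ""))
  L <- ncol(mat)
  n <- nrow(mat)
  D <- matrix(0, n, n)
  for (j in seq_len(L)) {
    D <- D + outer(mat[, j], mat[, j], "!=")
  }
  if (distance == "nei") {
    m <- L - D
    D <- ifelse(m == 0, Inf, -log(m / L))
    diag(D) <- 0
  }
  D
}

# Within-group SSD terms for a grouping: sum_g (1/n_g) sum_{i<j in g} d2.
ssd_within_terms <- function(D2, group) {
  vapply(unique(group), function(g) {
    idx <- which(group == g)
    sum(D2[idx, idx]) / (2 * length(idx))
  }, numeric(1))
}

#' Analysis of molecular variance (AMOVA) on chlorotypes
#'
#' One-level AMOVA partitioning squared inter-individual distances into
#' among-group and within-group components, with a Monte-Carlo permutation
#' test that shuffles individuals across groups keeping group sizes fixed.
#' With the default Hamming metric the squared distance between two samples
#' is the number of differing panel positions.
#'
#' SSD_total = (1/N) sum_{i<j} d2(i,j); SSD_within = sum_g (1/n_g)
#' sum_{i<j in g} d2; SSD_among is their difference. Mean squares use
#' df_among = G-1 and df_within = N-G; sigma2_within = MS_within and
#' sigma2_among = (MS_among - MS_within)/n0 with n0 = (N - sum n_g^2/N)/(G-1).
#' Negative variance components are floored at zero for the percentage
#' report (flagged). The permutation p-value is
#' (1 + #[sigma2_among_perm >= observed]) / (n_perm + 1).
#'
#' @param dataset A \code{\link{grouped_dataset}} free of \code{"?"} calls
#'   (use \code{\link{drop_inconclusive}}).
#' @param distance \code{"hamming"} (default) or \code{"nei"}.
#' @param n_perm Number of label permutations (999 by default).
#' @param seed Integer seed for the permutations; required for reproducible
#'   p-values.
#' @return Object of class \code{"amova_result"}: list with the sums of
#'   squared deviations, degrees of freedom, mean squares, variance
#'   components, percentage partition, permutation p-value, and per-group
#'   within-group contributions (percent of SSD_within).
#' @export
amova <- function(dataset, distance = c("hamming", "nei"), n_perm = 999,
                  seed = NULL) {
  distance <- match.arg(distance)
  groups <- attr(dataset, "groups")
  if (length(groups) < 2L) stop("AMOVA needs at least 2 groups")
  ng <- table(factor(dataset$group, levels = groups))
  if (any(ng == 0L)) {
    stop("empty group(s): ", paste(groups[ng == 0L], collapse = ", "))
  }
  D2 <- squared_distance_matrix(dataset$chlorotype, distance)
  N <- nrow(D2)
  G <- length(groups)
  ssd_total <- sum(D2) / (2 * N)
  wt <- ssd_within_terms(D2, dataset$group)
  ssd_within <- sum(wt)
  ssd_among <- ssd_total - ssd_within
  df_among <- G - 1L
  df_within <- N - G
  ms_among <- ssd_among / df_among
  ms_within <- ssd_within / df_within
  n0 <- (N - sum(ng^2) / N) / (G - 1)
  sigma2_within <- ms_within
  sigma2_among <- (ms_among - ms_within) / n0

  degenerate <- ssd_total == 0
  flag_negative <- FALSE
  if (degenerate) {
    pct_among <- pct_within <- NA_real_
  } else {
    a <- sigma2_among; w <- sigma2_within
    if (a < 0 || w < 0) {
      flag_negative <- TRUE
      a <- max(a, 0); w <- max(w, 0)
    }
    pct_among <- 100 * a / (a + w)
    pct_within <- 100 * w / (a + w)
  }
  contributions <- if (ssd_within > 0) 100 * wt / ssd_within else
    stats::setNames(rep(NA_real_, G), names(wt))

  p_perm <- NA_real_
  if (n_perm > 0 && !degenerate) {
    if (!is.null(seed)) set.seed(seed)
    grp <- dataset$group
    hits <- 0L
    for (b in seq_len(n_perm)) {
      pg <- sample(grp)
      ssd_w_p <- sum(ssd_within_terms(D2, pg))
      ms_a_p <- (ssd_total - ssd_w_p) / df_among
      ms_w_p <- ssd_w_p / df_within
      if ((ms_a_p - ms_w_p) / n0 >= sigma2_among) hits <- hits + 1L
    }
    p_perm <- (1 + hits) / (n_perm + 1)
  }

  structure(list(
    ssd_among = ssd_among, ssd_within = ssd_within, ssd_total = ssd_total,
    df_among = df_among, df_within = df_within,
    ms_among = ms_among, ms_within = ms_within,
    sigma2_among = sigma2_among, sigma2_within = sigma2_within,
    pct_among = pct_among, pct_within = pct_within,
    negative_component_floored = flag_negative, degenerate = degenerate,
    p_perm = p_perm, n_perm = n_perm,
    within_contributions = contributions,
    distance = distance, n = N, groups = as.vector(ng)
  ), class = "amova_result")
}

#' @export
print.amova_result <- function(x, ...) {
  cat("AMOVA (", x$distance, " squared distances, N = ", x$n, ", ",
      length(x$groups), " groups)\n", sep = "")
  if (x$degenerate) {
    cat("  all individuals identical: variance components undefined\n")
    return(invisible(x))
  }
  cat(sprintf("  among groups : SSD %.3f  df %d  sigma2 %.4f  %5.1f%%\n",
              x$ssd_among, x$df_among, x$sigma2_among, x$pct_among))
  cat(sprintf("  within groups: SSD %.3f  df %d  sigma2 %.4f  %5.1f%%\n",
              x$ssd_within, x$df_within, x$sigma2_within, x$pct_within))
  if (x$negative_component_floored) {
    cat("  (a negative variance component was floored at 0 for percentages)\n")
  }
  cat(sprintf("  permutation p = %.4g (%d permutations)\n", x$p_perm, x$n_perm))
  cat("  within-group contributions [%]:\n")
  for (g in names(x$within_contributions)) {
    cat(sprintf("    %-24s %5.1f\n", g, x$within_contributions[[g]]))
  }
  invisible(x)
}

#' Per-group contributions to the within-group variation
#'
#' contribution_g = 100 * [(1/n_g) sum_{i<j in g} d2] / SSD_within; the
#' contributions sum to 100. Undefined (all NA, with a warning) when
#' SSD_within is zero.
#'
#' @inheritParams amova
#' @return Named numeric vector of percentages, one per group.
#' @export
within_group_contributions <- function(dataset,
                                       distance = c("hamming", "nei")) {
  distance <- match.arg(distance)
  D2 <- squared_distance_matrix(dataset$chlorotype, distance)
  wt <- ssd_within_terms(D2, dataset$group)
  tot <- sum(wt)
  if (tot == 0) {
    warning("SSD_within is zero; contributions undefined")
    return(stats::setNames(rep(NA_real_, length(wt)), names(wt)))
  }
  100 * wt / tot
}
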