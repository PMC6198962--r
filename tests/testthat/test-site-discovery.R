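# Panel extension: polymorphic columns, informative digest discovery,
# greedy minimal panels, variable-site proportions.

test_that("polymorphic columns are located exactly", {
  aln <- c(a = "ACGTACGTAC", b = "ACGTACGTAC")
  expect_equal(nrow(find_polymorphic_columns(aln)), 0L)

  aln["b"] <- "ACGTTCGTAC"
  poly <- find_polymorphic_columns(aln)
  expect_equal(poly$column, 4L)
  expect_false(poly$indel)

  expect_error(find_polymorphic_columns(c(a = "ACGT", b = "ACG")), "ragged")
})

test_that("mixed SNP and gap columns match an exhaustive per-column check", {
  set.seed(17)
  base <- strsplit(random_dna(40), "")[[1]]
  aln <- vapply(1:4, function(i) paste(base, collapse = ""), "")
  names(aln) <- paste0("s", 1:4)
  m <- do.call(rbind, strsplit(aln, ""))
  m[2, 5] <- "T"; m[3, 5] <- if (base[5] == "G") "C" else "G"
  m[1, 12] <- "-"                       # pure indel, not polymorphic
  m[4, 20] <- "-"; m[2, 20] <- if (base[20] == "A") "C" else "A"
  aln <- apply(m, 1, paste, collapse = "")
  got <- find_polymorphic_columns(aln)
  expected <- which(vapply(seq_len(ncol(m)), function(j) {
    length(unique(m[m[, j] != "-", j])) >= 2
  }, logical(1))) - 1L
  expect_equal(got$column, expected)
  expect_equal(got$indel, c(FALSE, TRUE)[match(got$column, c(4L, 19L))])
})

test_that("a substitution breaking TCGA yields one TaqI diagnostic site", {
  cat10 <- default_enzyme_catalog()
  aln <- c(x = "AATCGATT", y = "AATCGGTT")   # TCGA vs TCGG at column 2
  sites <- discover_informative_digests(list(r = aln),
                                        catalog = cat10["TaqI"])
  expect_equal(nrow(sites), 1L)
  expect_equal(sites$enzyme, "TaqI")
  expect_equal(sites$column, 2L)
  expect_equal(sites$partition, "10")
})

test_that("discovery matches exhaustive enzyme-by-column enumeration", {
  cat10 <- default_enzyme_catalog()
  set.seed(8)
  for (rep in 1:5) {
    aln <- vapply(1:4, function(i) random_dna(120), "")
    names(aln) <- paste0("s", 1:4)
    got <- discover_informative_digests(list(reg = aln), cat10)
    # oracle: regex-scan every sequence per enzyme and compare column sets
    expected <- list()
    for (enz in cat10) {
      cols <- lapply(aln, oracle_scan, enzyme = enz)
      for (cc in sort(unique(unlist(cols)))) {
        pres <- vapply(cols, function(x) cc %in% x, logical(1))
        if (any(pres) && !all(pres)) {
          expected[[length(expected) + 1L]] <-
            c(enz$name, cc, paste(as.integer(pres), collapse = ""))
        }
      }
    }
    exp_df <- if (length(expected)) {
      do.call(rbind.data.frame, expected)
    } else data.frame(a = character(0), b = character(0), c = character(0))
    names(exp_df) <- c("enzyme", "column", "partition")
    exp_df$column <- as.integer(exp_df$column)
    exp_df <- exp_df[order(exp_df$enzyme, exp_df$column), ]
    o <- order(got$enzyme, got$column)
    expect_equal(got$enzyme[o], exp_df$enzyme)
    expect_equal(got$column[o], exp_df$column)
    expect_equal(got$partition[o], exp_df$partition)
  }
})

test_that("every discovered site induces a non-trivial bipartition", {
  set.seed(12)
  for (rep in 1:5) {
    aln <- vapply(1:5, function(i) random_dna(150), "")
    names(aln) <- paste0("s", 1:5)
    sites <- discover_informative_digests(list(reg = aln))
    for (p in sites$partition) {
      expect_true(grepl("1", p) && grepl("0", p))
    }
  }
})

test_that("adding a sequence never removes a site that still splits a pair", {
  set.seed(23)
  for (rep in 1:3) {
    aln <- vapply(1:4, function(i) random_dna(100), "")
    names(aln) <- paste0("s", 1:4)
    before <- discover_informative_digests(list(reg = aln))
    aln2 <- c(aln, s5 = random_dna(100))
    after <- discover_informative_digests(list(reg = aln2))
    key_b <- paste(before$enzyme, before$column)
    key_a <- paste(after$enzyme, after$column)
    still_split <- vapply(before$partition, function(p) {
      grepl("1", p) && grepl("0", p)
    }, logical(1))
    expect_true(all(key_b[still_split] %in% key_a))
  }
})

test_that("greedy minimal panels match exhaustive subset search", {
  # 4 haplotypes separable by 2 of 5 sites
  sites <- data.frame(
    region = "r", enzyme = paste0("E", 1:5), column = 1:5 * 10L,
    partition = c("1100", "1010", "0110", "1110", "0001"),
    stringsAsFactors = FALSE)
  pan <- select_minimal_panel(sites)
  expect_equal(nrow(pan), 2L)
  # exhaustive: what the full set separates must be separated by the panel
  split_pairs <- function(partitions) {
    prs <- combn(4, 2)
    Reduce(`|`, lapply(partitions, function(p) {
      ch <- strsplit(p, "")[[1]]
      ch[prs[1, ]] != ch[prs[2, ]]
    }))
  }
  chosen <- sites$partition[paste(sites$region, sites$enzyme, sites$column) %in%
                              paste(pan$region, pan$enzyme, pan$column)]
  expect_equal(split_pairs(chosen), split_pairs(sites$partition))
  best_size <- min(vapply(1:5, function(k) {
    combos <- combn(5, k, simplify = FALSE)
    hit <- vapply(combos, function(cc) {
      identical(split_pairs(sites$partition[cc]), split_pairs(sites$partition))
    }, logical(1))
    if (any(hit)) k else 99L
  }, numeric(1)))
  expect_equal(nrow(pan), best_size)

  expect_equal(nrow(select_minimal_panel(sites[0, ])), 0L)
})

test_that("the published 12-site partitions stay fully separated after selection", {
  types <- chlorotype_survey_frequencies("twelve_site")$chlorotype
  mat <- do.call(rbind, strsplit(types, ""))
  sites <- data.frame(region = "r", enzyme = sprintf("E%02d", 1:12),
                      column = 1:12, stringsAsFactors = FALSE)
  sites$partition <- apply(mat, 2, paste, collapse = "")
  pan <- select_minimal_panel(sites)
  idx <- match(paste(pan$region, pan$enzyme, pan$column),
               paste(sites$region, sites$enzyme, sites$column))
  reduced <- apply(mat[, sort(idx), drop = FALSE], 1, paste, collapse = "")
  expect_equal(length(unique(reduced)), 16L)
})

test_that("variable-site proportion counts polymorphic columns over width", {
  aln <- c(a = "ACGTACGTAC", b = "ACGTACGTAC")
  expect_equal(variable_site_proportion(aln)$pct, 0)
  aln["b"] <- "ACGTTCGTAC"
  vs <- variable_site_proportion(aln)
  expect_equal(vs$pct, 10)
  expect_equal(vs$length, 10L)
  set.seed(4)
  big <- c(a = random_dna(80), b = random_dna(80), c = random_dna(80))
  expect_equal(variable_site_proportion(big)$pct,
               100 * nrow(find_polymorphic_columns(big)) / 80)
})
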