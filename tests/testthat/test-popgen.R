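# Population statistics: Pearson chi-square, AMOVA variance components,
# permutation behaviour, within-group contributions.

test_that("pearson_chisq reproduces closed-form values and guards degeneracy", {
  same <- matrix(c(5, 3, 2, 5, 3, 2), ncol = 2)
  expect_warning(res <- pearson_chisq(same), "expected count < 5")
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)

  diag2 <- matrix(c(10, 0, 0, 10), ncol = 2)
  res <- suppressWarnings(pearson_chisq(diag2))
  expect_equal(res$statistic, 20)   # sum of (5)^2/5 over four cells
  expect_equal(res$df, 1)

  expect_error(pearson_chisq(matrix(1:3, ncol = 1)), "degenerate")
  w <- capture_warnings(pearson_chisq(rbind(c(5, 5), c(0, 0), c(4, 6))))
  expect_match(w, "zero-marginal", all = FALSE)
})

test_that("AMOVA components equal a direct-summation oracle on small data", {
  set.seed(101)
  cases <- list(
    list(chl = c("0000", "0001", "0011", "1100", "1110", "1111"),
         grp = c("a", "a", "a", "b", "b", "b")),
    list(chl = random_chlorotypes(8, 5),
         grp = c("a", "a", "a", "b", "b", "c", "c", "c")),
    list(chl = random_chlorotypes(7, 4),
         grp = c("a", "a", "b", "b", "b", "c", "c"))
  )
  for (cs in cases) {
    ds <- grouped_dataset(seq_along(cs$chl), cs$grp, cs$chl)
    got <- amova(ds, n_perm = 0)
    want <- oracle_amova(cs$chl, cs$grp)
    expect_equal(got$ssd_among, want$ssd_among)
    expect_equal(got$ssd_within, want$ssd_within)
    expect_equal(got$sigma2_among, want$sigma2_among)
    expect_equal(got$sigma2_within, want$sigma2_within)
    expect_equal(got$pct_among, want$pct_among, tolerance = 1e-12)
    expect_equal(within_group_contributions(ds),
                 want$contributions, tolerance = 1e-12)
  }
})

test_that("AMOVA percentages agree with ade4 on a reconstructed survey", {
  ds <- reconstruct_survey_dataset("twelve_site")
  got <- amova(ds, n_perm = 0)
  types <- unique(ds$chlorotype)
  Tm <- do.call(rbind, strsplit(types, ""))
  cnts <- data.frame(
    f = as.vector(table(factor(ds$chlorotype[ds$group == "florida_cultivars"],
                               levels = types))),
    k = as.vector(table(factor(ds$chlorotype[ds$group == "kousa_cultivars"],
                               levels = types))))
  rownames(cnts) <- types
  ref <- ade4::amova(samples = cnts, distances = stats::dist(Tm))
  pct <- ref$componentsofcovariance[, "%"]
  expect_equal(got$pct_among, pct[1], tolerance = 1e-8)
  expect_equal(got$pct_within, pct[2], tolerance = 1e-8)
})

test_that("fully-separated and label-symmetric designs hit the extremes", {
  ds <- grouped_dataset(1:16, rep(c("a", "b"), each = 8),
                        rep(c("0000", "1111"), each = 8))
  res <- amova(ds, n_perm = 99, seed = 1)
  expect_equal(res$pct_among, 100)
  expect_equal(res$pct_within, 0)
  expect_lt(res$p_perm, 0.05)

  set.seed(77)
  half <- random_chlorotypes(30, 6)
  ds2 <- grouped_dataset(1:60, rep(c("a", "b"), each = 30), c(half, half))
  res2 <- amova(ds2, n_perm = 199, seed = 2)
  expect_lt(res2$pct_among, 5)
  expect_gt(res2$p_perm, 0.5)
})

test_that("SSD components add up and duplication preserves the SSD partition", {
  set.seed(55)
  for (rep in 1:5) {
    chl <- random_chlorotypes(20, 8)
    grp <- sample(c("a", "b", "c"), 20, replace = TRUE,
                  prob = c(0.4, 0.4, 0.2))
    if (length(unique(grp)) < 2) next
    ds <- grouped_dataset(1:20, grp, chl)
    res <- amova(ds, n_perm = 0)
    expect_equal(res$ssd_among + res$ssd_within, res$ssd_total,
                 tolerance = 1e-9)
    # exact duplication doubles every SSD term, leaving their shares fixed;
    # the sigma^2 percentages move only through the df ratios and settle
    # with sample size
    dup <- grouped_dataset(1:40, c(grp, grp), c(chl, chl))
    res_dup <- amova(dup, n_perm = 0)
    expect_equal(res_dup$ssd_among / res_dup$ssd_total,
                 res$ssd_among / res$ssd_total, tolerance = 1e-9)
    expect_equal(res_dup$ssd_within, 2 * res$ssd_within, tolerance = 1e-9)
  }
  # with real group structure and larger N the sigma^2 percentages are
  # stable under duplication to within a fraction of a point
  chl <- rep(c("00000000", "00000011", "11111100", "11111111"),
             times = c(20, 10, 18, 12))
  grp <- rep(c("a", "b"), times = c(30, 30))
  res <- amova(grouped_dataset(1:60, grp, chl), n_perm = 0)
  res_dup <- amova(grouped_dataset(1:120, c(grp, grp), c(chl, chl)),
                   n_perm = 0)
  expect_equal(res_dup$pct_among, res$pct_among, tolerance = 0.01)
})

test_that("permutation p-values are uniform under a null labelling", {
  set.seed(303)
  chl <- random_chlorotypes(20, 12)
  pvals <- vapply(1:200, function(r) {
    grp <- sample(rep(c("a", "b"), each = 10))
    ds <- grouped_dataset(1:20, grp, chl)
    amova(ds, n_perm = 199, seed = 1000 + r)$p_perm
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_gt(mean(pvals), 0.40)
  expect_lt(mean(pvals), 0.60)
})

test_that("within-group contributions are symmetric and sum to 100", {
  ds <- grouped_dataset(1:8, rep(c("a", "b"), each = 4),
                        rep(c("0011", "0011", "0111", "1011"), 2))
  contrib <- within_group_contributions(ds)
  expect_equal(unname(contrib), c(50, 50))

  set.seed(9)
  chl <- random_chlorotypes(12, 5)
  grp <- rep(c("a", "b", "c"), each = 4)
  expect_equal(sum(within_group_contributions(grouped_dataset(1:12, grp, chl))),
               100, tolerance = 1e-9)

  same <- grouped_dataset(1:4, c("a", "a", "b", "b"), rep("0101", 4))
  expect_warning(res <- within_group_contributions(same), "undefined")
  expect_true(all(is.na(res)))
})

test_that("identical individuals give a flagged degenerate result, not an error", {
  ds <- grouped_dataset(1:6, rep(c("a", "b"), each = 3), rep("0101", 6))
  res <- amova(ds, n_perm = 0)
  expect_true(res$degenerate)
  expect_true(is.na(res$pct_among))
})
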