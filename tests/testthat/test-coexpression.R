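test_that("low-expression filter applies the count/fraction rule exactly", {
  counts <- matrix(c(10, 10, 10, 10,   # always high -> keep
                     5, 5, 0, 0,       # exactly at threshold in half -> keep
                     4, 9, 0, 0,       # >=5 in only 1 of 4 -> drop
                     0, 0, 0, 0),      # never -> drop
                   nrow = 4, byrow = TRUE,
                   dimnames = list(paste0("g", 1:4), paste0("s", 1:4)))
  kept <- filter_low_expression(counts, min_count = 5, min_fraction = 0.5)
  expect_equal(rownames(kept), c("g1", "g2"))
  expect_error(filter_low_expression(counts - 1), "negative")
  expect_error(filter_low_expression(counts, min_count = 100),
               "all genes removed")
})

test_that("TMM factors match a step-by-step reference implementation", {
  set.seed(31)
  counts <- matrix(rnbinom(200 * 6, mu = 100, size = 5), nrow = 200,
                   dimnames = list(paste0("g", 1:200), paste0("s", 1:6)))
  counts[, 3] <- counts[, 3] * 3L   # one deep library
  f <- tmm_factors(counts)
  expect_equal(unname(f), unname(oracle_tmm(counts)), tolerance = 1e-8)
  expect_equal(exp(mean(log(f))), 1, tolerance = 1e-12)
})

test_that("identical libraries give unit TMM factors; composition shifts them", {
  base <- matrix(rep(c(10L, 50L, 200L, 1000L), 5), nrow = 4,
                 dimnames = list(paste0("g", 1:4), paste0("s", 1:5)))
  expect_equal(unname(tmm_factors(base)), rep(1, 5))
  # pure depth scaling is absorbed by the library size, not the factor
  scaled <- base
  scaled[, 2] <- scaled[, 2] * 10L
  expect_equal(unname(tmm_factors(scaled)), rep(1, 5))
})

test_that("asinh-log2 transform sends 0 to 0 and tracks log2(2x) for large x", {
  counts <- matrix(c(0L, 1000000L, 0L, 1000000L), nrow = 2,
                   dimnames = list(c("zero", "big"), c("s1", "s2")))
  y <- normalize_transform(counts)
  expect_equal(y["zero", 1], 0)
  # CPM of the big gene is 1e6; asinh-log2 ~ log2(2 * 1e6)
  expect_equal(y["big", 1], log2(2e6), tolerance = 1e-6)
  # exact formula check on arbitrary values
  x <- 37.25
  expect_equal(log2(x + sqrt(x^2 + 1)), asinh(x) / log(2))
})

test_that("remove_pc1 annihilates a rank-1 pattern and preserves orthogonal signal", {
  set.seed(17)
  n <- 60; m <- 12
  v <- rnorm(m); v <- v - mean(v); v <- v / sqrt(sum(v^2))
  u <- rnorm(n)
  base <- matrix(rnorm(n * m, sd = 0.01), n, m,
                 dimnames = list(paste0("g", 1:n), paste0("s", 1:m)))
  x <- base + 10 * u %*% t(v) + 5
  res <- remove_pc1(x)
  # the dominant rank-1 pattern is gone: residual centered matrix is tiny
  resc <- res - rowMeans(res)
  expect_lt(max(svd(resc)$d), 1)
  # gene means are preserved
  expect_equal(rowMeans(res), rowMeans(x))
  # total centered variance strictly decreases
  xc <- x - rowMeans(x)
  expect_lt(sum(resc^2), sum(xc^2))
  expect_error(remove_pc1(matrix(1, 5, 5)), "constant matrix")
})

test_that("correlation p-values match cor.test and zero-variance genes give NA", {
  set.seed(23)
  x <- matrix(rnorm(5 * 10), 5, 10,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:10)))
  x[5, ] <- 7   # constant gene
  res <- correlation_with_pvalues(x)
  expect_s3_class(res, "correlation_result")
  for (i in 1:3) for (j in (i + 1):4) {
    ct <- cor.test(x[i, ], x[j, ])
    expect_equal(res$pcc[i, j], unname(ct$estimate), tolerance = 1e-12)
    expect_equal(res$pvalues[i, j], ct$p.value, tolerance = 1e-12)
  }
  expect_true(all(is.na(res$pcc[5, ])))
  expect_true(all(is.na(res$pvalues[, 5])))
  expect_equal(diag(res$pcc)[1:4], rep(1, 4), ignore_attr = TRUE)
  expect_equal(diag(res$pvalues)[1:4], rep(0, 4), ignore_attr = TRUE)
  expect_error(correlation_with_pvalues(x[, 1:3]), "at least 4 samples")
})

test_that("critical_pcc matches its closed form and rounds up", {
  # closed form at several (n, alpha)
  for (n in c(10, 22, 50)) for (a in c(0.05, 0.01)) {
    tstar <- qt(1 - a / 2, n - 2)
    expect_equal(critical_pcc(n, a), tstar / sqrt(tstar^2 + n - 2))
  }
  # the documented anchor: 22 samples, alpha 0.05 -> 0.4227 -> 0.43
  expect_equal(critical_pcc(22, 0.05), 0.4227, tolerance = 5e-5)
  expect_equal(critical_pcc(22, 0.05, digits = 2), 0.43)
  # rounding is upward, never downward
  expect_gte(critical_pcc(22, 0.05, digits = 2), critical_pcc(22, 0.05))
  # a rounded threshold is itself significant
  r <- critical_pcc(22, 0.05, digits = 2)
  t_at_r <- r * sqrt(20) / sqrt(1 - r^2)
  expect_lte(2 * pt(-t_at_r, 20), 0.05)
})

test_that("spatial quantile normalization is a near no-op on a homogeneous matrix", {
  set.seed(41)
  n <- 300
  # all bins share one correlation distribution: no expression-linked bias
  z <- matrix(rnorm(n * 40), n, 40)
  r <- cor(t(z))
  mu <- rnorm(n)
  out <- spatial_quantile_normalize(r, ngrp = 5, ref_grp = 4,
                                    mean_expression = mu)
  expect_equal(dim(out), dim(r))
  expect_equal(diag(out), rep(1, n), ignore_attr = TRUE)
  expect_true(isSymmetric(out, tol = 1e-12))
  off <- upper.tri(r)
  expect_lt(median(abs(out[off] - r[off])), 0.01)
})

test_that("spatial quantile normalization equalizes bin-specific inflation", {
  set.seed(43)
  n <- 300; m <- 40
  z <- matrix(rnorm(n * m), n, m)
  mu <- seq_len(n)                      # ranked mean expression
  # inflate correlations among the lowest-expression third via a shared factor
  low <- 1:100
  z[low, ] <- z[low, ] + 1.5 * matrix(rnorm(m), nrow = length(low),
                                      ncol = m, byrow = TRUE)
  r <- cor(t(z))
  before <- bin_density_diagnostic(r, n_bins = 3, mean_expression = mu)
  out <- spatial_quantile_normalize(r, ngrp = 3, ref_grp = 3, size_grp = 100,
                                    mean_expression = mu)
  after <- bin_density_diagnostic(out, n_bins = 3, mean_expression = mu)
  expect_gt(before$median[1], 0.3)      # the planted inflation
  expect_lt(abs(after$median[1]), abs(before$median[1]) / 3)
  # ordering within each cell is preserved (monotone mapping)
  blk_in <- r[low, low]; blk_out <- out[low, low]
  o <- upper.tri(blk_in)
  expect_equal(order(blk_in[o]), order(blk_out[o]))
})

test_that("bin diagnostic reports per-bin quartiles of off-diagonal correlations", {
  set.seed(47)
  r <- cor(t(matrix(rnorm(40 * 30), 40, 30)))
  mu <- seq_len(40)
  d <- bin_density_diagnostic(r, n_bins = 4, mean_expression = mu)
  expect_s3_class(d, "bin_density")
  expect_equal(d$bin, 1:4)
  expect_equal(d$n_genes, rep(10L, 4))
  blk <- r[1:10, 1:10]
  vals <- blk[row(blk) != col(blk)]
  expect_equal(d$median[1], median(vals))
  expect_equal(d$q1[1], unname(quantile(vals, 0.25)))
})

test_that("coexpression_stack is deterministic and exposes the raw correlations", {
  ds <- synthetic_regulon_dataset(seed = 19, genome_length = 60000,
                                  n_genes = 40, n_samples = 16)
  res1 <- coexpression_stack(ds$counts)
  res2 <- coexpression_stack(ds$counts)
  expect_equal(res1$pcc, res2$pcc)
  raw <- attr(res1, "pcc_raw")
  expect_equal(dim(raw), dim(res1$pcc))
  # raw correlations differ from the corrected ones (PC1 + spqn acted)
  off <- upper.tri(raw)
  expect_gt(median(abs(raw[off] - res1$pcc[off])), 0.01)
  # disabling both corrections reproduces the raw matrix
  res0 <- coexpression_stack(ds$counts, remove_pcs = 0, spqn_passes = 0)
  expect_equal(res0$pcc, attr(res0, "pcc_raw"), tolerance = 1e-12)
})
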