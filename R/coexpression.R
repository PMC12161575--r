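## Count-matrix normalization and bias-corrected co-expression.
##
## The stack mirrors standard bacterial RNA-seq co-expression practice:
## low-expression filter -> TMM -> asinh-in-log2-units transform -> removal
## of the first principal component -> all-to-all Pearson correlations with
## Student p-values -> spatial quantile normalization of the correlation
## matrix against a high-expression reference block.

#' Filter lowly expressed genes
#'
#' Keeps genes with at least `min_count` reads in at least `min_fraction` of
#' samples (the sample threshold is `ceiling(min_fraction * n_samples)`).
#'
#' @param counts Integer matrix, genes x samples, with rownames.
#' @param min_count,min_fraction Defaults 5 and 0.5.
#' @return Filtered count matrix.
#' @export
filter_low_expression <- function(counts, min_count = 5, min_fraction = 0.5) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)))
  if (any(counts < 0)) stop("negative counts")
  need <- ceiling(min_fraction * ncol(counts))
  keep <- rowSums(counts >= min_count) >= need
  if (!any(keep)) stop("all genes removed by the expression filter")
  counts[keep, , drop = FALSE]
}

#' TMM normalization factors
#'
#' Trimmed-mean-of-M-values factors via [edgeR::calcNormFactors()]: the
#' reference sample is the one whose upper quartile of library-size-scaled
#' positive counts is closest to the mean upper quartile; per-sample factors
#' are 2 to the weighted mean of gene-wise log-ratios (M) after trimming the
#' top/bottom `trim_m` by M and `trim_a` by average abundance, weighted by
#' inverse asymptotic binomial variance; factors are rescaled to log-mean 0.
#'
#' @param counts Genes x samples count matrix.
#' @param trim_m,trim_a Trim fractions (defaults 0.30 and 0.05).
#' @return Named numeric vector of per-sample factors.
#' @export
tmm_factors <- function(counts, trim_m = 0.30, trim_a = 0.05) {
  stopifnot(is.matrix(counts), ncol(counts) >= 2)
  if (any(colSums(counts) <= 0)) stop("sample with no counts")
  f <- edgeR::calcNormFactors(counts, method = "TMM",
                              logratioTrim = trim_m, sumTrim = trim_a)
  setNames(as.numeric(f), colnames(counts))
}

#' Normalize to CPM and transform with an asinh pseudocount
#'
#' Counts are scaled to counts-per-million of the effective library size
#' (library size x TMM factor), then mapped through the hyperbolic arcsine
#' in log2 units, `y = log2(x + sqrt(x^2 + 1))`. The transform sends 0 to 0
#' with no additive pseudocount constant and behaves as `log2(2x)` for large
#' `x`.
#'
#' @param counts Genes x samples count matrix.
#' @param factors Per-sample normalization factors (default all 1).
#' @return Expression matrix of the same shape.
#' @export
normalize_transform <- function(counts, factors = rep(1, ncol(counts))) {
  stopifnot(is.matrix(counts), length(factors) == ncol(counts),
            all(factors > 0))
  eff <- colSums(counts) * factors
  x <- sweep(counts, 2, eff, "/") * 1e6
  log2(x + sqrt(x^2 + 1))
}

#' Remove the first principal component from an expression matrix
#'
#' Centers each gene, removes every gene's projection on the first right
#' singular vector of the centered matrix (the dominant shared sample
#' pattern, typically a technical confounder in saturated designs), and adds
#' the gene means back. The total centered variance strictly decreases; a
#' second application removes the *next* dominant component, so the
#' operation is deliberately not idempotent.
#'
#' @param expression Genes x samples numeric matrix.
#' @param n_pc Number of leading components to remove (default 1).
#' @return Residual expression matrix, same shape and dimnames.
#' @export
remove_pc1 <- function(expression, n_pc = 1) {
  stopifnot(is.matrix(expression), ncol(expression) >= 3)
  mu <- rowMeans(expression)
  xc <- expression - mu
  if (all(abs(xc) < 1e-12)) stop("constant matrix: no variation to decompose")
  sv <- svd(xc, nu = 0, nv = n_pc)
  v <- sv$v[, seq_len(n_pc), drop = FALSE]
  res <- xc - (xc %*% v) %*% t(v) + mu
  dimnames(res) <- dimnames(expression)
  res
}

#' All-to-all Pearson correlations with Student p-values
#'
#' Pairwise Pearson `r` over samples with two-sided p-values from
#' `t = r sqrt(n-2) / sqrt(1-r^2)` on `n - 2` degrees of freedom. Genes with
#' zero variance get `NA` correlations and p-values (they are kept so gene
#' indexing stays stable downstream).
#'
#' @param expression Genes x samples matrix with rownames.
#' @param adjust Optional multiple-testing adjustment applied per row
#'   (passed to [stats::p.adjust()]; `"none"` by default — the conventional
#'   significance/PCC correspondence is stated on unadjusted p-values).
#' @return Object of class `correlation_result`: list with `pcc`, `pvalues`,
#'   `n_samples`, `mean_expression`.
#' @export
correlation_with_pvalues <- function(expression, adjust = "none") {
  stopifnot(is.matrix(expression))
  n <- ncol(expression)
  if (n < 4) stop("need at least 4 samples")
  v <- apply(expression, 1, var)
  r <- suppressWarnings(cor(t(expression)))
  r[v == 0, ] <- NA
  r[, v == 0] <- NA
  diag(r)[v > 0] <- 1
  df <- n - 2
  rr <- pmin(pmax(r, -1), 1)
  tt <- rr * sqrt(df) / sqrt(pmax(1 - rr^2, 0))
  p <- 2 * pt(-abs(tt), df)
  p[rr == 1 | rr == -1] <- 0
  diag(p)[v > 0] <- 0
  if (adjust != "none") {
    for (i in seq_len(nrow(p))) {
      off <- setdiff(seq_len(ncol(p)), i)
      p[i, off] <- stats::p.adjust(p[i, off], method = adjust)
    }
    p[lower.tri(p)] <- t(p)[lower.tri(p)]
  }
  structure(list(pcc = r, pvalues = p, n_samples = n,
                 mean_expression = rowMeans(expression)),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Correlation result: %d genes, %d samples\n",
              nrow(x$pcc), x$n_samples))
  invisible(x)
}

#' Critical absolute Pearson correlation at a significance level
#'
#' The smallest `|r|` significant at level `alpha` under the two-sided
#' Student test with `n - 2` degrees of freedom:
#' `r* = t* / sqrt(t*^2 + n - 2)` with `t*` the `1 - alpha/2` quantile.
#' When `digits` is given the value is rounded *up* at that precision, so
#' the reported threshold is itself significant (a rounded-down threshold
#' would admit non-significant correlations); 22 samples at `alpha = 0.05`
#' give 0.4227 exactly and 0.43 at two digits.
#'
#' @param n_samples Number of samples (>= 3).
#' @param alpha Two-sided significance level.
#' @param digits Optional printing precision (round up).
#' @return Critical absolute correlation.
#' @examples
#' critical_pcc(22, 0.05)
#' critical_pcc(22, 0.05, digits = 2)
#' @export
critical_pcc <- function(n_samples, alpha = 0.05, digits = NULL) {
  stopifnot(n_samples >= 3)
  if (!is.numeric(alpha) || alpha <= 0 || alpha > 1) stop("invalid alpha")
  df <- n_samples - 2
  tstar <- qt(1 - alpha / 2, df)
  r <- tstar / sqrt(tstar^2 + df)
  if (!is.null(digits)) r <- ceiling(r * 10^digits) / 10^digits
  r
}

## ---- spatial quantile normalization ----------------------------------------

# Center of an estimation window of w genes around bin k of ngrp bins over n
# genes, clamped so the window stays inside 1..n. Returns index range.
spqn_window <- function(k, ngrp, n, w) {
  bin_size <- n / ngrp
  center <- (k - 0.5) * bin_size
  lo <- round(center - w / 2)
  lo <- max(0, min(lo, n - w))
  c(lo + 1, lo + w)
}

# Map values onto the empirical distribution of `ref`, using the empirical
# CDF of `src` (linear interpolation between order statistics).
quantile_map <- function(values, src, ref) {
  src <- sort(src)
  ref <- sort(ref)
  ns <- length(src)
  nr <- length(ref)
  probs <- approx(x = src, y = seq(0, 1, length.out = ns), xout = values,
                  rule = 2, ties = "ordered")$y
  approx(x = seq(0, 1, length.out = nr), y = ref, xout = probs,
         rule = 2, ties = "ordered")$y
}

#' Spatial quantile normalization of a correlation matrix
#'
#' Removes mean-expression-dependent distortion of correlation-coefficient
#' distributions. Genes are sorted by mean expression and split into `ngrp`
#' equal rank bins, defining an `ngrp x ngrp` grid of correlation
#' sub-matrices. For each grid cell the local correlation distribution is
#' estimated from an enlarged window of `size_grp x size_grp` genes centered
#' on the cell (windows are shifted inward at the matrix borders so the
#' estimation sample size stays constant), and the cell's off-diagonal values
#' are quantile-mapped onto the distribution of the reference cell
#' `(ref_grp, ref_grp)` — a high- but not top-expression block whose
#' correlations are least distorted. The diagonal is kept at 1 and the result
#' is symmetrized by averaging with its transpose. The mapping is monotone,
#' so value ordering within each cell is preserved.
#'
#' @param corr A [correlation_with_pvalues()] result (or plain symmetric
#'   matrix plus `mean_expression`).
#' @param ngrp Number of expression bins (default 20).
#' @param size_grp Estimation-window size in genes; default
#'   `max(90, round(n_genes / ngrp))` capped at `n_genes`, i.e. one bin
#'   width (337 in the 20-bin, ~6700-gene regime this stack was designed
#'   around) but never fewer than 90 genes. A 90-gene window contributes
#'   about 4,000 gene pairs, the minimum needed to estimate the extreme
#'   quantiles that genuinely co-expressed pairs occupy; smaller windows
#'   clamp strong correlations toward the window maximum and destroy the
#'   biological signal the correction is meant to preserve.
#' @param ref_grp Index of the reference bin (default 18 of 20).
#' @param mean_expression Needed when `corr` is a plain matrix.
#' @return Corrected correlation matrix in the input gene order.
#' @export
spatial_quantile_normalize <- function(corr, ngrp = 20, size_grp = NULL,
                                       ref_grp = 18, mean_expression = NULL) {
  if (inherits(corr, "correlation_result")) {
    mean_expression <- corr$mean_expression
    mat <- corr$pcc
  } else {
    mat <- corr
  }
  stopifnot(is.matrix(mat), nrow(mat) == ncol(mat),
            !is.null(mean_expression), length(mean_expression) == nrow(mat))
  n <- nrow(mat)
  if (ngrp < 2 || ngrp > n) stop("ngrp must be between 2 and n_genes")
  if (ref_grp < 1 || ref_grp > ngrp) stop("ref_grp must index a bin")
  if (is.null(size_grp)) size_grp <- min(n, max(90L, round(n / ngrp)))
  if (size_grp > n) stop("size_grp exceeds the number of genes")
  ord <- order(mean_expression)
  m <- mat[ord, ord]
  # equal-size rank bins (remainder spread over the first bins)
  sizes <- rep(n %/% ngrp, ngrp) + c(rep(1, n %% ngrp), rep(0, ngrp - n %% ngrp))
  if (any(sizes < 1)) stop("degenerate bins: more bins than genes")
  ends <- cumsum(sizes)
  starts <- c(1, head(ends, -1) + 1)
  win <- lapply(seq_len(ngrp), function(k) spqn_window(k, ngrp, n, size_grp))
  rw <- win[[ref_grp]]
  ref_block <- m[rw[1]:rw[2], rw[1]:rw[2]]
  ref_vals <- ref_block[row(ref_block) != col(ref_block)]
  out <- m
  for (i in seq_len(ngrp)) {
    for (j in seq_len(ngrp)) {
      wi <- win[[i]]; wj <- win[[j]]
      est <- m[wi[1]:wi[2], wj[1]:wj[2]]
      if (identical(wi, wj)) est_vals <- est[row(est) != col(est)]
      else est_vals <- as.vector(est)
      ri <- starts[i]:ends[i]; rj <- starts[j]:ends[j]
      cell <- m[ri, rj, drop = FALSE]
      mapped <- quantile_map(as.vector(cell), est_vals, ref_vals)
      out[ri, rj] <- matrix(mapped, nrow = length(ri))
    }
  }
  out <- (out + t(out)) / 2
  diag(out) <- 1
  inv <- order(ord)
  out <- out[inv, inv]
  dimnames(out) <- dimnames(mat)
  out
}

#' Per-bin correlation-density diagnostic
#'
#' Sorts genes by mean expression, splits them into `n_bins` equal bins,
#' and summarizes the within-bin all-to-all off-diagonal correlations with
#' quartiles and a density grid — deviations of the bin medians from zero
#' indicate mean-expression-linked confounding.
#'
#' @param corr Correlation matrix or [correlation_with_pvalues()] result.
#' @param n_bins Number of bins (default 10).
#' @param mean_expression Needed when `corr` is a plain matrix.
#' @return Object of class `bin_density`: data.frame with `bin`, `n_genes`,
#'   `q1`, `median`, `q3`; attribute `densities` holds per-bin
#'   [stats::density()] objects.
#' @export
bin_density_diagnostic <- function(corr, n_bins = 10, mean_expression = NULL) {
  if (inherits(corr, "correlation_result")) {
    mean_expression <- corr$mean_expression
    corr <- corr$pcc
  }
  stopifnot(is.matrix(corr), !is.null(mean_expression))
  n <- nrow(corr)
  ord <- order(mean_expression)
  sizes <- rep(n %/% n_bins, n_bins) +
    c(rep(1, n %% n_bins), rep(0, n_bins - n %% n_bins))
  ends <- cumsum(sizes)
  starts <- c(1, head(ends, -1) + 1)
  dens <- vector("list", n_bins)
  rows <- lapply(seq_len(n_bins), function(k) {
    idx <- ord[starts[k]:ends[k]]
    block <- corr[idx, idx]
    vals <- block[row(block) != col(block)]
    vals <- vals[!is.na(vals)]
    dens[[k]] <<- if (length(vals) > 1) density(vals, from = -1, to = 1) else NULL
    q <- quantile(vals, c(0.25, 0.5, 0.75), na.rm = TRUE)
    data.frame(bin = k, n_genes = length(idx),
               q1 = q[[1]], median = q[[2]], q3 = q[[3]])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "densities") <- dens
  class(out) <- c("bin_density", "data.frame")
  out
}

#' @export
plot.bin_density <- function(x, ...) {
  dens <- attr(x, "densities")
  plot(NULL, xlim = c(-1, 1), ylim = c(0.5, nrow(x) + 1.5),
       xlab = "Pearson correlation", ylab = "Mean-expression bin", ...)
  abline(v = 0, lty = 2, col = "grey40")
  for (k in seq_len(nrow(x))) {
    d <- dens[[k]]
    if (is.null(d)) next
    y <- k + d$y / max(d$y)
    polygon(d$x, y, col = adjustcolor("steelblue", 0.4), border = "grey30")
    points(x$median[k], k, pch = 19, cex = 0.6)
  }
  invisible(x)
}

#' Run the full co-expression stack
#'
#' filter -> TMM -> asinh-log2 transform -> PC1 removal -> Pearson + Student
#' p-values -> spatial quantile normalization of the correlation matrix
#' (p-values are computed before the quantile mapping, as in the reference
#' workflow). Deterministic for fixed input.
#'
#' @param counts Genes x samples integer matrix.
#' @param min_count,min_fraction Expression filter parameters.
#' @param remove_pcs Number of leading principal components to remove (0
#'   disables).
#' @param spqn_ngrp,spqn_size,spqn_ref Spatial quantile normalization
#'   parameters; `spqn_passes = 0` disables the correction.
#' @param spqn_passes Number of normalization passes (default 1).
#' @return A `correlation_result` whose `pcc` is the corrected matrix;
#'   attribute `pcc_raw` keeps the fully uncorrected correlations (after
#'   normalization and transform but before PC removal and quantile
#'   normalization, i.e. the "before" panel of the bin diagnostic) and
#'   attribute `expression` the transformed (and PC-corrected) matrix.
#' @export
coexpression_stack <- function(counts, min_count = 5, min_fraction = 0.5,
                               remove_pcs = 1, spqn_ngrp = 20,
                               spqn_size = NULL, spqn_ref = 18,
                               spqn_passes = 1) {
  counts <- filter_low_expression(counts, min_count, min_fraction)
  f <- tmm_factors(counts)
  expr0 <- normalize_transform(counts, f)
  raw <- suppressWarnings(stats::cor(t(expr0)))
  expr <- if (remove_pcs > 0) remove_pc1(expr0, n_pc = remove_pcs) else expr0
  res <- correlation_with_pvalues(expr)
  for (i in seq_len(spqn_passes)) {
    res$pcc <- spatial_quantile_normalize(res, ngrp = spqn_ngrp,
                                          size_grp = spqn_size,
                                          ref_grp = spqn_ref)
  }
  attr(res, "pcc_raw") <- raw
  attr(res, "expression") <- expr
  res
}
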