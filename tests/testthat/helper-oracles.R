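# Independent reference implementations used as test oracles. Each is a
# deliberately naive re-derivation from the definitions, sharing no code
# with the package internals.

# PWM score of one sequence at one offset, base by base
oracle_score <- function(pwm, seq, offset) {
  bases <- strsplit(substr(seq, offset, offset + ncol(pwm$scores) - 1),
                    "")[[1]]
  if (length(bases) < ncol(pwm$scores)) return(NA_real_)
  s <- 0
  for (i in seq_along(bases)) {
    if (!bases[i] %in% rownames(pwm$scores)) return(NA_real_)
    s <- s + pwm$scores[bases[i], i]
  }
  s
}

oracle_revcomp <- function(seq) {
  map <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(map[strsplit(seq, "")[[1]]]), collapse = "")
}

# every-offset/strand brute-force scan of one sequence; returns a data.frame
# of 0-based start, strand, score for scores >= floor
oracle_scan <- function(pwm, seq, floor) {
  L <- ncol(pwm$scores)
  n <- nchar(seq)
  rows <- list()
  rc <- oracle_revcomp(seq)
  for (off in seq_len(n - L + 1)) {
    s_fwd <- oracle_score(pwm, seq, off)
    if (!is.na(s_fwd) && s_fwd >= floor)
      rows[[length(rows) + 1]] <- data.frame(start = off - 1L, strand = "+",
                                             score = s_fwd)
    # a "-" hit at 0-based start p means the reverse complement of
    # seq[p+1 .. p+L] matches the motif; equivalently score the rc string
    s_rev <- oracle_score(pwm, rc, n - L - off + 2)
    if (!is.na(s_rev) && s_rev >= floor)
      rows[[length(rows) + 1]] <- data.frame(start = off - 1L, strand = "-",
                                             score = s_rev)
  }
  if (length(rows) == 0)
    return(data.frame(start = integer(), strand = character(),
                      score = numeric()))
  do.call(rbind, rows)
}

# exact tail probability P(score >= s) for a random i.i.d. background
# sequence, by full k-mer enumeration (k = motif length, feasible for k <= 8)
oracle_tail_prob <- function(pwm, background, s) {
  L <- ncol(pwm$scores)
  bases <- rownames(pwm$scores)
  idx <- rep(1L, L)
  total <- 0
  repeat {
    kscore <- sum(pwm$scores[cbind(idx, seq_len(L))])
    if (kscore >= s)
      total <- total + prod(background[idx])
    j <- L
    while (j >= 1) {
      idx[j] <- idx[j] + 1L
      if (idx[j] <= 4L) break
      idx[j] <- 1L
      j <- j - 1
    }
    if (j < 1) break
  }
  total
}

# step-by-step TMM reference of the spec's stated formula
oracle_tmm <- function(counts, trim_m = 0.3, trim_a = 0.05) {
  lib <- colSums(counts)
  uq <- apply(counts, 2, function(x) quantile(x[x > 0] / sum(x), 0.75))
  ref <- which.min(abs(uq - mean(uq)))
  f <- vapply(seq_len(ncol(counts)), function(j) {
    obs <- counts[, j]; refc <- counts[, ref]
    keep <- obs > 0 & refc > 0
    obs <- obs[keep]; refc <- refc[keep]
    no <- sum(counts[, j]); nr <- sum(counts[, ref])
    m <- log2((obs / no) / (refc / nr))
    a <- (log2(obs / no) + log2(refc / nr)) / 2
    w <- (no - obs) / (no * obs) + (nr - refc) / (nr * refc)
    fin <- is.finite(m) & is.finite(a)
    m <- m[fin]; a <- a[fin]; w <- w[fin]
    lm <- quantile(m, c(trim_m, 1 - trim_m), names = FALSE)
    la <- quantile(a, c(trim_a, 1 - trim_a), names = FALSE)
    keep2 <- m >= lm[1] & m <= lm[2] & a >= la[1] & a <= la[2]
    if (!any(keep2)) return(1)
    2^(sum(m[keep2] / w[keep2]) / sum(1 / w[keep2]))
  }, numeric(1))
  f / exp(mean(log(f)))
}

# small random PWM over a random background, for oracle scans
random_pwm <- function(len, seed, background = rep(0.25, 4)) {
  set.seed(seed)
  counts <- matrix(rpois(4 * len, 5) + 1L, nrow = 4,
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  sites <- replicate(6, paste(
    vapply(seq_len(len), function(i)
      sample(c("A", "C", "G", "T"), 1, prob = counts[, i]), character(1)),
    collapse = ""))
  pfm_to_pwm(build_pfm(sites), as_background(background))
}

random_sequence <- function(n, seed, prob = rep(0.25, 4)) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = prob),
        collapse = "")
}

# tiny deterministic annotated genome used across regulon/cluster tests:
# 6 genes on one contig, two operons (+ strand g1-g3, - strand g4-g5) and a
# singleton g6
toy_genome <- function() {
  genes <- data.frame(
    gene_id = paste0("g", 1:6),
    contig = "chr",
    start = c(500, 1100, 1700, 2600, 3300, 4600),
    end = c(1000, 1600, 2300, 3200, 3900, 5200),
    strand = c("+", "+", "+", "-", "-", "+"),
    stringsAsFactors = FALSE)
  seq <- paste(rep("ACGT", 1500), collapse = "")
  annotated_genome(setNames(seq, "chr"), genes)
}

# correlation_result stub with a given pcc matrix (pvalues all tiny)
corr_stub <- function(pcc, n_samples = 24, pvalues = NULL) {
  if (is.null(pvalues)) {
    pvalues <- matrix(1e-6, nrow(pcc), ncol(pcc), dimnames = dimnames(pcc))
    diag(pvalues) <- 0
  }
  structure(list(pcc = pcc, pvalues = pvalues, n_samples = n_samples,
                 mean_expression = setNames(seq_len(nrow(pcc)),
                                            rownames(pcc))),
            class = "correlation_result")
}
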