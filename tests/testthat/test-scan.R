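test_that("reverse_complement and rc_pwm_scores agree with the definitions", {
  expect_equal(reverse_complement("ACGT"), "ACGT")
  expect_equal(reverse_complement("TTAGG"), "CCTAA")
  pwm <- random_pwm(5, seed = 1)
  rc <- regumine:::rc_pwm_scores(pwm$scores)
  # scoring a window with the rc matrix = scoring its reverse complement
  for (w in c("ACGTA", "TTTTT", "GATCA")) {
    s_rc <- sum(rc[cbind(match(strsplit(w, "")[[1]], c("A", "C", "G", "T")),
                         1:5)])
    expect_equal(s_rc, score_sequence(pwm, reverse_complement(w)))
  }
})

test_that("scan_genome equals the brute-force scanner on random sequences", {
  set.seed(42)
  for (case in 1:8) {
    len <- sample(4:8, 1)
    pwm <- random_pwm(len, seed = 100 + case)
    seq <- random_sequence(800, seed = 200 + case)
    ag <- annotated_genome(setNames(seq, "chr"),
                           data.frame(gene_id = "g1", contig = "chr",
                                      start = 100, end = 400, strand = "+",
                                      stringsAsFactors = FALSE))
    rg <- extract_regions(ag)
    # offset the floor so it cannot tie an achievable window score
    # (equality at the floor is decided by floating-point summation order)
    floor_bits <- quantile(replicate(50, score_sequence(
      pwm, random_sequence(len, seed = sample.int(1e6, 1)))), 0.8) +
      1.2345e-5
    hits <- scan_genome(ag, rg, pwm, floor_bits)
    ora <- oracle_scan(pwm, seq, floor_bits)
    key <- function(d) sort(sprintf("%d:%s:%.9f", d$start, d$strand, d$score))
    expect_equal(key(hits), key(ora))
  }
})

test_that("palindromic motifs hit both strands at the same location with equal score", {
  sites <- synthetic_iron_box_sites()
  pwm <- pfm_to_pwm(build_pfm(sites), gc_background(0.72))
  seq <- paste0(random_sequence(150, seed = 3, prob = c(.14, .36, .36, .14)),
                consensus_sequence(build_pfm(sites)),
                random_sequence(150, seed = 4, prob = c(.14, .36, .36, .14)))
  ag <- annotated_genome(setNames(seq, "chr"),
                         data.frame(gene_id = "g1", contig = "chr",
                                    start = 200, end = 300, strand = "+",
                                    stringsAsFactors = FALSE))
  hits <- scan_genome(ag, extract_regions(ag), pwm, 20)
  at <- hits[hits$start == 150, ]
  expect_equal(nrow(at), 2)
  expect_setequal(at$strand, c("+", "-"))
  # near-palindrome: both strands score close to each other, and the
  # forward score is the consensus score exactly
  expect_equal(max(at$score), pwm$max_score, tolerance = 1e-9)
})

test_that("exact p-value floor agrees with full k-mer enumeration", {
  for (case in 1:4) {
    len <- c(4, 5, 6, 7)[case]
    bg <- as_background(c(0.2, 0.3, 0.3, 0.2))
    pwm <- random_pwm(len, seed = 300 + case, background = c(0.2, 0.3, 0.3, 0.2))
    for (p in c(0.05, 0.01)) {
      s <- score_threshold_from_pvalue(pwm, bg, p = p)
      # column scores are floor-discretized to 0.001 bits, so the true tail
      # crosses p within one discretization step per column of the floor
      expect_lte(oracle_tail_prob(pwm, as.numeric(bg),
                                  as.numeric(s) + len * 0.001 + 1e-9), p)
      expect_gt(oracle_tail_prob(pwm, as.numeric(bg),
                                 as.numeric(s) - 0.001 - 1e-9), p)
      # the reported tail probability honors the target
      expect_lte(attr(s, "tail_prob"), p)
    }
  }
})

test_that("score floor is monotone in p and warns when p is unattainably small", {
  pwm <- pfm_to_pwm(build_pfm(c("TTAGG", "TTAGG", "TAAGG")),
                    gc_background(0.72))
  s1 <- score_threshold_from_pvalue(pwm, p = 0.05)
  s2 <- score_threshold_from_pvalue(pwm, p = 0.01)
  expect_gte(as.numeric(s2), as.numeric(s1))
  expect_warning(s3 <- score_threshold_from_pvalue(pwm, p = 1e-12),
                 "p too small")
  expect_equal(as.numeric(s3), pwm$max_score)
  expect_error(score_threshold_from_pvalue(pwm, p = 0), "strictly between")
})

test_that("hits are classified coding/noncoding by midpoint", {
  seq <- random_sequence(1000, seed = 5)
  ag <- annotated_genome(setNames(seq, "chr"),
                         data.frame(gene_id = "g1", contig = "chr",
                                    start = 300, end = 700, strand = "+",
                                    stringsAsFactors = FALSE))
  rg <- extract_regions(ag)
  pwm <- random_pwm(6, seed = 6)
  hits <- scan_genome(ag, rg, pwm, pwm$min_score)  # every offset hits
  mid <- hits$start + (hits$end - hits$start) %/% 2
  expect_equal(hits$region_class == "coding", mid >= 300 & mid < 700)
})

test_that("window annotation requires full containment", {
  seq <- random_sequence(1000, seed = 8)
  ag <- annotated_genome(setNames(seq, "chr"),
                         data.frame(gene_id = "g1", contig = "chr",
                                    start = 500, end = 800, strand = "+",
                                    stringsAsFactors = FALSE))
  rg <- extract_regions(ag, upstream = 100, downstream = 20)  # window [400, 520)
  pwm <- random_pwm(6, seed = 9)
  hits <- scan_genome(ag, rg, pwm, pwm$min_score)
  inside <- hits$start >= 400 & hits$end <= 520
  expect_equal(hits$windows == "g1", inside)
})

test_that("confidence tiers split at the configured fraction of max score", {
  pwm <- random_pwm(5, seed = 10)
  hits <- data.frame(score = c(pwm$max_score, 0.71 * pwm$max_score,
                               0.69 * pwm$max_score, 0))
  expect_equal(classify_confidence(hits, pwm),
               c("medium_high", "medium_high", "low", "low"))
  expect_equal(classify_confidence(hits, pwm, fraction = 0.5)[3],
               "medium_high")
})

test_that("hit-region association labels inside, peripheral and outside", {
  hits <- data.frame(contig = "chr",
                     start = c(1000, 14000, 30000, 60000),
                     end = c(1019, 14019, 30019, 60019),
                     stringsAsFactors = FALSE)
  regions <- data.frame(contig = "chr", start = 10000, end = 50000,
                        region_id = "bgc1", stringsAsFactors = FALSE)
  out <- associate_hits_with_regions(hits, regions, periphery = 5000)
  expect_equal(out$bgc_status, c("outside", "peripheral", "inside", "outside"))
  expect_equal(out$bgc_region, c(NA, "bgc1", "bgc1", NA))
})

test_that("BED export caps scores and keeps a full-precision sidecar", {
  ds <- synthetic_regulon_dataset(seed = 13, genome_length = 30000,
                                  n_genes = 20)
  ag <- annotated_genome(ds$genome,
                         ds$annotation[, c("gene_id", "contig", "start",
                                           "end", "strand")])
  pwm <- pfm_to_pwm(ds$pfm, gc_background(0.72))
  hits <- scan_genome(ag, extract_regions(ag), pwm, 10)
  expect_gt(nrow(hits), 0)
  bed <- tempfile(fileext = ".bed"); tsv <- tempfile(fileext = ".tsv")
  write_hits_bed(hits, bed, tsv)
  btab <- read.table(bed, sep = "\t")
  expect_equal(nrow(btab), nrow(hits))
  expect_true(all(btab$V5 <= 1000))
  expect_equal(btab$V2, hits$start)
  stab <- read.table(tsv, sep = "\t", header = TRUE)
  expect_equal(stab$score, hits$score, tolerance = 1e-6)
})
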