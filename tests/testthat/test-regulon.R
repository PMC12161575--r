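# locations helper matching the site_locations column contract
make_locations <- function(start, end, windows, contig = "chr",
                           score = 30, strands = "+-",
                           region_class = "noncoding") {
  loc <- data.frame(contig = contig, start = start, end = end, score = score,
                    strands = strands, windows = windows,
                    region_class = region_class,
                    n_hits = 2L, stringsAsFactors = FALSE)
  class(loc) <- c("site_locations", "data.frame")
  loc
}

test_that("assign_targets maps locations to window genes with distances", {
  ag <- toy_genome()
  # site in g1's upstream window; one divergent site shared by g3 (+) and
  # g4 (-); one orphan
  loc <- make_locations(start = c(380L, 2400L, 5800L),
                        end = c(399L, 2419L, 5819L),
                        windows = c("g1", "g3,g4", ""))
  out <- assign_targets(loc, ag)
  expect_equal(nrow(out), 4)
  expect_equal(out$location_id[1], "chr:380-399")
  g1 <- out[out$gene_id %in% "g1", ]
  expect_equal(g1$distance_to_start, abs(389.5 - 500))
  div <- out[out$location_id == "chr:2400-2419", ]
  expect_setequal(div$gene_id, c("g3", "g4"))
  # g3 is on "+": start codon at start = 1700... wait g3 ends 2300; site is
  # downstream of g3 but upstream of the "-" gene g4 whose start codon is
  # its end (3200)
  expect_equal(div$distance_to_start[div$gene_id == "g3"], abs(2409.5 - 1700))
  expect_equal(div$distance_to_start[div$gene_id == "g4"], abs(2409.5 - 3200))
  orphan <- out[out$location_id == "chr:5800-5819", ]
  expect_true(is.na(orphan$gene_id))
  expect_true(is.na(orphan$distance_to_start))
})

test_that("anticorrelation_filter assigns every status correctly", {
  genes <- c("reg", "a", "b", "c", "d")
  pcc <- diag(1, 5); dimnames(pcc) <- list(genes, genes)
  pv <- matrix(0, 5, 5, dimnames = list(genes, genes))
  set_pair <- function(i, j, r, p) {
    pcc[i, j] <<- r; pcc[j, i] <<- r; pv[i, j] <<- p; pv[j, i] <<- p
  }
  set_pair("reg", "a", -0.8, 1e-5)   # accepted
  set_pair("reg", "b", -0.8, 0.3)    # anti-correlated but not significant
  set_pair("reg", "c", 0.9, 1e-5)    # positively correlated
  set_pair("reg", "d", -0.1, 0.6)    # weak -> not significant
  corr <- corr_stub(pcc, pvalues = pv)
  cand <- data.frame(location_id = paste0("L", 1:6), contig = "chr",
                     site_start = 1:6, site_end = 21:26, score = 30,
                     gene_id = c("a", "b", "c", "d", NA, "unknown"),
                     strand = "+", distance_to_start = 100,
                     stringsAsFactors = FALSE)
  out <- anticorrelation_filter(cand, corr, "reg", r_threshold = -0.43)
  expect_equal(out$status,
               c("accepted", "not_significant", "positively_correlated",
                 "not_significant", "orphan", "untested"))
  expect_equal(out$pcc[1], -0.8)
  expect_equal(out$pvalue[2], 0.3)
  expect_error(anticorrelation_filter(cand, corr, "absent"),
               "regulator absent")
})

test_that("expand_operons walks strand-aware and stops at each rule", {
  ag <- toy_genome()
  # toy genome gaps: g1-g2 100, g2-g3 100, g3-g4 300 (and strand flips);
  # g4-g5 100 on "-"; g5-g6 700
  genes <- c("reg", paste0("g", 1:6))
  pcc <- matrix(0.9, 7, 7, dimnames = list(genes, genes)); diag(pcc) <- 1
  corr <- corr_stub(pcc)
  tg <- function(gene) data.frame(
    location_id = "L1", contig = "chr", site_start = 1, site_end = 20,
    score = 30, gene_id = gene, strand = "+", distance_to_start = 100,
    pcc = -0.8, pvalue = 1e-5, status = "accepted", stringsAsFactors = FALSE)
  # from g1 (+): extends to g2, g3; stops at g4 (strand flip + long gap)
  m1 <- expand_operons(tg("g1"), ag, corr)
  expect_equal(m1$gene_id, c("g1", "g2", "g3"))
  expect_equal(m1$role, c("target", "operon_member", "operon_member"))
  expect_equal(unique(m1$seed), "g1")
  # from g5 (-): walks downstream = decreasing coordinates -> g4
  m2 <- expand_operons(tg("g5"), ag, corr)
  expect_setequal(m2$gene_id, c("g5", "g4"))
  # co-expression break stops the walk
  pcc2 <- pcc; pcc2["g1", "g3"] <- pcc2["g3", "g1"] <- 0.1
  m3 <- expand_operons(tg("g1"), ag, corr_stub(pcc2), min_pcc = 0.43)
  expect_equal(m3$gene_id, c("g1", "g2"))
  # with anchor = "previous" the same walk continues (g2~g3 is still 0.9)
  m4 <- expand_operons(tg("g1"), ag, corr_stub(pcc2), min_pcc = 0.43,
                       anchor = "previous")
  expect_equal(m4$gene_id, c("g1", "g2", "g3"))
  # gap rule: lowering max_gap below 100 stops immediately
  m5 <- expand_operons(tg("g1"), ag, corr, max_gap = 50)
  expect_equal(m5$gene_id, "g1")
  # a gene reached twice is kept once, preferring the target role
  m6 <- expand_operons(rbind(tg("g1"), tg("g2")), ag, corr)
  expect_equal(sum(m6$gene_id == "g2"), 1)
  expect_equal(m6$role[m6$gene_id == "g2"], "target")
})

test_that("group_loci merges members within the intervening-gene bound", {
  ag <- toy_genome()
  # members g1, g3 (1 intervening), g6 (2 intervening after g3)
  loci <- group_loci(c("g1", "g3", "g6"), ag, max_intervening = 1)
  expect_equal(nrow(loci), 2)
  expect_equal(loci$members[1], "g1,g3")
  expect_equal(loci$n_members, c(2L, 1L))
  expect_equal(loci$start[1], 500)
  expect_equal(loci$end[1], 2300)
  # looser bound merges everything; count is non-increasing
  loci2 <- group_loci(c("g1", "g3", "g6"), ag, max_intervening = 5)
  expect_equal(nrow(loci2), 1)
  expect_equal(loci2$members, "g1,g3,g6")
  # empty input
  expect_equal(nrow(group_loci(character(0), ag)), 0)
})

test_that("regulon_statistics matches hand computation with exact Mann-Whitney", {
  genes <- c("reg", "m1", "m2", "m3")
  pcc <- diag(1, 4); dimnames(pcc) <- list(genes, genes)
  w <- c(0.9, 0.8, 0.7)           # within pairs m1m2, m1m3, m2m3
  pcc["m1", "m2"] <- pcc["m2", "m1"] <- w[1]
  pcc["m1", "m3"] <- pcc["m3", "m1"] <- w[2]
  pcc["m2", "m3"] <- pcc["m3", "m2"] <- w[3]
  r <- c(-0.6, -0.5, -0.4)
  for (i in 1:3) pcc["reg", paste0("m", i)] <-
    pcc[paste0("m", i), "reg"] <- r[i]
  st <- regulon_statistics(c("m1", "m2", "m3", "reg"), corr_stub(pcc), "reg")
  expect_equal(st$n_members, 3)
  expect_equal(st$n_within, 3)
  expect_equal(st$median_within, 0.8)
  expect_equal(st$median_regulator, -0.5)
  # all within (0.7-0.9) exceed all negated regulator pccs (0.4-0.6):
  # complete separation at 3 vs 3 gives exact one-sided p = 1/choose(6,3)
  expect_equal(st$p_value, 1 / choose(6, 3))
  expect_error(regulon_statistics("m1", corr_stub(pcc), "reg"),
               "at least 2 members")
})

test_that("build_regulon pipelines the steps and write_regulon round-trips", {
  ag <- toy_genome()
  genes <- c("g6", paste0("g", 1:5))   # g6 is the regulator
  pcc <- matrix(0.85, 6, 6, dimnames = list(genes, genes)); diag(pcc) <- 1
  for (g in paste0("g", 1:5)) pcc["g6", g] <- pcc[g, "g6"] <- -0.7
  corr <- corr_stub(pcc)
  loc <- make_locations(start = c(380L, 3950L), end = c(399L, 3969L),
                        windows = c("g1", "g5"))
  reg <- build_regulon(loc, ag, corr, "g6")
  expect_s3_class(reg, "regulon")
  expect_equal(nrow(reg$direct_targets), 2)
  expect_setequal(reg$members$gene_id, paste0("g", 1:5))
  expect_equal(nrow(reg$loci), 1)   # g1..g5 consecutive -> one locus
  expect_equal(reg$statistics$n_members, 5)
  expect_equal(reg$statistics$median_within, 0.85)
  expect_equal(reg$statistics$median_regulator, -0.7)
  expect_output(print(reg), "Regulon of g6")
  tsv <- tempfile(fileext = ".tsv"); bed <- tempfile(fileext = ".bed")
  write_regulon(reg, tsv, bed)
  tab <- read.table(tsv, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  expect_equal(tab$role[1], "regulator")
  expect_equal(tab$gene_id[1], "g6")
  expect_setequal(tab$gene_id[-1], paste0("g", 1:5))
  expect_true(all(tab$locus_id[-1] == "locus_01"))
  btab <- read.table(bed, sep = "\t")
  expect_equal(nrow(btab), 1)
  expect_equal(btab$V2, 500)
})
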