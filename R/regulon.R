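## Regulon assembly: unique binding-site locations -> candidate targets ->
## anti-correlation filter -> operon expansion -> genomic loci -> summary
## statistics.

#' Map unique binding-site locations to candidate target genes
#'
#' Each location's candidate targets are the gene(s) whose regulatory window
#' contains it — one gene, or two for a site in a divergent intergenic
#' region. Candidates carry their strand and the distance from the site to
#' the start codon. Locations inside no window are reported as orphans (one
#' row with `gene_id = NA`), not dropped.
#'
#' @param locations `site_locations` from [filter_and_dedupe()].
#' @param genome An [annotated_genome()].
#' @return `data.frame`: `location_id` (`contig:start-end`), `contig`,
#'   `site_start`, `site_end`, `score`, `gene_id`, `strand`,
#'   `distance_to_start` (bp from site midpoint to start codon; `NA` for
#'   orphans).
#' @export
assign_targets <- function(locations, genome) {
  stopifnot(inherits(genome, "annotated_genome"))
  g <- genome$genes
  rows <- lapply(seq_len(nrow(locations)), function(i) {
    loc <- locations[i, ]
    id <- sprintf("%s:%d-%d", loc$contig, loc$start, loc$end)
    genes <- strsplit(loc$windows, ",")[[1]]
    genes <- genes[nzchar(genes)]
    if (length(genes) == 0) {
      return(data.frame(location_id = id, contig = loc$contig,
                        site_start = loc$start, site_end = loc$end,
                        score = loc$score, gene_id = NA_character_,
                        strand = NA_character_,
                        distance_to_start = NA_real_,
                        stringsAsFactors = FALSE))
    }
    mid <- loc$start + (loc$end - loc$start) / 2
    do.call(rbind, lapply(genes, function(gid) {
      gg <- g[g$gene_id == gid, ]
      start_codon <- if (gg$strand == "+") gg$start else gg$end
      data.frame(location_id = id, contig = loc$contig,
                 site_start = loc$start, site_end = loc$end,
                 score = loc$score, gene_id = gid, strand = gg$strand,
                 distance_to_start = abs(mid - start_codon),
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Filter candidate targets by anti-correlation with the regulator
#'
#' A repressor's direct targets are expected to be anti-correlated with the
#' regulator's own transcript. Candidates are kept when
#' `PCC(candidate, regulator) < r_threshold` and `p < alpha`; failing
#' candidates stay in the output with a status flag (they are part of the
#' reported result, e.g. positively co-expressed regulators of the same
#' locus).
#'
#' @param candidates Output of [assign_targets()].
#' @param corr A [correlation_with_pvalues()] result.
#' @param regulator Regulator gene id (must be in the correlation matrix).
#' @param r_threshold Correlation threshold (strict `<`), default -0.43.
#' @param alpha Significance level on the Student p-value.
#' @return `candidates` with added `pcc`, `pvalue` and `status` in
#'   `accepted`, `not_significant`, `positively_correlated`, `untested`
#'   (absent from the expression data), `orphan`.
#' @export
anticorrelation_filter <- function(candidates, corr, regulator,
                                   r_threshold = -0.43, alpha = 0.05) {
  stopifnot(inherits(corr, "correlation_result"))
  if (!regulator %in% rownames(corr$pcc))
    stop("regulator absent from correlation matrix")
  out <- candidates
  out$pcc <- NA_real_
  out$pvalue <- NA_real_
  out$status <- "untested"
  known <- rownames(corr$pcc)
  for (i in seq_len(nrow(out))) {
    gid <- out$gene_id[i]
    if (is.na(gid)) { out$status[i] <- "orphan"; next }
    if (!gid %in% known) next
    r <- corr$pcc[regulator, gid]
    p <- corr$pvalues[regulator, gid]
    out$pcc[i] <- r
    out$pvalue[i] <- p
    if (is.na(r)) next
    out$status[i] <- if (r < r_threshold && p < alpha) "accepted"
    else if (r > abs(r_threshold) && p < alpha) "positively_correlated"
    else "not_significant"
  }
  out
}

#' Expand accepted targets through predicted operons
#'
#' From each accepted target, walks downstream in the target's transcription
#' direction and appends the next gene while it (a) lies on the same strand,
#' (b) is separated by an intergenic gap of at most `max_gap`, and (c) is
#' co-expressed with the operon's seed gene at `PCC >= min_pcc`; the walk
#' stops at the first failure. Anchoring co-expression to the seed (rather
#' than the preceding gene) prevents slow drift across long runs;
#' `anchor = "previous"` selects the alternative.
#'
#' @param targets Filtered candidates (only `status == "accepted"` rows are
#'   expanded; pass the full table).
#' @param genome An [annotated_genome()].
#' @param corr A [correlation_with_pvalues()] result.
#' @param max_gap Maximum intergenic gap in bp (default 200, a conventional
#'   bacterial operon spacing bound).
#' @param min_pcc Minimum co-expression with the seed; defaults to the
#'   critical PCC at the dataset's sample count ([critical_pcc()]).
#' @param anchor `"seed"` (default) or `"previous"`.
#' @return `data.frame`: `gene_id`, `role` (`target`/`operon_member`),
#'   `seed` (the operon's target gene), `location_id`, `score`, `pcc`,
#'   `pvalue`.
#' @export
expand_operons <- function(targets, genome, corr, max_gap = 200,
                           min_pcc = critical_pcc(corr$n_samples),
                           anchor = c("seed", "previous")) {
  stopifnot(inherits(genome, "annotated_genome"),
            inherits(corr, "correlation_result"))
  anchor <- match.arg(anchor)
  acc <- targets[targets$status == "accepted", , drop = FALSE]
  g <- genome$genes
  known <- rownames(corr$pcc)
  rows <- list()
  for (i in seq_len(nrow(acc))) {
    seed <- acc$gene_id[i]
    rows[[length(rows) + 1]] <- data.frame(
      gene_id = seed, role = "target", seed = seed,
      location_id = acc$location_id[i], score = acc$score[i],
      pcc = acc$pcc[i], pvalue = acc$pvalue[i], stringsAsFactors = FALSE)
    si <- which(g$gene_id == seed)
    strand <- g$strand[si]
    cur <- si
    ref <- seed
    repeat {
      nxt <- if (strand == "+") cur + 1L else cur - 1L
      if (nxt < 1 || nxt > nrow(g)) break
      if (g$contig[nxt] != g$contig[cur]) break
      if (g$strand[nxt] != strand) break
      gap <- if (strand == "+") g$start[nxt] - g$end[cur]
      else g$start[cur] - g$end[nxt]
      if (gap > max_gap) break
      gid <- g$gene_id[nxt]
      cmp <- if (anchor == "seed") seed else ref
      if (!(gid %in% known) || !(cmp %in% known)) break
      r <- corr$pcc[cmp, gid]
      if (is.na(r) || r < min_pcc) break
      rows[[length(rows) + 1]] <- data.frame(
        gene_id = gid, role = "operon_member", seed = seed,
        location_id = acc$location_id[i], score = NA_real_,
        pcc = corr$pcc[seed, gid], pvalue = corr$pvalues[seed, gid],
        stringsAsFactors = FALSE)
      cur <- nxt
      ref <- gid
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(gene_id = character(), role = character(),
                      seed = character(), location_id = character(),
                      score = numeric(), pcc = numeric(), pvalue = numeric(),
                      stringsAsFactors = FALSE)
  # a gene reached from two targets is kept once, preferring the target role
  out <- out[order(out$gene_id, out$role != "target"), , drop = FALSE]
  out <- out[!duplicated(out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Group regulon members into genomic loci
#'
#' Sorts members by genomic position and merges consecutive members
#' separated by at most `max_intervening` non-member genes into one locus.
#' Idempotent; the locus count is non-increasing in `max_intervening`.
#'
#' @param members Character vector of member gene ids (or the table from
#'   [expand_operons()]).
#' @param genome An [annotated_genome()].
#' @param max_intervening Maximum number of intervening non-member genes.
#' @return `data.frame`: `locus_id`, `contig`, `start`, `end`, `n_members`,
#'   `members` (comma-separated, in genomic order).
#' @export
group_loci <- function(members, genome, max_intervening = 5) {
  if (is.data.frame(members)) members <- members$gene_id
  g <- genome$genes
  idx <- which(g$gene_id %in% members)
  if (length(idx) == 0)
    return(data.frame(locus_id = character(), contig = character(),
                      start = integer(), end = integer(),
                      n_members = integer(), members = character(),
                      stringsAsFactors = FALSE))
  locus <- cumsum(c(1, diff(idx) > max_intervening + 1 |
                      g$contig[idx[-1]] != g$contig[idx[-length(idx)]]))
  out <- do.call(rbind, lapply(split(idx, locus), function(ii) {
    data.frame(contig = g$contig[ii[1]],
               start = min(g$start[ii]), end = max(g$end[ii]),
               n_members = length(ii),
               members = paste(g$gene_id[ii], collapse = ","),
               stringsAsFactors = FALSE)
  }))
  out <- cbind(data.frame(locus_id = sprintf("locus_%02d", seq_len(nrow(out))),
                          stringsAsFactors = FALSE), out)
  rownames(out) <- NULL
  out
}

#' Regulon co-expression statistics
#'
#' Reports the median pairwise PCC among regulon members (upper triangle),
#' the median PCC between members and the regulator, and a one-sided
#' Mann-Whitney U test of whether within-regulon correlations are
#' stochastically greater than the *negated* member-regulator correlations.
#' The U statistic is exact (full enumeration) when both groups have at most
#' 8 tie-free values, otherwise the normal approximation with tie and
#' continuity correction is used. The two groups share genes, so the
#' p-value is a descriptive index of separation, not an independent-sample
#' inference.
#'
#' @param members Member gene ids (regulator excluded automatically).
#' @param corr A [correlation_with_pvalues()] result.
#' @param regulator Regulator gene id.
#' @return List: `median_within`, `median_regulator`, `p_value`, `n_within`,
#'   `n_members`.
#' @export
regulon_statistics <- function(members, corr, regulator) {
  if (is.data.frame(members)) members <- members$gene_id
  members <- setdiff(intersect(members, rownames(corr$pcc)), regulator)
  if (length(members) < 2) stop("need at least 2 members with expression")
  sub <- corr$pcc[members, members]
  within <- sub[upper.tri(sub)]
  to_reg <- corr$pcc[members, regulator]
  within <- within[!is.na(within)]
  to_reg <- to_reg[!is.na(to_reg)]
  exact <- length(within) <= 8 && length(to_reg) <= 8 &&
    !any(duplicated(c(within, -to_reg)))
  p <- suppressWarnings(
    wilcox.test(within, -to_reg, alternative = "greater",
                exact = exact, correct = TRUE)$p.value)
  list(median_within = median(within),
       median_regulator = median(to_reg),
       p_value = p,
       n_within = length(within),
       n_members = length(members))
}

#' Assemble a regulon from locations and co-expression
#'
#' Convenience wrapper: [assign_targets()] -> [anticorrelation_filter()] ->
#' [expand_operons()] -> [group_loci()] -> [regulon_statistics()].
#'
#' @param locations `site_locations` from [filter_and_dedupe()].
#' @param genome An [annotated_genome()].
#' @param corr A [correlation_with_pvalues()] result.
#' @param regulator Regulator gene id.
#' @param r_threshold,alpha Anti-correlation filter parameters; the default
#'   threshold is minus the critical PCC at the dataset's sample count.
#' @param max_gap,min_pcc Operon-expansion parameters.
#' @param max_intervening Locus-grouping parameter.
#' @return Object of class `regulon`: list with `regulator`, `candidates`,
#'   `direct_targets`, `members` (expansion table), `loci`, `statistics`.
#' @export
build_regulon <- function(locations, genome, corr, regulator,
                          r_threshold = -critical_pcc(corr$n_samples),
                          alpha = 0.05, max_gap = 200,
                          min_pcc = critical_pcc(corr$n_samples),
                          max_intervening = 5) {
  candidates <- assign_targets(locations, genome)
  candidates <- anticorrelation_filter(candidates, corr, regulator,
                                       r_threshold, alpha)
  members <- expand_operons(candidates, genome, corr, max_gap, min_pcc)
  loci <- group_loci(members, genome, max_intervening)
  stats <- if (sum(!is.na(members$gene_id)) >= 2)
    regulon_statistics(members, corr, regulator) else NULL
  structure(list(regulator = regulator,
                 candidates = candidates,
                 direct_targets = candidates[candidates$status == "accepted", ],
                 members = members,
                 loci = loci,
                 statistics = stats),
            class = "regulon")
}

#' @export
print.regulon <- function(x, ...) {
  cat(sprintf("Regulon of %s\n", x$regulator))
  cat(sprintf("  %d candidate targets at %d unique locations\n",
              sum(!is.na(x$candidates$gene_id)),
              length(unique(x$candidates$location_id))))
  cat(sprintf("  %d accepted (anti-correlated) targets\n",
              nrow(x$direct_targets)))
  cat(sprintf("  %d members after operon expansion, %d loci\n",
              nrow(x$members), nrow(x$loci)))
  if (!is.null(x$statistics)) {
    cat(sprintf(
      "  median within-regulon PCC %.2f; median PCC to regulator %.2f (Mann-Whitney p = %.3g)\n",
      x$statistics$median_within, x$statistics$median_regulator,
      x$statistics$p_value))
  }
  invisible(x)
}

#' Write a regulon as TSV (+ loci BED)
#'
#' @param regulon A [build_regulon()] object.
#' @param tsv Member-table path (gene, role, location, score, PCC, p, locus).
#' @param loci_bed Optional BED path for the loci.
#' @return `tsv`, invisibly.
#' @export
write_regulon <- function(regulon, tsv, loci_bed = NULL) {
  tab <- regulon$members
  tab$locus_id <- rep(NA_character_, nrow(tab))
  for (i in seq_len(nrow(regulon$loci))) {
    ids <- strsplit(regulon$loci$members[i], ",")[[1]]
    tab$locus_id[tab$gene_id %in% ids] <- regulon$loci$locus_id[i]
  }
  reg_row <- data.frame(gene_id = regulon$regulator, role = "regulator",
                        seed = NA, location_id = NA, score = NA, pcc = NA,
                        pvalue = NA, locus_id = NA, stringsAsFactors = FALSE)
  write.table(rbind(reg_row, tab), tsv, sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(loci_bed)) {
    l <- regulon$loci
    write.table(data.frame(l$contig, l$start, l$end, l$locus_id,
                           l$n_members, "."),
                loci_bed, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  }
  invisible(tsv)
}
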