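## Genome scanning with an exact p-value-derived score floor.

encode_dna <- function(seq) {
  match(strsplit(toupper(seq), "", fixed = TRUE)[[1]], DNA_BASES)
}

#' Reverse complement of a DNA string
#'
#' @param seq Single DNA string (ACGT).
#' @return The reverse-complemented string.
#' @examples
#' reverse_complement("TTAGG")
#' @export
reverse_complement <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# PWM whose forward-strand score at offset i equals the original PWM's score
# of the reverse complement of the window at i.
rc_pwm_scores <- function(scores) {
  scores[4:1, ncol(scores):1, drop = FALSE]
}

#' Score floor for a target p-value by exact convolution
#'
#' Builds the exact null distribution of PWM scores of i.i.d. background
#' sequences: per-column scores are discretized to `granularity` bits
#' (rounded toward -Inf, so the floor is conservative) and convolved
#' position-wise. Returns the least score `s` with `P(score >= s) <= p`.
#'
#' @param pwm A [pfm_to_pwm()] object.
#' @param background Background composition (defaults to the PWM's own).
#' @param p Tail probability in (0, 1); the study regime uses 0.01.
#' @param granularity Discretization step in bits (default 0.001, negligible
#'   against thresholds of order 20 bits).
#' @return Score floor in bits, with attribute `tail_prob` giving the exact
#'   discretized tail probability at the floor.
#' @export
score_threshold_from_pvalue <- function(pwm, background = pwm$background,
                                        p = 0.01, granularity = 0.001) {
  stopifnot(inherits(pwm, "pwm"))
  if (!is.numeric(p) || length(p) != 1 || p <= 0 || p >= 1)
    stop("p must lie strictly between 0 and 1")
  bg <- as.numeric(as_background(background))
  L <- ncol(pwm$scores)
  units <- matrix(as.integer(floor(pwm$scores / granularity)), nrow = 4)
  col_min <- apply(units, 2, min)
  col_max <- apply(units, 2, max)
  # dist[k] = P(discretized score == offset + k - 1)
  dist <- 1
  offset <- 0L
  for (j in seq_len(L)) {
    width <- length(dist) + (col_max[j] - col_min[j])
    new <- numeric(width)
    for (b in 1:4) {
      sh <- units[b, j] - col_min[j]
      idx <- seq_along(dist) + sh
      new[idx] <- new[idx] + bg[b] * dist
    }
    dist <- new
    offset <- offset + col_min[j]
  }
  tail <- rev(cumsum(rev(dist)))   # tail[k] = P(score >= offset + k - 1)
  ok <- which(tail <= p)
  if (length(ok) == 0) {
    warning("p too small for any score to qualify; returning max_score")
    floor_bits <- pwm$max_score
    tp <- tail[length(tail)]
  } else {
    k <- ok[1]
    floor_bits <- (offset + k - 1) * granularity
    tp <- tail[k]
  }
  structure(floor_bits, tail_prob = tp)
}

score_offsets <- function(ints, scores) {
  # ints: integer-coded sequence; scores: 4 x L matrix
  L <- ncol(scores)
  n <- length(ints) - L + 1
  if (n < 1) return(numeric(0))
  s <- numeric(n)
  for (j in seq_len(L)) {
    s <- s + scores[, j][ints[j:(n + j - 1)]]
  }
  s
}

#' Scan an annotated genome for PWM matches above a score floor
#'
#' Every motif-length window of every contig is scored on the forward
#' sequence and on its reverse complement; placements with score >= `floor`
#' are reported with 0-based half-open forward-strand coordinates. Hits are
#' labelled `coding`/`noncoding` by their midpoint against the merged coding
#' intervals, annotated with every regulatory window that fully contains
#' them, and given a confidence tier via [classify_confidence()].
#'
#' Palindromic placements matching on both strands are emitted twice (once
#' per strand); deduplication into unique locations is the calibration
#' stage's job ([filter_and_dedupe()]).
#'
#' @param genome An [annotated_genome()].
#' @param regions A [extract_regions()] region set for the same genome.
#' @param pwm A [pfm_to_pwm()] object.
#' @param floor Score floor in bits, usually from
#'   [score_threshold_from_pvalue()].
#' @param confidence_fraction Passed to [classify_confidence()].
#' @return `data.frame` of class `motif_hits` with columns `contig`, `start`,
#'   `end`, `strand`, `score`, `region_class`, `windows` (comma-separated
#'   gene ids, `""` if none) and `confidence`.
#' @export
scan_genome <- function(genome, regions, pwm, floor,
                        confidence_fraction = 0.7) {
  stopifnot(inherits(genome, "annotated_genome"),
            inherits(regions, "region_set"), inherits(pwm, "pwm"))
  if (floor < pwm$min_score - 1e-9 || floor > pwm$max_score + 1e-9)
    stop("floor outside [min_score, max_score]")
  L <- motif_length(pwm)
  rc <- rc_pwm_scores(pwm$scores)
  hits <- lapply(names(genome$contigs), function(ct) {
    seq <- genome$contigs[[ct]]
    if (nchar(seq) < L) return(NULL)   # region shorter than motif: skipped
    ints <- encode_dna(seq)
    fwd <- score_offsets(ints, pwm$scores)
    rev <- score_offsets(ints, rc)
    fi <- which(fwd >= floor)
    ri <- which(rev >= floor)
    if (length(fi) + length(ri) == 0) return(NULL)
    data.frame(
      contig = ct,
      start = c(fi, ri) - 1L,
      end = c(fi, ri) - 1L + L,
      strand = rep(c("+", "-"), c(length(fi), length(ri))),
      score = c(fwd[fi], rev[ri]),
      stringsAsFactors = FALSE)
  })
  hits <- do.call(rbind, hits)
  if (is.null(hits))
    hits <- data.frame(contig = character(), start = integer(),
                       end = integer(), strand = character(),
                       score = numeric(), stringsAsFactors = FALSE)
  hits <- hits[order(hits$contig, hits$start, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  hits$region_class <- classify_region(hits, regions)
  hits$windows <- containing_windows(hits, regions)
  hits$confidence <- classify_confidence(hits, pwm, confidence_fraction)
  class(hits) <- c("motif_hits", "data.frame")
  attr(hits, "floor") <- floor
  attr(hits, "max_score") <- pwm$max_score
  hits
}

classify_region <- function(hits, regions) {
  if (nrow(hits) == 0) return(character(0))
  mid <- hits$start + (hits$end - hits$start) %/% 2L
  out <- rep("noncoding", nrow(hits))
  for (ct in unique(hits$contig)) {
    hi <- which(hits$contig == ct)
    cod <- regions$coding[regions$coding$contig == ct, , drop = FALSE]
    if (nrow(cod) == 0) next
    # midpoint m is coding iff some interval has start <= m < end
    idx <- findInterval(mid[hi], cod$start)
    inside <- idx >= 1 & mid[hi] < cod$end[pmax(idx, 1)]
    out[hi][inside] <- "coding"
  }
  out
}

containing_windows <- function(hits, regions) {
  if (nrow(hits) == 0) return(character(0))
  out <- character(nrow(hits))
  reg <- regions$regulatory
  for (ct in unique(hits$contig)) {
    hi <- which(hits$contig == ct)
    w <- reg[reg$contig == ct, , drop = FALSE]
    if (nrow(w) == 0) next
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(hits$start[hi] + 1L, hits$end[hi]),
      IRanges::IRanges(w$start + 1L, w$end),
      type = "within")
    ids <- split(w$gene_id[S4Vectors::subjectHits(ov)],
                 S4Vectors::queryHits(ov))
    for (q in names(ids)) {
      out[hi[as.integer(q)]] <- paste(sort(unique(ids[[q]])), collapse = ",")
    }
  }
  out
}

#' Confidence tier of motif hits
#'
#' Hits already above the p-value floor are split into tiers by score:
#' `medium_high` when score >= `fraction * max_score`, else `low`.
#'
#' @param hits `motif_hits` data.frame (or anything with a `score` column).
#' @param pwm The scanning PWM (supplies `max_score`).
#' @param fraction Fraction of the maximum attainable score (default 0.7).
#' @return Character vector, `"low"` or `"medium_high"`.
#' @export
classify_confidence <- function(hits, pwm, fraction = 0.7) {
  stopifnot(inherits(pwm, "pwm"), fraction >= 0)
  ifelse(hits$score >= fraction * pwm$max_score, "medium_high", "low")
}

#' Associate motif hits with candidate gene-cluster regions
#'
#' Labels each hit `inside`, `peripheral` or `outside` relative to a set of
#' genomic regions (e.g. predicted biosynthetic gene clusters). A hit is
#' `peripheral` when it lies within a region but within `periphery` bp of
#' either region edge.
#'
#' @param hits `motif_hits` data.frame.
#' @param bgc_regions `data.frame` with `contig`, `start`, `end` (0-based
#'   half-open) and optionally `region_id`.
#' @param periphery Edge margin in bp.
#' @return `hits` with added columns `bgc_status` and `bgc_region`.
#' @export
associate_hits_with_regions <- function(hits, bgc_regions, periphery = 5000) {
  stopifnot(is.data.frame(bgc_regions))
  if (is.null(bgc_regions$region_id))
    bgc_regions$region_id <- paste0("region_", seq_len(nrow(bgc_regions)))
  status <- rep("outside", nrow(hits))
  region <- rep(NA_character_, nrow(hits))
  mid <- hits$start + (hits$end - hits$start) %/% 2L
  for (i in seq_len(nrow(bgc_regions))) {
    r <- bgc_regions[i, ]
    inside <- hits$contig == r$contig & mid >= r$start & mid < r$end
    if (!any(inside)) next
    near_edge <- inside &
      (mid - r$start <= periphery | r$end - 1L - mid <= periphery)
    status[inside & status == "outside"] <- "inside"
    status[near_edge] <- "peripheral"
    region[inside] <- r$region_id
  }
  hits$bgc_status <- status
  hits$bgc_region <- region
  hits
}

#' Write motif hits as BED6 (+ full-precision sidecar TSV)
#'
#' BED name is the first regulatory-window gene (or `.`); BED score is the
#' PWM score in bits x 100, rounded and capped at 1000 per BED convention.
#' The sidecar TSV keeps full precision and all columns.
#'
#' @param hits `motif_hits` data.frame.
#' @param bed Output BED path.
#' @param tsv Optional sidecar TSV path.
#' @return `bed`, invisibly.
#' @export
write_hits_bed <- function(hits, bed, tsv = NULL) {
  name <- vapply(strsplit(hits$windows, ","), function(w)
    if (length(w) && nzchar(w[1])) w[1] else ".", character(1))
  bed_df <- data.frame(hits$contig, hits$start, hits$end, name,
                       pmin(1000L, as.integer(round(hits$score * 100))),
                       hits$strand)
  write.table(bed_df, bed, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  if (!is.null(tsv))
    write.table(hits, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(bed)
}
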