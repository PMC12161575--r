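## Species-level calibration of the motif score threshold from the
## non-coding/coding hit ratio, and deduplication of surviving hits into
## unique binding-site locations.

#' Non-coding/coding hit-ratio calibration curve
#'
#' For an ascending grid of score thresholds `s`, counts the hits with score
#' `>= s` in non-coding and coding regions and the bounded percentage ratio
#' `100 * n_noncoding / (n_noncoding + n_coding)` (reported as `NA` where no
#' hits remain). Random matches fall mostly in coding sequence of a dense
#' bacterial genome, while genuine binding sites sit in non-coding regulatory
#' DNA, so the ratio rises with the threshold.
#'
#' @param hits `motif_hits` data.frame carrying `score` and `region_class`.
#' @param grid_step Grid resolution in bits (default 0.125, which resolves
#'   thresholds quoted to 1/8 bit).
#' @param raw_quotient Also report the unbounded quotient
#'   `n_noncoding / n_coding` (`Inf` when no coding hits remain).
#' @return Object of class `calibration_curve`: data.frame with columns
#'   `threshold`, `n_noncoding`, `n_coding`, `ratio` (and optionally
#'   `quotient`).
#' @export
ratio_curve <- function(hits, grid_step = 0.125, raw_quotient = FALSE) {
  if (nrow(hits) == 0) stop("empty hit list")
  lo <- floor(min(hits$score) / grid_step) * grid_step
  hi <- ceiling(max(hits$score) / grid_step) * grid_step
  grid <- seq(lo, hi, by = grid_step)
  nc <- vapply(grid, function(s)
    sum(hits$score >= s & hits$region_class == "noncoding"), integer(1))
  cc <- vapply(grid, function(s)
    sum(hits$score >= s & hits$region_class == "coding"), integer(1))
  tot <- nc + cc
  ratio <- ifelse(tot > 0, 100 * nc / tot, NA_real_)
  out <- data.frame(threshold = grid, n_noncoding = nc, n_coding = cc,
                    ratio = ratio)
  if (raw_quotient) out$quotient <- ifelse(cc > 0, nc / cc, Inf)
  class(out) <- c("calibration_curve", "data.frame")
  out
}

#' Refined score threshold from the hit distribution
#'
#' Two readings of the published calibration are implemented:
#' \describe{
#'   \item{`ratio_median_crossing`}{the smallest grid score from which the
#'     non-coding/coding ratio stays at or above the median of its defined
#'     values — i.e. the score where non-coding hits durably start to
#'     dominate. The crossing is sustained, not first-touch: near the top
#'     of the S-curve single hits make the ratio jittery, and a momentary
#'     touch of the median at a low score would otherwise set the
#'     threshold. This is the recommended default: with a permissive
#'     p-value floor the hit list is dominated by near-floor random
#'     matches, and the crossing point is what actually separates them from
#'     binding-site-like scores.}
#'   \item{`median_hit_score`}{the plain median of all hit scores above the
#'     p-value floor (even counts give the midpoint of the central pair).}
#' }
#'
#' @param hits `motif_hits` data.frame.
#' @param method See above.
#' @param grid_step Grid resolution for `ratio_median_crossing`.
#' @return Threshold score in bits.
#' @export
refined_threshold <- function(hits,
                              method = c("ratio_median_crossing",
                                         "median_hit_score"),
                              grid_step = 0.125) {
  if (nrow(hits) == 0) stop("empty hit list")
  method <- match.arg(method)
  if (method == "median_hit_score") return(median(hits$score))
  curve <- ratio_curve(hits, grid_step = grid_step)
  defined <- !is.na(curve$ratio)
  med <- median(curve$ratio[defined])
  below <- which(defined & curve$ratio < med)
  if (length(below) == 0) return(curve$threshold[which(defined)[1]])
  after <- which(defined & seq_len(nrow(curve)) > max(below))
  if (length(after) == 0)
    stop("ratio never sustainedly reaches its median; degenerate curve")
  curve$threshold[after[1]]
}

#' Filter hits by a threshold and deduplicate into unique locations
#'
#' Keeps hits with `score >= threshold`, then collapses them into unique
#' binding-site locations: hits whose intervals overlap on the same contig
#' belong to one location, regardless of strand (palindromic motifs match
#' both strands) and regardless of how many regulatory windows report them.
#' One physical site typically produces several overlapping matches — the
#' reverse-complement match and shifted partial alignments of a repetitive
#' or palindromic motif — so several predicted sites collapse to far fewer
#' unique locations. Each location is represented by the interval of its
#' best-scoring hit and retains the strands it was seen on and the union of
#' candidate window genes.
#'
#' @param hits `motif_hits` data.frame.
#' @param threshold Score threshold in bits.
#' @return List with `hits` (surviving hits) and `locations` (data.frame of
#'   class `site_locations`: `contig,start,end,score,strands,windows,
#'   region_class,n_hits`).
#' @export
filter_and_dedupe <- function(hits, threshold) {
  keep <- hits[hits$score >= threshold, , drop = FALSE]
  if (nrow(keep) == 0) {
    loc <- data.frame(contig = character(), start = integer(),
                      end = integer(), score = numeric(),
                      strands = character(), windows = character(),
                      region_class = character(), n_hits = integer(),
                      stringsAsFactors = FALSE)
  } else {
    keep <- keep[order(keep$contig, keep$start, keep$end), , drop = FALSE]
    # chain overlapping intervals per contig into location clusters
    new_cluster <- c(TRUE, keep$contig[-1] != keep$contig[-nrow(keep)] |
                       keep$start[-1] >= cummax_by(keep$end, keep$contig)[-nrow(keep)])
    cluster <- cumsum(new_cluster)
    loc <- do.call(rbind, lapply(split(seq_len(nrow(keep)), cluster), function(i) {
      sub <- keep[i, , drop = FALSE]
      best <- sub[which.max(sub$score), , drop = FALSE]
      genes <- unlist(strsplit(sub$windows, ","))
      genes <- sort(unique(genes[nzchar(genes)]))
      data.frame(contig = best$contig, start = best$start,
                 end = best$end, score = best$score,
                 strands = paste(sort(unique(sub$strand)), collapse = ""),
                 windows = paste(genes, collapse = ","),
                 region_class = best$region_class, n_hits = nrow(sub),
                 stringsAsFactors = FALSE)
    }))
    loc <- loc[order(loc$contig, loc$start), , drop = FALSE]
    rownames(loc) <- NULL
  }
  class(loc) <- c("site_locations", "data.frame")
  list(hits = keep, locations = loc)
}

# running maximum of `x` restarted at each change of `group`
# (groups must be contiguous)
cummax_by <- function(x, group) {
  unlist(lapply(split(x, factor(group, levels = unique(group))), cummax),
         use.names = FALSE)
}

#' Plot a calibration curve
#'
#' Draws the hit-score distribution (shaded density, left axis) with the
#' non-coding/coding ratio S-curve (right axis, percent) and the chosen
#' threshold as a vertical line.
#'
#' @param x A [ratio_curve()] object.
#' @param hits The hit table the curve was computed from (for the density).
#' @param threshold Optional threshold to mark.
#' @param ... Base-graphics arguments.
#' @return Invisibly, `x`.
#' @export
plot.calibration_curve <- function(x, hits = NULL, threshold = NULL, ...) {
  op <- par(mar = c(5, 4, 2, 4))
  on.exit(par(op))
  plot(x$threshold, x$ratio, type = "l", col = "steelblue", lwd = 2,
       xlab = "PWM score threshold (bits)", ylab = "Non-coding hits (%)",
       ylim = c(0, 100), ...)
  if (!is.null(hits) && nrow(hits) > 1) {
    d <- density(hits$score)
    polygon(d$x, d$y / max(d$y) * 100, col = adjustcolor("grey", 0.5),
            border = NA)
    lines(x$threshold, x$ratio, col = "steelblue", lwd = 2)
  }
  if (!is.null(threshold)) abline(v = threshold, col = "darkorange", lty = 2)
  invisible(x)
}
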