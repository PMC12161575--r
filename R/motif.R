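#' @include regumine-package.R
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Background base composition from a GC fraction
#'
#' Strand-symmetric mononucleotide background: P(G) = P(C) = gc/2 and
#' P(A) = P(T) = (1 - gc)/2.
#'
#' @param gc GC fraction in (0, 1). Use 0.72 for a typical *Streptomyces*
#'   chromosome.
#' @return An object of class `background`: a named numeric vector over
#'   A, C, G, T with attribute `gc`.
#' @examples
#' gc_background(0.72)
#' @export
gc_background <- function(gc = 0.5) {
  stopifnot(is.numeric(gc), length(gc) == 1, is.finite(gc))
  if (gc <= 0 || gc >= 1) stop("gc must lie strictly between 0 and 1")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  structure(p, gc = gc, class = "background")
}

as_background <- function(x) {
  if (inherits(x, "background")) return(x)
  if (is.numeric(x) && length(x) == 1) return(gc_background(x))
  if (is.numeric(x) && length(x) == 4) {
    if (abs(sum(x) - 1) > 1e-8) stop("background probabilities must sum to 1")
    nm <- names(x)
    if (is.null(nm)) names(x) <- DNA_BASES else x <- x[DNA_BASES]
    return(structure(x, gc = unname(x["C"] + x["G"]), class = "background"))
  }
  stop("background must be a GC fraction or a 4-vector of base probabilities")
}

#' Build a position frequency matrix from aligned binding sites
#'
#' Counts base occurrences per column over a set of equal-length,
#' gap-free nucleotide strings (the curated binding-site alignment).
#'
#' @param sites Character vector of aligned sites, all of the same length,
#'   alphabet A/C/G/T only (no IUPAC ambiguity codes).
#' @return An object of class `pfm`: list with `counts` (4 x L integer
#'   matrix, rows A,C,G,T), `n_sites` and `length`.
#' @examples
#' build_pfm(c("TTAGG", "TTAGG", "TAAGG"))
#' @export
build_pfm <- function(sites) {
  if (inherits(sites, "DNAStringSet")) sites <- as.character(sites)
  stopifnot(is.character(sites))
  if (length(sites) < 1) stop("need at least one site")
  sites <- toupper(sites)
  L <- unique(nchar(sites))
  if (length(L) != 1) stop("sites must all have the same length")
  if (L < 1) stop("sites must be non-empty")
  chars <- matrix(unlist(strsplit(sites, "", fixed = TRUE), use.names = FALSE),
                  nrow = length(sites), ncol = L, byrow = TRUE)
  if (!all(chars %in% DNA_BASES)) {
    bad <- setdiff(unique(as.vector(chars)), DNA_BASES)
    stop("non-ACGT characters in sites: ", paste(bad, collapse = ", "))
  }
  counts <- vapply(seq_len(L), function(i) {
    tabulate(match(chars[, i], DNA_BASES), nbins = 4L)
  }, integer(4))
  dimnames(counts) <- list(DNA_BASES, NULL)
  structure(list(counts = counts, n_sites = length(sites), length = L),
            class = "pfm")
}

#' @export
print.pfm <- function(x, ...) {
  cat(sprintf("Position frequency matrix: %d sites, %d bp\n",
              x$n_sites, x$length))
  print(x$counts)
  cat("Consensus:", consensus_sequence(x), "\n")
  invisible(x)
}

#' Consensus sequence of a PFM (ties broken by A<C<G<T order)
#' @param pfm A [build_pfm()] object.
#' @return Character scalar.
#' @export
consensus_sequence <- function(pfm) {
  stopifnot(inherits(pfm, "pfm"))
  paste(DNA_BASES[apply(pfm$counts, 2, which.max)], collapse = "")
}

#' Convert a PFM to a background-aware position weight matrix
#'
#' Per-cell log2 likelihood ratio of the (pseudocount-smoothed) site
#' frequency against the background probability:
#' \deqn{s_{b,i} = \log_2\frac{(c_{b,i} + k\,p_b)/(n + k)}{p_b}}
#' with counts \eqn{c}, pseudocount \eqn{k} distributed over bases by the
#' background probabilities \eqn{p_b}, and \eqn{n} sites.
#'
#' @param pfm A [build_pfm()] object.
#' @param background A [gc_background()] object or GC fraction.
#' @param pseudocount Non-negative total pseudocount `k`. The default 0.8
#'   keeps every score finite for small site collections while perturbing
#'   observed frequencies by well under 10 percent.
#' @param allow_infinite With `pseudocount = 0`, a zero count yields a score
#'   of `-Inf`; this is rejected unless `allow_infinite = TRUE` (useful for
#'   exact textbook cases).
#' @return An object of class `pwm`: list with `scores` (4 x L), `background`,
#'   `pseudocount`, `max_score`, `min_score`.
#' @examples
#' pwm <- pfm_to_pwm(build_pfm(c("TTAGG", "TTAGG", "TAAGG")), gc_background(0.72))
#' pwm$max_score
#' @export
pfm_to_pwm <- function(pfm, background = gc_background(0.5), pseudocount = 0.8,
                       allow_infinite = FALSE) {
  stopifnot(inherits(pfm, "pfm"))
  background <- as_background(background)
  if (!is.numeric(pseudocount) || length(pseudocount) != 1 || pseudocount < 0)
    stop("pseudocount must be a non-negative scalar")
  if (pseudocount == 0 && any(pfm$counts == 0) && !allow_infinite)
    stop("pseudocount = 0 with zero counts gives -Inf scores; ",
         "set allow_infinite = TRUE to permit this")
  p <- as.numeric(background)
  freq <- (pfm$counts + pseudocount * p) / (pfm$n_sites + pseudocount)
  scores <- log2(freq / p)
  dimnames(scores) <- dimnames(pfm$counts)
  structure(list(scores = scores,
                 background = background,
                 pseudocount = pseudocount,
                 max_score = sum(apply(scores, 2, max)),
                 min_score = sum(apply(scores, 2, min))),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf(
    "Position weight matrix: %d bp, GC background %.2f, pseudocount %g\n",
    ncol(x$scores), attr(x$background, "gc"), x$pseudocount))
  cat(sprintf("Score range: [%.3f, %.3f] bits\n", x$min_score, x$max_score))
  print(round(x$scores, 3))
  invisible(x)
}

motif_length <- function(pwm) ncol(pwm$scores)

#' Per-position Shannon information content of a PFM
#'
#' Uniform-background logo convention: `IC_i = 2 - H_i` with
#' `H_i = -sum_b f_b log2 f_b` over the column frequencies (0 log 0 := 0).
#' The optional small-sample correction subtracts `3 / (2 ln2 n)`.
#' `type = "relative"` instead returns the relative entropy (Kullback-Leibler
#' divergence) of the column frequencies against `background`.
#'
#' @param pfm A [build_pfm()] object.
#' @param small_sample_correction Apply the classic small-sample bias
#'   correction (only with `type = "shannon"`).
#' @param type `"shannon"` (default, 2 - H) or `"relative"`.
#' @param background Background used for `type = "relative"`.
#' @return Numeric vector of per-position bits.
#' @export
information_content <- function(pfm, small_sample_correction = FALSE,
                                type = c("shannon", "relative"),
                                background = gc_background(0.5)) {
  stopifnot(inherits(pfm, "pfm"))
  type <- match.arg(type)
  f <- sweep(pfm$counts, 2, colSums(pfm$counts), "/")
  if (type == "relative") {
    p <- as.numeric(as_background(background))
    term <- f * log2(sweep(f, 1, p, "/"))
    term[f == 0] <- 0
    return(colSums(term))
  }
  h <- -f * log2(f)
  h[f == 0] <- 0
  ic <- 2 - colSums(h)
  if (small_sample_correction) ic <- ic - 3 / (2 * log(2) * pfm$n_sites)
  ic
}

#' @describeIn information_content Bar plot of the per-position information
#'   content (a simple text-free sequence-logo summary).
#' @param x,... `pfm` object and base-graphics arguments.
#' @export
plot.pfm <- function(x, ...) {
  ic <- information_content(x)
  barplot(ic, names.arg = strsplit(consensus_sequence(x), "")[[1]],
          ylab = "Information content (bits)", ylim = c(0, 2),
          xlab = "Consensus base by motif position", ...)
  invisible(x)
}

#' Score one sequence with a PWM
#'
#' Sums the per-position log-likelihood-ratio scores over a sequence of
#' exactly the motif length.
#'
#' @param pwm A [pfm_to_pwm()] object.
#' @param seq Character scalar, length equal to the motif length.
#' @return Score in bits.
#' @export
score_sequence <- function(pwm, seq) {
  stopifnot(inherits(pwm, "pwm"))
  b <- match(strsplit(toupper(seq), "")[[1]], DNA_BASES)
  if (length(b) != motif_length(pwm) || anyNA(b))
    stop("sequence must be ACGT of exactly the motif length")
  sum(pwm$scores[cbind(b, seq_along(b))])
}

## ---- motif I/O ------------------------------------------------------------

#' Read aligned binding sites from FASTA or plain text
#'
#' FASTA is detected by a leading `>`; otherwise one sequence per line is
#' assumed. Blank lines are dropped.
#'
#' @param path File path.
#' @return Character vector of sites.
#' @export
read_sites <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("no sequences in ", path)
  if (startsWith(lines[[1]], ">")) {
    as.character(Biostrings::readDNAStringSet(path))
  } else {
    toupper(trimws(lines))
  }
}

#' Write / read a PFM in JASPAR count format
#'
#' Four lines `A [ n n ... ]` etc., with an optional `>name` header.
#'
#' @param pfm A `pfm` object.
#' @param path File path.
#' @param name Motif name written to the header.
#' @return `write_jaspar` returns `path` invisibly; `read_jaspar` returns a
#'   `pfm` object.
#' @export
write_jaspar <- function(pfm, path, name = "motif") {
  stopifnot(inherits(pfm, "pfm"))
  rows <- vapply(DNA_BASES, function(b) {
    sprintf("%s  [ %s ]", b, paste(pfm$counts[b, ], collapse = " "))
  }, character(1))
  writeLines(c(paste0(">", name), rows), path)
  invisible(path)
}

#' @rdname write_jaspar
#' @export
read_jaspar <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, ">")]
  if (length(lines) != 4) stop("expected 4 count rows in ", path)
  base_of <- toupper(substr(trimws(lines), 1, 1))
  rows <- lapply(lines, function(l) {
    nums <- gsub("^[ACGTacgt]\\s*\\[?|\\]\\s*$", "", trimws(l))
    as.numeric(strsplit(trimws(nums), "\\s+")[[1]])
  })
  if (length(unique(lengths(rows))) != 1)
    stop("ragged JASPAR count rows in ", path)
  counts <- do.call(rbind, rows)
  rownames(counts) <- base_of
  counts <- counts[DNA_BASES, , drop = FALSE]
  n <- unique(colSums(counts))
  if (length(n) != 1) stop("JASPAR columns do not sum to a constant site count")
  structure(list(counts = counts, n_sites = n, length = ncol(counts)),
            class = "pfm")
}

#' Write a motif in minimal MEME format
#'
#' Emits a single-motif MEME text file (version 4 header, background from
#' the supplied composition, letter-probability matrix from the PFM column
#' frequencies).
#'
#' @param pfm A `pfm` object.
#' @param path Output path.
#' @param name Motif name.
#' @param background Background composition for the header.
#' @return `path`, invisibly.
#' @export
write_meme <- function(pfm, path, name = "motif",
                       background = gc_background(0.5)) {
  stopifnot(inherits(pfm, "pfm"))
  p <- as.numeric(as_background(background))
  f <- sweep(pfm$counts, 2, colSums(pfm$counts), "/")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "Background letter frequencies",
               sprintf("A %.5f C %.5f G %.5f T %.5f", p[1], p[2], p[3], p[4]),
               "",
               sprintf("MOTIF %s", name),
               sprintf("letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
                       pfm$length, pfm$n_sites)), con)
  writeLines(apply(f, 2, function(col) paste(sprintf("%.6f", col), collapse = " ")),
             con)
  invisible(path)
}

#' @rdname write_meme
#' @export
read_meme <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^letter-probability matrix", lines)
  if (length(hdr) < 1) stop("no letter-probability matrix in ", path)
  hdr <- hdr[[1]]
  w <- as.integer(sub(".*w= *([0-9]+).*", "\\1", lines[hdr]))
  n <- sub(".*nsites= *([0-9]+).*", "\\1", lines[hdr])
  n <- if (n == lines[hdr]) 20L else as.integer(n)
  rows <- lines[(hdr + 1):(hdr + w)]
  f <- t(vapply(rows, function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]]),
                numeric(4)))
  counts <- round(t(f) * n)
  dimnames(counts) <- list(DNA_BASES, NULL)
  structure(list(counts = counts, n_sites = n, length = w), class = "pfm")
}
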