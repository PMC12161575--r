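## Annotated genomes and region extraction.
##
## Internal coordinates are 0-based half-open throughout; GFF3 I/O converts
## to/from the 1-based inclusive convention at the boundary.

#' Construct an annotated genome
#'
#' @param contigs Named character vector (or `DNAStringSet`) of contig
#'   sequences.
#' @param genes `data.frame` with columns `gene_id`, `contig`, `start`, `end`
#'   (0-based half-open), `strand` (`"+"`/`"-"`).
#' @return Object of class `annotated_genome`.
#' @export
annotated_genome <- function(contigs, genes) {
  if (inherits(contigs, "DNAStringSet")) {
    contigs <- setNames(as.character(contigs), names(contigs))
  }
  stopifnot(is.character(contigs), !is.null(names(contigs)),
            is.data.frame(genes))
  need <- c("gene_id", "contig", "start", "end", "strand")
  if (!all(need %in% names(genes)))
    stop("genes must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(genes$gene_id)) stop("duplicate gene ids")
  if (!all(genes$contig %in% names(contigs)))
    stop("gene contigs missing from sequence set")
  if (any(genes$start >= genes$end)) stop("gene intervals need start < end")
  if (!all(genes$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  clen <- nchar(contigs)[genes$contig]
  if (any(genes$start < 0) || any(genes$end > clen))
    stop("gene intervals outside contig bounds")
  genes <- genes[order(genes$contig, genes$start), , drop = FALSE]
  rownames(genes) <- NULL
  structure(list(contigs = contigs, genes = genes),
            class = "annotated_genome")
}

#' @export
print.annotated_genome <- function(x, ...) {
  cat(sprintf("Annotated genome: %d contig(s), %s bp, %d genes\n",
              length(x$contigs), format(sum(nchar(x$contigs)), big.mark = ","),
              nrow(x$genes)))
  invisible(x)
}

#' Read a genome from FASTA + GFF3
#'
#' Keeps features of the requested type (default `CDS`) and takes gene ids
#' from the `locus_tag` attribute, falling back to `ID`.
#'
#' @param fasta,gff File paths.
#' @param feature_type GFF3 feature type to keep.
#' @return An [annotated_genome()].
#' @export
read_annotated_genome <- function(fasta, gff, feature_type = "CDS") {
  seqs <- Biostrings::readDNAStringSet(fasta)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  gr <- rtracklayer::import(gff, format = "gff3")
  gr <- gr[as.character(gr$type) %in% feature_type]
  ids <- if (!is.null(gr$locus_tag)) as.character(gr$locus_tag) else
    as.character(gr$ID)
  genes <- data.frame(
    gene_id = ids,
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,   # to 0-based half-open
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE)
  annotated_genome(seqs, genes)
}

#' Write an annotated genome as FASTA + GFF3
#'
#' @param genome An [annotated_genome()].
#' @param fasta,gff Output paths (either may be `NULL` to skip).
#' @param source GFF3 source column.
#' @return Invisibly, the genome.
#' @export
write_annotated_genome <- function(genome, fasta = NULL, gff = NULL,
                                   source = "regumine") {
  stopifnot(inherits(genome, "annotated_genome"))
  if (!is.null(fasta)) {
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome$contigs), fasta)
  }
  if (!is.null(gff)) {
    g <- genome$genes
    gr <- GenomicRanges::GRanges(
      seqnames = g$contig,
      ranges = IRanges::IRanges(start = g$start + 1L, end = g$end),
      strand = g$strand)
    gr$source <- source
    gr$type <- "CDS"
    gr$phase <- 0L
    gr$ID <- g$gene_id
    gr$locus_tag <- g$gene_id
    rtracklayer::export(gr, gff, format = "gff3")
  }
  invisible(genome)
}

merge_intervals <- function(start, end) {
  # start/end: 0-based half-open, same contig; returns merged, sorted
  if (length(start) == 0) return(data.frame(start = integer(), end = integer()))
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  ms <- start[1]; me <- end[1]
  out_s <- integer(); out_e <- integer()
  for (i in seq_along(start)[-1]) {
    if (start[i] <= me) me <- max(me, end[i]) else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- start[i]; me <- end[i]
    }
  }
  data.frame(start = c(out_s, ms), end = c(out_e, me))
}

#' Extract coding, non-coding and regulatory regions
#'
#' Coding regions are the merged union of gene intervals; non-coding regions
#' are their complement, so the two tile each contig exactly. Each gene also
#' gets a regulatory window around its start codon: `upstream` bp before to
#' `downstream` bp after the start (strand-aware), clipped at contig ends.
#' Regulatory windows are an overlay — they may overlap coding sequence and
#' are not part of the coding/non-coding partition.
#'
#' @param genome An [annotated_genome()].
#' @param upstream,downstream Window extent in bp relative to the start codon
#'   (defaults 350 and 50).
#' @return Object of class `region_set`: list with data.frames `coding`,
#'   `noncoding` (columns `contig,start,end`) and `regulatory`
#'   (`gene_id,contig,start,end,strand`).
#' @export
extract_regions <- function(genome, upstream = 350, downstream = 50) {
  stopifnot(inherits(genome, "annotated_genome"))
  g <- genome$genes
  coding <- do.call(rbind, lapply(names(genome$contigs), function(ct) {
    sub <- g[g$contig == ct, , drop = FALSE]
    m <- merge_intervals(sub$start, sub$end)
    if (nrow(m) == 0) return(NULL)
    cbind(data.frame(contig = ct, stringsAsFactors = FALSE), m)
  }))
  if (is.null(coding))
    coding <- data.frame(contig = character(), start = integer(),
                         end = integer())
  noncoding <- do.call(rbind, lapply(names(genome$contigs), function(ct) {
    len <- nchar(genome$contigs[[ct]])
    m <- coding[coding$contig == ct, , drop = FALSE]
    bounds_s <- c(0L, m$end)
    bounds_e <- c(m$start, len)
    keep <- bounds_s < bounds_e
    if (!any(keep)) return(NULL)
    data.frame(contig = ct, start = bounds_s[keep], end = bounds_e[keep],
               stringsAsFactors = FALSE)
  }))
  if (is.null(noncoding))
    noncoding <- data.frame(contig = character(), start = integer(),
                            end = integer())
  clen <- nchar(genome$contigs)[g$contig]
  ws <- ifelse(g$strand == "+", g$start - upstream, g$end - downstream)
  we <- ifelse(g$strand == "+", g$start + downstream, g$end + upstream)
  ws <- pmax(ws, 0L)
  we <- pmin(we, clen)
  reg <- data.frame(gene_id = g$gene_id, contig = g$contig,
                    start = as.integer(ws), end = as.integer(we),
                    strand = g$strand, stringsAsFactors = FALSE)
  empty <- reg$start >= reg$end
  if (any(empty)) {
    warning(sum(empty), " zero-length regulatory window(s) dropped")
    reg <- reg[!empty, , drop = FALSE]
  }
  rownames(reg) <- NULL
  structure(list(coding = coding, noncoding = noncoding, regulatory = reg,
                 upstream = upstream, downstream = downstream),
            class = "region_set")
}

#' @export
print.region_set <- function(x, ...) {
  cat(sprintf(
    "Region set: %d coding / %d non-coding segments, %d regulatory windows (-%d/+%d bp)\n",
    nrow(x$coding), nrow(x$noncoding), nrow(x$regulatory),
    x$upstream, x$downstream))
  invisible(x)
}
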