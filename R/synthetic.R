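## Synthetic genomes, annotations, planted binding sites and count matrices
## with known ground truth, so every pipeline stage has a no-download test
## surface. The generator emulates a GC-rich streptomycete-like chromosome:
## dense, stranded, non-overlapping genes organized in operons; an AT-rich
## palindromic repressor motif planted in regulatory windows; and
## negative-binomial counts in which the regulator is anti-correlated with
## its planted regulon and an optional mean-expression-linked confounder
## reproduces the bias the correlation corrections must remove.

#' Generate an i.i.d. background genome
#'
#' Bases are drawn independently with `P(G) = P(C) = gc/2` and
#' `P(A) = P(T) = (1 - gc)/2`.
#'
#' @param length Genome length in bp (>= 1000).
#' @param gc GC fraction in (0, 1); 0.72 mirrors a streptomycete chromosome.
#' @param seed Integer seed; identical seeds give identical sequences.
#' @param name Contig name.
#' @return Named character vector of length 1 (the contig).
#' @export
generate_genome <- function(length, gc = 0.72, seed = 1, name = "chr") {
  if (!is.numeric(length) || length < 1000) stop("length must be >= 1000")
  p <- gc_background(gc)   # validates gc
  set.seed(seed)
  seq <- paste(sample(DNA_BASES, length, replace = TRUE, prob = p),
               collapse = "")
  setNames(seq, name)
}

#' Generate a stranded, operon-structured gene annotation
#'
#' Lays out non-overlapping genes left to right. Genes are grouped into
#' operons: `operon_sizes` designates multi-gene (or single-gene) operons in
#' order, and any remaining genes become singleton operons. All genes of an
#' operon share one strand; intra-operon gaps are drawn from `intra_gap` and
#' gaps between operons from `inter_gap` (kept disjoint so the operon
#' structure is recoverable from spacing). For a `-` strand operon the
#' transcription order runs right to left; the `leader` flag marks each
#' operon's first transcribed gene.
#'
#' @param genome A named contig vector from [generate_genome()] (or any
#'   named character vector of sequences; genes go on the first contig).
#' @param n_genes Total number of genes.
#' @param operon_geometry List with `operon_sizes` (integer vector),
#'   `intra_gap`, `inter_gap`, `gene_length` (each a min/max bp range).
#' @param seed Integer seed.
#' @return `data.frame`: `gene_id`, `contig`, `start`, `end` (0-based
#'   half-open), `strand`, `operon_id`, `leader` (logical).
#' @export
generate_annotation <- function(genome, n_genes,
                                operon_geometry = list(), seed = 1) {
  geom <- utils::modifyList(list(operon_sizes = integer(),
                                 intra_gap = c(40, 120),
                                 inter_gap = c(240, 400),
                                 gene_length = c(700, 1200)),
                            operon_geometry)
  if (sum(geom$operon_sizes) > n_genes)
    stop("operon_sizes exceed n_genes")
  sizes <- c(geom$operon_sizes,
             rep(1L, n_genes - sum(geom$operon_sizes)))
  contig <- names(genome)[1]
  glen <- nchar(genome[[1]])
  set.seed(seed)
  rint <- function(range) if (range[1] == range[2]) range[1] else
    sample(range[1]:range[2], 1)
  pos <- rint(geom$inter_gap)
  rows <- vector("list", n_genes)
  gi <- 0L
  for (o in seq_along(sizes)) {
    strand <- sample(c("+", "-"), 1)
    n_in <- sizes[o]
    for (k in seq_len(n_in)) {
      len <- rint(geom$gene_length)
      if (pos + len > glen)
        stop("genome too short for requested genes")
      gi <- gi + 1L
      rows[[gi]] <- data.frame(
        gene_id = sprintf("gene_%04d", gi), contig = contig,
        start = pos, end = pos + len, strand = strand,
        operon_id = sprintf("operon_%03d", o),
        stringsAsFactors = FALSE)
      pos <- pos + len +
        if (k < n_in) rint(geom$intra_gap) else rint(geom$inter_gap)
    }
  }
  ann <- do.call(rbind, rows)
  # leader = first transcribed gene of each operon (strand-aware)
  ann$leader <- FALSE
  for (o in unique(ann$operon_id)) {
    idx <- which(ann$operon_id == o)
    lead <- if (ann$strand[idx[1]] == "+") idx[1] else idx[length(idx)]
    ann$leader[lead] <- TRUE
  }
  ann
}

sample_motif_instance <- function(pfm) {
  f <- sweep(pfm$counts, 2, colSums(pfm$counts), "/")
  paste(vapply(seq_len(pfm$length), function(i)
    sample(DNA_BASES, 1, prob = f[, i]), character(1)), collapse = "")
}

#' Plant motif instances in regulatory windows
#'
#' Writes one motif instance per target gene into the genome sequence, at a
#' position inside the gene's regulatory window (`upstream`/`downstream`
#' around the start codon). Instances are sampled column-wise from the PFM
#' frequencies and planted on a random strand (the reverse complement is
#' written for `-` placements). Offsets are chosen inside the non-coding
#' part of the window when it is wide enough (so planted sites do not
#' overwrite neighbouring coding sequence), avoiding previously planted
#' sites. Exact coordinates and strands are recorded in the returned truth.
#'
#' @param genome Named contig vector.
#' @param annotation Gene table from [generate_annotation()].
#' @param pfm Motif to plant, e.g. [synthetic_iron_box_pfm()].
#' @param target_genes Gene ids receiving one site each.
#' @param seed Integer seed.
#' @param upstream,downstream Regulatory window extent (must match the scan
#'   stage's window definition).
#' @param consensus Plant the consensus sequence instead of sampled
#'   instances.
#' @return List with `genome` (modified sequences) and `planted_sites`
#'   (data.frame `contig,start,end,strand,gene_id,sequence`).
#' @export
plant_motifs <- function(genome, annotation, pfm, target_genes, seed = 1,
                         upstream = 350, downstream = 50, consensus = FALSE) {
  stopifnot(all(target_genes %in% annotation$gene_id))
  ag <- annotated_genome(genome, annotation[, c("gene_id", "contig", "start",
                                                "end", "strand")])
  regions <- extract_regions(ag, upstream, downstream)
  L <- pfm$length
  set.seed(seed)
  seqs <- genome
  placed <- list()
  for (g in target_genes) {
    w <- regions$regulatory[regions$regulatory$gene_id == g, ]
    if (nrow(w) == 0 || w$end - w$start < L)
      stop("regulatory window of ", g, " too narrow for the motif")
    nc <- regions$noncoding[regions$noncoding$contig == w$contig, ]
    segs <- data.frame(start = pmax(nc$start, w$start),
                       end = pmin(nc$end, w$end))
    segs <- segs[segs$end - segs$start >= L, , drop = FALSE]
    if (nrow(segs) == 0) segs <- data.frame(start = w$start, end = w$end)
    site <- NULL
    for (try in 1:50) {
      seg <- segs[sample.int(nrow(segs), 1), ]
      s <- seg$start + sample.int(seg$end - seg$start - L + 1, 1) - 1L
      clash <- any(vapply(placed, function(p)
        p$contig == w$contig && s < p$end && p$start < s + L, logical(1)))
      if (!clash) { site <- s; break }
    }
    if (is.null(site)) stop("could not place a site for ", g,
                            " without overlapping earlier sites")
    inst <- if (consensus) consensus_sequence(pfm) else
      sample_motif_instance(pfm)
    strand <- sample(c("+", "-"), 1)
    written <- if (strand == "+") inst else reverse_complement(inst)
    substr(seqs[[w$contig]], site + 1L, site + L) <- written
    placed[[length(placed) + 1]] <- data.frame(
      contig = w$contig, start = site, end = site + L, strand = strand,
      gene_id = g, sequence = inst, stringsAsFactors = FALSE)
  }
  list(genome = seqs, planted_sites = do.call(rbind, placed))
}

#' Simulate a negative-binomial count matrix with a planted regulon
#'
#' Per-sample regulator activity `a_j ~ Uniform(0, 1)` drives the design:
#' regulon-operon means follow the repression proxy
#' `mu_g (1 - effect_size * a_j)` truncated at a small positive floor, and
#' the regulator's mean is inversely proportional to that proxy (rescaled
#' to average `regulator_mean`), i.e. it increases in `a_j` and member
#' log-expression is linear in regulator log-expression — the first-order
#' mass-action picture of a repressor titrating its operators. Other
#' operons share a lognormal latent profile, and every gene adds small
#' independent log-normal noise. Counts are drawn
#' negative-binomial with variance `mu + dispersion * mu^2`. When
#' `confounder_strength > 0`, a shared standard-normal sample factor `c_j`
#' multiplies each gene's mean by `exp(lambda_g c_j)` with a monotone
#' two-level loading: `lambda_g = confounder_strength` for genes in the top
#' 40 percent by base mean and `0.1 * confounder_strength` below. The
#' loading is non-decreasing in base expression, so the factor reproduces
#' the mean-linked correlation bias the PC1-removal and
#' spatial-quantile-normalization steps must remove. The two-level form is
#' deliberate: library-size normalization subtracts the read-weighted mean
#' loading, which annihilates any loading continuous in expression rank
#' exactly at its pivot and would leave those bins unconfounded; a loading
#' that jumps over its own pivot keeps every expression stratum visibly
#' biased, as observed in real data.
#'
#' @param truth A `synthetic_truth` object (see [synthetic_truth()]), which
#'   carries the operon map, regulon membership and dispersion.
#' @param n_samples Number of samples (>= 4).
#' @param params List overriding any of `base_mean` (100), `effect_size`
#'   (0.85), `dispersion` (taken from `truth`), `library_size_range`
#'   (`c(0.5, 2)`), `confounder_strength` (1), `regulator_mean` (800),
#'   `operon_profile_sd` (0.5), `gene_noise_sd` (0.1).
#' @param seed Integer seed.
#' @return Integer count matrix (genes x samples) with attribute `design`
#'   (list: `activity`, `confounder`, `base_mean`, `confounder_loading`,
#'   `library_factor`).
#' @export
simulate_counts <- function(truth, n_samples, params = list(), seed = 1) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (n_samples < 4) stop("need n_samples >= 4")
  p <- utils::modifyList(list(base_mean = 100, effect_size = 0.85,
                              dispersion = truth$dispersion,
                              library_size_range = c(0.5, 2),
                              confounder_strength = 1,
                              regulator_mean = 800,
                              operon_profile_sd = 0.5,
                              gene_noise_sd = 0.1),
                         params)
  if (p$dispersion <= 0) stop("dispersion must be positive")
  if (p$effect_size < 0 || p$effect_size > 1)
    stop("effect_size must lie in [0, 1]")
  genes <- names(truth$operon_map)
  n <- length(genes)
  set.seed(seed)
  a <- runif(n_samples)
  cj <- rnorm(n_samples)
  mu0 <- rlnorm(n, meanlog = log(p$base_mean), sdlog = 1)
  names(mu0) <- genes
  mu0[truth$regulator_gene] <- p$regulator_mean
  lambda <- p$confounder_strength * ifelse(rank(mu0) / n > 0.6, 1, 0.1)
  names(lambda) <- genes
  libf <- runif(n_samples, p$library_size_range[1], p$library_size_range[2])
  operons <- unique(truth$operon_map)
  regulon_ops <- unique(truth$operon_map[truth$regulon_genes])
  latent <- matrix(1, length(operons), n_samples,
                   dimnames = list(operons, NULL))
  for (o in operons) {
    latent[o, ] <- if (o %in% regulon_ops)
      pmax(1 - p$effect_size * a, 0.05)
    else exp(p$operon_profile_sd * rnorm(n_samples))
  }
  repression <- pmax(1 - p$effect_size * a, 0.05)
  reg_prof <- (1 / repression) / mean(1 / repression)
  mu <- matrix(0, n, n_samples, dimnames = list(genes, NULL))
  for (g in genes) {
    prof <- if (g == truth$regulator_gene) reg_prof
    else latent[truth$operon_map[[g]], ]
    mu[g, ] <- mu0[[g]] * prof *
      exp(p$gene_noise_sd * rnorm(n_samples)) *
      exp(lambda[[g]] * cj)
  }
  mu <- sweep(mu, 2, libf, "*")
  counts <- matrix(rnbinom(length(mu), mu = mu, size = 1 / p$dispersion),
                   nrow = n, dimnames = list(genes,
                                             sprintf("sample_%02d",
                                                     seq_len(n_samples))))
  attr(counts, "design") <- list(activity = a, confounder = cj,
                                 base_mean = mu0,
                                 confounder_loading = lambda,
                                 library_factor = libf)
  counts
}

#' Ground truth of a synthetic scenario
#'
#' @param planted_sites data.frame `contig,start,end,strand` (plus extras).
#' @param regulator_gene,regulon_genes Regulator id and regulon member ids
#'   (the regulator must not be a member).
#' @param operon_map Named character vector: gene id -> operon id.
#' @param dispersion Negative-binomial dispersion used for the counts.
#' @param confounder_loading Optional per-gene loading (filled by
#'   [simulate_counts()] wrappers).
#' @param seed Seed the scenario was built with.
#' @return Object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(planted_sites, regulator_gene, regulon_genes,
                            operon_map, dispersion = 0.05,
                            confounder_loading = NULL, seed = NA) {
  if (regulator_gene %in% regulon_genes)
    stop("regulon_genes must exclude the regulator")
  stopifnot(all(regulon_genes %in% names(operon_map)),
            regulator_gene %in% names(operon_map), dispersion > 0)
  structure(list(planted_sites = planted_sites,
                 regulator_gene = regulator_gene,
                 regulon_genes = regulon_genes,
                 operon_map = operon_map,
                 confounder_loading = confounder_loading,
                 dispersion = dispersion, seed = seed),
            class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf(
    "Synthetic truth: regulator %s, %d regulon genes, %d planted sites (seed %s)\n",
    x$regulator_gene, length(x$regulon_genes),
    if (is.null(x$planted_sites)) 0 else nrow(x$planted_sites),
    format(x$seed)))
  invisible(x)
}

#' Built-in synthetic iron-box motif
#'
#' Ten constructed 19-bp sites around an AT-rich palindromic consensus,
#' emulating the binding-site alignment of an iron-dependent repressor in a
#' GC-rich genome. These are synthetic stand-ins (the curated sites of the
#' real regulator are not redistributed here); they give a strongly
#' conserved motif whose instances score far above GC-rich background
#' matches, which is the regime the calibration stage is designed for.
#'
#' @return `synthetic_iron_box_sites()`: character vector of 10 sites;
#'   `synthetic_iron_box_pfm()`: the corresponding [build_pfm()] object.
#' @export
synthetic_iron_box_sites <- function() {
  c("TTAGGTTAGGCTAACCTAA",
    "TTAGGTTAGGCTAACCTAA",
    "TAAGGTTAGGCTAACCTAA",
    "TTAGGTTAGGCTAACCTAT",
    "TTAGGTGAGGCTAACCTAA",
    "TTAGGTTAGCCTAACCTAA",
    "CTAGGTTAGGCTAACCTAA",
    "TTAGGTTAGGCTAACCTGA",
    "TTAGGTTAGGTTAACCTAA",
    "TTACGTTAGGCTAACGTAA")
}

#' @rdname synthetic_iron_box_sites
#' @export
synthetic_iron_box_pfm <- function() build_pfm(synthetic_iron_box_sites())

#' Default synthetic regulon scenario
#'
#' The desk-scale study condition every end-to-end check runs on: a 200 kb
#' GC-rich (0.72) genome carrying 150 genes, a 20-gene regulon organized in
#' 8 operons (sizes 3,3,3,3,2,2,2,2) whose leaders each get one planted
#' iron-box instance, 12 background operons arranged so the regulon operons
#' sit pairwise in 4 well-separated genomic loci, one highly expressed
#' singleton regulator, and 24 samples of negative-binomial counts with the
#' mean-linked confounder switched on. When `n_genes` is below 57 (too few
#' for the full layout) a reduced layout with 2 regulon operons (5 genes,
#' 2 planted sites) in 2 loci is used; `n_genes` below 12 is an error.
#'
#' @param seed Integer seed controlling every random draw.
#' @param genome_length,n_genes,n_samples,gc Scenario scale.
#' @param params Overrides forwarded to [simulate_counts()].
#' @return List with `genome` (planted sequences), `annotation`, `truth`,
#'   `counts`, `pfm` and `sites`.
#' @export
synthetic_regulon_dataset <- function(seed = 1, genome_length = 200000,
                                      n_genes = 150, n_samples = 24,
                                      gc = 0.72, params = list()) {
  # interleave pairs of regulon operons with 9-gene background blocks so the
  # regulon occupies 4 well-separated genomic loci (locus grouping at the
  # default max_intervening = 5 keeps adjacent regulon operons together but
  # cannot bridge a 9-gene background block)
  if (n_genes >= 57) {
    regulon_sizes <- c(3, 3, 3, 3, 2, 2, 2, 2)
    background_sizes <- rep(c(2, 3, 4), 4)
    sizes <- c(regulon_sizes[1:2], background_sizes[1:3],
               regulon_sizes[3:4], background_sizes[4:6],
               regulon_sizes[5:6], background_sizes[7:9],
               regulon_sizes[7:8], background_sizes[10:12])
    regulon_op_idx <- c(1, 2, 6, 7, 11, 12, 16, 17)
  } else if (n_genes >= 12) {
    # reduced layout for small test genomes: 2 regulon operons (5 genes)
    # separated by a background block, remainder singleton operons
    sizes <- c(3, 3, 2, 3)
    regulon_op_idx <- c(1, 3)
  } else {
    stop("n_genes must be at least 12")
  }
  genome <- generate_genome(genome_length, gc = gc, seed = seed)
  ann <- generate_annotation(
    genome, n_genes,
    operon_geometry = list(operon_sizes = sizes),
    seed = seed + 1)
  regulon_ops <- sprintf("operon_%03d", regulon_op_idx)
  regulon_genes <- ann$gene_id[ann$operon_id %in% regulon_ops]
  leaders <- ann$gene_id[ann$leader & ann$operon_id %in% regulon_ops]
  pfm <- synthetic_iron_box_pfm()
  planted <- plant_motifs(genome, ann, pfm, leaders, seed = seed + 2)
  singles <- ann$gene_id[!(ann$operon_id %in%
                             sprintf("operon_%03d", seq_along(sizes)))]
  regulator <- singles[ceiling(length(singles) / 2)]
  operon_map <- setNames(ann$operon_id, ann$gene_id)
  truth <- synthetic_truth(planted$planted_sites, regulator, regulon_genes,
                           operon_map,
                           dispersion = if (!is.null(params$dispersion))
                             params$dispersion else 0.05,
                           seed = seed)
  counts <- simulate_counts(truth, n_samples, params, seed = seed + 3)
  truth$confounder_loading <- attr(counts, "design")$confounder_loading
  list(genome = planted$genome, annotation = ann, truth = truth,
       counts = counts, pfm = pfm, sites = synthetic_iron_box_sites())
}

#' Write a synthetic dataset to a directory
#'
#' Genome as FASTA, annotation as GFF3 (1-based inclusive `CDS` features
#' with `locus_tag`), counts as TSV (genes x samples), truth as JSON and the
#' motif sites as FASTA.
#'
#' @param dataset A [synthetic_regulon_dataset()] list.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_synthetic_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ag <- annotated_genome(dataset$genome,
                         dataset$annotation[, c("gene_id", "contig", "start",
                                                "end", "strand")])
  write_annotated_genome(ag, fasta = file.path(dir, "genome.fasta"),
                         gff = file.path(dir, "annotation.gff3"))
  write.table(data.frame(gene_id = rownames(dataset$counts), dataset$counts,
                         check.names = FALSE),
              file.path(dir, "counts.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  sites <- dataset$sites
  writeLines(as.vector(rbind(sprintf(">site_%02d", seq_along(sites)), sites)),
             file.path(dir, "sites.fasta"))
  truth <- dataset$truth
  jsonlite::write_json(
    list(planted_sites = truth$planted_sites,
         regulator_gene = truth$regulator_gene,
         regulon_genes = truth$regulon_genes,
         operon_map = as.list(truth$operon_map),
         dispersion = truth$dispersion,
         seed = truth$seed),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
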