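## End-to-end orchestration: simulate (or load) -> motif -> scan ->
## calibrate -> co-express -> regulon (-> cluster rules), with a
## reproducibility manifest.

#' Build a pipeline configuration
#'
#' Exactly one of the two input modes must be given: real inputs (paths to
#' genome FASTA, annotation GFF3, binding-site file, count TSV) or a
#' `simulation` block (arguments for [synthetic_regulon_dataset()]).
#'
#' @param genome,annotation,sites,counts Paths for a real-data run.
#' @param simulation List of [synthetic_regulon_dataset()] arguments for a
#'   simulated run (use `list()` for the default scenario).
#' @param regulator Regulator gene id; for simulated runs it defaults to the
#'   planted regulator.
#' @param gc Background GC fraction for the PWM and threshold (0.72).
#' @param pseudocount PWM pseudocount (0.8).
#' @param pvalue Scan p-value threshold (0.01).
#' @param upstream,downstream Regulatory window (350/50 bp).
#' @param threshold_method [refined_threshold()] method.
#' @param min_count,min_fraction Expression filter (5 in 50 percent).
#' @param remove_pcs,spqn_ngrp,spqn_size,spqn_ref,spqn_passes Correlation
#'   corrections (see [coexpression_stack()]).
#' @param max_gap,min_pcc Operon expansion; `min_pcc = NULL` uses the
#'   critical PCC at the dataset's sample count.
#' @param max_intervening Locus grouping.
#' @param alpha Anti-correlation significance level.
#' @param seed Integer seed.
#' @return Object of class `regumine_config` (a validated list).
#' @export
regumine_config <- function(genome = NULL, annotation = NULL, sites = NULL,
                            counts = NULL, simulation = NULL,
                            regulator = NULL, gc = 0.72, pseudocount = 0.8,
                            pvalue = 0.01, upstream = 350, downstream = 50,
                            threshold_method = "ratio_median_crossing",
                            min_count = 5, min_fraction = 0.5,
                            remove_pcs = 1, spqn_ngrp = 20, spqn_size = NULL,
                            spqn_ref = 18, spqn_passes = 1, max_gap = 200,
                            min_pcc = NULL, max_intervening = 5,
                            alpha = 0.05, seed = 1) {
  real <- !is.null(genome) || !is.null(annotation) || !is.null(sites) ||
    !is.null(counts)
  if (real && !is.null(simulation))
    stop("give either real inputs or a simulation block, not both")
  if (!real && is.null(simulation))
    stop("give real inputs or a simulation block")
  if (real && (is.null(genome) || is.null(annotation) || is.null(sites) ||
               is.null(counts)))
    stop("real runs need genome, annotation, sites and counts")
  if (real && is.null(regulator))
    stop("real runs need the regulator gene id")
  cfg <- as.list(environment())
  cfg$real <- real
  structure(cfg, class = "regumine_config")
}

#' Run the regulon-mining pipeline
#'
#' Stage order: build PFM/PWM from the binding sites; extract regions and
#' the exact-p-value score floor; scan both strands; calibrate the refined
#' threshold from the non-coding/coding hit ratio and deduplicate into
#' unique locations; run the co-expression stack; assemble the regulon.
#' All stage outputs are written under `out_dir` as plain TSV/BED/JSON
#' together with a `manifest.json` recording the configuration and package
#' version, so each stage can also be consumed standalone.
#'
#' @param config A [regumine_config()].
#' @param out_dir Output directory (`NULL` for no files).
#' @return List of class `regumine_run`: `pfm`, `pwm`, `floor`,
#'   `hits`, `threshold`, `locations`, `coexpression`, `regulon`, `truth`
#'   (simulated runs only), `recovery` (truth-vs-result report), `out_dir`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "regumine_config"))
  truth <- NULL
  if (config$real) {
    ag <- read_annotated_genome(config$genome, config$annotation)
    sites <- read_sites(config$sites)
    counts <- read_counts_tsv(config$counts)
    regulator <- config$regulator
  } else {
    ds <- do.call(synthetic_regulon_dataset,
                  c(list(seed = config$seed), config$simulation))
    ag <- annotated_genome(ds$genome,
                           ds$annotation[, c("gene_id", "contig", "start",
                                             "end", "strand")])
    sites <- ds$sites
    counts <- ds$counts
    truth <- ds$truth
    regulator <- if (is.null(config$regulator)) truth$regulator_gene
    else config$regulator
  }

  pfm <- build_pfm(sites)
  bg <- gc_background(config$gc)
  pwm <- pfm_to_pwm(pfm, bg, pseudocount = config$pseudocount)
  regions <- extract_regions(ag, config$upstream, config$downstream)
  floor_bits <- score_threshold_from_pvalue(pwm, bg, p = config$pvalue)
  hits <- scan_genome(ag, regions, pwm, floor_bits)
  if (nrow(hits) == 0) stop("scan stage produced no hits above the floor")
  threshold <- refined_threshold(hits, method = config$threshold_method)
  dedup <- filter_and_dedupe(hits, threshold)

  coexpr <- coexpression_stack(counts, min_count = config$min_count,
                               min_fraction = config$min_fraction,
                               remove_pcs = config$remove_pcs,
                               spqn_ngrp = config$spqn_ngrp,
                               spqn_size = config$spqn_size,
                               spqn_ref = config$spqn_ref,
                               spqn_passes = config$spqn_passes)
  min_pcc <- if (is.null(config$min_pcc)) critical_pcc(coexpr$n_samples)
  else config$min_pcc
  regulon <- build_regulon(dedup$locations, ag, coexpr, regulator,
                           r_threshold = -min_pcc, alpha = config$alpha,
                           max_gap = config$max_gap, min_pcc = min_pcc,
                           max_intervening = config$max_intervening)

  recovery <- if (!is.null(truth)) regulon_recovery(regulon, dedup, truth)
  else NULL

  run <- structure(list(pfm = pfm, pwm = pwm, floor = floor_bits,
                        hits = hits, threshold = threshold,
                        locations = dedup$locations, coexpression = coexpr,
                        regulon = regulon, truth = truth,
                        recovery = recovery, out_dir = out_dir),
                   class = "regumine_run")
  if (!is.null(out_dir)) write_run(run, config, out_dir)
  run
}

#' Truth-vs-result report for a simulated run
#'
#' @param regulon A [build_regulon()] object.
#' @param dedup `filter_and_dedupe()` output.
#' @param truth The scenario's `synthetic_truth`.
#' @return List: location-level `site_recall`/`site_precision` (locations
#'   matching planted intervals exactly) and member-level `sensitivity`/
#'   `precision` against the planted regulon.
#' @export
regulon_recovery <- function(regulon, dedup, truth) {
  loc_key <- sprintf("%s:%d-%d", dedup$locations$contig,
                     dedup$locations$start, dedup$locations$end)
  truth_key <- sprintf("%s:%d-%d", truth$planted_sites$contig,
                       truth$planted_sites$start, truth$planted_sites$end)
  found <- regulon$members$gene_id
  list(site_recall = mean(truth_key %in% loc_key),
       site_precision = if (length(loc_key)) mean(loc_key %in% truth_key)
       else NA_real_,
       n_locations = length(loc_key),
       sensitivity = mean(truth$regulon_genes %in% found),
       precision = if (length(found))
         mean(found %in% truth$regulon_genes) else NA_real_,
       n_members = length(found))
}

#' @export
print.regumine_run <- function(x, ...) {
  cat("regumine pipeline run\n")
  cat(sprintf("  score floor %.3f bits; refined threshold %.3f bits\n",
              as.numeric(x$floor), x$threshold))
  cat(sprintf("  %d hits above floor; %d above threshold; %d unique locations\n",
              nrow(x$hits), sum(x$hits$score >= x$threshold),
              nrow(x$locations)))
  print(x$regulon)
  if (!is.null(x$recovery)) {
    cat(sprintf("  planted-site recall %.2f, precision %.2f; member sensitivity %.2f, precision %.2f\n",
                x$recovery$site_recall, x$recovery$site_precision,
                x$recovery$sensitivity, x$recovery$precision))
  }
  invisible(x)
}

write_run <- function(run, config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_hits_bed(run$hits, file.path(out_dir, "hits.bed"),
                 tsv = file.path(out_dir, "hits.tsv"))
  write.table(run$locations, file.path(out_dir, "locations.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  curve <- ratio_curve(run$hits)
  write.table(curve, file.path(out_dir, "calibration_curve.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_matrix_tsv(run$coexpression$pcc, file.path(out_dir, "pcc.tsv"))
  write_matrix_tsv(run$coexpression$pvalues, file.path(out_dir, "pvalues.tsv"))
  write_regulon(run$regulon, file.path(out_dir, "regulon.tsv"),
                loci_bed = file.path(out_dir, "loci.bed"))
  cfg <- unclass(config)
  cfg$real <- NULL
  manifest <- list(
    tool = "regumine",
    version = as.character(utils::packageVersion("regumine")),
    config = cfg,
    stages = c("motif", "regions", "floor", "scan", "calibrate",
               "coexpression", "regulon"),
    floor = as.numeric(run$floor),
    threshold = run$threshold,
    recovery = run$recovery)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  invisible(out_dir)
}

#' Read / write a gene x sample count matrix TSV
#'
#' First column `gene_id`, remaining columns one per sample.
#'
#' @param path TSV path.
#' @return Integer matrix with gene rownames.
#' @export
read_counts_tsv <- function(path) {
  tab <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  storage.mode(m) <- "integer"
  m
}

write_matrix_tsv <- function(m, path) {
  write.table(data.frame(gene_id = rownames(m), m, check.names = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
}
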