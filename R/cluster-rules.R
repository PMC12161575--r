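## Declarative detection of co-localized gene sets from protein-domain
## content (e.g. the siderophore desABCD core and desGH accessory rules).

#' Define a cluster-detection rule
#'
#' @param name Rule name.
#' @param required_domains Pfam accessions required (with multiplicity; a
#'   repeated accession demands two distinct carrier genes). Version
#'   suffixes (`PF13523.9`) are stripped.
#' @param max_intergenic Maximum intergenic distance in bp between
#'   consecutive carrier genes of a chain.
#' @return Object of class `cluster_rule`.
#' @export
cluster_rule <- function(name, required_domains, max_intergenic) {
  if (length(required_domains) < 1) stop("need at least one required domain")
  if (max_intergenic <= 0) stop("max_intergenic must be positive")
  structure(list(name = name,
                 required_domains = strip_version(required_domains),
                 max_intergenic = max_intergenic),
            class = "cluster_rule")
}

strip_version <- function(acc) sub("\\.\\d+$", "", acc)

#' Built-in cluster rules
#'
#' Loads rules from a JSON config (fields `name`, `domains`,
#' `max_intergenic_bp`). The package ships presets for the desferrioxamine
#' core locus *desABCD* (PF00282, PF13434, PF13523, PF04183; 5 kbp) and the
#' accessory locus *desGH* (PF01804, PF13523; 1 kbp).
#'
#' @param path JSON config; defaults to the shipped presets.
#' @return Named list of [cluster_rule()] objects.
#' @export
load_cluster_rules <- function(path = system.file("extdata",
                                                  "cluster_rules.json",
                                                  package = "regumine")) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  rules <- lapply(seq_len(nrow(cfg)), function(i)
    cluster_rule(cfg$name[i], unlist(cfg$domains[i]),
                 cfg$max_intergenic_bp[i]))
  setNames(rules, cfg$name)
}

#' Read a gene/domain annotation table
#'
#' TSV with columns `gene_id`, `contig`, `start`, `end` and `domains`
#' (comma/semicolon-separated Pfam accessions) or one row per
#' (gene, domain) pair with a `domain` column.
#'
#' @param path TSV path.
#' @return `data.frame` with a list-column `domains` (version-stripped).
#' @export
read_domain_table <- function(path) {
  tab <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  if ("domain" %in% names(tab) && !"domains" %in% names(tab)) {
    agg <- split(tab$domain, tab$gene_id)
    tab <- tab[!duplicated(tab$gene_id),
               setdiff(names(tab), "domain"), drop = FALSE]
    tab$domains <- I(unname(agg[tab$gene_id]))
  } else {
    tab$domains <- I(strsplit(tab$domains, "[,;] *"))
  }
  tab$domains <- I(lapply(tab$domains, strip_version))
  tab
}

# Can the chain genes (list of domain vectors) cover all required domains,
# each requirement by a distinct gene unless multi_domain_carriers allows a
# gene to satisfy several *different* accessions? Tiny bipartite matching.
covers_rule <- function(gene_domains, required, multi_domain_carriers) {
  if (multi_domain_carriers) {
    # a gene may satisfy several different accessions, but a repeated
    # accession still needs distinct carriers
    for (acc in unique(required)) {
      need <- sum(required == acc)
      have <- sum(vapply(gene_domains, function(d) acc %in% d, logical(1)))
      if (have < need) return(FALSE)
    }
    return(TRUE)
  }
  # distinct gene per requirement: augmenting-path matching
  n_req <- length(required)
  match_of <- rep(0L, length(gene_domains))   # gene -> requirement
  try_assign <- function(req_i, seen) {
    for (gi in seq_along(gene_domains)) {
      if (seen[gi]) next
      if (!(required[req_i] %in% gene_domains[[gi]])) next
      seen[gi] <- TRUE
      if (match_of[gi] == 0L || try_assign(match_of[gi], seen)) {
        match_of[gi] <<- req_i
        return(TRUE)
      }
    }
    FALSE
  }
  for (r in seq_len(n_req)) {
    if (!try_assign(r, rep(FALSE, length(gene_domains)))) return(FALSE)
  }
  TRUE
}

#' Detect gene clusters matching a domain-content rule
#'
#' Carrier genes (those bearing any required domain) are chained along each
#' contig while consecutive carriers are at most `max_intergenic` bp apart
#' (end-of-gene to start-of-next, strand-agnostic; non-carrier genes in
#' between do not break the chain). Each maximal chain whose genes jointly
#' cover all required domains is reported. By default one gene carrying
#' several required domains may satisfy them all (covering e.g. naturally
#' fused genes); with `multi_domain_carriers = FALSE` every requirement
#' needs its own gene. A repeated accession in the rule always needs two
#' distinct carriers.
#'
#' @param gene_table `data.frame` with `gene_id`, `contig`, `start`, `end`
#'   and list-column `domains` (see [read_domain_table()]).
#' @param rule A [cluster_rule()].
#' @param multi_domain_carriers See above (default `TRUE`).
#' @return `data.frame`: `rule`, `contig`, `start`, `end`, `genes`
#'   (comma-separated carriers), `domain_assignment`
#'   (`accession=gene` pairs).
#' @export
detect_clusters <- function(gene_table, rule, multi_domain_carriers = TRUE) {
  stopifnot(inherits(rule, "cluster_rule"))
  if (nrow(gene_table) == 0) stop("empty gene table")
  domains <- lapply(gene_table$domains, strip_version)
  carrier <- vapply(domains, function(d)
    any(rule$required_domains %in% d), logical(1))
  tab <- gene_table[carrier, , drop = FALSE]
  doms <- domains[carrier]
  out <- list()
  for (ct in unique(tab$contig)) {
    sel <- which(tab$contig == ct)
    sel <- sel[order(tab$start[sel])]
    if (length(sel) == 0) next
    gaps <- pmax(tab$start[sel][-1] - tab$end[sel][-length(sel)], 0)
    chain <- cumsum(c(1, gaps > rule$max_intergenic))
    for (ch in split(sel, chain)) {
      gd <- doms[ch]
      if (!covers_rule(gd, rule$required_domains, multi_domain_carriers))
        next
      assign <- vapply(rule$required_domains, function(acc) {
        hit <- which(vapply(gd, function(d) acc %in% d, logical(1)))[1]
        sprintf("%s=%s", acc, tab$gene_id[ch[hit]])
      }, character(1))
      out[[length(out) + 1]] <- data.frame(
        rule = rule$name, contig = ct,
        start = min(tab$start[ch]), end = max(tab$end[ch]),
        genes = paste(tab$gene_id[ch], collapse = ","),
        domain_assignment = paste(assign, collapse = ";"),
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(rule = character(), contig = character(),
                      start = integer(), end = integer(), genes = character(),
                      domain_assignment = character(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Tabulate rule presence/absence across genomes
#'
#' @param genomes Named list of gene/domain tables (see
#'   [read_domain_table()]).
#' @param rules List of [cluster_rule()] objects (e.g.
#'   [load_cluster_rules()]).
#' @param multi_domain_carriers Passed to [detect_clusters()].
#' @return `data.frame` with one row per genome, one logical column per rule,
#'   plus `<rule>_loci` columns holding locus coordinates.
#' @export
tabulate_presence <- function(genomes, rules, multi_domain_carriers = TRUE) {
  if (inherits(rules, "cluster_rule")) rules <- list(rules)
  rows <- lapply(names(genomes), function(gn) {
    row <- data.frame(genome = gn, stringsAsFactors = FALSE)
    for (rule in rules) {
      loci <- if (nrow(genomes[[gn]]) == 0)
        data.frame() else detect_clusters(genomes[[gn]], rule,
                                          multi_domain_carriers)
      row[[rule$name]] <- nrow(loci) > 0
      row[[paste0(rule$name, "_loci")]] <- if (nrow(loci) > 0)
        paste(sprintf("%s:%d-%d", loci$contig, loci$start, loci$end),
              collapse = ";") else ""
    }
    row
  })
  do.call(rbind, rows)
}
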