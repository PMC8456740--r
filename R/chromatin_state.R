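# Stratification of genes into the three repressive-mark groups
# (single H3K27me3, single H3K9me2, double H3K27me3/H3K9me2) plus an
# unmarked remainder, from per-mark domain intervals.

#' Assign a chromatin state to each gene from mark domains
#'
#' A mark is "present" on a gene when the overlap between the gene body
#' and the mark's (merged) domains exceeds `min_overlap_fraction` of the
#' gene length; with the default 0 this means any overlap (>= 1 bp).
#' States: both marks -> `K27_K9`; one mark -> `K27_only`/`K9_only`;
#' neither -> `unmarked`.
#'
#' @param genes gene data.frame (see [read_gff_genes()]).
#' @param domains domain data.frame (see [read_bed_domains()]); rows are
#'   filtered to `allele` when an `allele` column is present.
#' @param min_overlap_fraction strict lower bound on the overlap fraction
#'   (default 0).
#' @param allele which allele's domains to use (default `"maternal"`,
#'   matching maternal-specific mark profiles in endosperm).
#' @return data.frame `gene_id`, `state`, `k27_fraction`, `k9_fraction`.
#' @export
assign_chromatin_state <- function(genes, domains,
                                   min_overlap_fraction = 0,
                                   allele = "maternal") {
  stopifnot(min_overlap_fraction >= 0, min_overlap_fraction < 1)
  if (!is.null(domains) && "allele" %in% names(domains)) {
    domains <- domains[domains$allele == allele, , drop = FALSE]
  }
  g <- intervals_to_granges(genes[c("chrom", "start", "end")])
  frac <- function(mark) {
    d <- domains[domains$mark == mark, , drop = FALSE]
    if (is.null(d) || nrow(d) == 0L) return(rep(0, nrow(genes)))
    dg <- GenomicRanges::reduce(
      intervals_to_granges(d[c("chrom", "start", "end")]))
    hits <- GenomicRanges::findOverlaps(g, dg, ignore.strand = TRUE)
    ov <- BiocGenerics::width(IRanges::pintersect(
      g[S4Vectors::queryHits(hits)], dg[S4Vectors::subjectHits(hits)],
      ignore.strand = TRUE))
    bp <- tapply(ov, S4Vectors::queryHits(hits), sum)
    res <- rep(0, nrow(genes))
    res[as.integer(names(bp))] <- as.numeric(bp)
    res / BiocGenerics::width(g)
  }
  k27 <- frac("H3K27me3")
  k9 <- frac("H3K9me2")
  has27 <- k27 > min_overlap_fraction
  has9 <- k9 > min_overlap_fraction
  state <- ifelse(has27 & has9, "K27_K9",
                  ifelse(has27, "K27_only",
                         ifelse(has9, "K9_only", "unmarked")))
  data.frame(gene_id = genes$gene_id,
             state = factor(state, levels = .STATES),
             k27_fraction = k27, k9_fraction = k9,
             stringsAsFactors = FALSE)
}

#' Partition genes by chromatin state
#'
#' @param genes gene data.frame.
#' @param domains domain data.frame.
#' @param ... passed to [assign_chromatin_state()].
#' @return named list of gene-id vectors, one per state (the four sets
#'   partition the input genes); sizes in attribute `"sizes"`.
#' @export
state_table <- function(genes, domains, ...) {
  st <- assign_chromatin_state(genes, domains, ...)
  out <- split(st$gene_id, st$state)
  attr(out, "sizes") <- vapply(out, length, integer(1))
  out
}
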