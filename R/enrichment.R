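# Contingency statistics: set-overlap Fisher tests, pairwise Fisher with
# Benjamini-Hochberg correction across strata, and promoter k-mer
# overrepresentation.  Two-sided Fisher p-values follow the
# probability-mass criterion (sum of hypergeometric probabilities of all
# tables at most as probable as the observed one), i.e. the standard
# convention of stats::fisher.test.

fisher_p <- function(a, b, c, d) {
  p <- stats::fisher.test(matrix(c(a, b, c, d), nrow = 2L,
                                 byrow = TRUE))$p.value
  min(p, 1)  # fisher.test can exceed 1 by a few ulp
}

table_odds_ratio <- function(a, b, c, d) {
  (a * d) / (b * c)
}

#' Fisher's exact test of the overlap between two gene sets
#'
#' Builds the 2x2 table a = |A intersect B|, b = |A \ B|, c = |B \ A|,
#' d = |universe \ (A union B)| and returns the two-sided Fisher p-value
#' and the sample odds ratio (a*d)/(b*c) (infinite when b*c = 0).
#'
#' @param setA,setB vectors of identifiers, subsets of `universe`.
#' @param universe vector of all identifiers.
#' @return list `table` (named counts a,b,c,d), `odds_ratio`, `p`.
#' @export
fisher_overlap <- function(setA, setB, universe) {
  setA <- unique(setA); setB <- unique(setB); universe <- unique(universe)
  if (length(setdiff(setA, universe)) > 0L ||
      length(setdiff(setB, universe)) > 0L) {
    stop("setA and setB must be subsets of the universe")
  }
  a <- length(intersect(setA, setB))
  b <- length(setdiff(setA, setB))
  c <- length(setdiff(setB, setA))
  d <- length(universe) - a - b - c
  list(table = c(a = a, b = b, c = c, d = d),
       odds_ratio = table_odds_ratio(a, b, c, d),
       p = fisher_p(a, b, c, d))
}

#' Pairwise Fisher tests across groups with BH correction
#'
#' Tests every unordered pair of groups on their (success, failure)
#' counts, then applies Benjamini-Hochberg correction across all pairs.
#' Groups with zero totals are excluded with a message and recorded in the
#' `"excluded"` attribute.
#'
#' @param success_counts integer vector of successes per group.
#' @param totals integer vector of totals per group.
#' @param group_labels group names (defaults to names of
#'   `success_counts`).
#' @return data.frame `group1`, `group2`, `s1`, `t1`, `s2`, `t2`,
#'   `odds_ratio`, `p`, `q`.
#' @export
pairwise_fisher_bh <- function(success_counts, totals,
                               group_labels = names(success_counts)) {
  if (is.null(group_labels)) {
    group_labels <- as.character(seq_along(success_counts))
  }
  stopifnot(length(success_counts) == length(totals),
            length(group_labels) == length(totals))
  if (any(success_counts > totals)) stop("successes exceed totals")
  keep <- totals > 0L
  excluded <- group_labels[!keep]
  if (length(excluded) > 0L) {
    message("excluding group(s) with zero total: ",
            paste(excluded, collapse = ", "))
  }
  s <- success_counts[keep]; t <- totals[keep]; lab <- group_labels[keep]
  if (length(s) < 2L) stop("need >= 2 groups with non-zero totals")
  pairs <- utils::combn(seq_along(s), 2L)
  out <- data.frame(
    group1 = lab[pairs[1L, ]], group2 = lab[pairs[2L, ]],
    s1 = s[pairs[1L, ]], t1 = t[pairs[1L, ]],
    s2 = s[pairs[2L, ]], t2 = t[pairs[2L, ]],
    stringsAsFactors = FALSE
  )
  out$odds_ratio <- table_odds_ratio(out$s1, out$t1 - out$s1, out$s2,
                                     out$t2 - out$s2)
  out$p <- mapply(fisher_p, out$s1, out$t1 - out$s1, out$s2,
                  out$t2 - out$s2)
  out$q <- bh_adjust(out$p)
  attr(out, "excluded") <- excluded
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment: q_(i) = min_{j >= i}
#' p_(j) * m / j over the sorted p-values, capped at 1 and mapped back to
#' the input order.
#'
#' @param p_values numeric vector of p-values in `[0, 1]` (NA allowed and
#'   propagated).
#' @return adjusted q-values in input order.
#' @export
bh_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values outside [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Promoter k-mer overrepresentation
#'
#' Counts, for every k-mer over A/C/G/T, the promoters of the target and
#' background gene sets containing the k-mer at least once on either
#' strand (presence/absence; multiple occurrences count once), and runs a
#' two-sided Fisher test per k-mer with BH correction across the k-mers
#' whose target presence reaches `min_target_with`.  Promoters are the
#' 1 kb (configurable) upstream of the translation start.  Target genes
#' are removed from the background internally.
#'
#' @param target_genes,background_genes vectors of gene ids.
#' @param genome a [Biostrings::DNAStringSet].
#' @param genes gene data.frame (must contain all ids).
#' @param k word size (default 6, hexamers); at most 8.
#' @param min_target_with minimum target promoters containing the k-mer
#'   for it to enter the tested family (default 3).
#' @param promoter_length upstream window in bp (default 1000).
#' @return data.frame `kmer`, `target_with`, `target_without`,
#'   `background_with`, `background_without`, `odds_ratio`, `p`, `q`,
#'   sorted by `p`; only tested k-mers are returned.
#' @export
kmer_promoter_enrichment <- function(target_genes, background_genes,
                                     genome, genes, k = 6L,
                                     min_target_with = 3L,
                                     promoter_length = 1000L) {
  if (k > 8L) stop("k > 8 not supported (table size guard)")
  target_genes <- unique(target_genes)
  background_genes <- setdiff(unique(background_genes), target_genes)
  all_ids <- c(target_genes, background_genes)
  missing <- setdiff(all_ids, genes$gene_id)
  if (length(missing) > 0L) {
    stop("gene id(s) not in annotation: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  }
  sel <- genes[match(all_ids, genes$gene_id), , drop = FALSE]
  proms <- promoter_regions(sel, genome, promoter_length)
  seqs <- extract_sequences(genome, proms, oriented = TRUE)
  ok <- !is.na(proms$start) & nchar(seqs) >= k
  seqs <- seqs[ok]
  is_target <- all_ids[ok] %in% target_genes
  if (sum(is_target) == 0L || sum(!is_target) == 0L) {
    stop("need promoters in both target and background sets")
  }
  counts <- Biostrings::oligonucleotideFrequency(
    Biostrings::DNAStringSet(seqs), width = k)
  pres <- counts > 0L
  kmers <- colnames(pres)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(kmers)))
  pres_either <- pres | pres[, rc, drop = FALSE]
  tw <- colSums(pres_either[is_target, , drop = FALSE])
  bw <- colSums(pres_either[!is_target, , drop = FALSE])
  nt <- sum(is_target); nb <- sum(!is_target)
  out <- data.frame(
    kmer = kmers,
    target_with = as.integer(tw), target_without = nt - as.integer(tw),
    background_with = as.integer(bw),
    background_without = nb - as.integer(bw),
    stringsAsFactors = FALSE
  )
  out <- out[out$target_with >= min_target_with, , drop = FALSE]
  if (nrow(out) == 0L) {
    out$odds_ratio <- numeric(0); out$p <- numeric(0); out$q <- numeric(0)
    return(out)
  }
  out$odds_ratio <- table_odds_ratio(out$target_with, out$target_without,
                                     out$background_with,
                                     out$background_without)
  # many k-mers share the same 2x2 table; test each unique table once
  key <- paste(out$target_with, out$background_with)
  uniq <- !duplicated(key)
  pu <- mapply(fisher_p, out$target_with[uniq], out$target_without[uniq],
               out$background_with[uniq], out$background_without[uniq])
  out$p <- pu[match(key, key[uniq])]
  out$q <- bh_adjust(out$p)
  out <- out[order(out$p, out$kmer), , drop = FALSE]
  rownames(out) <- NULL
  out
}
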