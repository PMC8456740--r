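# Expression normalisation, germination time-course statistics, and the
# expression-change classification used to stratify genes.

#' Reads per kilobase per million mapped reads
#'
#' @param read_count read count(s), >= 0.
#' @param gene_length_bp gene length(s) in bp, > 0.
#' @param library_mapped_reads total mapped reads in the library, > 0.
#' @return RPKM value(s): `count / (length/1e3 * library/1e6)`.
#' @examples
#' rpkm(100, 2000, 1e7)  # 5
#' @export
rpkm <- function(read_count, gene_length_bp, library_mapped_reads) {
  if (any(gene_length_bp <= 0)) stop("gene_length_bp must be positive")
  if (any(library_mapped_reads <= 0)) {
    stop("library_mapped_reads must be positive")
  }
  read_count / (gene_length_bp / 1e3 * library_mapped_reads / 1e6)
}

#' Per-gene relative expression profiles
#'
#' Each gene's values are divided by the gene's mean across time points,
#' giving a scale-free profile (a flat gene maps to all 1s).  Genes with
#' zero mean are undefined and returned as NA rows; their ids are recorded
#' in the `"undefined"` attribute.
#'
#' @param mat numeric matrix, genes x timepoints (>= 2 columns).
#' @return matrix of the same shape with per-gene mean 1 (NA rows for
#'   undefined genes).
#' @export
relative_profile <- function(mat) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 2L) stop("need >= 2 timepoints")
  mu <- rowMeans(mat)
  out <- sweep(mat, 1L, mu, "/")
  undef <- mu == 0 | is.na(mu)
  out[undef, ] <- NA_real_
  attr(out, "undefined") <- rownames(mat)[undef]
  out
}

# Wilcoxon rank-sum p-value: exact null enumeration when both samples have
# n <= 10 and there are no ties, normal approximation with tie and
# continuity correction otherwise.
wilcox_rank_sum <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) == 0L || length(y) == 0L) return(NA_real_)
  exact <- length(x) <= 10L && length(y) <= 10L &&
    !anyDuplicated(c(x, y))
  suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                       correct = TRUE)$p.value
  )
}

#' Wilcoxon shift test of each time point against a reference
#'
#' Two-sided Wilcoxon rank-sum test of a gene group's relative expression
#' values at each time point against the reference time point (typically
#' 1 hr of imbibition).  Exact enumeration is used when both samples have
#' at most 10 values and no ties; otherwise the normal approximation with
#' tie correction.  Groups of fewer than 3 genes are flagged (all p NA).
#'
#' @param profiles numeric matrix, genes x timepoints (e.g. from
#'   [relative_profile()]); column names identify time points.
#' @param reference_timepoint column name or index of the reference.
#' @return data.frame `timepoint`, `n`, `p`; attribute `"flagged"` is TRUE
#'   when the group was too small to test.
#' @export
timepoint_shift_test <- function(profiles, reference_timepoint = 1L) {
  profiles <- as.matrix(profiles)
  keep <- stats::complete.cases(profiles)
  profiles <- profiles[keep, , drop = FALSE]
  tps <- colnames(profiles)
  if (is.null(tps)) tps <- as.character(seq_len(ncol(profiles)))
  ref_idx <- if (is.character(reference_timepoint)) {
    match(reference_timepoint, tps)
  } else as.integer(reference_timepoint)
  if (is.na(ref_idx) || ref_idx < 1L || ref_idx > ncol(profiles)) {
    stop("reference timepoint not found")
  }
  out <- data.frame(timepoint = tps, n = nrow(profiles), p = NA_real_,
                    stringsAsFactors = FALSE)
  flagged <- nrow(profiles) < 3L
  if (!flagged) {
    ref <- profiles[, ref_idx]
    for (j in seq_len(ncol(profiles))) {
      out$p[j] <- if (j == ref_idx) 1 else
        wilcox_rank_sum(profiles[, j], ref)
    }
  }
  attr(out, "flagged") <- flagged
  out
}

#' Classify per-gene expression change
#'
#' `non_expressed` when the expressed flag is FALSE; `up` when
#' log2FC >= `fc_cut` and p < `alpha`; `down` when log2FC <= -`fc_cut` and
#' p < `alpha`; `stable` otherwise (expressed, but neither threshold met).
#'
#' @param log2fc log2 fold change(s) (condition over reference).
#' @param p p-value(s) in `[0, 1]`.
#' @param expressed logical flag(s).
#' @param fc_cut fold-change threshold (default 1).
#' @param alpha significance threshold (default 0.05).
#' @return factor with levels `up`, `down`, `stable`, `non_expressed`.
#' @export
classify_change <- function(log2fc, p, expressed, fc_cut = 1,
                            alpha = 0.05) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values outside [0, 1]")
  n <- max(length(log2fc), length(p), length(expressed))
  log2fc <- rep_len(log2fc, n)
  p <- rep_len(p, n)
  expressed <- rep_len(expressed, n)
  cls <- ifelse(!expressed, "non_expressed",
                ifelse(log2fc >= fc_cut & p < alpha, "up",
                       ifelse(log2fc <= -fc_cut & p < alpha, "down",
                              "stable")))
  factor(cls, levels = c("up", "down", "stable", "non_expressed"))
}

#' Flag expressed genes in an expression matrix
#'
#' A gene counts as expressed when at least one sample reaches
#' `min_rpkm`; "non-expressed" genes fall below it in every sample.
#'
#' @param mat numeric matrix, genes x samples (RPKM).
#' @param min_rpkm expression floor (default 1).
#' @return named logical vector.
#' @export
expressed_genes <- function(mat, min_rpkm = 1) {
  apply(as.matrix(mat) >= min_rpkm, 1L, any)
}

#' Plain two-group differential test for fabricating fixture DE tables
#'
#' Not the negative-binomial machinery used on real sequencing data: log2
#' fold change of group means with a pseudo-count, and a Welch t-test on
#' log2-transformed values.  Used only to fabricate differential
#' expression tables for synthetic runs.
#'
#' @param mat numeric matrix, genes x samples (RPKM).
#' @param cols_a,cols_b column names or indices of the two groups
#'   (reference = A), each with >= 2 replicates.
#' @param pseudo pseudo-count (default 1).
#' @return data.frame `gene_id`, `log2fc`, `p`, `q` (BH).
#' @export
simple_de_for_fixtures <- function(mat, cols_a, cols_b, pseudo = 1) {
  mat <- as.matrix(mat)
  a <- mat[, cols_a, drop = FALSE]
  b <- mat[, cols_b, drop = FALSE]
  if (ncol(a) < 2L || ncol(b) < 2L) {
    stop("need >= 2 replicates per group")
  }
  log2fc <- log2((rowMeans(b) + pseudo) / (rowMeans(a) + pseudo))
  p <- vapply(seq_len(nrow(mat)), function(i) {
    la <- log2(a[i, ] + pseudo); lb <- log2(b[i, ] + pseudo)
    if (stats::sd(c(la, lb)) == 0) return(1)
    tryCatch(stats::t.test(lb, la)$p.value, error = function(e) 1)
  }, numeric(1))
  data.frame(gene_id = rownames(mat), log2fc = log2fc, p = p,
             q = bh_adjust(p), stringsAsFactors = FALSE)
}
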