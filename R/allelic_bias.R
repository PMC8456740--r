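# Maternal expression ratios in endosperm and group-versus-background
# bias tests.  The endosperm is triploid (2 maternal : 1 paternal genome),
# so 2/3 is the neutral maternal fraction; bias is nevertheless assessed
# against the empirical all-genes background distribution.

#' Maternal expression ratio
#'
#' maternal / (maternal + paternal) read counts; undefined (NA) when both
#' are zero.
#'
#' @param maternal_reads,paternal_reads non-negative counts.
#' @return numeric ratio(s) in `[0, 1]`, NA where undefined.
#' @examples
#' maternal_ratio(20, 10)  # 2/3, the triploid neutral expectation
#' @export
maternal_ratio <- function(maternal_reads, paternal_reads) {
  if (any(maternal_reads < 0 | paternal_reads < 0)) {
    stop("negative read counts")
  }
  total <- maternal_reads + paternal_reads
  ifelse(total == 0, NA_real_, maternal_reads / total)
}

#' Filter allele-resolved count records by total coverage
#'
#' @param records data.frame with `maternal_reads`, `paternal_reads`.
#' @param min_total minimum maternal + paternal reads (default 10).
#' @return the retained rows.
#' @export
min_coverage_filter <- function(records, min_total = 10L) {
  keep <- (records$maternal_reads + records$paternal_reads) >= min_total
  records[keep, , drop = FALSE]
}

#' Wilcoxon bias test of gene groups against the all-genes background
#'
#' Two-sided Wilcoxon rank-sum test of each group's maternal ratios
#' against the background ratios, Benjamini-Hochberg correction across
#' the tested groups, and a direction call from the medians (maternal
#' when the group median exceeds the background median, paternal when
#' below, none at equality).  Groups with fewer than `min_n` ratios are
#' flagged and get NA p/q.
#'
#' @param group_ratios named list of numeric maternal-ratio vectors.
#' @param background_ratios numeric vector (all-genes background).
#' @param min_n minimum group size to test (default 3).
#' @return data.frame `group`, `n`, `median`, `background_median`, `p`,
#'   `q`, `direction`, `flagged`.
#' @export
group_bias_test <- function(group_ratios, background_ratios, min_n = 3L) {
  stopifnot(is.list(group_ratios), !is.null(names(group_ratios)))
  bg <- background_ratios[!is.na(background_ratios)]
  bg_med <- stats::median(bg)
  out <- data.frame(
    group = names(group_ratios),
    n = vapply(group_ratios, function(g) sum(!is.na(g)), integer(1)),
    median = vapply(group_ratios,
                    function(g) stats::median(g, na.rm = TRUE), numeric(1)),
    background_median = bg_med,
    p = NA_real_, q = NA_real_,
    stringsAsFactors = FALSE
  )
  out$flagged <- out$n < min_n
  for (i in seq_len(nrow(out))) {
    if (!out$flagged[i]) {
      g <- group_ratios[[i]]
      out$p[i] <- wilcox_rank_sum(g[!is.na(g)], bg)
    }
  }
  tested <- !is.na(out$p)
  out$q[tested] <- bh_adjust(out$p[tested])
  out$direction <- ifelse(is.na(out$median) | out$median == bg_med, "none",
                          ifelse(out$median > bg_med, "maternal",
                                 "paternal"))
  rownames(out) <- NULL
  out
}

#' Read an allele-resolved count table
#'
#' TSV with header columns `gene_id`, `maternal_reads`, `paternal_reads`,
#' `condition`.
#'
#' @param path input path.
#' @return data.frame with a derived `ratio` column.
#' @export
read_allelic_counts <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("gene_id", "maternal_reads", "paternal_reads", "condition")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L) {
    stop("allelic count table lacks column(s): ",
         paste(missing, collapse = ", "))
  }
  df$ratio <- maternal_ratio(df$maternal_reads, df$paternal_reads)
  df
}
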