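# Per-cytosine bisulfite counts and the three-state methylation call.
#
# A methylome is a data.frame/data.table with columns
#   chrom, pos (1-based), strand (+/-), context (CG/CHG/CHH),
#   count_methylated, count_total, sample_id, replicate, allele
# The on-disk interchange format is a CX-report-style TSV carrying
# count_unmethylated instead of count_total.

.METH_COLS <- c("chrom", "pos", "strand", "context", "count_methylated",
                "count_total", "sample_id", "replicate", "allele")

validate_methylome <- function(meth) {
  missing <- setdiff(c("chrom", "pos", "strand", "context",
                       "count_methylated", "count_total"), names(meth))
  if (length(missing) > 0L) {
    stop("methylome lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (any(meth$count_methylated > meth$count_total)) {
    stop("count_methylated exceeds count_total")
  }
  if (any(meth$count_methylated < 0L | meth$count_total < 0L)) {
    stop("negative read counts")
  }
  meth <- data.table::copy(data.table::as.data.table(meth))
  if (!"sample_id" %in% names(meth)) meth[, sample_id := "sample"]
  if (!"replicate" %in% names(meth)) meth[, replicate := 1L]
  if (!"allele" %in% names(meth)) meth[, allele := "unphased"]
  meth
}

#' Read a CX-report-style methylation TSV
#'
#' Expected columns (header row, tab-separated): `chrom`, `pos`, `strand`,
#' `count_methylated`, `count_unmethylated`, `context`, and optionally
#' `sample_id`, `replicate`, `allele` (defaults: `"sample"`, 1,
#' `"unphased"`).
#'
#' @param path input path.
#' @return a data.table with the standard methylome columns (including
#'   `count_total`).
#' @export
read_cx_report <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  need <- c("chrom", "pos", "strand", "count_methylated",
            "count_unmethylated", "context")
  missing <- setdiff(need, names(dt))
  if (length(missing) > 0L) {
    stop("CX report ", path, " lacks column(s): ",
         paste(missing, collapse = ", "))
  }
  bad <- setdiff(unique(dt$context), .CONTEXTS)
  if (length(bad) > 0L) {
    stop("invalid context value(s): ", paste(bad, collapse = ", "))
  }
  dt[, count_total := count_methylated + count_unmethylated]
  dt[, count_unmethylated := NULL]
  validate_methylome(dt)[]
}

#' Write a methylome as a CX-report-style TSV
#'
#' @param meth methylome data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cx_report <- function(meth, path) {
  meth <- validate_methylome(meth)
  out <- meth[, .(chrom, pos, strand, count_methylated,
                  count_unmethylated = count_total - count_methylated,
                  context, sample_id, replicate, allele)]
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

# vectorised call rules -------------------------------------------------

call_two_rep_status <- function(m1, t1, m2, t2, min_cov = 5L) {
  ifelse(t1 < min_cov | t2 < min_cov, "undetermined",
         ifelse(m1 >= 1L & m2 >= 1L, "methylated", "unmethylated"))
}

call_pooled_status <- function(m, t, min_cov = 5L) {
  ifelse(t < min_cov, "undetermined",
         ifelse(m >= 1L, "methylated", "unmethylated"))
}

#' Two-replicate methylation call for one cytosine
#'
#' A site is methylated when each replicate has at least `min_cov` reads
#' and each replicate carries at least one methylated read; undetermined
#' when either replicate is below `min_cov`; unmethylated otherwise.
#'
#' @param rep1,rep2 one-row data.frames (or lists) with
#'   `count_methylated`, `count_total` and optionally `chrom`/`pos`/`strand`
#'   (checked for agreement when present in both).
#' @param min_cov minimum reads per replicate (default 5).
#' @return list with `status` and `supporting` (per-replicate counts).
#' @export
call_site_two_replicates <- function(rep1, rep2, min_cov = 5L) {
  for (k in c("chrom", "pos", "strand", "context")) {
    if (!is.null(rep1[[k]]) && !is.null(rep2[[k]]) &&
        !identical(rep1[[k]], rep2[[k]])) {
      stop("replicates refer to different positions (", k, " differs)")
    }
  }
  status <- call_two_rep_status(rep1$count_methylated, rep1$count_total,
                                rep2$count_methylated, rep2$count_total,
                                min_cov)
  list(status = status,
       supporting = data.frame(
         replicate = c(1L, 2L),
         count_methylated = c(rep1$count_methylated, rep2$count_methylated),
         count_total = c(rep1$count_total, rep2$count_total)))
}

#' Pooled-replicate methylation call for one cytosine
#'
#' Counts are pooled across replicates; the pooled site is methylated when
#' it carries at least one methylated read among at least `min_cov` reads.
#'
#' @param records data.frame with `count_methylated`, `count_total`, one
#'   row per replicate, all for the same cytosine.
#' @param min_cov minimum pooled reads (default 5).
#' @return list with `status` and `supporting` (the pooled counts).
#' @export
call_site_pooled <- function(records, min_cov = 5L) {
  for (k in c("chrom", "pos", "strand", "context")) {
    if (!is.null(records[[k]]) && length(unique(records[[k]])) > 1L) {
      stop("records refer to different positions (", k, " differs)")
    }
  }
  m <- sum(records$count_methylated)
  t <- sum(records$count_total)
  list(status = call_pooled_status(m, t, min_cov),
       supporting = data.frame(count_methylated = m, count_total = t))
}

#' Per-position methylation calls across a methylome
#'
#' Applies the chosen call rule to every cytosine, grouping records by
#' (chrom, pos, strand, context, sample_id, allele).  Under the
#' two-replicate rule a replicate with no record at a position counts as
#' zero coverage (hence undetermined).
#'
#' @param meth methylome data.frame.
#' @param rule `"two_replicates"` or `"pooled"`.
#' @param min_cov coverage threshold (default 5).
#' @return data.table with the grouping columns plus `status`,
#'   `count_methylated`, `count_total` (summed over replicates).
#' @export
call_methylome <- function(meth, rule = c("two_replicates", "pooled"),
                           min_cov = 5L) {
  rule <- match.arg(rule)
  meth <- validate_methylome(meth)
  keys <- c("chrom", "pos", "strand", "context", "sample_id", "allele")
  if (rule == "pooled") {
    calls <- meth[, .(count_methylated = sum(count_methylated),
                      count_total = sum(count_total)), by = keys]
    calls[, status := call_pooled_status(count_methylated, count_total,
                                         min_cov)]
  } else {
    reps <- sort(unique(meth$replicate))
    per_rep <- meth[, .(m = sum(count_methylated), t = sum(count_total)),
                    by = c(keys, "replicate")]
    calls <- per_rep[, .(
      count_methylated = sum(m),
      count_total = sum(t),
      min_rep_cov = min(c(t, rep(0L, length(reps) - .N))),
      all_rep_meth = (.N == length(reps)) && all(m >= 1L)
    ), by = keys]
    calls[, status := ifelse(min_rep_cov < min_cov, "undetermined",
                             ifelse(all_rep_meth, "methylated",
                                    "unmethylated"))]
    calls[, c("min_rep_cov", "all_rep_meth") := NULL]
  }
  data.table::setorderv(calls, keys)
  calls[]
}

#' CHG-methylation status of REF6-binding sites
#'
#' A site is methylated when any CHG-context cytosine within it is called
#' methylated; unmethylated when all CHG cytosines with determinate calls
#' are unmethylated and at least one is determinate; undetermined when no
#' CHG cytosine yields a determinate call (including sites without any
#' CHG-context cytosine).  Positions with undetermined context or calls
#' are absent evidence, never treated as methylated.
#'
#' @param annotations data.frame from [annotate_site_positions()].
#' @param calls data.table from [call_methylome()].
#' @return data.frame with one row per site: `site_id`, `gene_id`,
#'   `chrom`, `start`, `end`, `strand`, `status`.
#' @export
refbs_chgm_status <- function(annotations, calls) {
  ann <- data.table::as.data.table(annotations)
  site_cols <- c("site_id", "gene_id", "chrom", "start", "end", "strand")
  sites <- unique(ann[, ..site_cols])
  chg <- ann[context == "CHG"]
  calls <- data.table::as.data.table(calls)
  merged <- merge(
    chg[, .(site_id, chrom, pos = genomic_coord, strand = cytosine_strand)],
    calls[, .(chrom, pos, strand, status)],
    by = c("chrom", "pos", "strand"), all.x = TRUE
  )
  merged[is.na(status), status := "undetermined"]
  per_site <- merged[, .(
    any_meth = any(status == "methylated"),
    any_det = any(status != "undetermined")
  ), by = site_id]
  out <- merge(sites, per_site, by = "site_id", all.x = TRUE)
  out[, status := ifelse(is.na(any_meth) | !any_det, "undetermined",
                         ifelse(any_meth, "methylated", "unmethylated"))]
  out[, c("any_meth", "any_det") := NULL]
  data.table::setorderv(out, c("chrom", "start", "strand"))
  as.data.frame(out)
}

#' Per-motif-position CHG methylation counts across sites
#'
#' For each motif position, the numerator counts sites whose CHG-context
#' cytosine at that position is called methylated and the denominator
#' counts sites with a determinate call there.  Positions without
#' CHG-context cytosines report a zero denominator.
#'
#' @param annotations data.frame from [annotate_site_positions()].
#' @param calls data.table from [call_methylome()].
#' @param n_positions motif width (default 8).
#' @return data.frame `motif_position`, `n_methylated`, `n_determinate`,
#'   `fraction` (NA when the denominator is zero).
#' @export
position_chgm_table <- function(annotations, calls, n_positions = 8L) {
  base <- data.frame(motif_position = seq_len(n_positions),
                     n_methylated = 0L, n_determinate = 0L)
  ann <- data.table::as.data.table(annotations)
  if (nrow(ann) > 0L) {
    chg <- ann[context == "CHG"]
    if (nrow(chg) > 0L) {
      calls <- data.table::as.data.table(calls)
      merged <- merge(
        chg[, .(site_id, motif_position, chrom, pos = genomic_coord,
                strand = cytosine_strand)],
        calls[, .(chrom, pos, strand, status)],
        by = c("chrom", "pos", "strand"), all.x = TRUE
      )
      merged[is.na(status), status := "undetermined"]
      tab <- merged[, .(
        n_methylated = sum(status == "methylated"),
        n_determinate = sum(status != "undetermined")
      ), by = motif_position]
      base$n_methylated[tab$motif_position] <- tab$n_methylated
      base$n_determinate[tab$motif_position] <- tab$n_determinate
    }
  }
  base$fraction <- ifelse(base$n_determinate > 0L,
                          base$n_methylated / base$n_determinate, NA_real_)
  base
}

#' Read-weighted methylation level of regions
#'
#' The level of a region is the sum of methylated reads divided by the sum
#' of total reads over covered cytosines of the requested context within
#' the region.  Regions without covered cytosines get an NA level flagged
#' `undefined` (never 0).  The presence/absence classification uses the
#' `> cut` rule (default cut 0.04; the boundary value is "absent").
#'
#' @param regions data.frame with `chrom`, `start`, `end` (and any id
#'   columns, which are carried through).
#' @param meth methylome data.frame.
#' @param context one of `"CG"`, `"CHG"`, `"CHH"`.
#' @param allele allele filter (default `"unphased"`).
#' @param cut classification cut-off on the level (default 0.04).
#' @return `regions` with added `level`, `covered_cytosines`,
#'   `classification` (`"present"`/`"absent"`/`"undefined"`).
#' @export
region_methylation_level <- function(regions, meth, context,
                                     allele = "unphased", cut = 0.04) {
  context <- match.arg(context, .CONTEXTS)
  meth <- validate_methylome(meth)
  sub <- meth[meth$context == context & meth$allele == allele]
  out <- as.data.frame(regions)
  out$level <- NA_real_
  out$covered_cytosines <- 0L
  if (nrow(sub) > 0L && nrow(out) > 0L) {
    mgr <- GenomicRanges::GRanges(sub$chrom,
                                  IRanges::IRanges(sub$pos, sub$pos))
    rgr <- intervals_to_granges(out[c("chrom", "start", "end")])
    hits <- GenomicRanges::findOverlaps(mgr, rgr, ignore.strand = TRUE)
    if (length(hits) > 0L) {
      dt <- data.table::data.table(
        region = S4Vectors::subjectHits(hits),
        m = sub$count_methylated[S4Vectors::queryHits(hits)],
        t = sub$count_total[S4Vectors::queryHits(hits)],
        key_pos = paste0(sub$chrom, ":", sub$pos, ":",
                         sub$strand)[S4Vectors::queryHits(hits)]
      )
      agg <- dt[, .(m = sum(m), t = sum(t),
                    n_cyt = data.table::uniqueN(key_pos)), by = region]
      agg <- agg[t > 0L]
      out$level[agg$region] <- agg$m / agg$t
      out$covered_cytosines[agg$region] <- agg$n_cyt
    }
  }
  out$classification <- ifelse(is.na(out$level), "undefined",
                               ifelse(out$level > cut, "present", "absent"))
  out
}

#' Binned methylation profile over a gene and its flanks
#'
#' Upstream and downstream flanks are fixed `flank` bp in genomic
#' coordinates (truncated at chromosome edges); the gene body is scaled to
#' `bins` bins.  All segments are oriented by the gene's strand (bin 1 of
#' the upstream segment is the 5'-most).  Replicates are pooled per
#' cytosine first and only cytosines reaching the pooled coverage
#' threshold (`min_cov`, default 5) contribute; per-bin levels are
#' read-weighted.
#'
#' @param gene one-row gene data.frame (`chrom`, `start`, `end`, `strand`).
#' @param meth methylome data.frame.
#' @param context one of `"CG"`, `"CHG"`, `"CHH"`.
#' @param allele allele filter (default `"unphased"`).
#' @param flank flank width in bp (default 2000).
#' @param bins number of bins per segment (default 20).
#' @param min_cov pooled coverage threshold per cytosine (default 5).
#' @return data.frame `segment` (`upstream`/`body`/`downstream`), `bin`,
#'   `start`, `end`, `level`, `covered_cytosines`.
#' @export
flank_profile <- function(gene, meth, context, allele = "unphased",
                          flank = 2000L, bins = 20L, min_cov = 5L) {
  context <- match.arg(context, .CONTEXTS)
  stopifnot(nrow(gene) == 1L)
  meth <- validate_methylome(meth)
  sub <- meth[meth$context == context & meth$allele == allele &
                meth$chrom == gene$chrom]
  pooled <- sub[, .(m = sum(count_methylated), t = sum(count_total)),
                by = .(pos)]
  pooled <- pooled[t >= min_cov]

  seg_bins <- function(lo, hi, k, reverse) {
    lo <- max(1L, lo)
    if (hi < lo) {
      return(data.frame(bin = integer(), start = integer(),
                        end = integer()))
    }
    edges <- round(seq(lo - 1L, hi, length.out = k + 1L))
    df <- data.frame(bin = seq_len(k), start = edges[-(k + 1L)] + 1L,
                     end = edges[-1L])
    df <- df[df$end >= df$start, , drop = FALSE]
    if (reverse) df$bin <- k + 1L - df$bin
    df[order(df$bin), , drop = FALSE]
  }
  minus <- identical(gene$strand, "-")
  up <- if (minus) {
    seg_bins(gene$end + 1L, gene$end + flank, bins, reverse = TRUE)
  } else {
    seg_bins(gene$start - flank, gene$start - 1L, bins, reverse = FALSE)
  }
  dn <- if (minus) {
    seg_bins(gene$start - flank, gene$start - 1L, bins, reverse = TRUE)
  } else {
    seg_bins(gene$end + 1L, gene$end + flank, bins, reverse = FALSE)
  }
  body <- seg_bins(gene$start, gene$end, bins, reverse = minus)
  segs <- rbind(
    cbind(segment = "upstream", up),
    cbind(segment = "body", body),
    cbind(segment = "downstream", dn)
  )
  segs$level <- NA_real_
  segs$covered_cytosines <- 0L
  segs$reads_methylated <- 0L
  segs$reads_total <- 0L
  for (i in seq_len(nrow(segs))) {
    inbin <- pooled[pos >= segs$start[i] & pos <= segs$end[i]]
    if (nrow(inbin) > 0L) {
      segs$level[i] <- sum(inbin$m) / sum(inbin$t)
      segs$covered_cytosines[i] <- nrow(inbin)
      segs$reads_methylated[i] <- sum(inbin$m)
      segs$reads_total[i] <- sum(inbin$t)
    }
  }
  rownames(segs) <- NULL
  segs
}

#' Average flank profile over a gene set
#'
#' Aggregates read counts per (segment, bin) across genes before dividing,
#' i.e. the group profile is read-weighted like the per-gene one.
#'
#' @inheritParams flank_profile
#' @param genes gene data.frame (one row per gene).
#' @return data.frame `segment`, `bin`, `level`, `covered_cytosines`.
#' @export
average_flank_profile <- function(genes, meth, context,
                                  allele = "unphased", flank = 2000L,
                                  bins = 20L, min_cov = 5L) {
  meth <- validate_methylome(meth)
  acc <- NULL
  for (i in seq_len(nrow(genes))) {
    prof <- flank_profile(genes[i, , drop = FALSE], meth, context, allele,
                          flank, bins, min_cov)
    acc <- rbind(acc, data.table::as.data.table(prof)[
      , .(segment, bin, covered_cytosines, reads_methylated, reads_total)])
  }
  if (is.null(acc)) {
    return(data.frame(segment = character(), bin = integer(),
                      level = numeric(), covered_cytosines = integer()))
  }
  out <- acc[, .(
    level = if (sum(reads_total) > 0L) sum(reads_methylated) / sum(reads_total)
            else NA_real_,
    covered_cytosines = sum(covered_cytosines)
  ), by = .(segment, bin)]
  as.data.frame(out)
}
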