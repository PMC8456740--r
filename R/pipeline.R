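# Orchestration of the analysis stages into the three headline analyses:
# CHG methylation of REF6-binding sites across chromatin states and its
# link to germination activation; maternal-ratio bias of the stratified
# gene groups; and differential-expression overlays on the strata.
# Every report embeds the fully resolved configuration so identical
# inputs and settings reproduce identical reports.

#' Default analysis configuration
#'
#' All thresholds carry the study defaults: methylation-call coverage
#' `min_cov` 5 reads, gene-body CHG presence cut 0.04, |log2FC| cut 1 with
#' alpha 0.05 for expression classes, promoter length 1000 bp, flank
#' width 2000 bp, expression comparison window 1 vs 38 hours of
#' imbibition.
#'
#' @param min_cov methylation-call coverage threshold.
#' @param chgm_cut gene-body CHG presence cut.
#' @param log2fc_cut expression-class fold-change threshold.
#' @param alpha expression-class significance threshold.
#' @param promoter_length promoter window (bp).
#' @param flank flank width (bp).
#' @param de_window hours of imbibition compared for expression change.
#' @param call_rule `"two_replicates"` or `"pooled"`.
#' @param min_allelic_total minimum allele-resolved reads per gene.
#' @param seed seed recorded in reports.
#' @return config list.
#' @export
default_run_config <- function(min_cov = 5L, chgm_cut = 0.04,
                               log2fc_cut = 1, alpha = 0.05,
                               promoter_length = 1000L, flank = 2000L,
                               de_window = c(1, 38),
                               call_rule = "two_replicates",
                               min_allelic_total = 10L, seed = 1L) {
  as.list(environment())
}

stage_required <- function(x, stage) {
  if (is.null(x)) stop("missing input for stage: ", stage, call. = FALSE)
  x
}

#' Gene-level REF6-binding-site methylation status
#'
#' Aggregates per-site statuses to genes: `methylated` when any site in
#' the gene is methylated; `unmethylated` when at least one site is
#' determinate and none methylated; `undetermined` when sites exist but
#' none is determinate; `no_site` for genes without sites.
#'
#' @param site_status data.frame from [refbs_chgm_status()].
#' @param genes gene data.frame (defines the gene universe).
#' @return data.frame `gene_id`, `refbs_status`.
#' @export
gene_refbs_status <- function(site_status, genes) {
  by_gene <- tapply(site_status$status, site_status$gene_id, function(s) {
    if (any(s == "methylated")) "methylated"
    else if (any(s == "unmethylated")) "unmethylated"
    else "undetermined"
  })
  out <- data.frame(gene_id = genes$gene_id,
                    refbs_status = "no_site",
                    stringsAsFactors = FALSE)
  idx <- match(names(by_gene), out$gene_id)
  out$refbs_status[idx[!is.na(idx)]] <-
    as.character(by_gene)[!is.na(idx)]
  out
}

#' CHG methylation of REF6-binding sites across chromatin states
#'
#' Runs the site-centric analysis: per-state percentage of REF6-binding
#' sites with CHG methylation (pairwise Fisher + BH, reported both on
#' determinate sites only and under the alternative convention counting
#' undetermined sites as unmethylated), the per-position CHG methylation
#' table per state, and - when a differential-expression table is
#' supplied - the percentage of upregulated genes stratified by
#' site-methylation status (pairwise Fisher + BH).
#'
#' @param genome a [Biostrings::DNAStringSet].
#' @param genes gene data.frame.
#' @param domains domain data.frame.
#' @param methylome methylome records.
#' @param de optional DE table (`gene_id`, `log2fc`, `p`, optional
#'   logical `expressed`).
#' @param config list from [default_run_config()].
#' @return report list: `config`, `inputs`, `states`, `site_status`,
#'   `chgm_by_state`, `pairwise_chgm` (+ `_undet_as_unmeth` variants),
#'   `position_table_by_state`, and `upregulated_by_category` /
#'   `pairwise_upregulated` when `de` is given.
#' @export
run_fig2_analysis <- function(genome, genes, domains, methylome,
                              de = NULL,
                              config = default_run_config()) {
  stage_required(genome, "genome")
  stage_required(genes, "genes")
  stage_required(domains, "domains")
  stage_required(methylome, "methylome")
  states <- assign_chromatin_state(genes, domains)
  sites <- scan_motif(genome, genes)
  ann <- annotate_site_positions(sites, genome)
  calls <- call_methylome(methylome, rule = config$call_rule,
                          min_cov = config$min_cov)
  site_status <- refbs_chgm_status(ann, calls)
  site_status$state <- as.character(
    states$state[match(site_status$gene_id, states$gene_id)])

  marked <- c("K27_only", "K9_only", "K27_K9")
  tab <- data.table::as.data.table(site_status)[state %in% marked]
  chgm_by_state <- as.data.frame(tab[, .(
    n_sites = .N,
    n_methylated = sum(status == "methylated"),
    n_determinate = sum(status != "undetermined")
  ), by = state])
  chgm_by_state$pct_chgm_determinate <- with(
    chgm_by_state, 100 * n_methylated / pmax(n_determinate, 1L))
  chgm_by_state$pct_chgm_all_sites <- with(
    chgm_by_state, 100 * n_methylated / pmax(n_sites, 1L))

  pairwise_chgm <- pairwise_fisher_bh(
    chgm_by_state$n_methylated, chgm_by_state$n_determinate,
    chgm_by_state$state)
  pairwise_chgm_alt <- pairwise_fisher_bh(
    chgm_by_state$n_methylated, chgm_by_state$n_sites,
    chgm_by_state$state)

  pos_tabs <- lapply(stats::setNames(marked, marked), function(st) {
    gene_sel <- states$gene_id[states$state == st]
    position_chgm_table(ann[ann$gene_id %in% gene_sel, , drop = FALSE],
                        calls)
  })

  report <- list(
    config = config,
    inputs = list(n_chromosomes = length(genome), n_genes = nrow(genes),
                  n_domains = nrow(domains), n_sites = nrow(sites),
                  n_methylome_records = nrow(methylome),
                  has_de = !is.null(de)),
    states = states,
    site_status = site_status,
    chgm_by_state = chgm_by_state,
    pairwise_chgm = pairwise_chgm,
    pairwise_chgm_undet_as_unmeth = pairwise_chgm_alt,
    position_table_by_state = pos_tabs
  )

  if (!is.null(de)) {
    expressed <- if ("expressed" %in% names(de)) de$expressed else TRUE
    de$class <- classify_change(de$log2fc, de$p, expressed,
                                fc_cut = config$log2fc_cut,
                                alpha = config$alpha)
    gs <- gene_refbs_status(site_status, genes)
    gs$state <- as.character(
      states$state[match(gs$gene_id, states$gene_id)])
    gs$class <- de$class[match(gs$gene_id, de$gene_id)]
    cats <- data.table::as.data.table(gs)[
      state %in% c("K27_only", "K27_K9") &
        refbs_status %in% c("methylated", "unmethylated") &
        !is.na(class)]
    up_tab <- as.data.frame(cats[, .(
      n_genes = .N, n_up = sum(class == "up")
    ), by = .(state, refbs_status)])
    up_tab$pct_up <- 100 * up_tab$n_up / pmax(up_tab$n_genes, 1L)
    lab <- paste(up_tab$state, up_tab$refbs_status, sep = ":")
    report$upregulated_by_category <- up_tab
    if (nrow(up_tab) >= 2L) {
      report$pairwise_upregulated <- pairwise_fisher_bh(
        up_tab$n_up, up_tab$n_genes, lab)
    }
  }
  report
}

#' Maternal-ratio bias of the stratified gene groups
#'
#' Computes maternal expression ratios per condition (after the
#' minimum-coverage filter), forms the (chromatin state x REF6-binding-
#' site methylation) groups, and tests each against the all-genes
#' background with pairwise Wilcoxon + BH per condition.
#'
#' @param allelic allele-resolved count table (`gene_id`,
#'   `maternal_reads`, `paternal_reads`, `condition`).
#' @param states data.frame from [assign_chromatin_state()].
#' @param gene_status data.frame from the fig2 report's `site_status`
#'   aggregated per gene (or any `gene_id`/`refbs_status` table).
#' @param config list from [default_run_config()].
#' @return report list: `config`, `inputs`, and per condition a
#'   `summary` (medians, IQRs, n) plus the `bias_test` table.
#' @export
run_fig8_analysis <- function(allelic, states, gene_status,
                              config = default_run_config()) {
  stage_required(allelic, "allelic counts")
  stage_required(states, "chromatin states")
  stage_required(gene_status, "REF6-BS methylation status")
  report <- list(config = config,
                 inputs = list(n_records = nrow(allelic),
                               n_genes = length(unique(allelic$gene_id))),
                 conditions = list())
  meta <- data.frame(
    gene_id = states$gene_id,
    state = as.character(states$state),
    refbs_status = gene_status$refbs_status[
      match(states$gene_id, gene_status$gene_id)],
    stringsAsFactors = FALSE
  )
  for (cond in unique(allelic$condition)) {
    rec <- allelic[allelic$condition == cond, , drop = FALSE]
    rec <- min_coverage_filter(rec, config$min_allelic_total)
    rec$ratio <- maternal_ratio(rec$maternal_reads, rec$paternal_reads)
    rec <- rec[!is.na(rec$ratio), , drop = FALSE]
    m <- meta[match(rec$gene_id, meta$gene_id), , drop = FALSE]
    groups <- list()
    for (st in c("K27_K9", "K27_only")) {
      for (ms in c("methylated", "unmethylated")) {
        sel <- !is.na(m$state) & m$state == st &
          !is.na(m$refbs_status) & m$refbs_status == ms
        if (sum(sel) > 0L) {
          groups[[paste(st, ms, sep = ":")]] <- rec$ratio[sel]
        }
      }
    }
    background <- rec$ratio
    test <- group_bias_test(groups, background)
    summ <- data.frame(
      group = c("all_genes", names(groups)),
      n = c(length(background), vapply(groups, length, integer(1))),
      median = c(stats::median(background),
                 vapply(groups, stats::median, numeric(1))),
      q25 = c(stats::quantile(background, 0.25),
              vapply(groups, stats::quantile, numeric(1), probs = 0.25)),
      q75 = c(stats::quantile(background, 0.75),
              vapply(groups, stats::quantile, numeric(1), probs = 0.75)),
      stringsAsFactors = FALSE
    )
    rownames(summ) <- NULL
    report$conditions[[cond]] <- list(summary = summ, bias_test = test)
  }
  report
}

#' Differential-expression overlay on the stratified gene groups
#'
#' Tests the enrichment of every (chromatin state x REF6-binding-site
#' methylation status) category among upregulated and among downregulated
#' genes against the all-genes universe (Fisher + BH per direction), and
#' returns a volcano-style table with category labels.
#'
#' @param de DE table (`gene_id`, `log2fc`, `p`, optional `expressed`).
#' @param states data.frame from [assign_chromatin_state()].
#' @param gene_status `gene_id`/`refbs_status` table.
#' @param config list from [default_run_config()].
#' @return report list: `config`, `inputs`, `volcano`, `enrichment`
#'   (one row per category x direction with p and q), `notes`.
#' @export
run_de_overlay <- function(de, states, gene_status,
                           config = default_run_config()) {
  stage_required(de, "differential-expression table")
  stage_required(states, "chromatin states")
  stage_required(gene_status, "REF6-BS methylation status")
  need <- c("gene_id", "log2fc", "p")
  missing_cols <- setdiff(need, names(de))
  if (length(missing_cols) > 0L) {
    stop("malformed DE table: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  }
  bad <- which(is.na(de$gene_id) | is.na(de$log2fc) | is.na(de$p) |
                 de$p < 0 | de$p > 1)
  if (length(bad) > 0L) {
    stop("malformed DE table at row ", bad[1L])
  }
  report <- list(config = config,
                 inputs = list(n_de_rows = nrow(de)),
                 notes = character())
  if (nrow(de) == 0L) {
    warning("empty DE table; empty report")
    report$volcano <- data.frame()
    report$enrichment <- data.frame()
    return(report)
  }
  expressed <- if ("expressed" %in% names(de)) de$expressed else TRUE
  de$class <- classify_change(de$log2fc, de$p, expressed,
                              fc_cut = config$log2fc_cut,
                              alpha = config$alpha)
  meta <- data.frame(
    gene_id = de$gene_id,
    state = as.character(states$state[match(de$gene_id,
                                            states$gene_id)]),
    refbs_status = gene_status$refbs_status[
      match(de$gene_id, gene_status$gene_id)],
    stringsAsFactors = FALSE
  )
  meta$category <- ifelse(
    is.na(meta$state) | is.na(meta$refbs_status), NA_character_,
    paste(meta$state, meta$refbs_status, sep = ":"))
  universe <- de$gene_id
  up_genes <- de$gene_id[de$class == "up"]
  down_genes <- de$gene_id[de$class == "down"]
  cats <- sort(unique(meta$category[!is.na(meta$category) &
                                      meta$refbs_status %in%
                                      c("methylated", "unmethylated")]))
  rows <- list()
  for (direction in c("up", "down")) {
    dir_genes <- if (direction == "up") up_genes else down_genes
    for (cat in cats) {
      cat_genes <- meta$gene_id[!is.na(meta$category) &
                                  meta$category == cat]
      if (length(cat_genes) == 0L) {
        report$notes <- c(report$notes,
                          paste0("category ", cat,
                                 " has zero members; excluded"))
        next
      }
      fr <- fisher_overlap(cat_genes, dir_genes, universe)
      rows[[length(rows) + 1L]] <- data.frame(
        direction = direction, category = cat,
        n_category = length(cat_genes),
        n_direction = length(dir_genes),
        n_overlap = unname(fr$table["a"]),
        odds_ratio = fr$odds_ratio, p = fr$p,
        stringsAsFactors = FALSE
      )
    }
  }
  enr <- do.call(rbind, rows)
  if (!is.null(enr)) {
    enr$q <- NA_real_
    for (direction in c("up", "down")) {
      sel <- enr$direction == direction
      enr$q[sel] <- bh_adjust(enr$p[sel])
    }
  } else {
    enr <- data.frame()
  }
  report$volcano <- data.frame(
    gene_id = de$gene_id, log2fc = de$log2fc, p = de$p,
    class = de$class, category = meta$category,
    stringsAsFactors = FALSE
  )
  report$enrichment <- enr
  report
}

#' Write a report's tables and manifest to a directory
#'
#' Data-frame elements become TSVs; the resolved configuration, input
#' dimensions and notes go into a JSON manifest.
#'
#' @param report a report list from one of the `run_*` functions.
#' @param dir output directory.
#' @return invisibly, the manifest path.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  flat <- function(x, prefix) {
    for (nm in names(x)) {
      el <- x[[nm]]
      name <- if (nzchar(prefix)) paste(prefix, nm, sep = "_") else nm
      if (is.data.frame(el)) {
        utils::write.table(el, file.path(dir, paste0(name, ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      } else if (is.list(el) && !is.null(names(el)) &&
                 !nm %in% c("config", "inputs")) {
        flat(el, name)
      }
    }
  }
  flat(report, "")
  manifest <- list(config = report$config, inputs = report$inputs,
                   notes = report$notes)
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
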