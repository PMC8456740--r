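# Synthetic study generator with planted ground truth.
#
# The generator emulates the shapes of the study's inputs: a small genome
# with genes carrying planted CTCTGYTY sites, replicate bisulfite
# methylomes whose CHG methylation at site positions depends on the
# gene's chromatin state, allele-resolved expression counts around the
# 2 maternal : 1 paternal endosperm baseline with state-dependent bias,
# and a germination time course with state-dependent late activation.
# Every stage is deterministic under (config, seed).

#' Default synthetic-study configuration
#'
#' Group sizes default to 300/300/300/600
#' (K27_only/K9_only/K27_K9/unmarked).  Per-position CHG methylation
#' probabilities at planted REF6-binding sites are per-site Bernoulli
#' probabilities that the cytosine is methylated (position 5: 0.7 in
#' K27_K9 and 0.5 in K9_only versus 0.05 in K27_only/unmarked, mirroring
#' the strong position-5 contrast between the double-marked and
#' single-H3K27me3 groups).  Methylated site cytosines read at level 0.8,
#' unmethylated ones at a non-conversion-like 0.005.  Background per-read
#' levels are CG 0.20, CHG 0.02, CHH 0.02, with gene-body CHG raised to
#' 0.10 in H3K9me2-containing states (the CHG/H3K9me2 feedback loop).
#' Maternal fractions: 2/3 neutral; 0.2 for K27_K9 genes with methylated
#' sites (both conditions); 0.85 for K27_only genes with unmethylated
#' sites in dormant seeds.  K27_only genes gain a +3 log2 activation at
#' late time points.
#'
#' @param n_per_state named integer vector of genes per chromatin state.
#' @param n_refbs_per_gene planted REF6-binding sites per gene.
#' @param gene_length,intergenic_length layout in bp.
#' @param p_chgm named list per state: probabilities for positions 3, 5, 8.
#' @param p_chgm_other probability for CHG-capable positions of
#'   non-default motifs (unused for CTCTGYTY).
#' @param methylated_site_level,unmethylated_site_level per-read
#'   methylation levels of methylated/unmethylated site cytosines.
#' @param background_levels per-read levels by context outside sites.
#' @param body_chg_k9 gene-body CHG level in H3K9me2-containing states.
#' @param neutral_maternal_fraction baseline maternal fraction (2/3).
#' @param mf_k27k9_methylated maternal fraction of K27_K9 genes with
#'   methylated sites.
#' @param mf_k27only_unmeth_dormant maternal fraction of K27_only genes
#'   with unmethylated sites in the dormant condition.
#' @param activation_log2fc late-time-point activation of K27_only genes.
#' @param timepoints hours of imbibition sampled by the time course.
#' @param activation_from earliest activated time point (hours).
#' @param depth_methylome,depth_allelic mean read depths.
#' @param n_replicates methylome replicates.
#' @param noise_sd log-normal replicate noise (sdlog) of the time course.
#' @return a config list.
#' @export
synthetic_config <- function(
    n_per_state = c(K27_only = 300L, K9_only = 300L, K27_K9 = 300L,
                    unmarked = 600L),
    n_refbs_per_gene = 2L,
    gene_length = 500L,
    intergenic_length = 200L,
    p_chgm = list(
      K27_only = c(pos3 = 0.05, pos5 = 0.05, pos8 = 0.05),
      K9_only = c(pos3 = 0.30, pos5 = 0.50, pos8 = 0.10),
      K27_K9 = c(pos3 = 0.30, pos5 = 0.70, pos8 = 0.10),
      unmarked = c(pos3 = 0.05, pos5 = 0.05, pos8 = 0.05)
    ),
    p_chgm_other = 0.05,
    methylated_site_level = 0.8,
    unmethylated_site_level = 0.005,
    background_levels = c(CG = 0.20, CHG = 0.02, CHH = 0.02),
    body_chg_k9 = 0.10,
    neutral_maternal_fraction = 2 / 3,
    mf_k27k9_methylated = 0.2,
    mf_k27only_unmeth_dormant = 0.85,
    activation_log2fc = 3,
    timepoints = c(1, 8, 16, 24, 32, 38),
    activation_from = 32,
    depth_methylome = 20,
    depth_allelic = 50,
    n_replicates = 2L,
    noise_sd = 0.2) {
  stopifnot(all(names(n_per_state) %in% .STATES),
            n_refbs_per_gene >= 0L, gene_length > 0L,
            intergenic_length >= 0L)
  as.list(environment())
}

#' Gene-level planted truth from a configuration
#'
#' @param config list from [synthetic_config()].
#' @return data.frame with one row per gene: `gene_id`, `state`,
#'   `n_planted_refbs`, `p_chgm_pos3/5/8`, `activation_log2fc`.
#' @export
synthetic_truth <- function(config = synthetic_config()) {
  states <- rep(names(config$n_per_state), config$n_per_state)
  n <- length(states)
  if (n == 0L) {
    return(data.frame(gene_id = character(), state = character(),
                      n_planted_refbs = integer(),
                      p_chgm_pos3 = numeric(), p_chgm_pos5 = numeric(),
                      p_chgm_pos8 = numeric(),
                      activation_log2fc = numeric(),
                      stringsAsFactors = FALSE))
  }
  p3 <- vapply(states, function(s) config$p_chgm[[s]][["pos3"]], numeric(1))
  p5 <- vapply(states, function(s) config$p_chgm[[s]][["pos5"]], numeric(1))
  p8 <- vapply(states, function(s) config$p_chgm[[s]][["pos8"]], numeric(1))
  data.frame(
    gene_id = sprintf("g%04d", seq_len(n)),
    state = states,
    n_planted_refbs = config$n_refbs_per_gene,
    p_chgm_pos3 = unname(p3), p_chgm_pos5 = unname(p5),
    p_chgm_pos8 = unname(p8),
    activation_log2fc = ifelse(states == "K27_only",
                               config$activation_log2fc, 0),
    stringsAsFactors = FALSE
  )
}

#' Simulate a genome with planted REF6-binding sites
#'
#' Random background sequence with genes laid head-to-tail (random
#' strand), separated by intergenic spacers; each gene body receives its
#' truth-specified number of non-overlapping concrete CTCTGYTY
#' realisations on random strands.  After assembly the whole genome is
#' re-scanned, so accidental motif occurrences are detected and included
#' in the returned registry (flagged `planted = FALSE`).
#'
#' @param truth gene-level truth from [synthetic_truth()].
#' @param gene_length,intergenic_length layout in bp (gene_length >= 8).
#' @param motif planted motif (default `"CTCTGYTY"`).
#' @param chrom_name chromosome name.
#' @param seed RNG seed.
#' @return list `genome` (DNAStringSet), `genes` (data.frame), `registry`
#'   (all motif occurrences genome-wide, with `gene_id` NA outside genes
#'   and a `planted` flag).
#' @export
simulate_genome <- function(truth, gene_length = 500L,
                            intergenic_length = 200L,
                            motif = "CTCTGYTY", chrom_name = "chr1",
                            seed = 1L) {
  if (gene_length < 8L) stop("gene_length must be >= 8")
  validate_iupac(motif)
  w <- nchar(motif)
  n <- nrow(truth)
  withr::local_seed(seed)
  total_len <- intergenic_length + n * (gene_length + intergenic_length)
  total_len <- max(total_len, intergenic_length, 1L)
  seq_chars <- sample(c("A", "C", "G", "T"), total_len, replace = TRUE)
  genes <- data.frame(gene_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), tss = integer(0),
                      stringsAsFactors = FALSE)
  planted <- data.frame(start = integer(0))
  if (n > 0L) {
    starts <- intergenic_length +
      (seq_len(n) - 1L) * (gene_length + intergenic_length) + 1L
    genes <- data.frame(
      gene_id = truth$gene_id,
      chrom = chrom_name,
      start = starts,
      end = starts + gene_length - 1L,
      strand = sample(c("+", "-"), n, replace = TRUE),
      stringsAsFactors = FALSE
    )
    genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end)
    sets <- lapply(validate_iupac(motif), iupac_set)
    planted_starts <- integer(0)
    for (i in seq_len(n)) {
      k <- truth$n_planted_refbs[i]
      if (k == 0L) next
      chosen <- integer(0)
      candidates <- seq(genes$start[i], genes$end[i] - w + 1L)
      for (tries in seq_len(1000L)) {
        if (length(chosen) == k || length(candidates) == 0L) break
        pos <- sample(candidates, 1L)
        if (all(abs(pos - chosen) >= w)) chosen <- c(chosen, pos)
      }
      if (length(chosen) < k) {
        stop("could not place ", k, " non-overlapping sites in gene ",
             genes$gene_id[i])
      }
      for (pos in chosen) {
        realization <- vapply(sets, function(s) {
          if (length(s) == 1L) s else sample(s, 1L)
        }, character(1))
        if (sample(c(TRUE, FALSE), 1L)) {
          realization <- rev(.complement[realization])
        }
        seq_chars[pos:(pos + w - 1L)] <- realization
      }
      planted_starts <- c(planted_starts, chosen)
    }
    planted <- data.frame(start = sort(planted_starts))
  }
  genome <- Biostrings::DNAStringSet(paste(seq_chars, collapse = ""))
  names(genome) <- chrom_name
  registry <- scan_motif(genome, genes = NULL, motif = motif)
  if (nrow(registry) > 0L && nrow(genes) > 0L) {
    hits <- GenomicRanges::findOverlaps(
      intervals_to_granges(registry[c("chrom", "start", "end")]),
      intervals_to_granges(genes[c("chrom", "start", "end")]),
      type = "within", ignore.strand = TRUE
    )
    registry$gene_id[S4Vectors::queryHits(hits)] <-
      genes$gene_id[S4Vectors::subjectHits(hits)]
  }
  registry$planted <- registry$start %in% planted$start
  list(genome = genome, genes = genes, registry = registry)
}

#' Enumerate all cytosines of a genome with their contexts
#'
#' Both strands; cytosines whose context is undetermined (chromosome
#' edges) are omitted.
#'
#' @param genome a [Biostrings::DNAStringSet].
#' @return data.table `chrom`, `pos`, `strand`, `context`.
#' @export
cytosine_table <- function(genome) {
  res <- list()
  for (ch in names(genome)) {
    chars <- strsplit(as.character(genome[[ch]]), "")[[1]]
    L <- length(chars)
    ctx_of <- function(b1, b2) {
      ifelse(is.na(b1) | b1 == "N", NA_character_,
             ifelse(b1 == "G", "CG",
                    ifelse(is.na(b2) | b2 == "N", NA_character_,
                           ifelse(b2 == "G", "CHG", "CHH"))))
    }
    # plus strand
    ip <- which(chars == "C")
    if (length(ip) > 0L) {
      b1 <- ifelse(ip + 1L <= L, chars[pmin(ip + 1L, L)], NA_character_)
      b2 <- ifelse(ip + 2L <= L, chars[pmin(ip + 2L, L)], NA_character_)
      ctx <- ctx_of(b1, b2)
      keep <- !is.na(ctx)
      res[[length(res) + 1L]] <- data.table::data.table(
        chrom = ch, pos = ip[keep], strand = "+", context = ctx[keep])
    }
    # minus strand: C where the plus strand has G; neighbours at pos-1/-2
    im <- which(chars == "G")
    if (length(im) > 0L) {
      b1 <- ifelse(im - 1L >= 1L, .complement[chars[pmax(im - 1L, 1L)]],
                   NA_character_)
      b2 <- ifelse(im - 2L >= 1L, .complement[chars[pmax(im - 2L, 1L)]],
                   NA_character_)
      ctx <- ctx_of(b1, b2)
      keep <- !is.na(ctx)
      res[[length(res) + 1L]] <- data.table::data.table(
        chrom = ch, pos = im[keep], strand = "-", context = ctx[keep])
    }
  }
  if (length(res) == 0L) {
    return(data.table::data.table(chrom = character(), pos = integer(),
                                  strand = character(),
                                  context = character()))
  }
  out <- data.table::rbindlist(res)
  data.table::setorderv(out, c("chrom", "pos", "strand"))
  out[]
}

#' Draw the planted methylation state of site cytosines
#'
#' For every CHG-context cytosine of every in-gene registry site, draws a
#' Bernoulli methylation state using the gene's per-position truth
#' probability (positions 3/5/8 of CTCTGYTY; other positions use
#' `config$p_chgm_other`).
#'
#' @param annotations site-position annotations
#'   ([annotate_site_positions()]) of the in-gene registry sites.
#' @param truth gene-level truth.
#' @param config configuration list.
#' @param seed RNG seed.
#' @return data.frame of the CHG annotation rows plus `p_methylated` and
#'   `is_methylated`.
#' @export
simulate_site_states <- function(annotations, truth,
                                 config = synthetic_config(), seed = 1L) {
  chg <- annotations[annotations$context == "CHG" &
                       !is.na(annotations$gene_id), , drop = FALSE]
  if (nrow(chg) == 0L) {
    chg$p_methylated <- numeric(0)
    chg$is_methylated <- logical(0)
    return(chg)
  }
  idx <- match(chg$gene_id, truth$gene_id)
  p <- rep(config$p_chgm_other, nrow(chg))
  p[chg$motif_position == 3L] <- truth$p_chgm_pos3[idx][chg$motif_position == 3L]
  p[chg$motif_position == 5L] <- truth$p_chgm_pos5[idx][chg$motif_position == 5L]
  p[chg$motif_position == 8L] <- truth$p_chgm_pos8[idx][chg$motif_position == 8L]
  withr::local_seed(seed)
  chg$p_methylated <- p
  chg$is_methylated <- stats::runif(nrow(chg)) < p
  rownames(chg) <- NULL
  chg
}

#' Simulate replicate bisulfite methylomes
#'
#' Per-cytosine coverage is Poisson(`depth_mean`) per replicate and
#' methylated reads are Binomial(coverage, level).  The per-read level is
#' the background context level everywhere except: CHG cytosines inside
#' gene bodies of H3K9me2-containing states read at `body_chg_k9`, and
#' planted site CHG cytosines read at `methylated_site_level` or
#' `unmethylated_site_level` according to their drawn state.
#'
#' @param truth gene-level truth.
#' @param genome a [Biostrings::DNAStringSet].
#' @param genes gene data.frame.
#' @param site_states data.frame from [simulate_site_states()].
#' @param config configuration list.
#' @param depth_mean mean coverage per replicate (default from config).
#' @param n_replicates number of replicates (default from config).
#' @param seed RNG seed.
#' @param sample_id,allele labels stamped on the records.
#' @return data.table of methylome records (zero-coverage draws omitted).
#' @export
simulate_methylome <- function(truth, genome, genes, site_states,
                               config = synthetic_config(),
                               depth_mean = config$depth_methylome,
                               n_replicates = config$n_replicates,
                               seed = 1L, sample_id = "wt",
                               allele = "unphased") {
  stopifnot(depth_mean > 0)
  cyt <- cytosine_table(genome)
  lambda <- unname(config$background_levels[cyt$context])
  # gene-body CHG in H3K9me2-containing states
  if (nrow(genes) > 0L) {
    k9_states <- c("K9_only", "K27_K9")
    k9_genes <- genes[genes$gene_id %in%
                        truth$gene_id[truth$state %in% k9_states], ,
                      drop = FALSE]
    if (nrow(k9_genes) > 0L) {
      cgr <- GenomicRanges::GRanges(cyt$chrom,
                                    IRanges::IRanges(cyt$pos, cyt$pos))
      hits <- GenomicRanges::findOverlaps(
        cgr, intervals_to_granges(k9_genes[c("chrom", "start", "end")]),
        ignore.strand = TRUE)
      sel <- unique(S4Vectors::queryHits(hits))
      sel <- sel[cyt$context[sel] == "CHG"]
      lambda[sel] <- config$body_chg_k9
    }
  }
  # planted site cytosines
  if (nrow(site_states) > 0L) {
    key_cyt <- paste(cyt$chrom, cyt$pos, cyt$strand)
    key_site <- paste(site_states$chrom, site_states$genomic_coord,
                      site_states$cytosine_strand)
    m <- match(key_cyt, key_site)
    hit <- !is.na(m)
    lambda[hit] <- ifelse(site_states$is_methylated[m[hit]],
                          config$methylated_site_level,
                          config$unmethylated_site_level)
  }
  withr::local_seed(seed)
  reps <- list()
  for (r in seq_len(n_replicates)) {
    cov <- stats::rpois(nrow(cyt), depth_mean)
    m <- stats::rbinom(nrow(cyt), cov, lambda)
    keep <- cov > 0L
    reps[[r]] <- data.table::data.table(
      chrom = cyt$chrom[keep], pos = cyt$pos[keep],
      strand = cyt$strand[keep], context = cyt$context[keep],
      count_methylated = m[keep], count_total = cov[keep],
      sample_id = sample_id, replicate = r, allele = allele
    )
  }
  data.table::rbindlist(reps)[]
}

#' Simulate allele-resolved expression counts
#'
#' Per gene and condition: total reads are Poisson(`depth_mean`) and
#' maternal reads Binomial(total, maternal fraction).  The truth must
#' carry `maternal_fraction_dormant` / `maternal_fraction_non_dormant`
#' columns (as added by [simulate_study()]); genes without them use the
#' neutral 2/3.
#'
#' @param truth gene-level truth.
#' @param depth_mean mean total reads per gene (default 50).
#' @param conditions condition labels.
#' @param seed RNG seed.
#' @param neutral fallback maternal fraction (default 2/3).
#' @return data.frame `gene_id`, `maternal_reads`, `paternal_reads`,
#'   `condition`, `ratio`.
#' @export
simulate_allelic_counts <- function(truth, depth_mean = 50,
                                    conditions = c("dormant",
                                                   "non_dormant"),
                                    seed = 1L, neutral = 2 / 3) {
  stopifnot(depth_mean > 0)
  withr::local_seed(seed)
  out <- list()
  for (cond in conditions) {
    col <- paste0("maternal_fraction_", cond)
    frac <- if (col %in% names(truth)) truth[[col]] else
      rep(neutral, nrow(truth))
    frac[is.na(frac)] <- neutral
    total <- stats::rpois(nrow(truth), depth_mean)
    m <- stats::rbinom(nrow(truth), total, frac)
    out[[cond]] <- data.frame(
      gene_id = truth$gene_id, maternal_reads = m,
      paternal_reads = total - m, condition = cond,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, out)
  out$ratio <- maternal_ratio(out$maternal_reads, out$paternal_reads)
  rownames(out) <- NULL
  out
}

#' Simulate a germination expression time course
#'
#' Log-normal per-gene baseline; genes with a non-zero planted
#' `activation_log2fc` are multiplied by `2^activation_log2fc` at time
#' points at or after `activation_from` (around endosperm rupture);
#' multiplicative log-normal replicate noise.
#'
#' @param truth gene-level truth.
#' @param timepoints hours of imbibition (>= 2).
#' @param n_replicates replicates per time point.
#' @param activation_from earliest activated time point.
#' @param noise_sd sdlog of the replicate noise.
#' @param seed RNG seed.
#' @return list `matrix` (genes x samples, RPKM-scale) and `sample_info`
#'   (`sample`, `timepoint`, `replicate`).
#' @export
simulate_timecourse <- function(truth, timepoints = c(1, 8, 16, 24, 32, 38),
                                n_replicates = 3L, activation_from = 32,
                                noise_sd = 0.2, seed = 1L) {
  if (length(timepoints) < 2L) stop("need >= 2 timepoints")
  withr::local_seed(seed)
  n <- nrow(truth)
  baseline <- stats::rlnorm(n, meanlog = log(10), sdlog = 1)
  info <- expand.grid(replicate = seq_len(n_replicates),
                      timepoint = timepoints)
  info$sample <- sprintf("t%g_r%d", info$timepoint, info$replicate)
  mat <- matrix(0, nrow = n, ncol = nrow(info),
                dimnames = list(truth$gene_id, info$sample))
  for (j in seq_len(nrow(info))) {
    fc <- if (info$timepoint[j] >= activation_from) {
      2^truth$activation_log2fc
    } else {
      rep(1, n)
    }
    mat[, j] <- baseline * fc * stats::rlnorm(n, 0, noise_sd)
  }
  list(matrix = mat,
       sample_info = info[, c("sample", "timepoint", "replicate")])
}

#' Fabricate a differential-expression table with planted classes
#'
#' Plants `down` classifications with probability `p_down_in` inside the
#' gene set `down_genes` and `p_down_out` elsewhere, and `up` with
#' probability `p_up` everywhere; remaining genes are stable.  Down/up
#' genes get log2 fold changes around -2/+2 with small p-values.  Clearly
#' a fixture generator, not a differential-expression method.
#'
#' @param truth gene-level truth.
#' @param down_genes gene ids targeted for downregulation.
#' @param p_down_in,p_down_out,p_up planting probabilities.
#' @param seed RNG seed.
#' @return data.frame `gene_id`, `log2fc`, `p`, `expressed`.
#' @export
simulate_de_table <- function(truth, down_genes, p_down_in = 0.6,
                              p_down_out = 0.05, p_up = 0.05, seed = 1L) {
  withr::local_seed(seed)
  n <- nrow(truth)
  in_set <- truth$gene_id %in% down_genes
  p_down <- ifelse(in_set, p_down_in, p_down_out)
  u <- stats::runif(n)
  is_down <- u < p_down
  is_up <- !is_down & (u < p_down + p_up)
  log2fc <- stats::rnorm(n, 0, 0.3)
  log2fc[is_down] <- stats::rnorm(sum(is_down), -2, 0.3)
  log2fc[is_up] <- stats::rnorm(sum(is_up), 2, 0.3)
  log2fc[is_down & log2fc > -1.2] <- -1.2
  log2fc[is_up & log2fc < 1.2] <- 1.2
  p <- stats::runif(n, 0.2, 1)
  p[is_down | is_up] <- stats::runif(sum(is_down | is_up), 0, 0.01)
  data.frame(gene_id = truth$gene_id, log2fc = log2fc, p = p,
             expressed = TRUE, stringsAsFactors = FALSE)
}

#' Chromatin-mark domains implied by the planted truth
#'
#' One maternal-allele domain per marked gene covering the gene body.
#'
#' @param genes gene data.frame.
#' @param truth gene-level truth.
#' @return domain data.frame (`chrom`, `start`, `end`, `mark`, `allele`).
#' @export
synthetic_domains <- function(genes, truth) {
  idx <- match(genes$gene_id, truth$gene_id)
  state <- truth$state[idx]
  rows <- list()
  for (mark in .MARKS) {
    need <- if (mark == "H3K27me3") c("K27_only", "K27_K9") else
      c("K9_only", "K27_K9")
    sel <- state %in% need
    if (any(sel)) {
      rows[[mark]] <- data.frame(
        chrom = genes$chrom[sel], start = genes$start[sel],
        end = genes$end[sel], mark = mark, allele = "maternal",
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), mark = character(),
                      allele = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate a full synthetic study
#'
#' Orchestrates genome, site states, domains, methylome, allele-resolved
#' counts and time course, and completes the truth with realised
#' site-methylation flags and maternal fractions: 2/3 everywhere except
#' K27_K9 genes with methylated sites (`mf_k27k9_methylated`, both
#' conditions) and K27_only genes with unmethylated sites in the dormant
#' condition (`mf_k27only_unmeth_dormant`).
#'
#' @param config configuration from [synthetic_config()].
#' @param seed master seed; stage seeds are derived as small offsets.
#' @return list `config`, `seed`, `truth`, `genome`, `genes`, `registry`,
#'   `domains`, `site_states`, `methylome`, `allelic`, `timecourse`
#'   (list of `matrix` + `sample_info`).
#' @export
simulate_study <- function(config = synthetic_config(), seed = 1L) {
  truth <- synthetic_truth(config)
  gen <- simulate_genome(truth, gene_length = config$gene_length,
                         intergenic_length = config$intergenic_length,
                         seed = seed)
  ann <- annotate_site_positions(
    gen$registry[!is.na(gen$registry$gene_id), , drop = FALSE],
    gen$genome)
  site_states <- simulate_site_states(ann, truth, config, seed = seed + 1L)
  meth_by_gene <- tapply(site_states$is_methylated, site_states$gene_id,
                         any)
  truth$refbs_methylated <- FALSE
  truth$refbs_methylated[match(names(meth_by_gene), truth$gene_id)] <-
    as.logical(meth_by_gene)
  nf <- config$neutral_maternal_fraction
  truth$maternal_fraction_dormant <- nf
  truth$maternal_fraction_non_dormant <- nf
  biased_pat <- truth$state == "K27_K9" & truth$refbs_methylated
  truth$maternal_fraction_dormant[biased_pat] <- config$mf_k27k9_methylated
  truth$maternal_fraction_non_dormant[biased_pat] <-
    config$mf_k27k9_methylated
  biased_mat <- truth$state == "K27_only" & !truth$refbs_methylated
  truth$maternal_fraction_dormant[biased_mat] <-
    config$mf_k27only_unmeth_dormant
  domains <- synthetic_domains(gen$genes, truth)
  methylome <- simulate_methylome(truth, gen$genome, gen$genes,
                                  site_states, config,
                                  seed = seed + 2L)
  allelic <- simulate_allelic_counts(truth,
                                     depth_mean = config$depth_allelic,
                                     seed = seed + 3L,
                                     neutral = nf)
  timecourse <- simulate_timecourse(truth,
                                    timepoints = config$timepoints,
                                    activation_from =
                                      config$activation_from,
                                    noise_sd = config$noise_sd,
                                    seed = seed + 4L)
  list(config = config, seed = seed, truth = truth, genome = gen$genome,
       genes = gen$genes, registry = gen$registry, domains = domains,
       site_states = site_states, methylome = methylome,
       allelic = allelic, timecourse = timecourse)
}

#' Write a synthetic study to disk
#'
#' Emits FASTA (genome), GFF3 (genes), BED per mark (maternal domains),
#' CX-style TSV (methylome), TSVs (allelic counts, expression matrix) and
#' a truth JSON.
#'
#' @param study list from [simulate_study()].
#' @param dir output directory (created if needed).
#' @return named vector of written paths, invisibly.
#' @export
write_synthetic_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    fasta = file.path(dir, "genome.fa"),
    gff = file.path(dir, "genes.gff3"),
    bed_k27 = file.path(dir, "domains_H3K27me3_maternal.bed"),
    bed_k9 = file.path(dir, "domains_H3K9me2_maternal.bed"),
    cx = file.path(dir, "methylome.cx.tsv"),
    allelic = file.path(dir, "allelic_counts.tsv"),
    expression = file.path(dir, "expression.tsv"),
    truth = file.path(dir, "truth.json")
  )
  write_genome_fasta(study$genome, paths[["fasta"]])
  write_gff3_genes(study$genes, paths[["gff"]])
  for (mark in .MARKS) {
    d <- study$domains[study$domains$mark == mark, , drop = FALSE]
    key <- if (mark == "H3K27me3") "bed_k27" else "bed_k9"
    write_bed_intervals(d, paths[[key]])
  }
  write_cx_report(study$methylome, paths[["cx"]])
  utils::write.table(study$allelic[c("gene_id", "maternal_reads",
                                     "paternal_reads", "condition")],
                     paths[["allelic"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  expr <- data.frame(gene_id = rownames(study$timecourse$matrix),
                     study$timecourse$matrix, check.names = FALSE)
  utils::write.table(expr, paths[["expression"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(seed = study$seed,
         truth = study$truth,
         site_states = study$site_states[
           , c("site_id", "gene_id", "motif_position", "genomic_coord",
               "cytosine_strand", "is_methylated")]),
    paths[["truth"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
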