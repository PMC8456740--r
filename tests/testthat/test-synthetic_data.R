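small_config <- function(...) {
  synthetic_config(
    n_per_state = c(K27_only = 12L, K9_only = 12L, K27_K9 = 12L,
                    unmarked = 24L), ...)
}

test_that("genome simulation is deterministic and registers every motif hit", {
  cfg <- small_config()
  truth <- synthetic_truth(cfg)
  g1 <- simulate_genome(truth, seed = 5L)
  g2 <- simulate_genome(truth, seed = 5L)
  expect_identical(as.character(g1$genome), as.character(g2$genome))
  expect_identical(g1$registry, g2$registry)
  g3 <- simulate_genome(truth, seed = 6L)
  expect_false(identical(as.character(g1$genome),
                         as.character(g3$genome)))

  # scan_motif over genes finds exactly the in-gene registry entries
  found <- scan_motif(g1$genome, g1$genes)
  reg <- g1$registry[!is.na(g1$registry$gene_id), ]
  cols <- c("gene_id", "chrom", "start", "end", "strand", "matched_seq")
  expect_equal(found[order(found$start, found$strand, found$gene_id), cols],
               reg[order(reg$start, reg$strand, reg$gene_id), cols],
               ignore_attr = TRUE)
  # at least the planted sites are present
  expect_gte(sum(g1$registry$planted), sum(truth$n_planted_refbs))
})

test_that("degenerate gene configurations are handled", {
  cfg0 <- synthetic_config(n_per_state = c(unmarked = 0L))
  t0 <- synthetic_truth(cfg0)
  g0 <- simulate_genome(t0, seed = 1L)
  expect_equal(nrow(g0$genes), 0L)
  expect_gt(unname(chrom_lengths(g0$genome)), 0L)
  expect_error(simulate_genome(synthetic_truth(small_config()),
                               gene_length = 7L), ">= 8")
})

test_that("degenerate methylation probabilities saturate the calls", {
  cfg <- small_config(p_chgm = list(
    K27_only = c(pos3 = 1, pos5 = 1, pos8 = 1),
    K9_only = c(pos3 = 1, pos5 = 1, pos8 = 1),
    K27_K9 = c(pos3 = 1, pos5 = 1, pos8 = 1),
    unmarked = c(pos3 = 1, pos5 = 1, pos8 = 1)),
    unmethylated_site_level = 0, background_levels = c(CG = 0, CHG = 0,
                                                       CHH = 0),
    body_chg_k9 = 0, depth_methylome = 30)
  truth <- synthetic_truth(cfg)
  gen <- simulate_genome(truth, seed = 2L)
  ann <- annotate_site_positions(
    gen$registry[!is.na(gen$registry$gene_id), ], gen$genome)
  ss <- simulate_site_states(ann, truth, cfg, seed = 3L)
  expect_true(all(ss$is_methylated))
  meth <- simulate_methylome(truth, gen$genome, gen$genes, ss, cfg,
                             seed = 4L)
  calls <- call_methylome(meth, "two_replicates")
  tab <- position_chgm_table(ann, calls)
  p5 <- tab[tab$motif_position == 5L, ]
  expect_gt(p5$n_determinate, 0L)
  expect_equal(p5$n_methylated, p5$n_determinate)

  # p = 0 everywhere: no methylated call anywhere
  cfg0 <- small_config(p_chgm = list(
    K27_only = c(pos3 = 0, pos5 = 0, pos8 = 0),
    K9_only = c(pos3 = 0, pos5 = 0, pos8 = 0),
    K27_K9 = c(pos3 = 0, pos5 = 0, pos8 = 0),
    unmarked = c(pos3 = 0, pos5 = 0, pos8 = 0)),
    p_chgm_other = 0,
    unmethylated_site_level = 0,
    background_levels = c(CG = 0, CHG = 0, CHH = 0), body_chg_k9 = 0)
  truth0 <- synthetic_truth(cfg0)
  gen0 <- simulate_genome(truth0, seed = 2L)
  ann0 <- annotate_site_positions(
    gen0$registry[!is.na(gen0$registry$gene_id), ], gen0$genome)
  ss0 <- simulate_site_states(ann0, truth0, cfg0, seed = 3L)
  meth0 <- simulate_methylome(truth0, gen0$genome, gen0$genes, ss0, cfg0,
                              seed = 4L)
  calls0 <- call_methylome(meth0, "two_replicates")
  expect_false(any(calls0$status == "methylated"))
})

test_that("methylome simulation is seed-deterministic", {
  cfg <- small_config()
  truth <- synthetic_truth(cfg)
  gen <- simulate_genome(truth, seed = 7L)
  ann <- annotate_site_positions(
    gen$registry[!is.na(gen$registry$gene_id), ], gen$genome)
  ss <- simulate_site_states(ann, truth, cfg, seed = 8L)
  m1 <- simulate_methylome(truth, gen$genome, gen$genes, ss, cfg, seed = 9L)
  m2 <- simulate_methylome(truth, gen$genome, gen$genes, ss, cfg, seed = 9L)
  expect_identical(m1, m2)
})

test_that("allelic counts honour planted fractions and determinism", {
  truth <- synthetic_truth(small_config())
  truth$maternal_fraction_dormant <- 1
  rec <- simulate_allelic_counts(truth, conditions = "dormant", seed = 1L)
  expect_true(all(rec$paternal_reads == 0L))
  rec2 <- simulate_allelic_counts(truth, conditions = "dormant", seed = 1L)
  expect_identical(rec, rec2)
})

test_that("the time course activates K27_only genes late and is deterministic", {
  cfg <- synthetic_config(
    n_per_state = c(K27_only = 100L, K9_only = 100L))
  truth <- synthetic_truth(cfg)
  tc <- simulate_timecourse(truth, seed = 3L)
  tc2 <- simulate_timecourse(truth, seed = 3L)
  expect_identical(tc$matrix, tc2$matrix)

  # collapse replicates to per-timepoint means
  info <- tc$sample_info
  tp_mat <- sapply(unique(info$timepoint), function(t)
    rowMeans(tc$matrix[, info$sample[info$timepoint == t], drop = FALSE]))
  colnames(tp_mat) <- as.character(unique(info$timepoint))
  rp <- relative_profile(tp_mat)
  k27 <- truth$state == "K27_only"
  res <- timepoint_shift_test(rp[k27, ], "1")
  expect_lt(res$p[res$timepoint == "38"], 1e-10)
  # the non-activated group is separated from the activated one by many
  # orders of magnitude (mean-scaling couples the compared columns, so
  # the across-gene rank-sum is mildly anticonservative under the null;
  # exact null calibration is not asserted)
  res9 <- timepoint_shift_test(rp[!k27, ], "1")
  expect_gt(res9$p[res9$timepoint == "38"], 1e-3)
  expect_gt(res9$p[res9$timepoint == "38"] /
              res$p[res$timepoint == "38"], 1e6)

  # null config: no activation anywhere
  cfg0 <- synthetic_config(n_per_state = c(K27_only = 100L),
                           activation_log2fc = 0)
  truth0 <- synthetic_truth(cfg0)
  tc0 <- simulate_timecourse(truth0, seed = 4L)
  tp0 <- sapply(unique(tc0$sample_info$timepoint), function(t)
    rowMeans(tc0$matrix[, tc0$sample_info$sample[
      tc0$sample_info$timepoint == t], drop = FALSE]))
  colnames(tp0) <- as.character(unique(tc0$sample_info$timepoint))
  res0 <- timepoint_shift_test(relative_profile(tp0), "1")
  # under the null the shift p-values are uniform; no systematic signal
  expect_lte(sum(res0$p <= 0.01), 1L)
  expect_gt(median(res0$p), 0.05)
})

test_that("a written study round-trips through every reader", {
  cfg <- small_config()
  st <- simulate_study(cfg, seed = 2L)
  dir <- withr::local_tempdir()
  paths <- write_synthetic_study(st, dir)

  genome <- read_genome_fasta(paths[["fasta"]])
  expect_equal(as.character(genome), as.character(st$genome))
  genes <- read_gff_genes(paths[["gff"]])
  expect_equal(genes[order(genes$gene_id), ],
               st$genes[order(st$genes$gene_id), ], ignore_attr = TRUE)
  d27 <- read_bed_domains(paths[["bed_k27"]], "H3K27me3", "maternal")
  d27_orig <- st$domains[st$domains$mark == "H3K27me3", ]
  expect_equal(d27[c("chrom", "start", "end")],
               d27_orig[c("chrom", "start", "end")], ignore_attr = TRUE)
  meth <- read_cx_report(paths[["cx"]])
  expect_equal(nrow(meth), nrow(st$methylome))
  expect_equal(sum(meth$count_methylated),
               sum(st$methylome$count_methylated))
  alle <- read_allelic_counts(paths[["allelic"]])
  expect_equal(alle[c("gene_id", "maternal_reads", "paternal_reads")],
               st$allelic[c("gene_id", "maternal_reads",
                            "paternal_reads")], ignore_attr = TRUE)
  truth_json <- jsonlite::read_json(paths[["truth"]])
  expect_equal(length(truth_json$truth), nrow(st$truth))
})

test_that("full study simulation is reproducible under the master seed", {
  cfg <- small_config()
  s1 <- simulate_study(cfg, seed = 3L)
  s2 <- simulate_study(cfg, seed = 3L)
  expect_identical(as.character(s1$genome), as.character(s2$genome))
  expect_identical(s1$methylome, s2$methylome)
  expect_identical(s1$allelic, s2$allelic)
  expect_identical(s1$timecourse$matrix, s2$timecourse$matrix)
  expect_identical(s1$truth, s2$truth)
})
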