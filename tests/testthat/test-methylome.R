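test_that("the two-replicate call rule matches its quoted definition", {
  r1 <- meth_rec("chr1", 10L, "+", "CHG", 1L, 5L)
  r2 <- meth_rec("chr1", 10L, "+", "CHG", 1L, 7L, replicate = 2L)
  expect_equal(call_site_two_replicates(r1, r2)$status, "methylated")

  r1 <- meth_rec("chr1", 10L, "+", "CHG", 4L, 4L)
  r2 <- meth_rec("chr1", 10L, "+", "CHG", 10L, 20L, replicate = 2L)
  expect_equal(call_site_two_replicates(r1, r2)$status, "undetermined")

  r1 <- meth_rec("chr1", 10L, "+", "CHG", 0L, 10L)
  r2 <- meth_rec("chr1", 10L, "+", "CHG", 0L, 12L, replicate = 2L)
  expect_equal(call_site_two_replicates(r1, r2)$status, "unmethylated")

  r2bad <- meth_rec("chr1", 11L, "+", "CHG", 1L, 9L, replicate = 2L)
  expect_error(call_site_two_replicates(r1, r2bad), "different positions")
})

test_that("the pooled call rule pools counts before thresholding", {
  recs <- rbind(meth_rec("chr1", 5L, "+", "CHG", 1L, 3L),
                meth_rec("chr1", 5L, "+", "CHG", 0L, 2L, replicate = 2L))
  expect_equal(call_site_pooled(recs)$status, "methylated")

  recs <- rbind(meth_rec("chr1", 5L, "+", "CHG", 1L, 2L),
                meth_rec("chr1", 5L, "+", "CHG", 1L, 1L, replicate = 2L))
  expect_equal(call_site_pooled(recs)$status, "undetermined")

  recs <- rbind(meth_rec("chr1", 5L, "+", "CHG", 0L, 4L),
                meth_rec("chr1", 5L, "+", "CHG", 0L, 4L, replicate = 2L))
  expect_equal(call_site_pooled(recs)$status, "unmethylated")
})

test_that("both rules agree exhaustively with their transcriptions up to 10 reads", {
  grid <- expand.grid(t1 = 0:10, t2 = 0:10)
  for (i in seq_len(nrow(grid))) {
    t1 <- grid$t1[i]; t2 <- grid$t2[i]
    for (m1 in 0:t1) for (m2 in 0:t2) {
      expect_equal(
        unname(call_two_rep_status(m1, t1, m2, t2)),
        oracle_call_two_rep(m1, t1, m2, t2),
        label = sprintf("two-rep m1=%d t1=%d m2=%d t2=%d", m1, t1, m2, t2))
      expect_equal(
        unname(call_pooled_status(m1 + m2, t1 + t2)),
        oracle_call_pooled(m1 + m2, t1 + t2),
        label = sprintf("pooled m=%d t=%d", m1 + m2, t1 + t2))
    }
  }
})

test_that("calls are monotone in added evidence and rules agree where both apply", {
  for (t1 in 5:10) for (m1 in 0:t1) for (t2 in 5:10) for (m2 in 0:t2) {
    s <- call_two_rep_status(m1, t1, m2, t2)
    # adding an unmethylated read never makes it methylated
    if (s == "unmethylated") {
      expect_equal(unname(call_two_rep_status(m1, t1 + 1L, m2, t2)),
                   "unmethylated")
    }
    # adding a methylated read never makes it unmethylated
    if (s == "methylated") {
      expect_equal(unname(call_two_rep_status(m1 + 1L, t1 + 1L, m2, t2)),
                   "methylated")
    }
    # both replicates covered with a methylated read each -> pooled agrees
    if (m1 >= 1L && m2 >= 1L) {
      expect_equal(s, unname(call_pooled_status(m1 + m2, t1 + t2)))
    }
  }
})

test_that("call_methylome treats a missing replicate as zero coverage", {
  meth <- rbind(
    meth_rec("chr1", 1L, "+", "CHG", 2L, 8L, replicate = 1L),
    meth_rec("chr1", 1L, "+", "CHG", 1L, 6L, replicate = 2L),
    meth_rec("chr1", 9L, "+", "CHG", 3L, 9L, replicate = 1L)  # rep2 absent
  )
  calls <- call_methylome(meth, rule = "two_replicates")
  expect_equal(calls$status[calls$pos == 1L], "methylated")
  expect_equal(calls$status[calls$pos == 9L], "undetermined")
  pooled <- call_methylome(meth, rule = "pooled")
  expect_equal(pooled$status[pooled$pos == 9L], "methylated")
})

test_that("site CHG status aggregates by the any-methylated rule", {
  w <- whole_gene_genome("CTCTGTTTAA")
  w$genes$end <- 8L
  s <- scan_motif(w$genome, w$genes)
  ann <- annotate_site_positions(s, w$genome)
  # CHG cytosines: pos 3 (chr1:3 +) and pos 5 (chr1:5 -)
  mk <- function(m3a, m3b, m5a, m5b) {
    rbind(meth_rec("chr1", 3L, "+", "CHG", m3a, 10L, 1L),
          meth_rec("chr1", 3L, "+", "CHG", m3b, 10L, 2L),
          meth_rec("chr1", 5L, "-", "CHG", m5a, 10L, 1L),
          meth_rec("chr1", 5L, "-", "CHG", m5b, 10L, 2L))
  }
  st <- refbs_chgm_status(ann, call_methylome(mk(1L, 2L, 0L, 0L)))
  expect_equal(st$status, "methylated")
  st <- refbs_chgm_status(ann, call_methylome(mk(0L, 0L, 0L, 0L)))
  expect_equal(st$status, "unmethylated")
  # all CHG cytosines below coverage -> undetermined
  low <- rbind(meth_rec("chr1", 3L, "+", "CHG", 1L, 2L, 1L),
               meth_rec("chr1", 3L, "+", "CHG", 1L, 3L, 2L))
  st <- refbs_chgm_status(ann, call_methylome(low))
  expect_equal(st$status, "undetermined")
})

test_that("the per-position table counts methylated over determinate sites", {
  w <- whole_gene_genome(paste(rep("CTCTGTTTAA", 10), collapse = ""))
  s <- scan_motif(w$genome, w$genes)
  expect_equal(nrow(s), 10L)
  ann <- annotate_site_positions(s, w$genome)
  # position-3 cytosines at genomic pos 3, 13, ..., methylated in first 4
  p3 <- ann[ann$motif_position == 3L, ]
  meth <- do.call(rbind, lapply(seq_len(10), function(i) {
    m <- if (i <= 4) 2L else 0L
    rbind(meth_rec("chr1", p3$genomic_coord[i], "+", "CHG", m, 10L, 1L),
          meth_rec("chr1", p3$genomic_coord[i], "+", "CHG", m, 10L, 2L))
  }))
  tab <- position_chgm_table(ann, call_methylome(meth))
  expect_equal(tab$n_methylated[tab$motif_position == 3], 4L)
  expect_equal(tab$n_determinate[tab$motif_position == 3], 10L)
  expect_equal(tab$fraction[tab$motif_position == 3], 0.4)
  # positions without CHG capability report zero denominators
  expect_equal(tab$n_determinate[tab$motif_position %in% c(1, 2, 4, 6, 7)],
               rep(0L, 5))
  # position 5 has CHG cytosines but no calls -> determinate 0
  expect_equal(tab$n_determinate[tab$motif_position == 5], 0L)

  empty <- position_chgm_table(ann[0, ], call_methylome(meth))
  expect_equal(sum(empty$n_methylated), 0L)
  expect_equal(sum(empty$n_determinate), 0L)
})

test_that("region methylation level is read-weighted with the 0.04 presence cut", {
  region <- data.frame(region_id = "r1", chrom = "chr1", start = 1L,
                       end = 100L)
  meth <- rbind(meth_rec("chr1", 10L, "+", "CHG", 1L, 10L),
                meth_rec("chr1", 20L, "+", "CHG", 0L, 10L))
  lv <- region_methylation_level(region, meth, "CHG")
  expect_equal(lv$level, 0.05)
  expect_equal(lv$covered_cytosines, 2L)
  expect_equal(lv$classification, "present")

  meth2 <- meth_rec("chr1", 10L, "+", "CHG", 1L, 25L)
  lv2 <- region_methylation_level(region, meth2, "CHG")
  expect_equal(lv2$level, 0.04)
  expect_equal(lv2$classification, "absent")  # boundary is absent

  lv3 <- region_methylation_level(region, meth[0, ], "CHG")
  expect_true(is.na(lv3$level))
  expect_equal(lv3$classification, "undefined")
})

test_that("levels combine read-weighted over region concatenation", {
  withr::local_seed(5)
  pos <- sort(sample.int(200L, 40L))
  meth <- meth_rec("chr1", pos, "+", "CHG",
                   m = rbinom(40L, 10L, 0.2), t = 10L)
  a <- region_methylation_level(data.frame(chrom = "chr1", start = 1L,
                                           end = 100L), meth, "CHG")
  b <- region_methylation_level(data.frame(chrom = "chr1", start = 101L,
                                           end = 200L), meth, "CHG")
  ab <- region_methylation_level(data.frame(chrom = "chr1", start = 1L,
                                            end = 200L), meth, "CHG")
  ta <- 10L * a$covered_cytosines
  tb <- 10L * b$covered_cytosines
  expect_equal(ab$level, (a$level * ta + b$level * tb) / (ta + tb))
})

test_that("flank profiles are uniform under uniform methylation and strand-oriented", {
  gene <- data.frame(gene_id = "g", chrom = "chr1", start = 3001L,
                     end = 4000L, strand = "+", tss = 3001L)
  pos <- seq(1L, 6000L, by = 10L)
  meth <- meth_rec("chr1", pos, "+", "CHG", m = 1L, t = 10L)
  prof <- flank_profile(gene, meth, "CHG", flank = 2000L, bins = 20L)
  expect_equal(nrow(prof), 60L)
  expect_true(all(abs(prof$level - 0.1) < 1e-12))

  # methylation only downstream of a minus-strand gene means upstream
  # bins are taken from higher coordinates
  gene_m <- transform(gene, strand = "-")
  meth_hi <- meth_rec("chr1", seq(4001L, 6000L, by = 10L), "+", "CHG",
                      m = 5L, t = 10L)
  prof_m <- flank_profile(gene_m, meth_hi, "CHG")
  up <- prof_m[prof_m$segment == "upstream", ]
  dn <- prof_m[prof_m$segment == "downstream", ]
  expect_true(all(up$level == 0.5, na.rm = TRUE))
  expect_true(all(up$covered_cytosines > 0))
  expect_true(all(dn$covered_cytosines == 0))

  # same records for a plus-strand gene land in the downstream segment
  prof_p <- flank_profile(gene, meth_hi, "CHG")
  expect_true(all(prof_p[prof_p$segment == "upstream",
                         "covered_cytosines"] == 0))
  expect_true(all(prof_p[prof_p$segment == "downstream", "level"] == 0.5,
                  na.rm = TRUE))
})

test_that("CX reports round-trip through the writer", {
  meth <- rbind(meth_rec("chr1", 3L, "+", "CHG", 2L, 9L, 1L),
                meth_rec("chr1", 3L, "+", "CHG", 0L, 7L, 2L),
                meth_rec("chr2", 11L, "-", "CG", 5L, 5L, 1L))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_cx_report(meth, path)
  back <- as.data.frame(read_cx_report(path))
  expect_equal(back[order(back$chrom, back$pos, back$replicate),
                    names(meth)],
               meth[order(meth$chrom, meth$pos, meth$replicate), ],
               ignore_attr = TRUE)
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines("a\tb", bad)
  expect_error(read_cx_report(bad), "lacks column")
})
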