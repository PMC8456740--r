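test_that("direct and reverse-complement motif instances are found", {
  w <- whole_gene_genome("CTCTGTTT")
  s <- scan_motif(w$genome, w$genes)
  expect_equal(nrow(s), 1L)
  expect_equal(s$strand, "+")
  expect_equal(c(s$start, s$end), c(1L, 8L))
  expect_equal(s$matched_seq, "CTCTGTTT")

  w2 <- whole_gene_genome("AAACAGAG")
  s2 <- scan_motif(w2$genome, w2$genes)
  expect_equal(nrow(s2), 1L)
  expect_equal(s2$strand, "-")
  expect_equal(c(s2$start, s2$end), c(1L, 8L))
  expect_equal(s2$matched_seq, "CTCTGTTT")
})

test_that("the Y positions reject non-pyrimidines and N never matches", {
  w <- whole_gene_genome("CTCTGATT")
  expect_equal(nrow(scan_motif(w$genome, w$genes)), 0L)
  wn <- whole_gene_genome("CTCTGNTT")
  expect_equal(nrow(scan_motif(wn$genome, wn$genes)), 0L)
})

test_that("sites must lie entirely within gene bodies; two genes give two records", {
  genome <- Biostrings::DNAStringSet(c(chr1 = "AACTCTGTTTAA"))
  genes <- data.frame(gene_id = c("g1", "g2", "g3"), chrom = "chr1",
                      start = c(1L, 3L, 5L), end = c(12L, 10L, 12L),
                      strand = "+", tss = c(1L, 3L, 5L),
                      stringsAsFactors = FALSE)
  s <- scan_motif(genome, genes)
  # site is [3,10]; inside g1 and g2 but not g3
  expect_setequal(s$gene_id, c("g1", "g2"))
  expect_equal(nrow(s), 2L)
})

test_that("non-IUPAC motifs are rejected", {
  w <- whole_gene_genome("CTCTGTTT")
  expect_error(scan_motif(w$genome, w$genes, motif = "CTCTGXTY"),
               "non-IUPAC")
})

test_that("scanner agrees with the regex oracle on random sequences", {
  withr::local_seed(7)
  for (i in 1:25) {
    seq_chr <- paste(sample(c("A", "C", "G", "T"), 10000, replace = TRUE),
                     collapse = "")
    w <- whole_gene_genome(seq_chr)
    got <- scan_motif(w$genome, w$genes)
    exp <- oracle_scan(seq_chr)
    expect_equal(nrow(got), nrow(exp))
    expect_equal(got$start, exp$start)
    expect_equal(got$strand, exp$strand)
    expect_equal(got$matched_seq, exp$matched_seq)
  }
})

test_that("scanning the reverse-complemented genome reflects coordinates", {
  withr::local_seed(11)
  seq_chr <- paste(sample(c("A", "C", "G", "T"), 50000, replace = TRUE),
                   collapse = "")
  L <- nchar(seq_chr)
  w <- whole_gene_genome(seq_chr)
  wrc <- whole_gene_genome(revcomp_chr(seq_chr))
  s <- scan_motif(w$genome, w$genes)
  src <- scan_motif(wrc$genome, wrc$genes)
  # reflect: start' = L - end + 1, strand flipped
  reflected <- data.frame(start = L - s$end + 1L,
                          strand = ifelse(s$strand == "+", "-", "+"),
                          matched_seq = s$matched_seq)
  reflected <- reflected[order(reflected$start, reflected$strand), ]
  expect_equal(src$start, reflected$start)
  expect_equal(src$strand, reflected$strand)
  expect_equal(src$matched_seq, reflected$matched_seq)
})

test_that("cytosine context follows the strand-aware definition", {
  g <- Biostrings::DNAStringSet(c(chr1 = "ACGT"))
  expect_equal(cytosine_context(g, "chr1", 2L, "+"), "CG")
  g2 <- Biostrings::DNAStringSet(c(chr1 = "ACTGA"))
  expect_equal(cytosine_context(g2, "chr1", 2L, "+"), "CHG")
  # C on the minus strand under a G: revcomp of TCAGA around pos 4 is CTG
  g3 <- Biostrings::DNAStringSet(c(chr1 = "TCAGA"))
  expect_equal(cytosine_context(g3, "chr1", 4L, "-"), "CHG")
  expect_error(cytosine_context(g, "chr1", 1L, "+"), "not C")
})

test_that("context is undetermined at edges and across N", {
  g <- Biostrings::DNAStringSet(c(chr1 = "AAC"))
  expect_equal(cytosine_context(g, "chr1", 3L, "+"), "undetermined")
  gn <- Biostrings::DNAStringSet(c(chr1 = "ACNG"))
  expect_equal(cytosine_context(gn, "chr1", 2L, "+"), "undetermined")
  # CG needs only one downstream base
  gcg <- Biostrings::DNAStringSet(c(chr1 = "ACG"))
  expect_equal(cytosine_context(gcg, "chr1", 2L, "+"), "CG")
})

test_that("site position annotation resolves cytosines on both strands", {
  w <- whole_gene_genome("CTCTGTTTAA")
  w$genes$end <- 8L
  s <- scan_motif(w$genome, w$genes)
  ann <- annotate_site_positions(s, w$genome)
  ctx <- setNames(ann$context, ann$motif_position)
  expect_equal(unname(ctx[c("1", "3", "5")]), c("CHH", "CHG", "CHG"))
  expect_equal(ann$cytosine_strand[ann$motif_position == 5], "-")
  expect_true(all(ann$context[ann$motif_position %in% c(2, 4, 6, 7, 8)] ==
                    "none"))
  # every annotated cytosine gets exactly one context value
  has_c <- !is.na(ann$cytosine_strand)
  expect_true(all(ann$context[has_c] %in%
                    c("CG", "CHG", "CHH", "undetermined")))
})

test_that("CTCTGCTC sites gain position 6/8 cytosines; ends are undetermined", {
  w <- whole_gene_genome("CTCTGCTCGA")
  w$genes$end <- 8L
  s <- scan_motif(w$genome, w$genes)
  ann <- annotate_site_positions(s, w$genome)
  expect_equal(ann$context[ann$motif_position == 6], "CHH")
  expect_equal(ann$context[ann$motif_position == 8], "CG")  # next base G

  # position 8 cytosine at the chromosome end -> undetermined
  w2 <- whole_gene_genome("CTCTGCTC")
  s2 <- scan_motif(w2$genome, w2$genes)
  ann2 <- annotate_site_positions(s2, w2$genome)
  expect_equal(ann2$context[ann2$motif_position == 8], "undetermined")
})

test_that("CHG-capable positions match the exhaustive enumeration", {
  expect_equal(chg_capable_positions("CTCTGYTY"), c(3L, 5L, 8L))
  expect_equal(chg_capable_positions("CG"), integer(0))
  # both cytosines of the CAG/CTG palindromic pair are CHG
  expect_equal(chg_capable_positions("CAG"), c(1L, 3L))
  expect_error(chg_capable_positions("CXG"), "non-IUPAC")

  for (motif in c("CTCTGYTY", "CG", "CAG", "CWG", "GYC", "CCGG", "NCG",
                  "CHG", "GGC")) {
    expect_equal(chg_capable_positions(motif), oracle_chg_capable(motif),
                 label = motif)
  }
})
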