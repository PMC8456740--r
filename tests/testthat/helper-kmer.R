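# Promoter fixture for k-mer overrepresentation tests: genes without
# planted REF6 sites and long intergenic spacers so promoters are mostly
# random sequence; optionally a hexamer inserted mid-promoter of selected
# genes, oriented with the gene.

KMER_FIXTURE_PROMOTER <- 300L

kmer_fixture <- function(n_genes = 30L, seed = 19L, plant = NULL,
                         plant_in = integer(0),
                         promoter_length = KMER_FIXTURE_PROMOTER) {
  cfg <- synthetic_config(
    n_per_state = c(unmarked = n_genes), n_refbs_per_gene = 0L,
    intergenic_length = 900L, gene_length = 200L)
  truth <- synthetic_truth(cfg)
  gen <- simulate_genome(truth, gene_length = 200L,
                         intergenic_length = 900L, seed = seed)
  if (!is.null(plant)) {
    chars <- strsplit(as.character(gen$genome[[1]]), "")[[1]]
    proms <- promoter_regions(gen$genes, gen$genome, promoter_length)
    for (i in plant_in) {
      mid <- as.integer((proms$start[i] + proms$end[i]) / 2)
      word <- if (gen$genes$strand[i] == "-") revcomp_chr(plant) else plant
      chars[mid:(mid + nchar(plant) - 1L)] <- strsplit(word, "")[[1]]
    }
    gen$genome <- Biostrings::DNAStringSet(paste(chars, collapse = ""))
    names(gen$genome) <- "chr1"
  }
  gen
}
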