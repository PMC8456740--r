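# Independent brute-force oracles used to validate the package's
# implementations.  These deliberately avoid the code paths they check.

ORACLE_COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

oracle_revcomp <- function(s) {
  paste(rev(ORACLE_COMP[strsplit(s, "")[[1]]]), collapse = "")
}

# all (possibly overlapping) occurrences of the REF6 motif on both strands
# of a plain character sequence, by regex with lookahead
oracle_scan <- function(seq_chr, pattern = "CTCTG[CT]T[CT]") {
  w <- 8L
  L <- nchar(seq_chr)
  find <- function(s) {
    m <- gregexpr(paste0("(?=", pattern, ")"), s, perl = TRUE)[[1]]
    if (m[1] == -1L) integer(0) else as.integer(m)
  }
  fwd <- find(seq_chr)
  rc <- oracle_revcomp(seq_chr)
  rev_rc <- find(rc)
  rev_start <- L - (rev_rc + w - 1L) + 1L
  out <- rbind(
    if (length(fwd)) data.frame(start = fwd, strand = "+",
                                matched_seq = substring(seq_chr, fwd,
                                                        fwd + w - 1L)),
    if (length(rev_start)) data.frame(
      start = rev_start, strand = "-",
      matched_seq = vapply(rev_start, function(p)
        oracle_revcomp(substring(seq_chr, p, p + w - 1L)), character(1)))
  )
  if (is.null(out)) {
    return(data.frame(start = integer(), strand = character(),
                      matched_seq = character()))
  }
  out$end <- out$start + w - 1L
  out[order(out$start, out$strand), c("start", "end", "strand",
                                      "matched_seq")]
}

# direct transcription of the methylation-call rules
oracle_call_two_rep <- function(m1, t1, m2, t2, min_cov = 5) {
  if (t1 < min_cov || t2 < min_cov) return("undetermined")
  if (m1 >= 1 && m2 >= 1) "methylated" else "unmethylated"
}

oracle_call_pooled <- function(m, t, min_cov = 5) {
  if (t < min_cov) return("undetermined")
  if (m >= 1) "methylated" else "unmethylated"
}

# two-sided Fisher p by hypergeometric tail summation (probability-mass
# criterion; the 1+1e-7 factor guards floating-point ties)
oracle_fisher <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0L, k - n); hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n, k)
  pobs <- stats::dhyper(a, m, n, k)
  min(1, sum(probs[probs <= pobs * (1 + 1e-7)]))
}

# Benjamini-Hochberg step-up by the direct formula
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# exact two-sided Wilcoxon rank-sum p by full enumeration (no ties)
oracle_wilcox <- function(x, y) {
  nx <- length(x)
  N <- nx + length(y)
  r <- rank(c(x, y))
  wobs <- sum(r[seq_len(nx)])
  combs <- utils::combn(N, nx)
  ws <- colSums(matrix(seq_len(N)[combs], nrow = nx))
  pl <- mean(ws <= wobs)
  pg <- mean(ws >= wobs)
  min(1, 2 * min(pl, pg))
}

# CHG capability by exhaustive enumeration over all motif realisations
# and all flanking dinucleotides on both sides
oracle_chg_capable <- function(motif) {
  letters <- strsplit(motif, "")[[1]]
  sets <- lapply(letters, function(l)
    strsplit(Biostrings::IUPAC_CODE_MAP[[l]], "")[[1]])
  n <- length(letters)
  bases <- c("A", "C", "G", "T")
  flanks <- expand.grid(l1 = bases, l2 = bases, r1 = bases, r2 = bases,
                        stringsAsFactors = FALSE)
  reals <- expand.grid(sets, stringsAsFactors = FALSE)
  ctx_at <- function(chars, i, strand) {
    if (strand == "+") {
      b <- chars[i]; b1 <- chars[i + 1L]; b2 <- chars[i + 2L]
    } else {
      b <- ORACLE_COMP[chars[i]]; b1 <- ORACLE_COMP[chars[i - 1L]]
      b2 <- ORACLE_COMP[chars[i - 2L]]
    }
    if (is.na(b) || b != "C") return(NA_character_)
    if (is.na(b1)) return("undetermined")
    if (b1 == "G") return("CG")
    if (is.na(b2)) return("undetermined")
    if (b2 == "G") "CHG" else "CHH"
  }
  found <- logical(n)
  for (ri in seq_len(nrow(reals))) {
    for (fi in seq_len(nrow(flanks))) {
      chars <- c(flanks$l1[fi], flanks$l2[fi],
                 as.character(unlist(reals[ri, ])),
                 flanks$r1[fi], flanks$r2[fi])
      for (p in seq_len(n)) {
        if (found[p]) next
        i <- p + 2L
        if (identical(ctx_at(chars, i, "+"), "CHG") ||
            identical(ctx_at(chars, i, "-"), "CHG")) {
          found[p] <- TRUE
        }
      }
    }
    if (all(found)) break
  }
  which(found)
}

# build a genome + single gene covering it, for scan tests
whole_gene_genome <- function(seq_chr, chrom = "chr1") {
  genome <- Biostrings::DNAStringSet(seq_chr)
  names(genome) <- chrom
  genes <- data.frame(gene_id = "g1", chrom = chrom, start = 1L,
                      end = nchar(seq_chr), strand = "+", tss = 1L,
                      stringsAsFactors = FALSE)
  list(genome = genome, genes = genes)
}

# minimal methylome record constructor
meth_rec <- function(chrom, pos, strand, context, m, t, replicate = 1L,
                     sample_id = "s", allele = "unphased") {
  data.frame(chrom = chrom, pos = pos, strand = strand, context = context,
             count_methylated = m, count_total = t, sample_id = sample_id,
             replicate = replicate, allele = allele,
             stringsAsFactors = FALSE)
}
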