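# All coordinates inside the package are 1-based inclusive.  BED files
# (0-based half-open) are converted at the file boundary:
#   start_internal = start_bed + 1 ; end_internal = end_bed.

#' Read a genome FASTA into a DNAStringSet
#'
#' Sequences are uppercased and validated against the alphabet A/C/G/T/N.
#' Header names are taken up to the first whitespace and must be unique.
#'
#' @param path path to a FASTA file.
#' @return a [Biostrings::DNAStringSet] named by chromosome.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1", "ctctgttt"), fa)
#' read_genome_fasta(fa)
#' @export
read_genome_fasta <- function(path) {
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L) {
    stop("empty FASTA file: ", path)
  }
  nm <- sub("\\s.*$", "", names(raw))
  dup <- nm[duplicated(nm)]
  if (length(dup) > 0L) {
    stop("duplicate FASTA header(s): ", paste(unique(dup), collapse = ", "))
  }
  seqs <- toupper(as.character(raw))
  bad <- regexpr("[^ACGTN]", seqs)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stop(sprintf(
      "invalid character '%s' at position %d of sequence '%s' (allowed: A,C,G,T,N)",
      substr(seqs[i], bad[i], bad[i]), bad[i], nm[i]
    ))
  }
  genome <- Biostrings::DNAStringSet(seqs)
  names(genome) <- nm
  genome
}

#' Write a genome to FASTA
#'
#' @param genome a named [Biostrings::DNAStringSet].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path, width = 70L)
  invisible(path)
}

#' Chromosome lengths of a genome
#'
#' @param genome a named [Biostrings::DNAStringSet].
#' @return named integer vector of lengths.
#' @export
chrom_lengths <- function(genome) {
  stats::setNames(BiocGenerics::width(genome), names(genome))
}

# fetch single bases (as characters) at 1-based positions; vectorised over
# chrom/pos.  Positions outside the chromosome yield NA.
genome_letters <- function(genome, chrom, pos) {
  out <- rep(NA_character_, length(pos))
  lens <- chrom_lengths(genome)
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    ok <- !is.na(pos[idx]) & pos[idx] >= 1L & pos[idx] <= lens[[ch]]
    if (any(ok)) {
      s <- as.character(genome[[ch]])
      out[idx[ok]] <- substring(s, pos[idx][ok], pos[idx][ok])
    }
  }
  out
}

#' Read gene models from a GFF3 file
#'
#' Gene features must carry an `ID` attribute.  The translation start
#' defaults to the 5' end of the gene per strand; when CDS features whose
#' `Parent` (or `ID`) points at the gene are present, the 5'-most CDS
#' boundary is used instead.
#'
#' @param path path to a GFF3 file.
#' @return a data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`, `tss` (translation start, 1-based bp).
#' @export
read_gff_genes <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  genes <- gr[as.character(gr$type) == "gene"]
  ids <- if (is.null(genes$ID)) rep(NA_character_, length(genes)) else
    as.character(genes$ID)
  if (length(genes) > 0L && (anyNA(ids) || any(ids == ""))) {
    stop("GFF gene feature without an ID attribute in ", path)
  }
  if (anyDuplicated(ids)) {
    stop("duplicate gene IDs in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  strand <- as.character(BiocGenerics::strand(genes))
  strand[strand == "*"] <- "+"
  df <- data.frame(
    gene_id = ids,
    chrom = as.character(GenomicRanges::seqnames(genes)),
    start = BiocGenerics::start(genes),
    end = BiocGenerics::end(genes),
    strand = strand,
    stringsAsFactors = FALSE
  )
  df$tss <- ifelse(df$strand == "+", df$start, df$end)
  cds <- gr[as.character(gr$type) == "CDS"]
  if (length(cds) > 0L) {
    parent <- as.character(S4Vectors::unstrsplit(cds$Parent, sep = ","))
    if (all(parent == "") && !is.null(cds$ID)) parent <- as.character(cds$ID)
    for (i in seq_len(nrow(df))) {
      sel <- parent == df$gene_id[i]
      if (any(sel)) {
        df$tss[i] <- if (df$strand[i] == "+") {
          min(BiocGenerics::start(cds)[sel])
        } else {
          max(BiocGenerics::end(cds)[sel])
        }
      }
    }
  }
  bad <- df$tss < df$start | df$tss > df$end
  if (any(bad)) {
    stop("translation start outside gene body for: ",
         paste(df$gene_id[bad], collapse = ", "))
  }
  df
}

#' Write gene models to GFF3
#'
#' Emits one `gene` line per model and, when the translation start differs
#' from the 5' gene end, a matching `CDS` line so the default rule of
#' [read_gff_genes()] round-trips.
#'
#' @param genes data.frame as returned by [read_gff_genes()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gff3_genes <- function(genes, path) {
  lines <- "##gff-version 3"
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    lines <- c(lines, sprintf("%s\tepigerm\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                              g$chrom, g$start, g$end, g$strand, g$gene_id))
    five_prime <- if (g$strand == "+") g$start else g$end
    if (!is.null(g$tss) && !is.na(g$tss) && g$tss != five_prime) {
      cds_start <- if (g$strand == "+") g$tss else g$start
      cds_end <- if (g$strand == "+") g$end else g$tss
      lines <- c(lines, sprintf(
        "%s\tepigerm\tCDS\t%d\t%d\t.\t%s\t0\tID=%s.cds;Parent=%s",
        g$chrom, cds_start, cds_end, g$strand, g$gene_id, g$gene_id))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read genomic intervals from a BED file
#'
#' BED 0-based half-open coordinates are converted to the internal 1-based
#' inclusive convention.  Zero-length and negative-coordinate records are
#' rejected.
#'
#' @param path path to a BED file (3+ columns).
#' @return data.frame with columns `chrom`, `start`, `end`, `name`,
#'   `strand` (`.` when absent in the file).
#' @export
read_bed_intervals <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  if (length(gr) > 0L && any(BiocGenerics::width(gr) < 1L)) {
    stop("zero-length BED interval(s) in ", path)
  }
  if (length(gr) > 0L && any(BiocGenerics::start(gr) < 1L)) {
    stop("negative BED coordinate(s) in ", path)
  }
  nm <- if (!is.null(gr$name)) as.character(gr$name) else rep(".", length(gr))
  strand <- as.character(BiocGenerics::strand(gr))
  strand[strand == "*"] <- "."
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr),
    end = BiocGenerics::end(gr),
    name = nm,
    strand = strand,
    stringsAsFactors = FALSE
  )
}

#' Write internal intervals to BED
#'
#' @param intervals data.frame with columns `chrom`, `start`, `end` and
#'   optionally `name`, `score`, `strand` (internal 1-based inclusive).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed_intervals <- function(intervals, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(intervals)))
  if (any(intervals$end < intervals$start)) {
    stop("interval with end < start")
  }
  nm <- if ("name" %in% names(intervals)) intervals$name else "."
  sc <- if ("score" %in% names(intervals)) intervals$score else 0L
  st <- if ("strand" %in% names(intervals)) intervals$strand else "."
  out <- data.frame(intervals$chrom, intervals$start - 1L, intervals$end,
                    nm, sc, st)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read chromatin-mark domains from BED
#'
#' @param path path to a BED file of domain intervals.
#' @param mark one of `"H3K27me3"`, `"H3K9me2"`.
#' @param allele one of `"maternal"`, `"paternal"`, `"unphased"`.
#' @return data.frame with columns `chrom`, `start`, `end`, `mark`,
#'   `allele` (internal 1-based inclusive coordinates).
#' @export
read_bed_domains <- function(path, mark, allele = "maternal") {
  mark <- match.arg(mark, .MARKS)
  allele <- match.arg(allele, .ALLELES)
  iv <- read_bed_intervals(path)
  data.frame(
    chrom = iv$chrom, start = iv$start, end = iv$end,
    mark = mark, allele = allele,
    stringsAsFactors = FALSE
  )
}

#' Promoter regions upstream of translation starts
#'
#' Returns up to `length` bp immediately 5' of each gene's translation
#' start on the gene's strand, truncated at chromosome edges (never an
#' error).  A gene whose translation start sits at the chromosome edge
#' gets an empty promoter (NA coordinates).
#'
#' @param genes data.frame as from [read_gff_genes()].
#' @param genome optional genome ([Biostrings::DNAStringSet]) used to
#'   truncate minus-strand promoters at chromosome ends.
#' @param length promoter length in bp (default 1000, i.e. 1 kb upstream).
#' @return data.frame `gene_id`, `chrom`, `start`, `end`, `strand`;
#'   `start`/`end` are NA for empty promoters.
#' @export
promoter_regions <- function(genes, genome = NULL, length = 1000L) {
  stopifnot(length >= 1L)
  start <- ifelse(genes$strand == "+", pmax(1L, genes$tss - length),
                  genes$tss + 1L)
  end <- ifelse(genes$strand == "+", genes$tss - 1L, genes$tss + length)
  if (!is.null(genome)) {
    lens <- chrom_lengths(genome)
    end <- pmin(end, as.integer(lens[genes$chrom]))
  }
  empty <- end < start
  start[empty] <- NA_integer_
  end[empty] <- NA_integer_
  data.frame(
    gene_id = genes$gene_id,
    chrom = genes$chrom,
    start = as.integer(start),
    end = as.integer(end),
    strand = genes$strand,
    stringsAsFactors = FALSE
  )
}

# data.frame of intervals -> GRanges (internal coordinates are already
# 1-based inclusive, i.e. GRanges convention)
intervals_to_granges <- function(df) {
  strand <- if ("strand" %in% names(df)) {
    s <- df$strand
    s[!s %in% c("+", "-")] <- "*"
    s
  } else "*"
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start, end = df$end),
    strand = strand
  )
}

#' Extract region sequences from a genome
#'
#' @param genome a [Biostrings::DNAStringSet].
#' @param regions data.frame with `chrom`, `start`, `end` and optionally
#'   `strand`; rows with NA coordinates yield empty strings.
#' @param oriented reverse-complement minus-strand regions (default TRUE).
#' @return character vector of sequences.
#' @export
extract_sequences <- function(genome, regions, oriented = TRUE) {
  n <- nrow(regions)
  out <- character(n)
  for (i in seq_len(n)) {
    if (is.na(regions$start[i]) || is.na(regions$end[i])) next
    s <- as.character(Biostrings::subseq(
      genome[[regions$chrom[i]]], regions$start[i], regions$end[i]))
    if (oriented && "strand" %in% names(regions) &&
        identical(regions$strand[i], "-")) {
      s <- revcomp_chr(s)
    }
    out[i] <- s
  }
  out
}
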