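# REF6-binding-site scanning.  The REF6 zinc fingers recognise CTCTGYTY
# (Y = C or T); CHG methylation inside the site repels binding, so each
# motif position is annotated with its cytosine context (CG/CHG/CHH) on
# whichever strand carries the cytosine.

.IUPAC <- Biostrings::IUPAC_CODE_MAP

iupac_set <- function(letter) {
  strsplit(.IUPAC[[letter]], "")[[1]]
}

validate_iupac <- function(motif) {
  letters <- strsplit(motif, "")[[1]]
  bad <- setdiff(letters, names(.IUPAC))
  if (length(bad) > 0L) {
    stop("non-IUPAC letter(s) in motif '", motif, "': ",
         paste(unique(bad), collapse = ", "))
  }
  letters
}

#' Scan a genome for an IUPAC motif within gene bodies
#'
#' Finds all occurrences of `motif` on both strands.  Minus-strand matches
#' are reported with plus-strand coordinates of the covered interval and
#' `matched_seq` in motif orientation.  With `genes` supplied, only
#' occurrences whose 8 bp (motif width) lie entirely within a gene body are
#' kept, one record per overlapping gene; an occurrence inside two genes
#' yields two records.  Occurrences are deduplicated per
#' (gene, region, strand).  An N inside the match window never matches.
#'
#' @param genome a [Biostrings::DNAStringSet].
#' @param genes optional gene data.frame (see [read_gff_genes()]); `NULL`
#'   scans the whole genome and leaves `gene_id` NA.
#' @param motif IUPAC motif string (default `"CTCTGYTY"`, the REF6-binding
#'   site).
#' @return data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`, `matched_seq` (motif orientation), sorted by position.
#' @export
scan_motif <- function(genome, genes = NULL, motif = "CTCTGYTY") {
  validate_iupac(motif)
  pat <- Biostrings::DNAString(motif)
  w <- length(pat)
  res <- list()
  for (ch in names(genome)) {
    subj <- genome[[ch]]
    for (std in c("+", "-")) {
      p <- if (std == "+") pat else Biostrings::reverseComplement(pat)
      m <- Biostrings::matchPattern(p, subj, fixed = "subject")
      if (length(m) == 0L) next
      seqs <- as.character(m)
      if (std == "-") seqs <- revcomp_chr(seqs)
      res[[length(res) + 1L]] <- data.frame(
        chrom = ch,
        start = BiocGenerics::start(m),
        end = BiocGenerics::end(m),
        strand = std,
        matched_seq = seqs,
        stringsAsFactors = FALSE
      )
    }
  }
  sites <- if (length(res) > 0L) do.call(rbind, res) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               strand = character(), matched_seq = character(),
               stringsAsFactors = FALSE)
  if (is.null(genes)) {
    sites$gene_id <- rep(NA_character_, nrow(sites))
  } else {
    if (nrow(sites) > 0L && nrow(genes) > 0L) {
      hits <- GenomicRanges::findOverlaps(
        intervals_to_granges(sites[c("chrom", "start", "end")]),
        intervals_to_granges(genes[c("chrom", "start", "end")]),
        type = "within", ignore.strand = TRUE
      )
      sites <- sites[S4Vectors::queryHits(hits), , drop = FALSE]
      sites$gene_id <- genes$gene_id[S4Vectors::subjectHits(hits)]
    } else {
      sites <- sites[integer(0), , drop = FALSE]
      sites$gene_id <- character(0)
    }
  }
  sites <- unique(sites)
  sites <- sites[order(sites$chrom, sites$start, sites$strand), , drop = FALSE]
  rownames(sites) <- NULL
  sites$site_id <- if (nrow(sites) == 0L) character(0) else
    paste0(sites$chrom, ":", sites$start, ":", sites$strand,
           ifelse(is.na(sites$gene_id), "",
                  paste0(":", sites$gene_id)))
  sites[, c("site_id", "gene_id", "chrom", "start", "end", "strand",
            "matched_seq")]
}

#' Bisulfite sequence context of a cytosine
#'
#' Context is read 5'->3' on the strand carrying the cytosine: CG if the
#' next base is G; CHG if the next base is H (A/C/T) and the one after is
#' G; CHH otherwise.  Returns `"undetermined"` when the required flanking
#' bases run off the chromosome or contain N.  Vectorised over
#' `chrom`/`pos`/`strand`.
#'
#' @param genome a [Biostrings::DNAStringSet].
#' @param chrom chromosome name(s).
#' @param pos 1-based position(s); the base there (on `strand`) must be C.
#' @param strand `"+"` or `"-"` per position.
#' @return character vector in `c("CG","CHG","CHH","undetermined")`.
#' @export
cytosine_context <- function(genome, chrom, pos, strand) {
  n <- max(length(chrom), length(pos), length(strand))
  chrom <- rep_len(chrom, n); pos <- rep_len(pos, n)
  strand <- rep_len(strand, n)
  base <- genome_letters(genome, chrom, pos)
  base_on_strand <- ifelse(strand == "+", base, .complement[base])
  if (any(is.na(base_on_strand) | base_on_strand != "C")) {
    i <- which(is.na(base_on_strand) | base_on_strand != "C")[1L]
    stop(sprintf("base at %s:%d(%s) is '%s', not C",
                 chrom[i], pos[i], strand[i],
                 ifelse(is.na(base_on_strand[i]), "NA", base_on_strand[i])))
  }
  off1 <- ifelse(strand == "+", pos + 1L, pos - 1L)
  off2 <- ifelse(strand == "+", pos + 2L, pos - 2L)
  b1 <- genome_letters(genome, chrom, off1)
  b2 <- genome_letters(genome, chrom, off2)
  b1 <- ifelse(strand == "+", b1, .complement[b1])
  b2 <- ifelse(strand == "+", b2, .complement[b2])
  ctx <- rep("undetermined", n)
  known1 <- !is.na(b1) & b1 != "N"
  known2 <- !is.na(b2) & b2 != "N"
  ctx[known1 & b1 == "G"] <- "CG"
  h1 <- known1 & b1 %in% c("A", "C", "T")
  ctx[h1 & known2 & b2 == "G"] <- "CHG"
  ctx[h1 & known2 & b2 != "G"] <- "CHH"
  ctx
}

#' Annotate the cytosine context of every motif position of a site
#'
#' Positions are numbered in motif orientation (1 = the first C of
#' CTCTGYTY) for plus- and minus-strand sites alike.  A position whose
#' motif-orientation base is C carries a sense-strand cytosine; a G carries
#' an antisense-strand cytosine (the C on the other strand); other bases
#' have no cytosine (`context = "none"`).
#'
#' @param sites data.frame from [scan_motif()].
#' @param genome a [Biostrings::DNAStringSet].
#' @return data.frame with one row per (site, motif position): the site
#'   columns plus `motif_position` (1..motif width), `genomic_coord`,
#'   `cytosine_strand` (`NA` when no cytosine) and `context`
#'   (`CG`/`CHG`/`CHH`/`undetermined`/`none`).
#' @export
annotate_site_positions <- function(sites, genome) {
  if (nrow(sites) == 0L) {
    out <- cbind(sites[integer(0), , drop = FALSE],
                 data.frame(motif_position = integer(),
                            genomic_coord = integer(),
                            cytosine_strand = character(),
                            context = character()))
    return(out)
  }
  w <- unique(nchar(sites$matched_seq))
  stopifnot(length(w) == 1L)
  idx <- rep(seq_len(nrow(sites)), each = w)
  p <- rep(seq_len(w), times = nrow(sites))
  ann <- sites[idx, , drop = FALSE]
  ann$motif_position <- p
  ann$genomic_coord <- ifelse(ann$strand == "+",
                              ann$start + p - 1L, ann$end - p + 1L)
  motif_base <- substring(ann$matched_seq, p, p)
  ann$cytosine_strand <- ifelse(
    motif_base == "C", ann$strand,
    ifelse(motif_base == "G", ifelse(ann$strand == "+", "-", "+"),
           NA_character_))
  ann$context <- "none"
  has_c <- !is.na(ann$cytosine_strand)
  if (any(has_c)) {
    ann$context[has_c] <- cytosine_context(
      genome, ann$chrom[has_c], ann$genomic_coord[has_c],
      ann$cytosine_strand[has_c])
  }
  rownames(ann) <- NULL
  ann
}

#' Motif positions at which CHG methylation is attainable
#'
#' A motif position qualifies when some concrete realisation of the IUPAC
#' motif, together with some choice of bases flanking the motif, places a
#' cytosine there (on either strand) in CHG context.  For the REF6-binding
#' site CTCTGYTY these are positions 3, 5 and 8.
#'
#' @param motif IUPAC motif string.
#' @return sorted integer vector of qualifying positions.
#' @examples
#' chg_capable_positions("CTCTGYTY")  # 3 5 8
#' @export
chg_capable_positions <- function(motif) {
  letters <- validate_iupac(motif)
  n <- length(letters)
  sets <- lapply(letters, iupac_set)
  free <- c("A", "C", "G", "T")
  at <- function(i) if (i >= 1L && i <= n) sets[[i]] else free
  H <- c("A", "C", "T")
  capable <- vapply(seq_len(n), function(p) {
    # cytosine on the motif strand: C at p, some H at p+1, G at p+2
    via_c <- ("C" %in% sets[[p]]) &&
      any(at(p + 1L) %in% H) && ("G" %in% at(p + 2L))
    # cytosine on the opposite strand under a G at p; reading 5'->3' on
    # that strand visits the complements of positions p, p-1, p-2
    via_g <- ("G" %in% sets[[p]]) &&
      any(.complement[at(p - 1L)] %in% H) &&
      ("G" %in% .complement[at(p - 2L)])
    via_c || via_g
  }, logical(1))
  which(capable)
}

#' Export motif sites to BED6 and a per-position annotation TSV
#'
#' @param sites data.frame from [scan_motif()].
#' @param annotations data.frame from [annotate_site_positions()].
#' @param bed_path,tsv_path output paths (either may be `NULL` to skip).
#' @return invisibly, a list of the written paths.
#' @export
export_sites <- function(sites, annotations = NULL, bed_path = NULL,
                         tsv_path = NULL) {
  if (!is.null(bed_path)) {
    iv <- data.frame(chrom = sites$chrom, start = sites$start,
                     end = sites$end,
                     name = ifelse(is.na(sites$gene_id), sites$site_id,
                                   paste0(sites$gene_id, ":", sites$start)),
                     score = 0L, strand = sites$strand)
    write_bed_intervals(iv, bed_path)
  }
  if (!is.null(tsv_path) && !is.null(annotations)) {
    utils::write.table(annotations, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(list(bed = bed_path, tsv = tsv_path))
}
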