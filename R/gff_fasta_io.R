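#' @title FASTA and GFF3 I/O
#' @description FASTA goes through Biostrings; GFF3 through rtracklayer.
#' GFF3 1-based closed intervals are converted to the internal 0-based
#' half-open convention on read and back on write.
#' @name gff_fasta_io
NULL

#' Read reference sequences from FASTA
#'
#' @param path FASTA file
#' @return a [reference_sequences()] set
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  s <- as.character(x)
  names(s) <- sub("\\s.*$", "", names(x))
  reference_sequences(s)
}

#' Write reference sequences to FASTA
#'
#' @param ref a [reference_sequences()] set
#' @param path output file
#' @return invisibly, `path`
#' @export
write_fasta <- function(ref, path) {
  x <- Biostrings::DNAStringSet(unclass(ref))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read transcript models from GFF3
#'
#' Expects gene/mRNA/exon/CDS features linked by Parent attributes. Each mRNA
#' becomes a [transcript_model()]; minus-strand transcripts keep
#' genomic-sorted exon order with the strand flag. When a reference is given,
#' each CDS is validated (length divisible by 3, ATG start, stop end);
#' `warn_only = TRUE` downgrades validation failures to warnings.
#'
#' @param path GFF3 file
#' @param reference optional [reference_sequences()] set for CDS validation
#' @param warn_only validate with warnings instead of errors
#' @return named list of [transcript_model()] (by transcript_id)
#' @export
read_gff3 <- function(path, reference = NULL, warn_only = FALSE) {
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  ids <- if ("ID" %in% names(S4Vectors::mcols(gr))) as.character(gr$ID)
         else rep(NA_character_, length(gr))
  parents <- if ("Parent" %in% names(S4Vectors::mcols(gr))) {
    vapply(gr$Parent, function(p) if (length(p)) as.character(p[1])
           else NA_character_, "")
  } else rep(NA_character_, length(gr))
  mrna_idx <- which(type %in% c("mRNA", "transcript"))
  mrna_ids <- ids[mrna_idx]
  if (anyNA(mrna_ids)) stop("mRNA feature without ID attribute")
  orphan <- which(type == "CDS" & !(parents %in% mrna_ids))
  if (length(orphan))
    stop("orphan CDS feature(s) with Parent not matching any mRNA: ",
         paste(unique(parents[orphan]), collapse = ", "))
  out <- list()
  for (i in mrna_idx) {
    tid <- ids[i]
    gene <- if (!is.na(parents[i])) parents[i] else tid
    take <- function(what) {
      j <- which(type == what & parents == tid)
      if (!length(j)) return(NULL)
      data.frame(start = GenomicRanges::start(gr)[j] - 1L,
                 end = GenomicRanges::end(gr)[j])
    }
    exons <- take("exon"); cds <- take("CDS")
    if (is.null(cds)) next  # non-coding transcript: out of scope
    if (is.null(exons)) exons <- cds
    t <- transcript_model(gene, tid,
                          as.character(GenomicRanges::seqnames(gr))[i],
                          as.character(GenomicRanges::strand(gr))[i],
                          exons, cds)
    if (!is.null(reference)) validate_transcript(t, reference, warn_only)
    out[[tid]] <- t
  }
  out
}

#' Write transcript models as GFF3
#'
#' Emits gene, mRNA, exon and CDS features linked by Parent attributes;
#' intervals converted back to GFF3 1-based closed coordinates.
#'
#' @param transcripts list of [transcript_model()]
#' @param path output file
#' @return invisibly, `path`
#' @export
write_gff3 <- function(transcripts, path) {
  rows <- list()
  add <- function(chrom, start0, end, strand, type, id, parent,
                  phase = NA_integer_) {
    rows[[length(rows) + 1L]] <<- data.frame(
      chrom = chrom, start = start0 + 1L, end = end, strand = strand,
      type = type, ID = id, Parent = parent, phase = phase,
      stringsAsFactors = FALSE)
  }
  for (t in transcripts) {
    span <- gene_span(t)
    add(t$chrom, span[1], span[2], t$strand, "gene", t$gene_id, NA)
    add(t$chrom, span[1], span[2], t$strand, "mRNA", t$transcript_id,
        t$gene_id)
    for (i in seq_len(nrow(t$exons)))
      add(t$chrom, t$exons$start[i], t$exons$end[i], t$strand, "exon",
          paste0(t$transcript_id, ".exon", i), t$transcript_id)
    lens <- t$cds$end - t$cds$start
    tx_order <- if (t$strand == "+") seq_len(nrow(t$cds))
                else rev(seq_len(nrow(t$cds)))
    cum <- 0L
    for (i in tx_order) {
      add(t$chrom, t$cds$start[i], t$cds$end[i], t$strand, "CDS",
          paste0(t$transcript_id, ".cds", i), t$transcript_id,
          phase = (3L - cum %% 3L) %% 3L)
      cum <- cum + lens[i]
    }
  }
  d <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    seqnames = d$chrom,
    ranges = IRanges::IRanges(start = d$start, end = d$end),
    strand = d$strand)
  gr$type <- d$type
  gr$phase <- d$phase
  gr$ID <- d$ID
  gr$Parent <- IRanges::CharacterList(lapply(d$Parent, function(p) {
    if (is.na(p)) character() else p
  }))
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
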