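#' Gene model utilities
#'
#' A gene model is a plain data.frame (class `gene_model`) in GFF3-like
#' long form with columns `seqid`, `type` (gene, mRNA, exon, CDS,
#' five_prime_UTR, three_prime_UTR, miRNA), `start`, `end` (1-based
#' inclusive), `strand`, `ID`, `Parent` and `phase` (CDS only).
#'
#' @param df data.frame with the columns above.
#' @return the validated `gene_model`.
#' @export
gene_model <- function(df) {
  needed <- c("seqid", "type", "start", "end", "strand", "ID", "Parent",
              "phase")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    stop("gene model is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (any(df$end < df$start)) stop("gene model has end < start", call. = FALSE)
  df <- df[, needed]
  class(df) <- c("gene_model", "data.frame")
  df
}

#' @export
transcripts <- function(model) model$ID[model$type == "mRNA"]

#' Genes with exactly one annotated transcript
#' @param model a `gene_model`.
#' @export
single_transcript_genes <- function(model) {
  tx <- model[model$type == "mRNA", ]
  tab <- table(tx$Parent)
  names(tab)[tab == 1L]
}

tx_row <- function(model, tx_id) model[model$type == "mRNA" &
                                         model$ID == tx_id, ][1, ]

tx_children <- function(model, tx_id, type) {
  out <- model[model$type == type & !is.na(model$Parent) &
                 model$Parent == tx_id, ]
  out[order(out$start), ]
}

#' Exons of a transcript, in transcription order
#' @export
tx_exons <- function(model, tx_id) {
  ex <- tx_children(model, tx_id, "exon")
  if (nrow(ex) && tx_row(model, tx_id)$strand == "-") ex <- ex[rev(seq_len(nrow(ex))), ]
  ex
}

#' Introns of a transcript (gaps between exons), in transcription order
#'
#' @return data.frame `seqid`, `start`, `end`, `strand`, `ordinal` where
#'   ordinal 1 is the intron closest to the transcription start site.
#' @export
tx_introns <- function(model, tx_id) {
  ex <- tx_children(model, tx_id, "exon")   # genomic order
  if (nrow(ex) < 2L) {
    return(data.frame(seqid = character(), start = integer(),
                      end = integer(), strand = character(),
                      ordinal = integer()))
  }
  strand <- tx_row(model, tx_id)$strand
  ints <- data.frame(seqid = ex$seqid[1],
                     start = ex$end[-nrow(ex)] + 1L,
                     end = ex$start[-1] - 1L,
                     strand = strand)
  ints$ordinal <- if (strand == "-") rev(seq_len(nrow(ints))) else
    seq_len(nrow(ints))
  ints[ints$end >= ints$start, ]
}

#' Genomic positions of a transcript's CDS, in transcription order
#' @export
cds_positions <- function(model, tx_id) {
  cds <- tx_children(model, tx_id, "CDS")   # genomic order
  if (!nrow(cds)) return(integer())
  pos <- unlist(lapply(seq_len(nrow(cds)),
                       function(i) seq(cds$start[i], cds$end[i])))
  if (tx_row(model, tx_id)$strand == "-") pos <- rev(pos)
  pos
}

#' Spliced CDS sequence of a transcript in reading orientation
#' @param genome `DNAStringSet` holding the chromosome sequences.
#' @export
cds_sequence <- function(model, genome, tx_id) {
  row <- tx_row(model, tx_id)
  chars <- seq_chars(genome[[row$seqid]])
  pos <- cds_positions(model, tx_id)
  s <- chars[pos]
  if (row$strand == "-") s <- complement_chars(s)
  chars_seq(s)
}

#' Translate a CDS with the standard genetic code
#' @param cds character scalar, length divisible by 3.
#' @return amino-acid string (`*` for stop codons).
#' @export
translate_cds <- function(cds) {
  if (nchar(cds) %% 3 != 0) stop("CDS length not divisible by 3",
                                 call. = FALSE)
  codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
  paste(Biostrings::GENETIC_CODE[codons], collapse = "")
}

#' Write / read a gene model as GFF3
#'
#' Serialisation goes through [rtracklayer::export()]; `Parent` is written
#' as a GFF3 attribute so the file round-trips.
#' @param model a `gene_model`.
#' @param path output file.
#' @export
write_gene_model <- function(model, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = model$seqid,
    ranges = IRanges::IRanges(model$start, model$end),
    strand = model$strand)
  S4Vectors::mcols(gr)$type <- model$type
  S4Vectors::mcols(gr)$ID <- model$ID
  S4Vectors::mcols(gr)$Parent <- ifelse(is.na(model$Parent), NA_character_,
                                        model$Parent)
  S4Vectors::mcols(gr)$phase <- model$phase
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' @rdname write_gene_model
#' @export
read_gene_model <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  parent <- vapply(as.list(S4Vectors::mcols(gr)$Parent), function(p)
    if (length(p)) p[[1]] else NA_character_, character(1))
  phase <- S4Vectors::mcols(gr)$phase
  if (is.null(phase)) phase <- rep(NA_integer_, length(gr))
  gene_model(data.frame(
    seqid = as.character(GenomicRanges::seqnames(gr)),
    type = as.character(S4Vectors::mcols(gr)$type),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    ID = as.character(S4Vectors::mcols(gr)$ID),
    Parent = parent,
    phase = as.integer(phase),
    stringsAsFactors = FALSE))
}
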