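#' The severity hierarchy of consequence categories
#'
#' Fourteen categories in a strict severity order (rank 1 most severe);
#' when a variant hits several transcripts or features, the category with
#' the lowest rank wins. The order is configurable: pass any permutation
#' (or subset replacement) as a named integer vector.
#'
#' @return named integer vector mapping category name to rank.
#' @export
consequence_hierarchy <- function() {
  c(splice_donor = 1L, splice_acceptor = 2L, stop_gained = 3L,
    stop_lost = 4L, start_lost = 5L, missense = 6L, splice_region = 7L,
    synonymous = 8L, five_prime_utr = 9L, three_prime_utr = 10L,
    non_coding_transcript = 11L, intron = 12L,
    upstream_downstream = 13L, intergenic = 14L)
}

#' Splice-site window conventions
#'
#' Intronic offsets 1-2 from the intron's transcription ends are the
#' splice donor (5' end) and acceptor (3' end); intronic offsets
#' `3..intron_region` and exonic offsets `1..exon_region` from an
#' exon/intron boundary are splice region.
#' @param donor_acceptor,intron_region,exon_region window widths in bp.
#' @export
splice_windows <- function(donor_acceptor = 2L, intron_region = 8L,
                           exon_region = 3L) {
  list(donor_acceptor = donor_acceptor, intron_region = intron_region,
       exon_region = exon_region)
}

# per-transcript cache of exon/intron/CDS structure
build_tx_index <- function(model, genome) {
  txs <- transcripts(model)
  lapply(setNames(txs, txs), function(tx) {
    row <- tx_row(model, tx)
    gpos <- cds_positions(model, tx)
    list(tx = tx, chrom = row$seqid, strand = row$strand,
         start = row$start, end = row$end,
         exons = tx_children(model, tx, "exon"),
         introns = tx_introns(model, tx),
         utr5 = tx_children(model, tx, "five_prime_UTR"),
         utr3 = tx_children(model, tx, "three_prime_UTR"),
         cds_gpos = gpos,
         cds_seq = if (length(gpos)) cds_sequence(model, genome, tx) else "")
  })
}

# coding consequence of variants inside a transcript's CDS
coding_consequence <- function(idx, pos, alt) {
  cdsmap <- match(pos, idx$cds_gpos)
  stopifnot(!anyNA(cdsmap))
  alt_tx <- if (idx$strand == "-") complement_chars(alt) else alt
  codon_no <- (cdsmap - 1L) %/% 3L        # 0-based codon index
  codon_pos <- (cdsmap - 1L) %% 3L + 1L
  ref_codon <- substring(idx$cds_seq, 3L * codon_no + 1L, 3L * codon_no + 3L)
  alt_codon <- ref_codon
  substr(alt_codon, codon_pos, codon_pos) <- alt_tx
  gc <- Biostrings::GENETIC_CODE
  ref_aa <- unname(gc[ref_codon])
  alt_aa <- unname(gc[alt_codon])
  category <- ifelse(ref_aa == alt_aa, "synonymous", "missense")
  category[ref_aa != "*" & alt_aa == "*"] <- "stop_gained"
  category[ref_aa == "*" & alt_aa != "*"] <- "stop_lost"
  category[codon_no == 0L & alt_codon != "ATG"] <- "start_lost"
  data.frame(category = category, ref_aa = ref_aa, alt_aa = alt_aa,
             codon_pos = codon_pos, stringsAsFactors = FALSE)
}

#' Annotate variants with consequence categories and coding details
#'
#' A self-contained consequence classifier over a [gene_model()]: for each
#' variant, all overlapping transcript features are evaluated (coding
#' change via the standard genetic code on the strand-corrected codon,
#' splice donor/acceptor/region windows, UTRs, introns, miRNA transcripts,
#' gene flanks) and the most severe category under the hierarchy is kept.
#'
#' @param variants data.frame with `chrom`, `pos`, `ref`, `alt`.
#' @param model a `gene_model`.
#' @param genome `DNAStringSet` (for codon lookup).
#' @param hierarchy see [consequence_hierarchy()].
#' @param flank_size bp up/downstream of a gene span still assigned
#'   `upstream_downstream` rather than `intergenic`.
#' @param splice see [splice_windows()].
#' @return data.frame: the variant columns plus `category`, `ref_aa`,
#'   `alt_aa`, `codon_pos` (NA outside CDS).
#' @export
annotate_consequence <- function(variants, model, genome,
                                 hierarchy = consequence_hierarchy(),
                                 flank_size = 1000L,
                                 splice = splice_windows()) {
  n <- nrow(variants)
  chrom_len <- setNames(Biostrings::width(genome), names(genome))
  bad <- variants$pos < 1L | variants$pos > chrom_len[variants$chrom]
  if (any(bad | is.na(bad))) {
    stop("coordinate error: variant beyond chromosome end", call. = FALSE)
  }
  rank_best <- rep(hierarchy[["intergenic"]], n)
  cat_best <- rep("intergenic", n)
  aa <- data.frame(ref_aa = rep(NA_character_, n),
                   alt_aa = rep(NA_character_, n),
                   codon_pos = rep(NA_integer_, n))
  coding_rank_best <- rep(Inf, n)

  propose <- function(i, category) {
    r <- hierarchy[category]
    upd <- which(r < rank_best[i])
    rank_best[i[upd]] <<- r[upd]
    cat_best[i[upd]] <<- category[upd]
  }

  tx_index <- build_tx_index(model, genome)
  for (idx in tx_index) {
    on_chrom <- which(variants$chrom == idx$chrom)
    if (!length(on_chrom)) next
    pos <- variants$pos[on_chrom]

    if (length(idx$cds_gpos)) {
      in_cds <- on_chrom[pos %in% idx$cds_gpos]
      if (length(in_cds)) {
        cc <- coding_consequence(idx, variants$pos[in_cds],
                                 variants$alt[in_cds])
        propose(in_cds, cc$category)
        # keep aa detail from the most severe coding annotation seen
        r <- hierarchy[cc$category]
        upd <- which(r < coding_rank_best[in_cds])
        tgt <- in_cds[upd]
        coding_rank_best[tgt] <- r[upd]
        aa$ref_aa[tgt] <- cc$ref_aa[upd]
        aa$alt_aa[tgt] <- cc$alt_aa[upd]
        aa$codon_pos[tgt] <- cc$codon_pos[upd]
      }
    }

    # exonic splice region: within exon_region bp of an exon boundary that
    # abuts an intron
    if (nrow(idx$introns)) {
      for (k in seq_len(nrow(idx$introns))) {
        istart <- idx$introns$start[k]; iend <- idx$introns$end[k]
        w <- splice$exon_region
        ex_hit <- on_chrom[(pos >= istart - w & pos <= istart - 1L) |
                             (pos >= iend + 1L & pos <= iend + w)]
        if (length(ex_hit)) propose(ex_hit, rep("splice_region",
                                                length(ex_hit)))
        # intronic side
        in_int <- on_chrom[pos >= istart & pos <= iend]
        if (length(in_int)) {
          p <- variants$pos[in_int]
          off_low <- p - istart + 1L     # offset from low-coordinate end
          off_high <- iend - p + 1L
          if (idx$strand == "+") {
            donor_off <- off_low; acceptor_off <- off_high
          } else {
            donor_off <- off_high; acceptor_off <- off_low
          }
          cat_i <- rep("intron", length(p))
          min_off <- pmin(off_low, off_high)
          cat_i[min_off <= splice$intron_region] <- "splice_region"
          cat_i[acceptor_off <= splice$donor_acceptor] <- "splice_acceptor"
          cat_i[donor_off <= splice$donor_acceptor] <- "splice_donor"
          propose(in_int, cat_i)
        }
      }
    }

    for (u in seq_len(nrow(idx$utr5))) {
      hit <- on_chrom[pos >= idx$utr5$start[u] & pos <= idx$utr5$end[u]]
      if (length(hit)) propose(hit, rep("five_prime_utr", length(hit)))
    }
    for (u in seq_len(nrow(idx$utr3))) {
      hit <- on_chrom[pos >= idx$utr3$start[u] & pos <= idx$utr3$end[u]]
      if (length(hit)) propose(hit, rep("three_prime_utr", length(hit)))
    }
  }

  mirna <- model[model$type == "miRNA", ]
  for (m in seq_len(nrow(mirna))) {
    hit <- which(variants$chrom == mirna$seqid[m] &
                   variants$pos >= mirna$start[m] &
                   variants$pos <= mirna$end[m])
    if (length(hit)) propose(hit, rep("non_coding_transcript", length(hit)))
  }

  genes <- model[model$type == "gene", ]
  for (g in seq_len(nrow(genes))) {
    hit <- which(variants$chrom == genes$seqid[g] &
                   variants$pos >= genes$start[g] - flank_size &
                   variants$pos <= genes$end[g] + flank_size)
    if (length(hit)) propose(hit, rep("upstream_downstream", length(hit)))
  }

  out <- variants
  out$category <- cat_best
  out$ref_aa <- aa$ref_aa
  out$alt_aa <- aa$alt_aa
  out$codon_pos <- aa$codon_pos
  out
}

#' Consequence category of each variant (most severe across features)
#' @inheritParams annotate_consequence
#' @return character vector of categories.
#' @export
classify_consequence <- function(variants, model, genome,
                                 hierarchy = consequence_hierarchy(),
                                 flank_size = 1000L,
                                 splice = splice_windows()) {
  annotate_consequence(variants, model, genome, hierarchy, flank_size,
                       splice)$category
}
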