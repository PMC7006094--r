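STOP_CODONS <- c("TAA", "TAG", "TGA")

all_codons <- function() {
  g <- expand.grid(b3 = DNA_BASES, b2 = DNA_BASES, b1 = DNA_BASES)
  paste0(g$b1, g$b2, g$b3)
}

random_orf <- function(n_codons) {
  sense <- setdiff(all_codons(), STOP_CODONS)
  body <- sample(sense, n_codons - 2L, replace = TRUE)
  paste(c("ATG", body, sample(STOP_CODONS, 1L)), collapse = "")
}

# split `len` into k contiguous pieces, each at least `min_piece`
split_lengths <- function(len, k, min_piece = 3L) {
  if (k == 1L) return(len)
  stopifnot(len >= k * min_piece)
  cuts <- sort(sample(seq(min_piece, len - min_piece), k - 1L))
  while (any(diff(c(0L, cuts, len)) < min_piece)) {
    cuts <- sort(sample(seq(min_piece, len - min_piece), k - 1L))
  }
  diff(c(0L, cuts, len))
}

#' Generate a synthetic gene model and a compatible genome
#'
#' Places non-overlapping genes along the chromosomes and rewrites the
#' reference so that every transcript's spliced CDS is a valid open reading
#' frame (ATG start, no internal stop, terminal stop codon, length
#' divisible by 3). Transcripts have a 5'UTR, 1 or more exons separated by
#' introns of at least `intron_length_range[1]` bases, and a 3'UTR; strand
#' is drawn at random. miRNA intervals are placed in intergenic space,
#' disjoint from all gene spans. An optional fraction of genes receives a
#' second transcript (identical CDS, shortened terminal UTR) so that
#' multi-transcript handling can be exercised; by default every gene has
#' exactly one transcript.
#'
#' @param reference `DNAStringSet` to place genes on (it is copied and
#'   modified, not changed in place).
#' @param n_genes,n_mirnas feature counts.
#' @param seed integer seed.
#' @param n_exons_range,n_codons_range,intron_length_range,utr5_range,
#'   utr3_range,spacing_range,mirna_length_range integer ranges (inclusive)
#'   the generator draws from; `spacing_range` is the intergenic gap
#'   between consecutive gene spans.
#' @param multi_transcript_fraction fraction of genes given a second
#'   transcript.
#' @return `list(model = <gene_model>, genome = <DNAStringSet>)`.
#' @export
generate_gene_model <- function(reference, n_genes = 4L, n_mirnas = 2L,
                                seed = 1L,
                                n_exons_range = c(1L, 3L),
                                n_codons_range = c(20L, 50L),
                                intron_length_range = c(12L, 60L),
                                utr5_range = c(8L, 20L),
                                utr3_range = c(8L, 30L),
                                spacing_range = c(250L, 400L),
                                mirna_length_range = c(60L, 90L),
                                multi_transcript_fraction = 0) {
  check_count(n_genes, "n_genes")
  check_count(n_mirnas, "n_mirnas", min = 0)
  check_count(seed, "seed", min = 0)
  rng_draw <- function(range) sample(seq(range[1], range[2]), 1L)

  withr::with_seed(seed, {
    chrom_names <- names(reference)
    chrom_len <- setNames(Biostrings::width(reference), chrom_names)
    genome_chars <- lapply(chrom_names, function(ch) seq_chars(reference[[ch]]))
    names(genome_chars) <- chrom_names

    rows <- list()
    gene_spans <- list()
    chrom_i <- 1L
    cursor <- rng_draw(spacing_range)
    multi <- runif(n_genes) < multi_transcript_fraction

    for (g in seq_len(n_genes)) {
      repeat {
        n_ex <- rng_draw(n_exons_range)
        n_codons <- rng_draw(n_codons_range)
        cds_len <- 3L * n_codons
        utr5 <- rng_draw(utr5_range)
        utr3 <- rng_draw(utr3_range)
        introns <- if (n_ex > 1L)
          replicate(n_ex - 1L, rng_draw(intron_length_range)) else integer()
        span <- utr5 + cds_len + sum(introns) + utr3
        if (cursor + span - 1L <= chrom_len[chrom_i] - spacing_range[1]) break
        chrom_i <- chrom_i + 1L
        cursor <- rng_draw(spacing_range)
        if (chrom_i > length(chrom_names)) {
          stop("configuration error: genes do not fit on the supplied ",
               "chromosomes", call. = FALSE)
        }
      }
      chrom <- chrom_names[chrom_i]
      strand <- sample(c("+", "-"), 1L)
      gene_id <- paste0("gene", g)
      tx_id <- paste0(gene_id, ".t1")
      gstart <- cursor
      gend <- cursor + span - 1L
      # genomic segment layout: [left utr][cds piece 1]..introns..[cds k][right utr]
      left_len <- if (strand == "+") utr5 else utr3
      right_len <- if (strand == "+") utr3 else utr5
      pieces <- split_lengths(cds_len, n_ex)
      # genomic CDS piece intervals
      cds_iv <- matrix(NA_integer_, nrow = n_ex, ncol = 2)
      p <- gstart + left_len
      for (i in seq_len(n_ex)) {
        cds_iv[i, ] <- c(p, p + pieces[i] - 1L)
        p <- p + pieces[i] + if (i < n_ex) introns[i] else 0L
      }
      # exon intervals: first exon includes left utr, last includes right utr
      ex_iv <- cds_iv
      ex_iv[1, 1] <- gstart
      ex_iv[n_ex, 2] <- gend
      # write ORF into the genome in transcription order
      orf <- seq_chars(random_orf(n_codons))
      gpos <- unlist(lapply(seq_len(n_ex),
                            function(i) seq(cds_iv[i, 1], cds_iv[i, 2])))
      if (strand == "-") {
        genome_chars[[chrom]][rev(gpos)] <- complement_chars(orf)
      } else {
        genome_chars[[chrom]][gpos] <- orf
      }
      # phases in transcription order, attached to genomic rows
      tx_order <- if (strand == "-") rev(seq_len(n_ex)) else seq_len(n_ex)
      cum_before <- c(0L, cumsum(pieces[tx_order]))[seq_len(n_ex)]
      phase_tx <- (3L - cum_before %% 3L) %% 3L
      phase_genomic <- integer(n_ex)
      phase_genomic[tx_order] <- phase_tx

      add <- function(type, start, end, id, parent, phase = NA_integer_) {
        data.frame(seqid = chrom, type = type, start = start, end = end,
                   strand = strand, ID = id, Parent = parent, phase = phase,
                   stringsAsFactors = FALSE)
      }
      utr5_iv <- if (strand == "+") c(gstart, gstart + left_len - 1L) else
        c(gend - right_len + 1L, gend)
      utr3_iv <- if (strand == "+") c(gend - right_len + 1L, gend) else
        c(gstart, gstart + left_len - 1L)
      tx_rows <- function(tid, span_start, span_end, u5, u3, ex, suffix) {
        ex[1, 1] <- span_start; ex[nrow(ex), 2] <- span_end
        out <- list(add("mRNA", span_start, span_end, tid, gene_id))
        for (i in seq_len(nrow(ex))) {
          out[[length(out) + 1L]] <-
            add("exon", ex[i, 1], ex[i, 2], paste0(tid, ".exon", i), tid)
        }
        for (i in seq_len(n_ex)) {
          out[[length(out) + 1L]] <-
            add("CDS", cds_iv[i, 1], cds_iv[i, 2], paste0(tid, ".cds", i),
                tid, phase_genomic[i])
        }
        out[[length(out) + 1L]] <- add("five_prime_UTR", u5[1], u5[2],
                                       paste0(tid, ".utr5"), tid)
        out[[length(out) + 1L]] <- add("three_prime_UTR", u3[1], u3[2],
                                       paste0(tid, ".utr3"), tid)
        out
      }
      rows[[length(rows) + 1L]] <- add("gene", gstart, gend, gene_id,
                                       NA_character_)
      rows <- c(rows, tx_rows(tx_id, gstart, gend, utr5_iv, utr3_iv, ex_iv))
      if (multi[g] && right_len > 4L) {
        # second transcript: same CDS, terminal UTR shortened by half
        trim <- right_len %/% 2L
        t2 <- paste0(gene_id, ".t2")
        if (strand == "+") {
          u5 <- utr5_iv; u3 <- c(utr3_iv[1], utr3_iv[2] - trim)
          rows <- c(rows, tx_rows(t2, gstart, gend - trim, u5, u3, ex_iv))
        } else {
          u5 <- utr5_iv; u3 <- c(utr3_iv[1] + trim, utr3_iv[2])
          rows <- c(rows, tx_rows(t2, gstart + trim, gend, u5, u3, ex_iv))
        }
      }
      gene_spans[[length(gene_spans) + 1L]] <-
        data.frame(chrom = chrom, start = gstart, end = gend)
      cursor <- gend + rng_draw(spacing_range)
    }

    # miRNAs in intergenic space, at least 25 bp clear of gene spans
    spans <- do.call(rbind, gene_spans)
    placed <- 0L
    for (ch in chrom_names) {
      if (placed >= n_mirnas) break
      sp <- spans[spans$chrom == ch, ]
      blocked <- IRanges::reduce(IRanges::IRanges(
        pmax(1L, sp$start - 25L), pmin(chrom_len[[ch]], sp$end + 25L)))
      free <- BiocGenerics::setdiff(IRanges::IRanges(1L, chrom_len[[ch]]),
                                    blocked)
      gaps <- data.frame(start = IRanges::start(free),
                         end = IRanges::end(free))
      i <- 1L
      while (placed < n_mirnas && i <= nrow(gaps)) {
        len <- rng_draw(mirna_length_range)
        if (gaps$end[i] - gaps$start[i] + 1L < len + 50L) {
          i <- i + 1L
          next
        }
        s <- gaps$start[i] + 25L
        placed <- placed + 1L
        rows[[length(rows) + 1L]] <- data.frame(
          seqid = ch, type = "miRNA", start = s, end = s + len - 1L,
          strand = "+", ID = paste0("mirna", placed),
          Parent = NA_character_, phase = NA_integer_,
          stringsAsFactors = FALSE)
        gaps$start[i] <- s + len + 25L
      }
    }
    if (placed < n_mirnas) {
      stop("configuration error: could not place all miRNAs", call. = FALSE)
    }

    model <- gene_model(do.call(rbind, rows))
    genome <- Biostrings::DNAStringSet(vapply(genome_chars, chars_seq,
                                              character(1)))
    names(genome) <- chrom_names
    list(model = model, genome = genome)
  })
}
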