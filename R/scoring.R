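#' PHRED-like log-rank transform of raw classifier scores
#'
#' Sorts raw scores in descending order, assigns ranks `i = 1..N` and the
#' score `-10 * log10(i / N)`: rank 1 (most deleterious) receives
#' `10 * log10(N)`, rank N receives 0, the top 1% lie at or above 20 and
#' the top 0.1% at or above 30. Tied raw scores all receive the rank of
#' the first element of the tied block (the minimum `i`), so equal raw
#' scores map to equal — and within the block maximal — transformed
#' scores.
#'
#' @param raw numeric vector of raw scores (all finite; `NaN` signals an
#'   upstream error).
#' @return object of class `score_ranking`: data.frame `raw`, `rank`,
#'   `phred` in the input order, with attribute `N`.
#' @export
phred_transform <- function(raw) {
  if (!length(raw)) stop("input error: no scores", call. = FALSE)
  if (any(!is.finite(raw))) {
    stop("upstream error: non-finite raw score", call. = FALSE)
  }
  n <- length(raw)
  # descending min-rank with ties sharing the first rank of their block
  rank_desc <- rank(-raw, ties.method = "min")
  phred <- -10 * log10(rank_desc / n)
  out <- data.frame(raw = raw, rank = rank_desc, phred = phred)
  attr(out, "N") <- n
  class(out) <- c("score_ranking", "data.frame")
  out
}

#' Percentile of a score within a reference set
#'
#' The fraction of reference scores strictly below the query, times 100.
#' @param score query score (scalar).
#' @param reference numeric vector (non-empty).
#' @export
percentile_of <- function(score, reference) {
  if (!length(reference)) {
    stop("input error: empty reference set", call. = FALSE)
  }
  100 * mean(reference < score)
}

#' Per-position summary of the three alternate-allele scores
#'
#' For genome-browser style tracks: the maximum, median, minimum and
#' standard deviation (population formula over the 3 values) of the
#' transformed scores at each position.
#'
#' @param scored data.frame `chrom`, `pos`, `alt`, `phred` with exactly 3
#'   alternates per position.
#' @return data.frame `chrom`, `pos`, `max`, `median`, `min`, `std` in
#'   coordinate order.
#' @export
summarize_positions <- function(scored) {
  key <- paste(scored$chrom, scored$pos)
  counts <- table(key)
  if (any(counts != 3L)) {
    stop("incomplete scoring: every position needs exactly 3 alternates",
         call. = FALSE)
  }
  scored <- scored[order(scored$chrom, scored$pos, scored$alt), ]
  idx <- seq(1L, nrow(scored), by = 3L)
  v <- matrix(scored$phred, nrow = 3L)
  pop_sd <- sqrt(colMeans(v^2) - colMeans(v)^2)
  data.frame(chrom = scored$chrom[idx], pos = scored$pos[idx],
             max = apply(v, 2, max), median = apply(v, 2, median),
             min = apply(v, 2, min), std = pop_sd)
}

#' Enumerate all possible SNVs over a genomic window
#'
#' @param genome `DNAStringSet`.
#' @param chrom chromosome name (default: all chromosomes).
#' @param start,end 1-based window bounds (default: whole chromosome).
#' @return data.frame `chrom`, `pos`, `ref`, `alt` with the three
#'   alternates per position in lexical order.
#' @export
enumerate_substitutions <- function(genome, chrom = names(genome),
                                    start = NULL, end = NULL) {
  out <- lapply(chrom, function(ch) {
    chars <- seq_chars(genome[[ch]])
    s <- start %||% 1L
    e <- end %||% length(chars)
    pos <- seq(s, e)
    ref <- chars[pos]
    keep <- ref %in% DNA_BASES
    pos <- pos[keep]; ref <- ref[keep]
    others <- rbind(A = c("C", "G", "T"), C = c("A", "G", "T"),
                    G = c("A", "C", "T"), T = c("A", "C", "G"))
    data.frame(chrom = ch, pos = rep(pos, each = 3L),
               ref = rep(ref, each = 3L),
               alt = as.vector(t(others[ref, , drop = FALSE])),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Write a coordinate-sorted score table (optionally bgzip + tabix)
#'
#' Columns: chrom, pos (1-based), ref, alt, raw, phred; user-facing scores
#' at 3 decimals. With `index = TRUE` the TSV is bgzip-compressed and
#' tabix-indexed via Rsamtools.
#'
#' @param scored data.frame `chrom`, `pos`, `ref`, `alt`, `raw`, `phred`.
#' @param path output TSV path (uncompressed name; `.bgz` is appended by
#'   the indexer).
#' @param index compress and index the output.
#' @return the path of the written file.
#' @export
write_score_table <- function(scored, path, index = FALSE) {
  scored <- scored[order(scored$chrom, scored$pos, scored$alt), ]
  out <- data.frame(chrom = scored$chrom, pos = scored$pos,
                    ref = scored$ref, alt = scored$alt,
                    raw = sprintf("%.6g", scored$raw),
                    phred = sprintf("%.3f", scored$phred))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (index) {
    bgz <- Rsamtools::bgzip(path, overwrite = TRUE)
    Rsamtools::indexTabix(bgz, seq = 1, start = 2, end = 2, skip = 1L)
    return(invisible(bgz))
  }
  invisible(path)
}

#' Write the four per-position summary tracks as bedGraph-style TSVs
#'
#' @param summaries output of [summarize_positions()].
#' @param dir output directory; files `max.tsv`, `median.tsv`, `min.tsv`,
#'   `std.tsv` are written.
#' @export
write_summary_tracks <- function(summaries, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (stat in c("max", "median", "min", "std")) {
    out <- data.frame(chrom = summaries$chrom,
                      start = summaries$pos - 1L,
                      end = summaries$pos,
                      value = sprintf("%.3f", summaries[[stat]]))
    write.table(out, file.path(dir, paste0(stat, ".tsv")), sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  invisible(dir)
}
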