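#' Generate synthetic conservation tracks and a tissue expression table
#'
#' Emulates per-position conservation scores (three tracks, standing in
#' for phyloP / phastCons / GERP-like inputs) as Gaussian noise with an
#' additive boost inside CDS intervals, plus configurable coverage gaps to
#' exercise downstream imputation. Also emits a per-gene, per-tissue
#' expression table with a designated housekeeping set: housekeeping genes
#' are expressed uniformly high in all tissues, every other gene is
#' expressed high only in its own assigned tissue.
#'
#' @param genome `DNAStringSet` (defines chromosomes and lengths).
#' @param model `gene_model` (CDS intervals get boosted conservation; genes
#'   receive expression values).
#' @param seed integer seed.
#' @param coverage fraction of positions covered, recycled over tracks; 1
#'   means no gaps.
#' @param cds_boost additive conservation boost inside CDS.
#' @param tissues character vector of tissue names.
#' @param n_housekeeping number of genes designated housekeeping.
#' @param expr_high,expr_low means of the expression values (arbitrary
#'   RMA-like units) for active and inactive gene/tissue combinations.
#' @return list with elements `tracks` (named list of data.frames `chrom`,
#'   `pos`, `value`), `expression` (data.frame `gene_id`, `tissue`,
#'   `value`), `gene_sets` (data.frame `gene_id`, `set_name`; housekeeping
#'   plus one set per tissue) and `housekeeping` (character vector).
#' @export
generate_tracks <- function(genome, model, seed = 1L,
                            coverage = c(phylop = 1, phastcons = 1, gerp = 1),
                            cds_boost = 1.5,
                            tissues = c("blood", "liver", "muscle", "neuronal"),
                            n_housekeeping = 2L,
                            expr_high = 400, expr_low = 20) {
  check_count(seed, "seed", min = 0)
  track_names <- names(coverage) %||% c("phylop", "phastcons", "gerp")
  if (is.null(names(coverage))) names(coverage) <- track_names
  for (v in coverage) check_fraction(v, "coverage", 0, 1, open = FALSE)

  withr::with_seed(seed, {
    cds <- model[model$type == "CDS", ]
    tracks <- lapply(track_names, function(tn) {
      out <- lapply(names(genome), function(ch) {
        n <- Biostrings::width(genome)[match(ch, names(genome))]
        value <- rnorm(n)
        in_cds <- rep(FALSE, n)
        ch_cds <- cds[cds$seqid == ch, ]
        for (i in seq_len(nrow(ch_cds))) {
          in_cds[seq(ch_cds$start[i], ch_cds$end[i])] <- TRUE
        }
        value[in_cds] <- value[in_cds] + cds_boost
        keep <- runif(n) <= coverage[[tn]]
        data.frame(chrom = ch, pos = which(keep), value = value[keep])
      })
      do.call(rbind, out)
    })
    names(tracks) <- track_names

    genes <- model$ID[model$type == "gene"]
    n_housekeeping <- min(n_housekeeping, length(genes))
    hk <- sample(genes, n_housekeeping)
    others <- setdiff(genes, hk)
    tissue_of <- setNames(sample(tissues, length(others), replace = TRUE),
                          others)
    expression <- do.call(rbind, lapply(genes, function(g) {
      mu <- if (g %in% hk) rep(expr_high, length(tissues)) else
        ifelse(tissues == tissue_of[[g]], expr_high, expr_low)
      data.frame(gene_id = g, tissue = tissues,
                 value = pmax(0, rnorm(length(tissues), mu, mu / 10)))
    }))
    gene_sets <- rbind(
      data.frame(gene_id = hk,
                 set_name = rep("housekeeping", length(hk))),
      data.frame(gene_id = others, set_name = unname(tissue_of)))
    list(tracks = tracks, expression = expression, gene_sets = gene_sets,
         housekeeping = hk)
  })
}

#' Write / read a per-position track as TSV (`chrom`, `pos`, `value`)
#' @param track data.frame with columns `chrom`, `pos` (1-based), `value`.
#' @param path file path.
#' @export
write_track <- function(track, path) {
  write.table(track[, c("chrom", "pos", "value")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_track
#' @export
read_track <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
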