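score_at <- function(site_scores, chrom, pos) {
  site_scores$score[match(paste(chrom, pos),
                          paste(site_scores$chrom, site_scores$pos))]
}

#' Codon-position score contrasts over single-transcript genes
#'
#' For every gene with exactly one annotated transcript, collects the
#' per-site score (conventionally the minimum over the three alternates)
#' at each CDS site, grouped by position within the codon, and runs the
#' six ordered one-tailed Mann-Whitney tests (each position tested for
#' higher scores than each other position). P-values are Bonferroni
#' corrected per comparison across genes. Genes whose CDS length is not
#' divisible by 3 are skipped with a warning.
#'
#' @param model a `gene_model`.
#' @param site_scores data.frame `chrom`, `pos`, `score` (per-site
#'   summary, minimum-of-alternates for this analysis).
#' @param alpha significance level on the adjusted p-value.
#' @return list with `counts` (3x3 matrix: entry \[smaller, larger\] = how
#'   many genes scored `larger` significantly above `smaller`) and
#'   `per_gene` (long data.frame of all tests).
#' @export
codon_position_tests <- function(model, site_scores, alpha = 0.05) {
  genes <- single_transcript_genes(model)
  res <- list()
  for (g in genes) {
    tx <- model$ID[model$type == "mRNA" & !is.na(model$Parent) &
                     model$Parent == g][1]
    gpos <- cds_positions(model, tx)
    if (length(gpos) %% 3L != 0L) {
      warning("gene ", g, " skipped: CDS length not divisible by 3")
      next
    }
    chrom <- tx_row(model, tx)$seqid
    codon_pos <- (seq_along(gpos) - 1L) %% 3L + 1L
    s <- score_at(site_scores, chrom, gpos)
    sets <- split(s[!is.na(s)], codon_pos[!is.na(s)])
    if (length(sets) < 3L || any(lengths(sets) < 2L)) next
    for (larger in 1:3) for (smaller in setdiff(1:3, larger)) {
      t <- mann_whitney_one_tailed(sets[[as.character(larger)]],
                                   sets[[as.character(smaller)]],
                                   "greater")
      t$gene <- g; t$larger <- larger; t$smaller <- smaller
      res[[length(res) + 1L]] <- t
    }
  }
  per_gene <- do.call(rbind, res)
  counts <- matrix(0L, 3, 3, dimnames = list(smaller = 1:3, larger = 1:3))
  diag(counts) <- NA_integer_
  if (!is.null(per_gene)) {
    for (larger in 1:3) for (smaller in setdiff(1:3, larger)) {
      sel <- per_gene$larger == larger & per_gene$smaller == smaller
      padj <- bonferroni(per_gene$p_value[sel])
      per_gene$p_adjusted[sel] <- padj
      counts[smaller, larger] <- sum(padj < alpha)
    }
  }
  list(counts = counts, per_gene = per_gene)
}

#' miRNA versus flanking-region score test
#'
#' Compares per-site scores (maximum over alternates) inside annotated
#' miRNA intervals against equally long sequences immediately up- and
#' downstream (pooled), globally and per miRNA (Bonferroni corrected).
#' Flanks extending past a contig edge are truncated with a message;
#' miRNAs overlapping any supplied training-variant position are excluded.
#'
#' @param model a `gene_model`.
#' @param site_scores data.frame `chrom`, `pos`, `score`.
#' @param chrom_lengths named integer vector (defaults to the maximum
#'   scored position per chromosome).
#' @param training_positions optional data.frame `chrom`, `pos` of
#'   training variants.
#' @param alpha significance level.
#' @return list with `global` (one-row test data.frame), `per_mirna`
#'   (per-miRNA tests with `p_adjusted` and `significant`), `n_excluded`.
#' @export
mirna_flank_test <- function(model, site_scores, chrom_lengths = NULL,
                             training_positions = NULL, alpha = 0.05) {
  mirna <- model[model$type == "miRNA", ]
  if (!nrow(mirna)) stop("input error: no miRNA annotations", call. = FALSE)
  if (is.null(chrom_lengths)) {
    chrom_lengths <- tapply(site_scores$pos, site_scores$chrom, max)
  }
  n_excluded <- 0L
  per <- list()
  mir_scores <- list(); flank_scores <- list()
  for (i in seq_len(nrow(mirna))) {
    ch <- mirna$seqid[i]
    s <- mirna$start[i]; e <- mirna$end[i]
    if (!is.null(training_positions)) {
      tp <- training_positions$pos[training_positions$chrom == ch]
      if (any(tp >= s & tp <= e)) {
        n_excluded <- n_excluded + 1L
        next
      }
    }
    len <- e - s + 1L
    up <- seq(max(1L, s - len), s - 1L)
    down_end <- min(chrom_lengths[[ch]], e + len)
    down <- if (e + 1L <= down_end) seq(e + 1L, down_end) else integer()
    if (length(up) < len || length(down) < len) {
      message("miRNA ", mirna$ID[i], ": flank truncated at contig edge")
    }
    ms <- score_at(site_scores, ch, seq(s, e))
    fs <- score_at(site_scores, ch, c(up, down))
    ms <- ms[!is.na(ms)]; fs <- fs[!is.na(fs)]
    if (!length(ms) || !length(fs)) next
    t <- mann_whitney_one_tailed(ms, fs, "greater")
    t$mirna <- mirna$ID[i]
    per[[length(per) + 1L]] <- t
    mir_scores[[length(mir_scores) + 1L]] <- ms
    flank_scores[[length(flank_scores) + 1L]] <- fs
  }
  if (!length(per)) stop("input error: no scorable miRNAs", call. = FALSE)
  per_mirna <- do.call(rbind, per)
  per_mirna$p_adjusted <- bonferroni(per_mirna$p_value)
  per_mirna$significant <- per_mirna$p_adjusted < alpha
  global <- mann_whitney_one_tailed(unlist(mir_scores), unlist(flank_scores),
                                    "greater")
  list(global = global, per_mirna = per_mirna, n_excluded = n_excluded)
}

#' Intron-position enrichment tests
#'
#' For each transcript with at least two introns and each intron ordinal
#' up to `max_position`, tests whether the intron's per-site scores are
#' higher than the pooled scores of all other introns of the same
#' transcript (one-tailed Mann-Whitney, Bonferroni corrected per ordinal
#' across transcripts). The number of possible tests decreases with the
#' ordinal, so rejected counts are also reported normalised by the number
#' of conducted tests.
#'
#' @param model a `gene_model`.
#' @param site_scores data.frame `chrom`, `pos`, `score`.
#' @param max_position largest intron ordinal tested.
#' @param alpha significance level.
#' @return data.frame `position`, `n_tests`, `n_significant`,
#'   `normalized`.
#' @export
intron_position_tests <- function(model, site_scores, max_position = 20L,
                                  alpha = 0.05) {
  txs <- transcripts(model)
  p_by_pos <- vector("list", max_position)
  for (tx in txs) {
    ints <- tx_introns(model, tx)
    if (nrow(ints) < 2L) next
    chrom <- tx_row(model, tx)$seqid
    scores <- lapply(order(ints$ordinal), function(k)
      score_at(site_scores, chrom, seq(ints$start[k], ints$end[k])))
    scores <- lapply(scores, function(s) s[!is.na(s)])
    for (j in seq_len(min(nrow(ints), max_position))) {
      x <- scores[[j]]
      y <- unlist(scores[-j])
      if (!length(x) || !length(y)) next
      p_by_pos[[j]] <- c(p_by_pos[[j]],
                         mann_whitney_one_tailed(x, y, "greater")$p_value)
    }
  }
  out <- do.call(rbind, lapply(seq_len(max_position), function(j) {
    p <- p_by_pos[[j]]
    n <- length(p)
    sig <- if (n) sum(bonferroni(p) < alpha) else 0L
    data.frame(position = j, n_tests = n, n_significant = sig,
               normalized = if (n) sig / n else NA_real_)
  }))
  out[out$n_tests > 0, , drop = FALSE]
}

# unique CDS intervals of a set of genes (a CDS present in more than one
# transcript is counted once)
unique_cds_sites <- function(model, genes) {
  tx <- model[model$type == "mRNA" & model$Parent %in% genes, ]
  cds <- model[model$type == "CDS" & model$Parent %in% tx$ID, ]
  cds <- cds[!duplicated(cds[, c("seqid", "start", "end")]), ]
  if (!nrow(cds)) return(data.frame(chrom = character(), pos = integer()))
  do.call(rbind, lapply(seq_len(nrow(cds)), function(i)
    data.frame(chrom = cds$seqid[i], pos = seq(cds$start[i], cds$end[i]))))
}

#' Tissue-specific versus housekeeping gene-set score tests
#'
#' Annotates the unique CDS sites of each gene set with per-site scores
#' (maximum over alternates) and tests each tissue set for *lower* scores
#' than the housekeeping set (one-tailed Mann-Whitney "tissue <
#' housekeeping", Bonferroni across tissues); the reverse tail is also
#' reported since some tissues score above housekeeping. The effect size
#' is the ROC-AUC of housekeeping versus tissue: values above 0.5 mean
#' housekeeping sites score higher.
#'
#' @param expression data.frame `gene_id`, `tissue`, `value`.
#' @param gene_sets data.frame `gene_id`, `set_name`; one set must be
#'   named `housekeeping`.
#' @param model a `gene_model`.
#' @param site_scores data.frame `chrom`, `pos`, `score`.
#' @param min_expression activity filter: a tissue gene is kept when its
#'   expression in its own tissue reaches this level, a housekeeping gene
#'   when its mean expression across tissues does.
#' @param alpha significance level.
#' @return data.frame per tissue: `tissue`, `n_genes`, `n_sites`,
#'   `p_less`, `p_less_adjusted`, `p_greater`, `p_greater_adjusted`,
#'   `auc_housekeeping`, `significant_lower`.
#' @export
tissue_vs_housekeeping <- function(expression, gene_sets, model,
                                   site_scores, min_expression = 100,
                                   alpha = 0.05) {
  if (!"housekeeping" %in% gene_sets$set_name) {
    stop("data error: no housekeeping set defined", call. = FALSE)
  }
  hk_genes <- gene_sets$gene_id[gene_sets$set_name == "housekeeping"]
  hk_mean <- tapply(expression$value, expression$gene_id, mean)
  hk_genes <- hk_genes[hk_genes %in% names(hk_mean)[hk_mean >=
                                                      min_expression]]
  if (!length(hk_genes)) {
    stop("data error: housekeeping set empty after expression filter",
         call. = FALSE)
  }
  hk_sites <- unique_cds_sites(model, hk_genes)
  hk_scores <- score_at(site_scores, hk_sites$chrom, hk_sites$pos)
  hk_scores <- hk_scores[!is.na(hk_scores)]

  tissues <- setdiff(unique(gene_sets$set_name), "housekeeping")
  rows <- list()
  for (ti in tissues) {
    genes <- gene_sets$gene_id[gene_sets$set_name == ti]
    expr_ti <- expression[expression$tissue == ti, ]
    active <- expr_ti$gene_id[expr_ti$value >= min_expression]
    genes <- intersect(genes, active)
    if (!length(genes)) {
      stop("data error: tissue set '", ti,
           "' empty after expression filter", call. = FALSE)
    }
    sites <- unique_cds_sites(model, genes)
    s <- score_at(site_scores, sites$chrom, sites$pos)
    s <- s[!is.na(s)]
    t_less <- mann_whitney_one_tailed(s, hk_scores, "less")
    t_greater <- mann_whitney_one_tailed(s, hk_scores, "greater")
    auc_hk <- mann_whitney_one_tailed(hk_scores, s, "greater")$effect_size
    rows[[length(rows) + 1L]] <- data.frame(
      tissue = ti, n_genes = length(genes), n_sites = length(s),
      p_less = t_less$p_value, p_greater = t_greater$p_value,
      auc_housekeeping = auc_hk)
  }
  out <- do.call(rbind, rows)
  out$p_less_adjusted <- bonferroni(out$p_less)
  out$p_greater_adjusted <- bonferroni(out$p_greater)
  out$significant_lower <- out$p_less_adjusted < alpha
  out[, c("tissue", "n_genes", "n_sites", "p_less", "p_less_adjusted",
          "p_greater", "p_greater_adjusted", "auc_housekeeping",
          "significant_lower")]
}

#' Rank segregating variants by score times allele frequency
#'
#' The prioritisation product is the PHRED-like score multiplied by the
#' alternate-allele frequency; the top `top_k` variants are returned with
#' both factors.
#'
#' @param variants data.frame with `phred` and `af` columns (plus any
#'   identifying columns, which are carried through).
#' @param top_k number of rows to return.
#' @return `variants` rows with an added `product` column, sorted
#'   descending by product, truncated to `top_k`.
#' @export
prioritize_segregating <- function(variants, top_k = 20L) {
  if (any(variants$af < 0 | variants$af > 1, na.rm = TRUE) ||
      anyNA(variants$af)) {
    stop("data error: allele frequency outside [0, 1]", call. = FALSE)
  }
  variants$product <- variants$phred * variants$af
  variants <- variants[order(-variants$product), , drop = FALSE]
  head(variants, top_k)
}
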