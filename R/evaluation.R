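#' ROC-AUC via the rank (Mann-Whitney) identity
#'
#' Equals `U / (n1 * n0)` where U counts positive/negative score pairs
#' with the positive scored higher, ties counting 1/2.
#'
#' @param scores numeric scores (higher = more positive-like).
#' @param labels 0/1 labels.
#' @return area in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  if (length(unique(labels)) < 2L) {
    stop("input error: both labels must be present", call. = FALSE)
  }
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' The six genomic evaluation subsets
#'
#' Membership predicates over consequence categories. `cDNA` covers every
#' transcribed consequence (coding categories plus UTRs, introns, splice
#' sites and non-coding transcripts); `not_cDNA` is its complement
#' (intergenic and gene-flank variants); `CDS` is the coding categories;
#' `cDNA_not_CDS` the transcribed non-coding remainder; `synonymous` and
#' `missense` the two coding extremes.
#'
#' @return named list of character vectors of categories.
#' @export
subset_specs <- function() {
  cds <- c("missense", "synonymous", "stop_gained", "stop_lost",
           "start_lost")
  cdna <- c(cds, "five_prime_utr", "three_prime_utr", "intron",
            "splice_donor", "splice_acceptor", "splice_region",
            "non_coding_transcript")
  list(all = names(consequence_hierarchy()),
       not_cDNA = c("intergenic", "upstream_downstream"),
       cDNA = cdna,
       cDNA_not_CDS = setdiff(cdna, cds),
       CDS = cds,
       synonymous = "synonymous",
       missense = "missense")
}

#' Per-subset evaluation report of a scored test set
#'
#' Partitions the test set by consequence category into the standard
#' genomic subsets and reports size, class proportions and ROC-AUC for
#' each (AUC is `NA` for subsets without both classes).
#'
#' @param test data.frame with `category`, `class` columns.
#' @param scores numeric scores aligned with `test` rows.
#' @param specs subset definitions, see [subset_specs()].
#' @return data.frame `subset`, `n`, `prop_of_test`, `n_simulated`,
#'   `n_derived`, `pct_simulated`, `pct_derived`, `auc`.
#' @export
evaluate_subsets <- function(test, scores, specs = subset_specs()) {
  stopifnot(nrow(test) == length(scores))
  rows <- lapply(names(specs), function(nm) {
    sel <- test$category %in% specs[[nm]]
    n <- sum(sel)
    n1 <- sum(test$class[sel] == 1)
    n0 <- n - n1
    auc <- if (n1 > 0 && n0 > 0) roc_auc(scores[sel], test$class[sel]) else
      NA_real_
    data.frame(subset = nm, n = n,
               prop_of_test = n / nrow(test),
               n_simulated = n1, n_derived = n0,
               pct_simulated = if (n > 0) 100 * n1 / n else NA_real_,
               pct_derived = if (n > 0) 100 * n0 / n else NA_real_,
               auc = auc)
  })
  do.call(rbind, rows)
}
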