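#' Estimate windowed CpG-aware substitution rates from ancestor pairs
#'
#' Counts inferred substitutions between gapless equal-length alignments of
#' an older and a younger ancestor sequence, in non-overlapping windows
#' tiling each chromosome, separately for CpG and non-CpG context (context
#' is taken on the older sequence: the C or G of a forward-strand CpG).
#' For each window, context and ordered base change X->Y the rate is the
#' substitution count divided by the number of aligned columns carrying X
#' in that context (the opportunity count), pooled over pairs. Windows with
#' zero opportunity yield `NA` rates, flagged for imputation from the
#' pooled genome-wide rate at simulation time.
#'
#' @param pairs list of `list(older = , younger = )` sequence sets (e.g.
#'   from [ancestor_pairs()]); all sequences of a chromosome must have
#'   equal length.
#' @param window_size tile width in bases (default 100000, i.e. 100 kb).
#' @return object of class `rate_table`: data.frame `chrom`,
#'   `window_start` (1-based), `context` (`CpG`/`nonCpG`), `ref`, `alt`,
#'   `count`, `opportunities`, `rate`.
#' @export
estimate_rates <- function(pairs, window_size = 100000L) {
  check_count(window_size, "window_size")
  if (!length(pairs)) stop("alignment error: no ancestor pairs", call. = FALSE)
  chroms <- names(pairs[[1]]$older)
  subs <- expand.grid(ref = DNA_BASES, alt = DNA_BASES,
                      stringsAsFactors = FALSE)
  subs <- subs[subs$ref != subs$alt, ]

  out <- list()
  for (ch in chroms) {
    n <- unique(vapply(pairs, function(p) {
      lo <- Biostrings::width(p$older)[match(ch, names(p$older))]
      ly <- Biostrings::width(p$younger)[match(ch, names(p$younger))]
      if (lo != ly) stop("alignment error: unequal sequence lengths for ",
                         ch, call. = FALSE)
      lo
    }, numeric(1)))
    if (length(n) != 1L) {
      stop("alignment error: pairs disagree on length of ", ch,
           call. = FALSE)
    }
    win_start <- seq(1L, n, by = window_size)
    win_id <- findInterval(seq_len(n), win_start)
    # accumulate counts over pairs
    acc <- NULL
    for (p in pairs) {
      older <- seq_chars(p$older[[ch]])
      younger <- seq_chars(p$younger[[ch]])
      ctx <- ifelse(cpg_context(older), "CpG", "nonCpG")
      opp <- as.data.frame(table(win = win_id, context = ctx, ref = older),
                           stringsAsFactors = FALSE)
      names(opp)[names(opp) == "Freq"] <- "opportunities"
      diff <- older != younger
      cnt <- as.data.frame(table(win = win_id[diff], context = ctx[diff],
                                 ref = older[diff], alt = younger[diff]),
                           stringsAsFactors = FALSE)
      names(cnt)[names(cnt) == "Freq"] <- "count"
      grid <- merge(expand.grid(win = unique(win_id),
                                context = c("CpG", "nonCpG"),
                                stringsAsFactors = FALSE),
                    subs)
      grid$win <- as.character(grid$win)
      m <- merge(grid, opp, all.x = TRUE)
      m <- merge(m, cnt, all.x = TRUE)
      m$opportunities[is.na(m$opportunities)] <- 0L
      m$count[is.na(m$count)] <- 0L
      if (is.null(acc)) {
        acc <- m
      } else {
        acc <- merge(acc, m, by = c("win", "context", "ref", "alt"),
                     suffixes = c("", ".new"))
        acc$opportunities <- acc$opportunities + acc$opportunities.new
        acc$count <- acc$count + acc$count.new
        acc <- acc[, c("win", "context", "ref", "alt", "opportunities",
                       "count")]
      }
    }
    acc$chrom <- ch
    acc$window_start <- win_start[as.integer(acc$win)]
    out[[ch]] <- acc[, c("chrom", "window_start", "context", "ref", "alt",
                         "count", "opportunities")]
  }
  rt <- do.call(rbind, out)
  rt$rate <- ifelse(rt$opportunities > 0, rt$count / rt$opportunities, NA_real_)
  rt <- rt[order(rt$chrom, rt$window_start, rt$context, rt$ref, rt$alt), ]
  rownames(rt) <- NULL
  attr(rt, "window_size") <- as.integer(window_size)
  class(rt) <- c("rate_table", "data.frame")
  rt
}

#' Pooled genome-wide rates of a rate table (used to impute empty windows)
#' @param rate_table a [estimate_rates()] result.
#' @return data.frame `context`, `ref`, `alt`, `rate`.
#' @export
pooled_rates <- function(rate_table) {
  agg <- stats::aggregate(cbind(count, opportunities) ~ context + ref + alt,
                          data = rate_table, FUN = sum)
  agg$rate <- ifelse(agg$opportunities > 0, agg$count / agg$opportunities, 0)
  agg
}

#' Configuration of the de novo variant simulator
#' @param n_variants number of SNVs to draw.
#' @param seed integer seed.
#' @param restrict_to_known_ancestral only simulate at sites whose oldest-
#'   ancestor allele is known (i.e. where the supplied mask is TRUE).
#' @export
simulator_config <- function(n_variants, seed = 1L,
                             restrict_to_known_ancestral = TRUE) {
  check_count(n_variants, "n_variants")
  check_count(seed, "seed", min = 0)
  structure(list(n_variants = as.integer(n_variants),
                 seed = as.integer(seed),
                 restrict_to_known_ancestral =
                   isTRUE(restrict_to_known_ancestral)),
            class = "simulator_config")
}

#' Simulate de novo SNVs (the proxy-deleterious class)
#'
#' Draws `n_variants` substitutions without replacement over eligible
#' `(site, alternate)` pairs, with sampling weight equal to the window- and
#' context-appropriate substitution rate for the host base at the site.
#' Rates in windows with no opportunity are imputed from the pooled
#' genome-wide rate. The simulated variants carry class label 1.
#'
#' @param rate_table a [estimate_rates()] result covering the host genome.
#' @param host `DNAStringSet`: the sequence variants are simulated on.
#' @param mask named list (per chromosome) of logical vectors marking sites
#'   with a known oldest-ancestor allele, or `NULL` for all-known.
#' @param config a [simulator_config()].
#' @param exclude optional data.frame `chrom`, `pos` of positions that may
#'   not receive simulated variants (e.g. the derived set).
#' @return data.frame `chrom`, `pos`, `ref`, `alt`, `class` (1).
#' @export
simulate_variants <- function(rate_table, host, mask = NULL, config,
                              exclude = NULL) {
  stopifnot(inherits(config, "simulator_config"))
  window_size <- attr(rate_table, "window_size") %||% 100000L
  pooled <- pooled_rates(rate_table)

  rate_of <- function(chrom, win_start, context, ref, alt) {
    # vectorised lookup with pooled-rate fallback for NA/absent windows
    key <- paste(chrom, win_start, context, ref, alt)
    tab_key <- paste(rate_table$chrom, rate_table$window_start,
                     rate_table$context, rate_table$ref, rate_table$alt)
    r <- rate_table$rate[match(key, tab_key)]
    miss <- is.na(r)
    if (any(miss)) {
      pool_key <- paste(pooled$context, pooled$ref, pooled$alt)
      r[miss] <- pooled$rate[match(paste(context, ref, alt)[miss], pool_key)]
      r[is.na(r)] <- 0
    }
    r
  }

  cand <- list()
  for (ch in names(host)) {
    chars <- seq_chars(host[[ch]])
    known <- if (config$restrict_to_known_ancestral && !is.null(mask)) {
      mask[[ch]]
    } else {
      rep(TRUE, length(chars))
    }
    ok <- known & chars %in% DNA_BASES
    if (!is.null(exclude)) {
      ok[exclude$pos[exclude$chrom == ch]] <- FALSE
    }
    pos <- which(ok)
    if (!length(pos)) next
    ctx <- ifelse(cpg_context(chars), "CpG", "nonCpG")[pos]
    ref <- chars[pos]
    win <- (findInterval(pos, seq(1L, length(chars), by = window_size)) - 1L) *
      window_size + 1L
    # three alternates per site
    others <- rbind(A = c("C", "G", "T"), C = c("A", "G", "T"),
                    G = c("A", "C", "T"), T = c("A", "C", "G"))
    alt <- lapply(1:3, function(k) others[ref, k])
    for (k in 1:3) {
      cand[[length(cand) + 1L]] <- data.frame(
        chrom = ch, pos = pos, ref = ref, alt = alt[[k]],
        weight = rate_of(ch, win, ctx, ref, alt[[k]]),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(cand)) {
    stop("capacity error: no eligible sites to simulate from", call. = FALSE)
  }
  cand <- do.call(rbind, cand)
  cand <- cand[cand$weight > 0, , drop = FALSE]
  if (nrow(cand) < config$n_variants) {
    stop("capacity error: requested ", config$n_variants,
         " variants but only ", nrow(cand),
         " eligible (site, alternate) combinations", call. = FALSE)
  }
  idx <- withr::with_seed(config$seed,
                          sample.int(nrow(cand), config$n_variants,
                                     prob = cand$weight))
  out <- cand[idx, c("chrom", "pos", "ref", "alt")]
  out$class <- 1L
  out <- out[order(out$chrom, out$pos, out$alt), ]
  rownames(out) <- NULL
  out
}

#' Downsample the simulated class to match the derived class size
#'
#' The training design is class-balanced: as many simulated as derived
#' variants enter the dataset.
#' @param derived,simulated variant data.frames with a `class` column.
#' @param seed integer seed.
#' @return combined data.frame with balanced classes.
#' @export
balance_classes <- function(derived, simulated, seed = 1L) {
  n <- nrow(derived)
  if (nrow(simulated) < n) {
    stop("capacity error: fewer simulated than derived variants",
         call. = FALSE)
  }
  keep <- withr::with_seed(seed, sample.int(nrow(simulated), n))
  cols <- c("chrom", "pos", "ref", "alt", "class")
  out <- rbind(derived[, cols], simulated[keep, cols])
  rownames(out) <- NULL
  out
}
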