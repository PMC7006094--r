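#' Specification of a synthetic reference genome
#'
#' @param n_chromosomes number of chromosomes to generate.
#' @param chrom_length length of every chromosome in bases.
#' @param gc_content target GC fraction, strictly between 0 and 1 except for
#'   the degenerate values 0 and 1 which produce AT-only / GC-only sequence.
#' @param seed integer seed; generation is a pure function of the spec.
#' @return an object of class `genome_spec`.
#' @export
synthetic_genome_spec <- function(n_chromosomes = 1L, chrom_length = 10000L,
                                  gc_content = 0.42, seed = 1L) {
  check_count(n_chromosomes, "n_chromosomes")
  check_count(chrom_length, "chrom_length")
  check_fraction(gc_content, "gc_content", 0, 1, open = FALSE)
  check_count(seed, "seed", min = 0)
  structure(list(n_chromosomes = as.integer(n_chromosomes),
                 chrom_length = as.integer(chrom_length),
                 gc_content = gc_content, seed = as.integer(seed)),
            class = "genome_spec")
}

#' Generate a synthetic reference genome
#'
#' Draws i.i.d. bases with `P(G) = P(C) = gc_content / 2` and
#' `P(A) = P(T) = (1 - gc_content) / 2`, so the realised GC fraction of a
#' chromosome is binomially distributed around the target.
#'
#' @param spec a [synthetic_genome_spec()].
#' @return a named [Biostrings::DNAStringSet] (`chr1`, `chr2`, ...).
#' @export
generate_reference <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  gc <- spec$gc_content
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seqs <- withr::with_seed(spec$seed, {
    vapply(seq_len(spec$n_chromosomes), function(i) {
      chars_seq(sample(DNA_BASES, spec$chrom_length, replace = TRUE,
                       prob = probs))
    }, character(1))
  })
  names(seqs) <- paste0("chr", seq_len(spec$n_chromosomes))
  Biostrings::DNAStringSet(seqs)
}

#' Ancestor chain with per-branch substitution probabilities
#'
#' Describes a chain of increasingly distant ancestors of the reference;
#' node `i` evolves from node `i - 1` (the first node from the reference)
#' with the given per-site substitution probability. CpG-context sites
#' (the C and the G of a forward-strand CpG on the parent sequence) mutate
#' at `cpg_multiplier` times the branch probability.
#'
#' @param branch_probs named numeric vector of per-branch substitution
#'   probabilities, each in `[0, 0.5)`; names become the ancestor names.
#' @param cpg_multiplier hypermutability ratio for CpG-context sites, >= 1.
#' @return an object of class `ancestor_tree`.
#' @export
ancestor_tree <- function(branch_probs = c(anc_close = 0.01, anc_mid1 = 0.02,
                                           anc_mid2 = 0.04, anc_far = 0.06),
                          cpg_multiplier = 4) {
  if (is.null(names(branch_probs)) || any(names(branch_probs) == "")) {
    stop("configuration error: branch_probs must be a named vector",
         call. = FALSE)
  }
  for (p in branch_probs) check_fraction(p, "branch_probs", 0, 0.5, open = FALSE)
  if (any(branch_probs >= 0.5)) {
    stop("configuration error: branch probabilities must be < 0.5",
         call. = FALSE)
  }
  if (!is.numeric(cpg_multiplier) || cpg_multiplier < 1) {
    stop("configuration error: cpg_multiplier must be >= 1", call. = FALSE)
  }
  structure(list(branch_probs = branch_probs,
                 cpg_multiplier = cpg_multiplier),
            class = "ancestor_tree")
}

#' Evolve a chain of ancestor sequences from a reference
#'
#' Applies SNV-only evolution along the ancestor chain: sequence length is
#' conserved, each non-CpG site mutates with the branch probability, CpG
#' context sites with `min(1, multiplier * p)`, and the mutated base is
#' uniform over the three alternatives. CpG context is determined on the
#' parent sequence at mutation time.
#'
#' @param reference a [Biostrings::DNAStringSet].
#' @param tree an [ancestor_tree()].
#' @param seed integer seed.
#' @return named list of [Biostrings::DNAStringSet], one per ancestor node,
#'   ordered from closest to most distant.
#' @export
evolve_ancestors <- function(reference, tree, seed = 1L) {
  stopifnot(inherits(tree, "ancestor_tree"))
  check_count(seed, "seed", min = 0)
  withr::with_seed(seed, {
    parent <- reference
    out <- list()
    for (node in names(tree$branch_probs)) {
      p <- tree$branch_probs[[node]]
      child <- Biostrings::DNAStringSet(vapply(seq_along(parent), function(i) {
        chars <- seq_chars(parent[[i]])
        p_site <- rep(p, length(chars))
        p_site[cpg_context(chars)] <- pmin(1, tree$cpg_multiplier * p)
        hit <- runif(length(chars)) < p_site
        if (any(hit)) chars[hit] <- random_other_base(chars[hit])
        chars_seq(chars)
      }, character(1)))
      names(child) <- names(parent)
      out[[node]] <- child
      parent <- child
    }
    out
  })
}

#' Gapless ancestor-pair alignments for rate estimation
#'
#' Pairs each of the more distant ancestors (older) with the closest
#' ancestor (younger), the configuration used to estimate substitution
#' rates along the lineage leading to the study species.
#'
#' @param ancestors list returned by [evolve_ancestors()].
#' @param younger name of the younger node (default: the first).
#' @param older names of older nodes (default: all others).
#' @return list of `list(older = , younger = )` pairs of `DNAStringSet`s.
#' @export
ancestor_pairs <- function(ancestors, younger = names(ancestors)[1],
                           older = setdiff(names(ancestors), younger)) {
  lapply(older, function(o) list(older = ancestors[[o]],
                                 younger = ancestors[[younger]]))
}
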