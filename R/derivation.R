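#' Configuration of the derived-variant (proxy benign/neutral) selection
#'
#' @param high_af_threshold a population allele qualifies as (nearly) fixed
#'   when its frequency is strictly greater than this (default 0.9).
#' @param ancestral_af_ceiling a site is removed when an allele equal to
#'   the ancestral allele segregates at a frequency strictly greater than
#'   this (default 0.05).
#' @param adjacency_exclusion drop sites with another variant site at
#'   distance exactly 1 bp (guards against alignment artefacts near
#'   indels).
#' @param adjacent_includes_segregating whether segregating population
#'   sites (not only fixed differences) count as "another variant site".
#' @return object of class `derivation_config`.
#' @export
derivation_config <- function(high_af_threshold = 0.9,
                              ancestral_af_ceiling = 0.05,
                              adjacency_exclusion = TRUE,
                              adjacent_includes_segregating = TRUE) {
  check_fraction(high_af_threshold, "high_af_threshold")
  check_fraction(ancestral_af_ceiling, "ancestral_af_ceiling")
  if (!(ancestral_af_ceiling < high_af_threshold)) {
    stop("configuration error: ancestral_af_ceiling must be below ",
         "high_af_threshold", call. = FALSE)
  }
  structure(list(high_af_threshold = high_af_threshold,
                 ancestral_af_ceiling = ancestral_af_ceiling,
                 adjacency_exclusion = isTRUE(adjacency_exclusion),
                 adjacent_includes_segregating =
                   isTRUE(adjacent_includes_segregating)),
            class = "derivation_config")
}

ancestral_base_at <- function(ancestor, chrom, pos) {
  if (!chrom %in% names(ancestor)) {
    stop("data-consistency error: chromosome ", chrom,
         " absent from ancestor sequence", call. = FALSE)
  }
  n <- Biostrings::width(ancestor)[match(chrom, names(ancestor))]
  if (any(pos < 1L | pos > n)) {
    stop("data-consistency error: site outside ancestor coverage",
         call. = FALSE)
  }
  toupper(substring(as.character(ancestor[[chrom]]), pos, pos))
}

#' Select derived (proxy benign/neutral) variants
#'
#' Compares population allele frequencies against the closest inferred
#' ancestral sequence and keeps the sites where a (nearly) fixed population
#' allele differs from the ancestral allele:
#'
#' 1. the ancestral allele must be known (A/C/G/T; `N` is unknown,
#'    lowercase soft-masked bases are accepted);
#' 2. the population's major allele must have frequency strictly above
#'    `high_af_threshold` and differ from the ancestral allele;
#' 3. sites where an allele equal to the ancestral allele segregates at a
#'    frequency strictly above `ancestral_af_ceiling` are removed;
#' 4. with `adjacency_exclusion`, sites with another variant site
#'    (polymorphic population site or population-vs-ancestor fixed
#'    difference) at distance 1 bp are removed.
#'
#' Multi-allelic sites (several records at one position) are skipped with a
#' warning. Non-SNV records are a format error.
#'
#' @param sites population site table: data.frame `chrom`, `pos`, `ref`,
#'   `alt`, `af` (alternate-allele frequency).
#' @param ancestor closest-ancestor `DNAStringSet`.
#' @param config a [derivation_config()].
#' @param reference optional reference `DNAStringSet`; when supplied,
#'   positions where reference and ancestor disagree also count as variant
#'   sites for the adjacency rule even if absent from `sites`.
#' @return data.frame `chrom`, `pos`, `ref` (ancestral allele), `alt`
#'   (derived allele), `af` (derived-allele frequency), `class` (0).
#' @export
find_derived_variants <- function(sites, ancestor, config = derivation_config(),
                                  reference = NULL) {
  stopifnot(inherits(config, "derivation_config"))
  needed <- c("chrom", "pos", "ref", "alt", "af")
  if (!all(needed %in% names(sites))) {
    stop("format error: site table must have columns ",
         paste(needed, collapse = ", "), call. = FALSE)
  }
  sites$ref <- toupper(sites$ref)
  sites$alt <- toupper(sites$alt)
  if (any(nchar(sites$ref) != 1L | nchar(sites$alt) != 1L) ||
      any(!sites$ref %in% DNA_BASES) || any(!sites$alt %in% DNA_BASES)) {
    stop("format error: non-SNV record in site table", call. = FALSE)
  }
  key <- paste(sites$chrom, sites$pos)
  multi <- duplicated(key) | duplicated(key, fromLast = TRUE)
  if (any(multi)) {
    warning(sum(multi), " records at multi-allelic sites skipped")
    sites <- sites[!multi, , drop = FALSE]
  }

  anc <- vapply(seq_len(nrow(sites)), function(i)
    ancestral_base_at(ancestor, sites$chrom[i], sites$pos[i]), character(1))
  known <- anc %in% DNA_BASES

  major <- ifelse(sites$af > 0.5, sites$alt, sites$ref)
  major_af <- pmax(sites$af, 1 - sites$af)
  minor <- ifelse(sites$af > 0.5, sites$ref, sites$alt)
  minor_af <- 1 - major_af

  # strict threshold comparisons with a small tolerance so that
  # frequencies landing exactly on a threshold (up to floating-point
  # representation error) are not counted as exceeding it
  eps <- 1e-9
  keep <- known &
    major_af > config$high_af_threshold + eps &
    major != anc &
    !(minor_af > config$ancestral_af_ceiling + eps & minor == anc)

  if (config$adjacency_exclusion) {
    variant_pos <- if (config$adjacent_includes_segregating) {
      split(sites$pos, sites$chrom)
    } else {
      split(sites$pos[keep], sites$chrom[keep])
    }
    if (!is.null(reference)) {
      for (ch in names(ancestor)) {
        if (!ch %in% names(reference)) next
        rc <- seq_chars(reference[[ch]])
        ac <- seq_chars(ancestor[[ch]])
        n <- min(length(rc), length(ac))
        mism <- which(rc[seq_len(n)] != ac[seq_len(n)] &
                        ac[seq_len(n)] %in% DNA_BASES)
        variant_pos[[ch]] <- c(variant_pos[[ch]], mism)
      }
    }
    adjacent <- vapply(seq_len(nrow(sites)), function(i) {
      vp <- variant_pos[[sites$chrom[i]]]
      any(vp == sites$pos[i] - 1L | vp == sites$pos[i] + 1L)
    }, logical(1))
    keep <- keep & !adjacent
  }

  out <- data.frame(chrom = sites$chrom[keep], pos = sites$pos[keep],
                    ref = anc[keep],
                    alt = major[keep],
                    af = major_af[keep],
                    class = rep(0L, sum(keep)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$chrom, out$pos), , drop = FALSE]
}
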