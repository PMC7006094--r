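#' Specification of a synthetic population variant set
#'
#' The generator emits biallelic SNV sites with allele frequencies on a
#' grid of `1 / (2 * n_individuals)`, in three ground-truth categories that
#' straddle the derivation thresholds:
#'
#' * `fixed_derived`: the alternate (non-ancestral) allele is (nearly) fixed
#'   -- frequency > 0.9 -- and the residual ancestral allele segregates at
#'   <= 0.05, so the site qualifies as proxy benign/neutral.
#' * `ancestral_minor`: the alternate allele has frequency in (0.9, 0.95),
#'   leaving the ancestral allele above the 0.05 ceiling; the site is a
#'   designed casualty of the ancestral-frequency removal rule.
#' * `segregating`: alternate frequency in (0.05, 0.9]; an ordinary
#'   polymorphism, and a "variant site" for adjacency exclusion.
#'
#' @param n_sites total number of sites to emit.
#' @param frac_fixed_derived,frac_ancestral_minor fractions of sites in the
#'   first two categories (the remainder is `segregating`).
#' @param n_individuals number of diploid individuals the allele-frequency
#'   grid emulates (>= 2).
#' @param seed integer seed.
#' @return an object of class `population_spec`.
#' @export
population_spec <- function(n_sites = 200L, frac_fixed_derived = 0.4,
                            frac_ancestral_minor = 0.1,
                            n_individuals = 48L, seed = 1L) {
  check_count(n_sites, "n_sites")
  check_fraction(frac_fixed_derived, "frac_fixed_derived", 0, 1, open = FALSE)
  check_fraction(frac_ancestral_minor, "frac_ancestral_minor", 0, 1,
                 open = FALSE)
  if (frac_fixed_derived + frac_ancestral_minor > 1) {
    stop("configuration error: category fractions exceed 1", call. = FALSE)
  }
  check_count(n_individuals, "n_individuals", min = 2)
  check_count(seed, "seed", min = 0)
  structure(list(n_sites = as.integer(n_sites),
                 frac_fixed_derived = frac_fixed_derived,
                 frac_ancestral_minor = frac_ancestral_minor,
                 n_individuals = as.integer(n_individuals),
                 seed = as.integer(seed)),
            class = "population_spec")
}

# allele-count windows for each truth category, on a 2N grid with strict
# thresholds (> 0.9 fixed; ancestral residue > 0.05 for removal)
category_count_range <- function(category, two_n) {
  switch(category,
    fixed_derived = {
      lo <- ceiling(0.95 * two_n)           # residual ancestral <= 0.05
      if (lo / two_n <= 0.9) lo <- floor(0.9 * two_n) + 1L
      c(lo, two_n)
    },
    ancestral_minor = {
      lo <- floor(0.9 * two_n) + 1L          # af > 0.9
      hi <- ceiling(0.95 * two_n) - 1L       # ancestral residue > 0.05
      c(lo, hi)
    },
    segregating = {
      lo <- floor(0.05 * two_n) + 1L         # af > 0.05
      hi <- floor(0.9 * two_n)               # af <= 0.9
      c(lo, hi)
    },
    stop("unknown category: ", category))
}

#' Generate a synthetic population variant table
#'
#' Sites are placed at positions where the supplied ancestor agrees with
#' the reference (so the VCF REF allele is also the ancestral allele) and
#' carry ground-truth category labels sufficient to compute the exact
#' expected output of the derivation step.
#'
#' @param reference the reference genome (`DNAStringSet`).
#' @param ancestor the closest-ancestor sequence set (`DNAStringSet`).
#' @param spec a [population_spec()].
#' @return data.frame with columns `chrom`, `pos`, `ref`, `alt`, `af`
#'   (alternate-allele frequency), `truth`.
#' @export
generate_population <- function(reference, ancestor, spec) {
  stopifnot(inherits(spec, "population_spec"))
  two_n <- 2L * spec$n_individuals
  if (category_count_range("ancestral_minor", two_n)[1] >
      category_count_range("ancestral_minor", two_n)[2] &&
      spec$frac_ancestral_minor > 0) {
    stop("configuration error: n_individuals too small to represent ",
         "frequencies between 0.9 and 0.95", call. = FALSE)
  }
  n_fixed <- round(spec$n_sites * spec$frac_fixed_derived)
  n_minor <- round(spec$n_sites * spec$frac_ancestral_minor)
  n_seg <- spec$n_sites - n_fixed - n_minor
  withr::with_seed(spec$seed, {
    per_chrom <- table(sample(names(reference), spec$n_sites, replace = TRUE))
    out <- list()
    for (chrom in names(per_chrom)) {
      n_here <- per_chrom[[chrom]]
      ref_chars <- seq_chars(reference[[chrom]])
      anc_chars <- seq_chars(ancestor[[chrom]])
      eligible <- which(ref_chars == anc_chars & ref_chars %in% DNA_BASES)
      if (length(eligible) < n_here) {
        stop("configuration error: not enough ancestrally conserved sites",
             call. = FALSE)
      }
      pos <- sort(sample(eligible, n_here))
      out[[chrom]] <- data.frame(chrom = chrom, pos = pos,
                                 ref = ref_chars[pos],
                                 stringsAsFactors = FALSE)
    }
    sites <- do.call(rbind, out)
    rownames(sites) <- NULL
    truth <- sample(rep(c("fixed_derived", "ancestral_minor", "segregating"),
                        c(n_fixed, n_minor, n_seg)))
    sites$alt <- random_other_base(sites$ref)
    counts <- vapply(truth, function(cat) {
      rng <- category_count_range(cat, two_n)
      if (rng[1] > rng[2]) stop("configuration error: empty frequency window",
                                call. = FALSE)
      window <- seq(rng[1], rng[2])
      window[sample.int(length(window), 1L)]
    }, integer(1), USE.NAMES = FALSE)
    sites$af <- counts / two_n
    sites$truth <- truth
    sites[order(sites$chrom, sites$pos), , drop = FALSE]
  })
}
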