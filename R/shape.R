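SHAPE_PARAMS <- c("mgw", "roll", "prot", "helt")

#' Deterministic synthetic pentamer shape table
#'
#' Stand-in lookup mapping every DNA pentamer to four structural
#' parameters (minor groove width, roll, propeller twist, helix twist).
#' The values are synthetic: a fixed deterministic function of the
#' pentamer (seeded from its base composition and sequence), not measured
#' DNA-shape data. They provide a complete, reproducible table with the
#' right interface so that shape-delta features can be computed and
#' tested; substitute a real pentamer table for production use.
#'
#' @return data.frame `pentamer`, `mgw`, `roll`, `prot`, `helt`.
#' @export
synthetic_shape_table <- function() {
  g <- expand.grid(b5 = DNA_BASES, b4 = DNA_BASES, b3 = DNA_BASES,
                   b2 = DNA_BASES, b1 = DNA_BASES,
                   stringsAsFactors = FALSE)
  pent <- paste0(g$b1, g$b2, g$b3, g$b4, g$b5)
  code <- vapply(strsplit(pent, ""), function(b)
    sum((match(b, DNA_BASES) - 1) * 4^(0:4)), numeric(1))
  # smooth deterministic pseudo-values in plausible ranges per parameter
  data.frame(
    pentamer = pent,
    mgw = 4.0 + 2.0 * (sin(code * 0.37) + 1) / 2,
    roll = -5 + 10 * (sin(code * 0.11 + 1) + 1) / 2,
    prot = -12 + 8 * (sin(code * 0.53 + 2) + 1) / 2,
    helt = 31 + 6 * (sin(code * 0.29 + 3) + 1) / 2)
}

#' Shape delta between reference and alternate sequence context
#'
#' Slides a pentamer window over each context, averages the looked-up
#' shape parameters, and returns the alternate-minus-reference difference
#' per parameter. Contexts must be equal-length windows centred on the
#' variant (length >= 5). A context containing a base outside A/C/G/T, or
#' a pentamer absent from the lookup, makes all four deltas missing.
#'
#' @param ref_context,alt_context character scalars.
#' @param lookup a pentamer table as from [synthetic_shape_table()].
#' @return named numeric vector `mgw_delta`, `roll_delta`, `prot_delta`,
#'   `helt_delta` (all `NA` when undefined).
#' @export
shape_delta <- function(ref_context, alt_context,
                        lookup = synthetic_shape_table()) {
  missing_out <- setNames(rep(NA_real_, 4), paste0(SHAPE_PARAMS, "_delta"))
  if (nchar(ref_context) != nchar(alt_context)) {
    stop("shape contexts must have equal length", call. = FALSE)
  }
  if (nchar(ref_context) < 5L) return(missing_out)
  mean_shape <- function(ctx) {
    ctx <- toupper(ctx)
    if (grepl("[^ACGT]", ctx)) return(NULL)
    n <- nchar(ctx)
    pents <- substring(ctx, 1:(n - 4L), 5:n)
    idx <- match(pents, lookup$pentamer)
    if (anyNA(idx)) return(NULL)
    colMeans(lookup[idx, SHAPE_PARAMS, drop = FALSE])
  }
  r <- mean_shape(ref_context)
  a <- mean_shape(alt_context)
  if (is.null(r) || is.null(a)) return(missing_out)
  setNames(as.numeric(a - r), paste0(SHAPE_PARAMS, "_delta"))
}

#' Extract the sequence context around a variant and its alternate version
#'
#' @param genome `DNAStringSet`.
#' @param chrom,pos,alt variant fields (vectorised).
#' @param width odd context width (default 9 giving five pentamer
#'   windows); positions closer than `width %/% 2` to a contig edge yield
#'   `NA` contexts.
#' @return data.frame `ref_context`, `alt_context`.
#' @export
variant_context <- function(genome, chrom, pos, alt, width = 9L) {
  stopifnot(width %% 2 == 1, width >= 5)
  half <- width %/% 2L
  n <- length(pos)
  ref_ctx <- rep(NA_character_, n)
  alt_ctx <- rep(NA_character_, n)
  for (ch in unique(chrom)) {
    sel <- which(chrom == ch)
    s <- as.character(genome[[ch]])
    len <- nchar(s)
    ok <- pos[sel] - half >= 1L & pos[sel] + half <= len
    i <- sel[ok]
    ref_ctx[i] <- substring(s, pos[i] - half, pos[i] + half)
    alt_ctx[i] <- ref_ctx[i]
    substr(alt_ctx[i], half + 1L, half + 1L) <- alt[i]
  }
  data.frame(ref_context = ref_ctx, alt_context = alt_ctx,
             stringsAsFactors = FALSE)
}
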