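DNA_BASES <- c("A", "C", "G", "T")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Split a sequence into a character vector of single bases
#' @noRd
seq_chars <- function(x) {
  strsplit(toupper(as.character(x)), "", fixed = TRUE)[[1]]
}

chars_seq <- function(x) paste(x, collapse = "")

complement_chars <- function(x) chartr("ACGTN", "TGCAN", x)

revcomp <- function(x) chars_seq(rev(complement_chars(seq_chars(x))))

#' CpG-context positions of a sequence
#'
#' A position is in CpG context when it is the C or the G of a 5'-CG-3'
#' dinucleotide on the forward strand; both members of the pair count.
#' @param chars character vector of single bases
#' @return logical vector, one entry per position
#' @noRd
cpg_context <- function(chars) {
  n <- length(chars)
  is_c <- chars == "C"
  is_g <- chars == "G"
  c_of_cg <- is_c & c(is_g[-1], FALSE)   # C followed by G
  g_of_cg <- is_g & c(FALSE, is_c[-n])   # G preceded by C
  c_of_cg | g_of_cg
}

#' Draw, for each reference base, a uniformly random different base
#' @noRd
random_other_base <- function(ref) {
  vapply(ref, function(b) sample(setdiff(DNA_BASES, b), 1L), character(1),
         USE.NAMES = FALSE)
}

#' Check that a value is a single finite number inside a range
#' @noRd
check_fraction <- function(x, name, lo = 0, hi = 1, open = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (open) x > lo && x < hi else x >= lo && x <= hi)
  if (!ok) {
    stop(sprintf("configuration error: `%s` must be a number in %s%g, %g%s",
                 name, if (open) "(" else "[", lo, hi,
                 if (open) ")" else "]"), call. = FALSE)
  }
  invisible(x)
}

check_count <- function(x, name, min = 1) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    x == as.integer(x) && x >= min
  if (!ok) {
    stop(sprintf("configuration error: `%s` must be an integer >= %d",
                 name, min), call. = FALSE)
  }
  invisible(as.integer(x))
}
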