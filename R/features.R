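#' Look up per-position track values for variants
#'
#' @param variants data.frame with `chrom`, `pos`.
#' @param tracks named list of data.frames `chrom`, `pos`, `value`.
#' @return data.frame with one numeric column per track; positions in a
#'   coverage gap are `NA` (missing is a value, not an error).
#' @export
annotate_tracks <- function(variants, tracks) {
  out <- lapply(names(tracks), function(tn) {
    tr <- tracks[[tn]]
    tr$value[match(paste(variants$chrom, variants$pos),
                   paste(tr$chrom, tr$pos))]
  })
  names(out) <- names(tracks)
  as.data.frame(out)
}

#' Feature-building configuration
#'
#' @param flank_size,splice passed to the consequence classifier.
#' @param context_width context width for shape deltas.
#' @param track_impute value imputed for missing conservation-track
#'   entries (0 = neutral, the CADD-family convention).
#' @export
feature_config <- function(flank_size = 1000L, splice = splice_windows(),
                           context_width = 9L, track_impute = 0) {
  list(flank_size = flank_size, splice = splice,
       context_width = context_width, track_impute = track_impute)
}

#' Build the numeric feature matrix for a variant set
#'
#' Composes consequence category (one-hot over the training-observed
#' levels), Grantham distance, DNA-shape deltas and conservation-track
#' values into a numeric matrix, then imputes missing values (tracks to
#' `track_impute`, other numeric columns to the training median) adding a
#' paired was-missing indicator per imputable column, and finally scales
#' every non-constant column by its training standard deviation.
#'
#' When `catalogue` is `NULL` the function fits imputation values, scaling
#' divisors and category levels on the supplied variants (training mode)
#' and returns them in the catalogue; passing a stored catalogue reuses
#' the training parameters so scoring-time rows see no leakage. A
#' scoring-time category unseen in training maps to all-zero indicators
#' with a warning.
#'
#' @param variants data.frame `chrom`, `pos`, `ref`, `alt`.
#' @param model,genome gene model and genome for consequence calls.
#' @param tracks named list of per-position tracks.
#' @param shape_table pentamer lookup (NULL disables shape features).
#' @param catalogue a catalogue from a previous (training) call, or NULL.
#' @param config a [feature_config()].
#' @return object of class `feature_matrix`: list with `x` (numeric
#'   matrix), `catalogue`, `variants` (annotated).
#' @export
build_feature_matrix <- function(variants, model, genome, tracks,
                                 shape_table = synthetic_shape_table(),
                                 catalogue = NULL,
                                 config = feature_config()) {
  ann <- annotate_consequence(variants, model, genome,
                              flank_size = config$flank_size,
                              splice = config$splice)
  raw <- data.frame(row.names = seq_len(nrow(ann)))
  raw$grantham <- grantham(ann$ref_aa, ann$alt_aa)
  if (!is.null(shape_table)) {
    ctx <- variant_context(genome, ann$chrom, ann$pos, ann$alt,
                           width = config$context_width)
    sh <- t(vapply(seq_len(nrow(ctx)), function(i) {
      if (is.na(ctx$ref_context[i])) {
        setNames(rep(NA_real_, 4), paste0(SHAPE_PARAMS, "_delta"))
      } else {
        shape_delta(ctx$ref_context[i], ctx$alt_context[i], shape_table)
      }
    }, numeric(4)))
    raw <- cbind(raw, as.data.frame(sh))
  }
  trk <- annotate_tracks(ann, tracks)
  track_cols <- names(trk)
  raw <- cbind(raw, trk)

  fitting <- is.null(catalogue)
  if (fitting) {
    levels_seen <- sort(unique(ann$category))
    impute <- lapply(names(raw), function(col) {
      if (col %in% track_cols) config$track_impute else
        median(raw[[col]], na.rm = TRUE)
    })
    names(impute) <- names(raw)
    impute <- lapply(impute, function(v) if (is.na(v)) 0 else v)
  } else {
    levels_seen <- catalogue$levels
    impute <- catalogue$impute
    unseen <- setdiff(unique(ann$category), levels_seen)
    if (length(unseen)) {
      warning("categories unseen in training map to all-zero indicators: ",
              paste(unseen, collapse = ", "))
    }
  }

  onehot <- vapply(levels_seen, function(lv) as.numeric(ann$category == lv),
                   numeric(nrow(ann)))
  if (is.null(dim(onehot))) onehot <- matrix(onehot, nrow = nrow(ann))
  colnames(onehot) <- paste0("consequence_", levels_seen)

  x <- as.matrix(raw)
  miss <- is.na(x)
  indicators <- miss * 1
  colnames(indicators) <- paste0(colnames(x), "_missing")
  for (col in colnames(x)) {
    x[miss[, col], col] <- impute[[col]]
  }
  x <- cbind(onehot, x, indicators)

  if (fitting) {
    scales <- apply(x, 2, sd)
    scales[!is.finite(scales) | scales == 0] <- 1
  } else {
    if (!identical(colnames(x), catalogue$columns)) {
      # align column order defensively
      x <- x[, catalogue$columns, drop = FALSE]
    }
    scales <- catalogue$scales
  }
  x <- sweep(x, 2, scales, "/")

  if (fitting) {
    catalogue <- list(columns = colnames(x), levels = levels_seen,
                      impute = impute, scales = scales)
    catalogue$fingerprint <- rlang::hash(catalogue)
  }
  structure(list(x = x, catalogue = catalogue, variants = ann),
            class = "feature_matrix")
}

#' Row subset of a feature matrix (same catalogue)
#'
#' @param fm a `feature_matrix`.
#' @param rows integer or logical row index.
#' @return a `feature_matrix` restricted to `rows`.
#' @export
subset_feature_matrix <- function(fm, rows) {
  structure(list(x = fm$x[rows, , drop = FALSE],
                 catalogue = fm$catalogue,
                 variants = fm$variants[rows, , drop = FALSE]),
            class = "feature_matrix")
}

#' Serialize a feature matrix to TSV with a JSON catalogue sidecar
#'
#' @param fm a `feature_matrix`.
#' @param path TSV path; the catalogue is written to `<path>.json`.
#' @export
write_feature_matrix <- function(fm, path) {
  write.table(cbind(fm$variants[, c("chrom", "pos", "ref", "alt")],
                    as.data.frame(fm$x)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(fm$catalogue, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_catalogue <- function(path) {
  cat <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  cat$impute <- as.list(cat$impute)
  cat
}
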