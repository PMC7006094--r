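#' Training configuration for the logistic classifier
#'
#' @param l2_penalty ridge strength: the objective is the negative
#'   log-likelihood plus `0.5 * l2_penalty * ||w||^2` over the feature
#'   weights; the intercept is not penalised. Default 0.1.
#' @param max_iterations Newton iteration cap (default 100; convergence is
#'   normally reached far earlier and is logged).
#' @param internal_rescaling whether to standardise columns inside the
#'   trainer; off by default because scaling is owned by the feature
#'   matrix step.
#' @param seed integer seed (the fit itself is deterministic; the seed
#'   covers any randomised companion steps).
#' @export
training_config <- function(l2_penalty = 0.1, max_iterations = 100L,
                            internal_rescaling = FALSE, seed = 1L) {
  if (!is.numeric(l2_penalty) || l2_penalty < 0) {
    stop("configuration error: l2_penalty must be >= 0", call. = FALSE)
  }
  check_count(max_iterations, "max_iterations")
  structure(list(l2_penalty = l2_penalty,
                 max_iterations = as.integer(max_iterations),
                 internal_rescaling = isTRUE(internal_rescaling),
                 seed = as.integer(seed)),
            class = "training_config")
}

#' Class-balanced random train/test split
#'
#' Splits by row index, preserving the class balance: within each class,
#' `round(n_class * test_fraction)` rows go to the test set.
#'
#' @param variants data.frame with a `class` column (0/1).
#' @param test_fraction fraction of each class held out; the customary
#'   design uses about 1/11, i.e. a 10:1 train:test ratio.
#' @param seed integer seed.
#' @return `list(train = , test = )` of disjoint data.frames.
#' @export
split_train_test <- function(variants, test_fraction = 1 / 11, seed = 1L) {
  check_fraction(test_fraction, "test_fraction", 0, 1, open = FALSE)
  classes <- unique(variants$class)
  if (any(table(variants$class) < 2L)) {
    stop("input error: each class needs at least 2 members", call. = FALSE)
  }
  test_idx <- withr::with_seed(seed, {
    unlist(lapply(classes, function(cl) {
      rows <- which(variants$class == cl)
      n_test <- round(length(rows) * test_fraction)
      if (n_test == 0L) integer() else sample(rows, n_test)
    }))
  })
  list(train = variants[setdiff(seq_len(nrow(variants)), test_idx), ,
                        drop = FALSE],
       test = variants[test_idx, , drop = FALSE])
}

sigmoid <- function(eta) 1 / (1 + exp(-eta))

#' Train the L2-regularised logistic regression
#'
#' Fits P(class = 1 | x) by penalised maximum likelihood with a Newton
#' (iteratively reweighted least squares) solver. The fit is fully
#' deterministic; `config$max_iterations` caps the Newton steps and a
#' larger `l2_penalty` never increases the weight norm.
#'
#' @param fm a `feature_matrix` (or plain numeric matrix).
#' @param labels 0/1 vector (0 = derived proxy benign, 1 = simulated
#'   proxy deleterious).
#' @param config a [training_config()].
#' @return object of class `cadd_model` with `weights`, `intercept`,
#'   `fingerprint`, `converged`, `iterations`.
#' @export
train_model <- function(fm, labels, config = training_config()) {
  x <- if (inherits(fm, "feature_matrix")) fm$x else as.matrix(fm)
  fingerprint <- if (inherits(fm, "feature_matrix"))
    fm$catalogue$fingerprint else rlang::hash(colnames(x))
  if (!all(labels %in% c(0, 1))) {
    stop("input error: labels must be 0/1", call. = FALSE)
  }
  if (length(unique(labels)) < 2L) {
    stop("input error: both classes must be present", call. = FALSE)
  }
  if (any(!is.finite(x))) {
    stop("input error: feature matrix must be finite (impute first)",
         call. = FALSE)
  }
  scales <- rep(1, ncol(x))
  if (config$internal_rescaling) {
    scales <- apply(x, 2, sd)
    scales[scales == 0 | !is.finite(scales)] <- 1
    x <- sweep(x, 2, scales, "/")
  }
  n <- nrow(x); p <- ncol(x)
  xb <- cbind(`(intercept)` = 1, x)
  pen <- c(0, rep(config$l2_penalty, p))     # intercept unpenalised
  beta <- rep(0, p + 1L)
  objective <- function(b) {
    eta <- drop(xb %*% b)
    log1pe <- pmax(eta, 0) + log1p(exp(-abs(eta)))   # stable log(1 + e^eta)
    -sum(labels * eta - log1pe) + 0.5 * sum(pen * b^2)
  }
  obj <- objective(beta)
  converged <- FALSE
  it <- 0L
  while (it < config$max_iterations) {
    it <- it + 1L
    eta <- drop(xb %*% beta)
    mu <- sigmoid(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    grad <- drop(crossprod(xb, labels - mu)) - pen * beta
    hess <- crossprod(xb * w, xb) + diag(pen, p + 1L)
    step <- solve(hess, grad)
    # step-halving line search on the penalised objective
    alpha <- 1
    repeat {
      cand <- beta + alpha * step
      new_obj <- objective(cand)
      if (is.finite(new_obj) && new_obj <= obj + 1e-12) break
      alpha <- alpha / 2
      if (alpha < 1e-8) break
    }
    beta_new <- beta + alpha * step
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    obj <- objective(beta)
    if (delta < 1e-8) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    message("train_model: iteration cap (", config$max_iterations,
            ") reached before convergence")
  }
  weights <- beta[-1] / scales
  names(weights) <- colnames(x)
  structure(list(weights = weights, intercept = unname(beta[1]),
                 fingerprint = fingerprint, config = config,
                 converged = converged, iterations = it),
            class = "cadd_model")
}

#' Posterior probability of being proxy deleterious
#'
#' @param object a `cadd_model`.
#' @param fm a `feature_matrix` built with the training catalogue (the
#'   catalogue fingerprint must match).
#' @param ... unused.
#' @return numeric vector of probabilities in (0, 1).
#' @export
predict.cadd_model <- function(object, fm, ...) {
  if (inherits(fm, "feature_matrix")) {
    if (!identical(fm$catalogue$fingerprint, object$fingerprint)) {
      stop("model/feature incompatibility: catalogue fingerprint mismatch",
           call. = FALSE)
    }
    x <- fm$x
  } else {
    x <- as.matrix(fm)
  }
  sigmoid(drop(x %*% object$weights) + object$intercept)
}

#' Serialize / restore a trained model as JSON
#' @param model a `cadd_model`.
#' @param path JSON file path.
#' @export
write_model <- function(model, path) {
  jsonlite::write_json(
    list(weights = as.list(model$weights), intercept = model$intercept,
         fingerprint = model$fingerprint,
         config = unclass(model$config),
         converged = model$converged, iterations = model$iterations),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(weights = unlist(obj$weights), intercept = obj$intercept,
                 fingerprint = obj$fingerprint,
                 config = do.call(training_config, obj$config[
                   c("l2_penalty", "max_iterations", "internal_rescaling",
                     "seed")]),
                 converged = obj$converged, iterations = obj$iterations),
            class = "cadd_model")
}
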