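mwu_u_statistic <- function(x, y) {
  # U for "x versus y": number of (xi, yj) pairs with xi > yj, ties 1/2
  r <- rank(c(x, y))
  sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
}

mwu_exact_p <- function(x, y, alternative) {
  pooled <- c(x, y)
  n1 <- length(x)
  u_obs <- mwu_u_statistic(x, y)
  combos <- combn(length(pooled), n1)
  u_all <- apply(combos, 2, function(idx)
    mwu_u_statistic(pooled[idx], pooled[-idx]))
  eps <- 1e-9
  if (alternative == "greater") mean(u_all >= u_obs - eps)
  else mean(u_all <= u_obs + eps)
}

mwu_normal_p <- function(x, y, alternative) {
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  u <- mwu_u_statistic(x, y)
  mu <- n1 * n2 / 2
  ties <- table(c(x, y))
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
  if (sigma2 <= 0) return(1)
  # continuity-corrected normal approximation
  if (alternative == "greater") {
    pnorm((u - mu - 0.5) / sqrt(sigma2), lower.tail = FALSE)
  } else {
    pnorm((u - mu + 0.5) / sqrt(sigma2), lower.tail = TRUE)
  }
}

#' One-tailed Mann-Whitney U test
#'
#' The U statistic counts pairs with `x > y` (ties contribute 1/2); its
#' normalisation `U / (n1 * n2)` is reported as the ROC-AUC effect size.
#' For `n1 + n2 <= 12` the p-value is computed by exact enumeration of all
#' label assignments of the pooled sample (valid under ties); larger
#' samples use the normal approximation with tie and continuity
#' correction.
#'
#' @param x,y numeric samples (both non-empty).
#' @param alternative `"greater"` tests x stochastically greater than y,
#'   `"less"` the reverse.
#' @param exact_max pooled-size threshold for exact enumeration.
#' @return data.frame with `statistic` (U), `p_value`, `effect_size`
#'   (U / (n1 n2)), `direction`, `n_x`, `n_y`.
#' @export
mann_whitney_one_tailed <- function(x, y,
                                    alternative = c("greater", "less"),
                                    exact_max = 12L) {
  alternative <- match.arg(alternative)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (!length(x) || !length(y)) {
    stop("input error: both samples must be non-empty", call. = FALSE)
  }
  u <- mwu_u_statistic(x, y)
  p <- if (length(x) + length(y) <= exact_max) {
    mwu_exact_p(x, y, alternative)
  } else {
    mwu_normal_p(x, y, alternative)
  }
  data.frame(statistic = u, p_value = p,
             effect_size = u / (length(x) * length(y)),
             direction = alternative, n_x = length(x), n_y = length(y))
}

#' Bonferroni adjustment (p_adjusted = min(1, p * m))
#' @param p vector of p-values; `m` defaults to `length(p)`.
#' @export
bonferroni <- function(p, m = length(p)) pmin(1, p * m)
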