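#' Estimate the empirical-Bayes variance prior
#'
#' Fits a scaled inverse chi-square prior with `d0` degrees of freedom and
#' location `s0sq` to a set of per-protein sample variances, by matching the
#' first two moments of `e_g = log(s2_g) - digamma(df_g/2) + log(df_g/2)`.
#' `d0` is obtained by monotone inversion of the trigamma function on
#'
#'   mean_g[ (e_g - mean(e))^2 * G/(G-1) - trigamma(df_g/2) ]
#'
#' and `s0sq = exp(mean(e) + digamma(d0/2) - log(d0/2))`, since under the
#' scaled inverse chi-square prior `E[e_g] = log(s0sq) + log(d0/2) -
#' digamma(d0/2)`. When the excess dispersion is non-positive the prior
#' degrees of freedom are infinite and `s0sq` is the mean sample variance:
#' all proteins share one variance.
#'
#' @param sample_vars per-protein sample variances (only positive values
#'   with positive degrees of freedom are used).
#' @param dfs per-protein residual degrees of freedom.
#' @return list with elements `d0` (possibly `Inf`) and `s0sq`.
#' @export
estimate_variance_prior <- function(sample_vars, dfs) {
  stopifnot(length(sample_vars) == length(dfs))
  use <- which(sample_vars > 0 & dfs >= 1)
  if (length(use) < 2)
    stop("need at least 2 proteins with positive variance and df >= 1")
  s2 <- sample_vars[use]
  df <- dfs[use]
  e <- log(s2) - digamma(df / 2) + log(df / 2)
  G <- length(e)
  ebar <- mean(e)
  rhs <- mean((e - ebar)^2 * G / (G - 1) - trigamma(df / 2))
  if (rhs <= 0)
    return(list(d0 = Inf, s0sq = mean(s2)))
  d0 <- 2 * trigamma_inverse(rhs)
  s0sq <- exp(ebar + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s0sq = s0sq)
}

#' Invert the trigamma function
#'
#' Solves `trigamma(x) = y` for `x > 0` by Newton iteration on the
#' decreasing convex function, with asymptotic starting points for extreme
#' arguments.
#'
#' @param y positive value.
#' @return x such that `trigamma(x) = y`.
#' @export
trigamma_inverse <- function(y) {
  stopifnot(is.numeric(y), length(y) == 1, y > 0)
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (abs(dif / x) < 1e-10) break
  }
  x
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Sorts the p-values ascending, computes `q_i = p_i * m / i`, enforces
#' monotonicity from the largest rank downwards, caps at 1, and returns the
#' adjusted values in the input order.
#'
#' @param pvalues numeric vector in [0, 1].
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  if (any(is.na(pvalues) | pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(pvalues)
  if (m == 0) return(numeric(0))
  o <- order(pvalues)
  q <- pvalues[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

#' Moderated one-sample t-test on a protein ratio matrix
#'
#' For every protein with at least two non-missing replicate ratios,
#' computes the mean oriented ratio, the sample variance, the posterior
#' (shrunken) variance
#' `(d0 * s0sq + df * s2) / (d0 + df)`, the moderated t statistic
#' `t = mean * sqrt(n) / sqrt(posterior_var)` and a two-sided p-value on
#' `d0 + df` degrees of freedom (standard normal in the `d0 = Inf` limit).
#' P-values are adjusted across all tested proteins by [bh_adjust()], and
#' each protein is called `down37` (adjusted p <= alpha, mean > 0, i.e.
#' less abundant at 37 degrees), `up37` (adjusted p <= alpha, mean < 0) or
#' `ns`.
#'
#' @param matrix a `protein_ratio_matrix`, or a plain numeric matrix of
#'   per-replicate oriented ratios with protein row names.
#' @param prior `"estimate"` (default) to fit the prior with
#'   [estimate_variance_prior()], or a list with elements `d0` and `s0sq`.
#' @param alpha FDR level for the directional calls (default 0.01).
#' @return data.frame with columns `protein_id`, `mean_log2`, `n_reps`,
#'   `sample_var`, `df`, `posterior_var`, `t`, `p`, `adj_p`, `call`; the
#'   fitted prior is attached as attribute `"prior"`.
#' @export
moderated_test <- function(matrix, prior = "estimate", alpha = 0.01) {
  x <- if (inherits(matrix, "protein_ratio_matrix")) matrix$ratios else matrix
  stopifnot(is.matrix(x), !is.null(rownames(x)))
  n <- rowSums(!is.na(x))
  excluded <- rownames(x)[n < 2]
  if (length(excluded) > 0)
    message(length(excluded), " protein(s) with < 2 replicates excluded")
  x <- x[n >= 2, , drop = FALSE]
  n <- n[n >= 2]
  if (nrow(x) == 0) stop("no protein has >= 2 non-missing replicates")
  xbar <- rowMeans(x, na.rm = TRUE)
  s2 <- rowSums((x - xbar)^2, na.rm = TRUE) / (n - 1)
  df <- n - 1
  if (identical(prior, "estimate"))
    prior <- estimate_variance_prior(s2, df)
  stopifnot(is.list(prior), prior$s0sq > 0, prior$d0 > 0)
  if (is.infinite(prior$d0)) {
    post_var <- rep(prior$s0sq, length(s2))
    tt <- xbar / sqrt(post_var / n)
    p <- 2 * pnorm(-abs(tt))
  } else {
    post_var <- (prior$d0 * prior$s0sq + df * s2) / (prior$d0 + df)
    tt <- xbar / sqrt(post_var / n)
    p <- 2 * pt(-abs(tt), df = prior$d0 + df)
  }
  adj_p <- bh_adjust(p)
  call <- ifelse(adj_p <= alpha & xbar > 0, "down37",
                 ifelse(adj_p <= alpha & xbar < 0, "up37", "ns"))
  res <- data.frame(
    protein_id = rownames(x),
    mean_log2 = xbar,
    n_reps = as.integer(n),
    sample_var = s2,
    df = as.integer(df),
    posterior_var = post_var,
    t = tt,
    p = p,
    adj_p = adj_p,
    call = call,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
  attr(res, "prior") <- prior
  res
}

#' Fold-change reporting
#'
#' Converts an oriented log2(30C/37C) ratio into the fold change and
#' direction at the elevated temperature: a positive log2 ratio means the
#' protein is more abundant at 30 degrees, hence down-regulated at 37.
#' The fold is `2^|log2_ratio|` rounded to 2 decimals for reporting.
#'
#' @param log2_ratio numeric vector of oriented log2 ratios.
#' @return data.frame with columns `fold` and `direction` ("up"/"down" at
#'   37 degrees; NA for a ratio of exactly 0).
#' @export
fold_change <- function(log2_ratio) {
  stopifnot(all(is.finite(log2_ratio)))
  data.frame(
    fold = round(2^abs(log2_ratio), 2),
    direction = ifelse(log2_ratio > 0, "down",
                       ifelse(log2_ratio < 0, "up", NA_character_)),
    stringsAsFactors = FALSE
  )
}

#' Sign concordance between two differential datasets
#'
#' Restricts to proteins significant (adjusted p <= alpha) in both result
#' sets and reports how many there are and the fraction whose mean log2
#' ratios agree in sign.
#'
#' @param a,b moderated-test result data.frames (see [moderated_test()]).
#' @param alpha significance level (default 0.01).
#' @return list with elements `n_common_significant` and `frac_same_sign`
#'   (NA when the intersection is empty).
#' @export
concordance <- function(a, b, alpha = 0.01) {
  sig_a <- a[a$adj_p <= alpha, c("protein_id", "mean_log2")]
  sig_b <- b[b$adj_p <= alpha, c("protein_id", "mean_log2")]
  common <- merge(sig_a, sig_b, by = "protein_id",
                  suffixes = c("_a", "_b"))
  n <- nrow(common)
  if (n == 0)
    return(list(n_common_significant = 0L, frac_same_sign = NA_real_))
  list(n_common_significant = n,
       frac_same_sign = mean(sign(common$mean_log2_a) ==
                               sign(common$mean_log2_b)))
}
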