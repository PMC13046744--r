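#' @importFrom rlang .data abort warn .env
#' @importFrom stats sd quantile median coef lm predict rnorm runif rbinom
#'   rlnorm rexp complete.cases pnorm qnorm p.adjust optim fft var cor
#'   as.formula relevel terms setNames aggregate
#' @importFrom utils head tail
NULL

# Deterministic per-unit seed stream: cohorts must reproduce under
# subsetting, so each subject gets a seed derived from (seed, id).
derive_seed <- function(seed, i) {
  as.integer((as.double(seed) %% 59999L * 31013 + as.double(i) * 7919 + 104729) %% 2147483629)
}

# Population-SD coefficient of variation in percent (divisor n).
cv_percent <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2L || mean(x) == 0) return(NA_real_)
  100 * sqrt(mean((x - mean(x))^2)) / mean(x)
}

# Rolling mean with a centered window; circular wrapping optional.
roll_mean <- function(x, k, circular = FALSE) {
  n <- length(x)
  if (circular) {
    xx <- c(tail(x, k), x, head(x, k))
    cs <- cumsum(c(0, xx))
    out <- (cs[(k + 1 + seq_len(n))] - cs[seq_len(n) + 1]) / k
    return(out)
  }
  h <- k %/% 2
  lo <- pmax(1, seq_len(n) - h); hi <- pmin(n, seq_len(n) + h)
  cs <- cumsum(c(0, x))
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

# Mean of each leading window of length k starting at positions 1..n-k+1.
window_means <- function(x, k) {
  n <- length(x)
  if (k > n) return(numeric(0))
  cs <- cumsum(c(0, x))
  (cs[(k + 1):(n + 1)] - cs[1:(n - k + 1)]) / k
}

#' Area under the ROC curve by the rank statistic
#'
#' Equivalent to the Wilcoxon–Mann–Whitney estimate: the probability that a
#' randomly chosen positive scores above a randomly chosen negative, with
#' ties counted half.
#'
#' @param scores Numeric predictions (higher = more positive).
#' @param labels Binary labels (0/1 or logical).
#' @return A single number in \[0, 1\].
#' @export
auc_rank <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  stopifnot(length(scores) == length(labels))
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) abort("AUC needs both classes present")
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Matthews correlation coefficient from predictions
#'
#' @param pred Predicted classes (0/1 or logical), or probabilities together
#'   with `threshold`.
#' @param labels True binary labels.
#' @param threshold Probability cutoff applied when `pred` is numeric in
#'   \[0, 1\] and not already binary.
#' @return MCC in \[-1, 1\]; 0 when a marginal is degenerate.
#' @export
mcc_score <- function(pred, labels, threshold = 0.5) {
  labels <- as.integer(as.logical(labels))
  if (is.numeric(pred) && !all(pred %in% c(0, 1))) pred <- as.integer(pred >= threshold)
  pred <- as.integer(as.logical(pred))
  tp <- sum(pred == 1 & labels == 1); tn <- sum(pred == 0 & labels == 0)
  fp <- sum(pred == 1 & labels == 0); fn <- sum(pred == 0 & labels == 1)
  denom <- sqrt(as.double(tp + fp)) * sqrt(as.double(tp + fn)) *
    sqrt(as.double(tn + fp)) * sqrt(as.double(tn + fn))
  if (denom == 0) return(0)
  (as.double(tp) * tn - as.double(fp) * fn) / denom
}

# Gaussian 1/f^beta noise via spectral synthesis (beta = 1 is pink).
# Returns a length-n vector with sd ~ 1.
pink_noise <- function(n, beta = 1) {
  m <- 2^ceiling(log2(n))
  f <- c(1, seq_len(m / 2), seq(m / 2 - 1, 1))  # rfft-style frequency index
  amp <- f^(-beta / 2)
  amp[1] <- 0
  phase <- runif(m, 0, 2 * pi)
  spec <- amp * exp(1i * phase)
  # enforce conjugate symmetry for a real signal
  spec[(m / 2 + 2):m] <- Conj(spec[seq(m / 2, 2)])
  spec[m / 2 + 1] <- Re(spec[m / 2 + 1])
  x <- Re(fft(spec, inverse = TRUE)) / m
  x <- x[seq_len(n)]
  s <- sd(x)
  if (s > 0) x / s else x
}

# Quantile with linear interpolation (the documented convention everywhere).
pct <- function(x, p) unname(quantile(x, p, type = 7, na.rm = TRUE))

assert_cols <- function(df, cols, what = "input") {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    abort(sprintf("%s is missing required column(s): %s", what,
                  paste(miss, collapse = ", ")))
  }
}

# Fast grouped means via rowsum (C path); g must be integer-like.
# Returns means ordered by sorted unique group, names = group values.
grp_mean <- function(x, g) {
  sums <- rowsum(x, g, reorder = TRUE)
  cnts <- rowsum(rep(1, length(x)), g, reorder = TRUE)
  out <- as.numeric(sums / cnts)
  names(out) <- rownames(sums)
  out
}

grp_sum <- function(x, g) {
  out0 <- rowsum(as.numeric(x), g, reorder = TRUE)
  out <- as.numeric(out0)
  names(out) <- rownames(out0)
  out
}
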