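#' Shapley feature attributions by exact enumeration or permutation sampling
#'
#' The coalition value of a feature subset S for an instance x is the
#' expected model prediction with the in-coalition features fixed at x and
#' the rest marginalized over a background sample:
#' v(S) = mean over background rows b of f(x_S, b_rest). Exact mode
#' enumerates all 2^p coalitions (p <= 12) and applies the Shapley weights;
#' sampling mode averages marginal contributions over random feature
#' permutations. Both satisfy the efficiency axiom: attributions sum to
#' f(x) minus the base value (the mean background prediction) exactly.
#'
#' @param predict_fn Function mapping a feature data frame to numeric
#'   predictions.
#' @param background Data frame of background rows (the marginal
#'   distribution used for absent features).
#' @param instances Data frame of instances to explain (same columns).
#' @param mode `"exact"` or `"sampling"`.
#' @param n_permutations Permutations per instance in sampling mode.
#' @param seed Seed for sampling mode.
#' @return A `shap_result`: `values` (instances x features matrix),
#'   `base_value`, `ranking` (tibble with mean |value| and the sign of the
#'   feature-attribution correlation), and in sampling mode `se` (Monte
#'   Carlo standard errors).
#' @export
shapley_attributions <- function(predict_fn, background, instances,
                                 mode = c("exact", "sampling"),
                                 n_permutations = 200, seed = 1L) {
  mode <- match.arg(mode)
  if (is.null(background) || nrow(background) == 0) abort("empty background")
  background <- as.data.frame(background)
  instances <- as.data.frame(instances)
  stopifnot(identical(names(background), names(instances)))
  p <- ncol(background)
  nb <- nrow(background)
  base_value <- mean(predict_fn(background))

  if (mode == "exact") {
    if (p > 12) abort("exact mode supports at most 12 features")
    n_co <- 2^p
    # coalition membership matrix: row s+1 = bitmask s
    member <- matrix(FALSE, n_co, p)
    for (j in seq_len(p)) member[, j] <- bitwAnd(seq_len(n_co) - 1L, bitwShiftL(1L, j - 1L)) > 0
    wts <- factorial(0:(p - 1)) * factorial(p - 1 - (0:(p - 1))) / factorial(p)
    vals <- matrix(0, nrow(instances), p,
                   dimnames = list(NULL, names(background)))
    for (i in seq_len(nrow(instances))) {
      x <- instances[i, , drop = FALSE]
      big <- background[rep(seq_len(nb), n_co), , drop = FALSE]
      co <- rep(seq_len(n_co), each = nb)
      for (j in seq_len(p)) {
        on <- member[co, j]
        big[on, j] <- x[[j]]
      }
      pr <- predict_fn(big)
      v <- as.numeric(tapply(pr, co, mean))        # v[s+1] = v(coalition s)
      sizes <- rowSums(member)
      for (j in seq_len(p)) {
        without <- which(!member[, j])
        with_j <- without + 2^(j - 1)
        vals[i, j] <- sum(wts[sizes[without] + 1] * (v[with_j] - v[without]))
      }
    }
    res <- list(values = vals, base_value = base_value, mode = "exact")
  } else {
    set.seed(seed)
    vals <- matrix(0, nrow(instances), p,
                   dimnames = list(NULL, names(background)))
    ses <- vals
    for (i in seq_len(nrow(instances))) {
      x <- instances[i, , drop = FALSE]
      contrib <- matrix(0, n_permutations, p)
      # build all (permutation x step) coalitions, one batched predict
      big <- background[rep(seq_len(nb), n_permutations * p), , drop = FALSE]
      orders <- replicate(n_permutations, sample.int(p), simplify = FALSE)
      row0 <- 0L
      for (k in seq_len(n_permutations)) {
        ord <- orders[[k]]
        on <- logical(p)
        for (st in seq_len(p)) {
          on[ord[st]] <- TRUE
          rows <- row0 + seq_len(nb)
          for (j in which(on)) big[rows, j] <- x[[j]]
          row0 <- row0 + nb
        }
      }
      pr <- predict_fn(big)
      vmat <- matrix(colMeans(matrix(pr, nrow = nb)), nrow = p)  # step x perm
      for (k in seq_len(n_permutations)) {
        ord <- orders[[k]]
        vprev <- base_value
        for (st in seq_len(p)) {
          contrib[k, ord[st]] <- vmat[st, k] - vprev
          vprev <- vmat[st, k]
        }
      }
      vals[i, ] <- colMeans(contrib)
      ses[i, ] <- apply(contrib, 2, sd) / sqrt(n_permutations)
    }
    res <- list(values = vals, base_value = base_value, mode = "sampling",
                se = ses)
  }

  dir <- vapply(seq_len(p), function(j) {
    fv <- instances[[j]]
    if (length(unique(fv)) < 2 || sd(res$values[, j]) == 0) return(0)
    sign(cor(fv, res$values[, j]))
  }, 0)
  res$ranking <- tibble::tibble(
    feature = names(background),
    mean_abs = colMeans(abs(res$values)),
    direction = dir) |> dplyr::arrange(dplyr::desc(.data$mean_abs))
  structure(res, class = "shap_result")
}

#' @export
print.shap_result <- function(x, ...) {
  cat(sprintf("<shap_result> %s mode, %d instance(s), base value %.4f\n",
              x$mode, nrow(x$values), x$base_value))
  print(utils::head(x$ranking, 10))
  invisible(x)
}
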