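test_that("correlation pruning collapses redundant clusters deterministically", {
  set.seed(1)
  y <- rbinom(200, 1, 0.5)
  a <- rnorm(200) + y
  f <- tibble::tibble(a = a, a_copy = a, b = rnorm(200))
  pr <- spearman_prune(f, y)
  expect_equal(sum(pr$retained[pr$feature %in% c("a", "a_copy")]), 1)
  expect_true(pr$retained[pr$feature == "b"])

  # all pairwise |rho| <= 0.7: everything retained
  set.seed(2)
  f2 <- tibble::tibble(x = rnorm(100), y2 = rnorm(100), z = rnorm(100))
  expect_true(all(spearman_prune(f2, rbinom(100, 1, 0.5))$retained))
})

test_that("pruning a constructed six-feature set matches the hand-derived answer", {
  set.seed(42)
  n <- 600
  y <- rbinom(n, 1, 0.5)
  base <- rnorm(n)
  # f1 strongly relevant; f2 = noisy copy of f1 (rho > 0.7, less relevant)
  f1 <- base + 2 * y
  f2 <- f1 + rnorm(n, 0, 0.3)
  # f3/f4 correlated pair, f4 more relevant
  u <- rnorm(n)
  f3 <- u
  f4 <- u + rnorm(n, 0, 0.3) + 0.8 * y
  # f5, f6 independent
  f5 <- rnorm(n); f6 <- rnorm(n)
  f <- tibble::tibble(f1 = f1, f2 = f2, f3 = f3, f4 = f4, f5 = f5, f6 = f6)
  rho <- cor(as.matrix(f), method = "spearman")
  expect_gt(abs(rho["f1", "f2"]), 0.7)
  expect_gt(abs(rho["f3", "f4"]), 0.7)
  pr <- spearman_prune(f, y)
  expect_setequal(pr$feature[pr$retained], c("f1", "f4", "f5", "f6"))
  expect_equal(pr$dropped_with[pr$feature == "f2"], "f1")
})

test_that("MRMR greedy ranking equals exhaustive criterion evaluation", {
  set.seed(3)
  n <- 400
  y <- rbinom(n, 1, 0.5)
  f <- tibble::tibble(
    a = rnorm(n) + 1.5 * y, b = rnorm(n) + 0.7 * y, c = rnorm(n),
    d = rnorm(n) + 0.3 * y, e = rnorm(n, sd = 2))
  got <- mrmr_select(f, y, k = 5)
  # independent exhaustive greedy evaluation of the MID criterion
  rel <- vapply(names(f), function(v) mutual_information(f[[v]], y), 0)
  sel <- character(0)
  for (step in 1:5) {
    cand <- setdiff(names(f), sel)
    sc <- vapply(cand, function(v) {
      red <- if (!length(sel)) 0 else
        mean(vapply(sel, function(s) mutual_information(f[[v]], f[[s]]), 0))
      rel[v] - red
    }, 0)
    sel <- c(sel, cand[order(-sc, cand)][1])
  }
  expect_identical(got$feature, sel)

  # single candidate is trivially first
  expect_identical(mrmr_select(f[, "a", drop = FALSE], y, k = 1)$feature, "a")
})

test_that("an exact duplicate of the top feature is pushed down by redundancy", {
  set.seed(4)
  n <- 500
  y <- rbinom(n, 1, 0.5)
  top <- rnorm(n) + 2 * y
  f <- tibble::tibble(top = top, top_dup = top, weak = rnorm(n) + 0.5 * y)
  r <- mrmr_select(f, y, k = 3)
  expect_equal(r$feature[1], "top")
  expect_equal(r$feature[2], "weak")   # duplicate penalized below weaker feature
  # a constant feature has zero MI and does not break selection
  f$flat <- 1
  expect_silent(r2 <- mrmr_select(f, y, k = 4))
  expect_equal(mutual_information(f$flat, y), 0)
})

test_that("the stratified split is exact, seeded, disjoint and exhaustive", {
  set.seed(5)
  y <- rbinom(1000, 1, 0.45)
  sp <- split_train_val_test(y, seed = 7)
  expect_equal(lengths(sp), c(train = 650, validation = 150, test = 200))
  all_idx <- unname(unlist(sp))
  expect_equal(sort(all_idx), 1:1000)
  expect_equal(length(unique(all_idx)), 1000)
  # stratification: class balance preserved within ~1 subject
  for (part in sp)
    expect_equal(mean(y[part]), mean(y), tolerance = 0.012)
  expect_identical(sp, split_train_val_test(y, seed = 7))
  expect_false(identical(sp, split_train_val_test(y, seed = 8)))
})

test_that("evaluation metrics match closed-form confusion arithmetic", {
  # MCC of TP=40, FP=10, FN=10, TN=40 is 1500/2500 = 0.6
  labels <- rep(c(1, 0), each = 50)
  pred <- c(rep(1, 40), rep(0, 10), rep(1, 10), rep(0, 40))
  expect_equal(mcc_score(pred, labels), 0.6)

  # AUC and MCC agree with brute-force reimplementation on random instances
  set.seed(6)
  for (rep in 1:100) {
    n <- sample(10:40, 1)
    sc <- rnorm(n)
    lb <- rbinom(n, 1, 0.5)
    if (length(unique(lb)) < 2) next
    pos <- sc[lb == 1]; neg <- sc[lb == 0]
    brute <- mean(outer(pos, neg, function(p, q)
      (p > q) + 0.5 * (p == q)))
    expect_equal(auc_rank(sc, lb), brute, tolerance = 1e-12)
    pr <- as.integer(sc >= 0)
    tp <- sum(pr & lb); tn <- sum(!pr & !lb)
    fp <- sum(pr & !lb); fn <- sum(!pr & lb)
    den <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
    expect_equal(mcc_score(pr, lb),
                 if (den == 0) 0 else (tp * tn - fp * fn) / den,
                 tolerance = 1e-12)
  }
})

test_that("training pipeline separates separable data and errors on one class", {
  set.seed(7)
  n <- 300
  y <- rbinom(n, 1, 0.5)
  f <- tibble::tibble(x1 = y + rnorm(n, 0, 0.05), x2 = rnorm(n))
  clf <- suppressWarnings(          # perfect separation is the point
    train_and_evaluate(f, y, model = "logistic", seed = 1))
  expect_equal(clf$report$auc, 1)
  expect_equal(clf$report$mcc, 1)
  expect_equal(clf$report$accuracy, 1)
  expect_error(train_and_evaluate(f, rep(1, n), model = "logistic", seed = 1),
               "single-class")
})

test_that("label-permuted data scores chance-level AUC", {
  set.seed(8)
  n <- 400
  f <- tibble::tibble(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
  aucs <- vapply(1:20, function(s) {
    set.seed(s)
    y <- sample(rep(0:1, each = n / 2))
    train_and_evaluate(f, y, model = "logistic", seed = s)$report$auc
  }, 0)
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})
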