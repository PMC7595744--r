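# small synthetic feature matrices exercise the CART/bagging machinery
mk_xy <- function(n, p = 5, rule = NULL, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p)
  y <- if (is.null(rule)) sample(rep(1:2, length.out = n)) else rule(x)
  list(x = x, y = y)
}

test_that("a single tree grows to purity with deterministic splits", {
  d <- mk_xy(20, rule = function(x) ifelse(x[, 2] > 0.3, 2L, 1L))
  tree <- grow_tree(d$x, d$y, m_try = 5)
  expect_equal(predict(tree, d$x), d$y)  # pure growth on distinct rows

  # single class -> single leaf
  leaf <- grow_tree(d$x, rep(2L, 20), m_try = 5, n_class = 2)
  expect_equal(leaf$feature, -1L)
  expect_equal(leaf$pred, 2L)

  # 1-D perfectly separated: one split strictly between the class extremes
  x1 <- matrix(c(1, 2, 3, 10, 11, 12), ncol = 1)
  y1 <- c(1L, 1L, 1L, 2L, 2L, 2L)
  t1 <- grow_tree(x1, y1, m_try = 1)
  expect_equal(sum(t1$feature != -1L), 1L)
  expect_gt(t1$threshold[1], 3)
  expect_lt(t1$threshold[1], 10)
})

test_that("bagging is reproducible and has the binomial OOB rate", {
  d <- mk_xy(29, rule = function(x) ifelse(x[, 1] + x[, 2] > 0, 2L, 1L))
  e1 <- fit_ensemble(list(x = d$x, y = d$y), n_trees = 200, seed = 42)
  e2 <- fit_ensemble(list(x = d$x, y = d$y), n_trees = 200, seed = 42)
  expect_identical(predict(e1), predict(e2))
  expect_identical(oob_accuracy(e1), oob_accuracy(e2))

  # OOB membership frequency ~ (1 - 1/n)^n -> exp(-1)
  oob_frac <- mean(e1$inbag == 0L)
  expect_gt(oob_frac, 0.33)
  expect_lt(oob_frac, 0.41)

  single <- fit_ensemble(list(x = d$x, y = d$y), n_trees = 1, seed = 1)
  expect_length(single$trees, 1)

  expect_error(fit_ensemble(list(x = d$x, y = rep(1L, 29))),
               "configuration error")
})

test_that("OOB accuracy separates signal from chance", {
  sep <- mk_xy(200, rule = function(x) ifelse(x[, 3] > 0, 2L, 1L), seed = 2)
  e <- fit_ensemble(list(x = sep$x, y = sep$y), n_trees = 300, seed = 3)
  expect_gte(oob_accuracy(e), 0.95)

  noise <- mk_xy(200, seed = 4)  # permuted balanced labels
  e2 <- fit_ensemble(list(x = noise$x, y = noise$y), n_trees = 300, seed = 5)
  acc <- oob_accuracy(e2)
  expect_gt(acc, 0.4)
  expect_lt(acc, 0.6)
})

test_that("permutation importance ranks features and shares credit", {
  d <- mk_xy(120, rule = function(x) ifelse(x[, 2] > 0, 2L, 1L), seed = 6)
  e <- fit_ensemble(list(x = d$x, y = d$y), n_trees = 300, seed = 7)
  imp <- permutation_importance(e, seed = 8)
  expect_equal(max(abs(imp)), 1)
  expect_equal(which.max(imp), 2L)
  expect_true(all(abs(imp[-2]) <= 0.2))  # pure-noise features

  imp2 <- permutation_importance(e, seed = 8)
  expect_identical(imp, imp2)

  # duplicating the informative feature splits its credit
  x_dup <- cbind(d$x, d$x[, 2])
  e_dup <- fit_ensemble(list(x = x_dup, y = d$y), n_trees = 300, seed = 7)
  raw_imp <- function(en, s) {
    # un-normalized mean/sd deltas, for cross-model comparison
    set.seed(s)
    p <- ncol(en$x)
    delta <- matrix(NA_real_, en$n_trees, p)
    for (b in seq_len(en$n_trees)) {
      oob <- which(en$inbag[, b] == 0L)
      if (length(oob) < 2L) next
      xo <- en$x[oob, , drop = FALSE]; yo <- en$y[oob]
      err0 <- mean(predict(en$trees[[b]], xo) != yo)
      for (f in seq_len(p)) {
        xp <- xo; xp[, f] <- xp[sample.int(length(oob)), f]
        delta[b, f] <- mean(predict(en$trees[[b]], xp) != yo) - err0
      }
    }
    mu <- colMeans(delta, na.rm = TRUE)
    mu / apply(delta, 2, sd, na.rm = TRUE)
  }
  expect_lt(raw_imp(e_dup, 8)[2], raw_imp(e, 8)[2])
})

test_that("ensemble agrees with an independent random-forest implementation", {
  skip_if_not_installed("randomForest")
  d <- mk_xy(100, rule = function(x) ifelse(x[, 1] - x[, 4] > 0, 2L, 1L),
             seed = 9)
  e <- fit_ensemble(list(x = d$x, y = d$y), n_trees = 500, seed = 10)
  set.seed(10)
  rf <- randomForest::randomForest(d$x, factor(d$y), ntree = 500)
  rf_acc <- mean(rf$predicted == factor(d$y))
  expect_lt(abs(oob_accuracy(e) - rf_acc), 0.1)
})

test_that("lateral importance averages hemispheres correctly", {
  kinds <- feature_kinds()
  imp <- setNames(rep(0.4, length(kinds)), names(kinds))
  lat <- lateral_importance(imp)
  expect_equal(unname(lat), c(0.4, 0.4))

  imp2 <- imp
  imp2[c("rate_L_SFG", "rate_L_MFG", "rate_L_MedFG")] <- c(0.1, 0.2, 0.3)
  imp2[c("rate_R_SFG", "rate_R_MFG", "rate_R_MedFG")] <- c(0.7, 0.8, 0.9)
  lat2 <- lateral_importance(imp2)
  expect_equal(unname(lat2), c(mean(c(0.1, 0.2, 0.3)), mean(c(0.7, 0.8, 0.9))))

  expect_error(lateral_importance(imp2[-1]), "config error")

  # a cohort whose signal lives only in right-hemisphere features
  spec <- cohort_spec(sizes = c("PD-POS" = 25, "PD-NEG" = 25), seed = 14)
  ft <- generate_feature_table(spec)
  left <- paste0("rate_L_", c("SFG", "MFG", "MedFG"))
  ft[, left] <- matrix(rnorm(nrow(ft) * 3), ncol = 3)  # left = pure noise
  ft$label <- ifelse(rowMeans(ft[, paste0("rate_R_", c("SFG", "MFG", "MedFG"))]) > 0,
                     "PD-POS", "PD-NEG")
  e <- fit_ensemble(ft, n_trees = 300, seed = 15)
  lat3 <- lateral_importance(permutation_importance(e, seed = 16))
  expect_gt(lat3[["right"]], lat3[["left"]])
})

test_that("the three trials run on a cohort and exclude controls", {
  spec <- cohort_spec(sizes = c("HC" = 4, "PD-OH" = 8, "PD-POS" = 12,
                                "PD-NEG" = 10), seed = 17)
  ft <- generate_feature_table(spec)
  expect_message(
    res <- run_trials(ft, n_trees = 150, seed = 18, importance = FALSE),
    "excluding 4 HC"
  )
  expect_length(res, 3)
  for (r in res) {
    expect_true(r$oob_accuracy_mean >= 0 && r$oob_accuracy_mean <= 1)
  }

  # the binary subgroup trial is easier than the three-class trial
  expect_gt(res[["PD-NEG vs PD-POS"]]$oob_accuracy_mean,
            res[["PD-NEG vs PD-POS vs PD-OH"]]$oob_accuracy_mean)

  # chance level for the three-class trial under permuted labels
  set.seed(19)
  ftp <- ft[ft$label != "HC", ]
  ftp$label <- sample(ftp$label)
  accs <- vapply(1:5, function(r) {
    e <- fit_ensemble(ftp, n_trees = 150, seed = 20 + r)
    oob_accuracy(e)
  }, numeric(1))
  expect_lt(mean(accs), 0.55)  # near the 1/3-1/2 chance band, far below signal

  # empty class is a configuration error
  expect_error(
    run_trials(ft[ft$label %in% c("HC", "PD-POS", "PD-NEG"), ],
               n_trees = 50, seed = 1, importance = FALSE),
    "configuration error"
  )
})
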