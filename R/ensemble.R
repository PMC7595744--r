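#' Bagged decision-tree classification of orthostatic-intolerance subgroups
#'
#' A 1000-tree bagged ensemble (random feature subsets at each split, i.e.
#' the random-forest method) is trained on the subjects-by-features table of
#' six gyrus rate-of-HbO-change features plus clinical covariates. Each tree
#' is grown on a bootstrap resample; subjects absent from a tree's bootstrap
#' are its out-of-bag (OOB) set, giving an internal accuracy estimate and a
#' permuted-delta-error feature importance. Healthy controls carry no
#' PD-severity metrics and never enter classification.
#'
#' @name classification
NULL

#' Feature columns and their kinds
#'
#' @return Named character vector mapping feature column names to
#'   `"oxygenation"` or `"clinical"`.
#' @export
feature_kinds <- function() {
  c(
    rate_L_SFG = "oxygenation", rate_R_SFG = "oxygenation",
    rate_L_MFG = "oxygenation", rate_R_MFG = "oxygenation",
    rate_L_MedFG = "oxygenation", rate_R_MedFG = "oxygenation",
    age = "clinical", sex = "clinical", hypertension = "clinical",
    hy_stage = "clinical", updrs3 = "clinical", compass = "clinical",
    cass = "clinical", mmse = "clinical", moca = "clinical",
    motor_symptom = "clinical", nonmotor_symptom = "clinical"
  )
}

.feature_matrix <- function(table, features = names(feature_kinds())) {
  missing <- setdiff(features, names(table))
  if (length(missing)) {
    stop("feature table missing column(s): ", paste(missing, collapse = ", "))
  }
  as.matrix(table[, features, drop = FALSE])
}

#' Fit a bagged ensemble of classification trees
#'
#' @param table Feature table (data.frame) with a `label` column and the
#'   feature columns of [feature_kinds()]; or a list `list(x, y)` with a
#'   numeric matrix and class labels.
#' @param n_trees Number of trees.
#' @param seed Integer seed fixing all ensemble randomness.
#' @param m_try Features tried per split; default `ceiling(sqrt(p))`.
#' @param features Feature columns to use.
#' @return Object of class `bag_ensemble`: `trees`, `inbag` (n x n_trees
#'   bootstrap count matrix), `classes` (sorted label levels), `x`, `y`.
#' @export
fit_ensemble <- function(table, n_trees = 1000, seed = NULL,
                         m_try = NULL, features = names(feature_kinds())) {
  if (is.data.frame(table)) {
    x <- .feature_matrix(table, features)
    y_raw <- table$label
  } else {
    x <- table$x
    y_raw <- table$y
  }
  classes <- sort(unique(as.character(y_raw)))
  if (length(classes) < 2) {
    stop("configuration error: at least 2 classes are required")
  }
  y <- match(as.character(y_raw), classes)
  n <- nrow(x)
  p <- ncol(x)
  if (is.null(m_try)) m_try <- ceiling(sqrt(p))
  if (!is.null(seed)) set.seed(seed)
  trees <- vector("list", n_trees)
  inbag <- matrix(0L, n, n_trees)
  for (b in seq_len(n_trees)) {
    boot <- sample.int(n, n, replace = TRUE)
    inbag[, b] <- tabulate(boot, n)
    trees[[b]] <- grow_tree(x[boot, , drop = FALSE], y[boot],
                            m_try = m_try, n_class = length(classes))
  }
  structure(
    list(trees = trees, inbag = inbag, classes = classes, x = x, y = y,
         m_try = m_try, n_trees = n_trees, seed = seed,
         feature_names = colnames(x)),
    class = "bag_ensemble"
  )
}

#' Ensemble prediction by majority vote
#' @param object A `bag_ensemble`.
#' @param newdata Feature matrix; defaults to the training matrix.
#' @param ... Unused.
#' @return Character class predictions.
#' @export
predict.bag_ensemble <- function(object, newdata = object$x, ...) {
  votes <- matrix(0L, nrow(newdata), length(object$classes))
  for (tr in object$trees) {
    pr <- predict(tr, newdata)
    votes[cbind(seq_len(nrow(newdata)), pr)] <-
      votes[cbind(seq_len(nrow(newdata)), pr)] + 1L
  }
  object$classes[apply(votes, 1, which.max)]
}

#' Out-of-bag accuracy
#'
#' Each subject is predicted by majority vote among the trees whose
#' bootstrap excluded it (vote ties resolve to the lowest class index);
#' accuracy is the fraction of correct OOB predictions. Subjects that are
#' never out of bag are excluded from the estimate with a warning.
#'
#' @param e A `bag_ensemble`.
#' @return Numeric accuracy in [0, 1].
#' @export
oob_accuracy <- function(e) {
  n <- nrow(e$x)
  votes <- matrix(0L, n, length(e$classes))
  for (b in seq_len(e$n_trees)) {
    oob <- which(e$inbag[, b] == 0L)
    if (!length(oob)) next
    pr <- predict(e$trees[[b]], e$x[oob, , drop = FALSE])
    votes[cbind(oob, pr)] <- votes[cbind(oob, pr)] + 1L
  }
  covered <- rowSums(votes) > 0L
  if (!all(covered)) {
    warning(sum(!covered), " subject(s) never out of bag; excluded from estimate")
  }
  pred <- apply(votes[covered, , drop = FALSE], 1, which.max)
  mean(pred == e$y[covered])
}

#' Permuted-delta-error feature importance
#'
#' For every tree and feature, the feature's values are permuted among the
#' tree's out-of-bag subjects and the change in that tree's OOB
#' misclassification error is recorded. A feature's importance is the mean
#' of these deltas over trees divided by their standard deviation (0 when
#' the deltas are constant), then the vector is normalized by its maximum
#' absolute value so the most important feature reads +/-1.
#'
#' @param e A `bag_ensemble`.
#' @param seed Integer seed for the permutations.
#' @return Named numeric importance vector over features.
#' @export
permutation_importance <- function(e, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- ncol(e$x)
  delta <- matrix(NA_real_, e$n_trees, p)
  for (b in seq_len(e$n_trees)) {
    oob <- which(e$inbag[, b] == 0L)
    if (length(oob) < 2L) next
    xo <- e$x[oob, , drop = FALSE]
    yo <- e$y[oob]
    err0 <- mean(predict(e$trees[[b]], xo) != yo)
    for (f in seq_len(p)) {
      xp <- xo
      xp[, f] <- xp[sample.int(length(oob)), f]
      delta[b, f] <- mean(predict(e$trees[[b]], xp) != yo) - err0
    }
  }
  mu <- colMeans(delta, na.rm = TRUE)
  sd_ <- apply(delta, 2, stats::sd, na.rm = TRUE)
  imp <- ifelse(sd_ > 0, mu / sd_, 0)
  m <- max(abs(imp))
  if (m > 0) imp <- imp / m
  stats::setNames(imp, e$feature_names)
}

#' Hemisphere-averaged oxygenation-feature importance
#'
#' @param imp Named importance vector containing the six `rate_*` features.
#' @return Named numeric `c(left = ..., right = ...)`: arithmetic means of
#'   the three left- and three right-gyrus oxygenation importances.
#' @export
lateral_importance <- function(imp) {
  kinds <- feature_kinds()
  oxy <- names(kinds)[kinds == "oxygenation"]
  if (!all(oxy %in% names(imp))) {
    stop("config error: importance vector missing oxygenation features")
  }
  left <- oxy[grepl("_L_", oxy)]
  right <- oxy[grepl("_R_", oxy)]
  c(left = mean(imp[left]), right = mean(imp[right]))
}

.TRIAL_DEFS <- list(
  list(name = "PD-NOR vs PD-OH",
       map = c("PD-POS" = "PD-NOR", "PD-NEG" = "PD-NOR", "PD-OH" = "PD-OH")),
  list(name = "PD-NEG vs PD-POS",
       map = c("PD-POS" = "PD-POS", "PD-NEG" = "PD-NEG")),
  list(name = "PD-NEG vs PD-POS vs PD-OH",
       map = c("PD-POS" = "PD-POS", "PD-NEG" = "PD-NEG", "PD-OH" = "PD-OH"))
)

.trial_table <- function(table, def) {
  if (any(table$label == "HC")) {
    message("excluding ", sum(table$label == "HC"),
            " HC subject(s) from classification")
    table <- table[table$label != "HC", , drop = FALSE]
  }
  keep <- table$label %in% names(def$map)
  tab <- table[keep, , drop = FALSE]
  tab$label <- unname(def$map[tab$label])
  if (length(unique(tab$label)) < length(unique(def$map))) {
    stop("configuration error: empty class in trial ", def$name)
  }
  tab
}

#' Run the three classification trials
#'
#' Trials: (1) PD-NOR vs PD-OH, (2) PD-NEG vs PD-POS, (3) PD-NEG vs PD-POS
#' vs PD-OH, each with a freshly fitted bagged ensemble. When `tables` is a
#' list of replicate cohorts, OOB accuracy is reported as mean and sd over
#' replicates and the importance vectors are averaged.
#'
#' @param tables A feature table, or a list of replicate feature tables.
#' @param n_trees Trees per ensemble.
#' @param seed Base seed; replicate r of trial k uses `seed + 1000*k + r`.
#' @param importance Compute permutation importance (set FALSE to skip the
#'   slowest step when only accuracies are needed).
#' @return List of three `ensemble_result` objects: `trial`,
#'   `oob_accuracy_mean`, `oob_accuracy_sd`, `accuracies`, `importance`,
#'   `lateral`.
#' @export
run_trials <- function(tables, n_trees = 1000, seed = 1, importance = TRUE) {
  if (is.data.frame(tables)) tables <- list(tables)
  results <- vector("list", length(.TRIAL_DEFS))
  for (k in seq_along(.TRIAL_DEFS)) {
    def <- .TRIAL_DEFS[[k]]
    accs <- numeric(length(tables))
    imps <- NULL
    for (r in seq_along(tables)) {
      tab <- .trial_table(tables[[r]], def)
      s <- seed + 1000L * k + r
      e <- fit_ensemble(tab, n_trees = n_trees, seed = s)
      accs[r] <- oob_accuracy(e)
      if (importance) {
        imp <- permutation_importance(e, seed = s + 500000L)
        imps <- if (is.null(imps)) imp else imps + imp
      }
    }
    imp_mean <- if (importance) imps / length(tables) else NULL
    results[[k]] <- structure(
      list(trial = def$name,
           oob_accuracy_mean = mean(accs),
           oob_accuracy_sd = if (length(accs) > 1) stats::sd(accs) else NA_real_,
           accuracies = accs,
           importance = imp_mean,
           lateral = if (importance) lateral_importance(imp_mean) else NULL),
      class = "ensemble_result"
    )
  }
  names(results) <- vapply(.TRIAL_DEFS, `[[`, character(1), "name")
  results
}

#' @export
print.ensemble_result <- function(x, ...) {
  cat("<ensemble_result> ", x$trial, ": OOB accuracy ",
      sprintf("%.1f%%", 100 * x$oob_accuracy_mean),
      if (!is.na(x$oob_accuracy_sd)) sprintf(" +/- %.1f%%", 100 * x$oob_accuracy_sd),
      " (", length(x$accuracies), " replicate(s))\n", sep = "")
  invisible(x)
}

#' Write a feature table to CSV with feature-kind tags
#'
#' The first line is a comment tagging each feature column with its kind;
#' [read_feature_table()] restores it.
#'
#' @param table Feature table.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  kinds <- feature_kinds()
  tag <- paste(sprintf("%s=%s", names(kinds), kinds), collapse = ",")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# feature_kinds: ", tag), con)
  utils::write.csv(table, con, row.names = FALSE)
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#' @param path CSV path.
#' @return Feature table data.frame.
#' @export
read_feature_table <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Serialize trial results as JSON
#' @param results List of `ensemble_result` from [run_trials()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_trial_results_json <- function(results, path) {
  out <- lapply(results, function(r) {
    list(trial = r$trial,
         oob_accuracy_mean = r$oob_accuracy_mean,
         oob_accuracy_sd = r$oob_accuracy_sd,
         importance = as.list(r$importance),
         lateral = as.list(r$lateral))
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
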