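## Evaluation metrics (F1 / ACC / AUC), the repeated-randomization and
## cross-validation protocols, and thin adapters for baseline learners.

#' Confusion counts
#'
#' @param labels_true,labels_pred vectors of equal length; anything equal to
#'   `"positive"` or `1` counts as positive.
#' @return object of class `confusion_counts`: list with TP, TN, FP, FN.
#' @export
confusion_counts <- function(labels_true, labels_pred) {
  if (length(labels_true) != length(labels_pred))
    stop("label vectors must have equal length")
  as_pos <- function(x) x == "positive" | x == 1 | x == TRUE
  yt <- as_pos(labels_true); yp <- as_pos(labels_pred)
  structure(list(
    TP = sum(yt & yp), TN = sum(!yt & !yp),
    FP = sum(!yt & yp), FN = sum(yt & !yp)), class = "confusion_counts")
}

#' F1, accuracy, precision and recall from confusion counts
#'
#' `F1 = 2 P R / (P + R)`, `ACC = (TP + TN) / total`,
#' `P = TP / (TP + FP)`, `R = TP / (TP + FN)`. Degenerate 0/0 ratios are
#' reported as 0 and flagged.
#'
#' @param cc a [confusion_counts()].
#' @return list with F1, ACC, Precision, Recall and `degenerate` (logical).
#' @export
f1_acc <- function(cc) {
  degenerate <- FALSE
  safe <- function(num, den) {
    if (den == 0) { degenerate <<- TRUE; 0 } else num / den
  }
  precision <- safe(cc$TP, cc$TP + cc$FP)
  recall <- safe(cc$TP, cc$TP + cc$FN)
  f1 <- safe(2 * precision * recall, precision + recall)
  acc <- safe(cc$TP + cc$TN, cc$TP + cc$TN + cc$FP + cc$FN)
  list(F1 = f1, ACC = acc, Precision = precision, Recall = recall,
       degenerate = degenerate)
}

#' Rank-based AUC (Mann-Whitney, midrank ties)
#'
#' @param scores numeric scores (larger = more positive).
#' @param labels_true truth vector (positives as `"positive"`/`1`/`TRUE`).
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(scores, labels_true) {
  pos <- labels_true == "positive" | labels_true == 1 | labels_true == TRUE
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0)
    stop("AUC requires both classes present")
  r <- rank(scores)  # midranks
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

format_pm <- function(mean, sd) sprintf("%.3f ± %.3f", mean, sd)

new_eval_report <- function(per_repeat, protocol) {
  agg <- do.call(rbind, lapply(split(per_repeat, per_repeat$learner),
    function(d) data.frame(
      learner = d$learner[1],
      F1_mean = mean(d$F1), F1_sd = stats::sd(d$F1),
      ACC_mean = mean(d$ACC), ACC_sd = stats::sd(d$ACC),
      AUC_mean = mean(d$AUC), AUC_sd = stats::sd(d$AUC),
      stringsAsFactors = FALSE)))
  rownames(agg) <- NULL
  agg[is.na(agg)] <- 0  # single repeat: SD reported as 0
  structure(list(per_repeat = per_repeat, summary = agg,
                 protocol = protocol), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("Evaluation report (%s, %d repeat(s))\n",
              x$protocol$name, x$protocol$n_repeats))
  for (i in seq_len(nrow(x$summary))) {
    s <- x$summary[i, ]
    cat(sprintf("  %-12s F1 %s  ACC %s  AUC %s\n", s$learner,
                format_pm(s$F1_mean, s$F1_sd),
                format_pm(s$ACC_mean, s$ACC_sd),
                format_pm(s$AUC_mean, s$AUC_sd)))
  }
  invisible(x)
}

#' Serialize an evaluation report
#' @param report an `eval_report`.
#' @param path_json,path_tsv optional output paths.
#' @export
report_to_json <- function(report, path_json = NULL, path_tsv = NULL) {
  js <- jsonlite::toJSON(list(summary = report$summary,
                              per_repeat = report$per_repeat,
                              protocol = report$protocol),
                         auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(path_tsv))
    utils::write.table(report$summary, path_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(path_json)) { writeLines(js, path_json); return(invisible(js)) }
  js
}

## stratified index split by s into fractions (train, val, test)
stratified_split <- function(s, fractions = c(0.5, 0.2, 0.3)) {
  part <- integer(length(s))
  for (cls in unique(s)) {
    idx <- sample(which(s == cls))
    n <- length(idx)
    n_train <- round(fractions[1] * n)
    n_val <- round(fractions[2] * n)
    part[idx[seq_len(n_train)]] <- 1L
    part[idx[n_train + seq_len(min(n_val, n - n_train))]] <- 2L
    part[idx[part[idx] == 0L]] <- 3L
  }
  part
}

#' Learner specification for the evaluation protocols
#'
#' The default (`family = "pande"`, `n = 2`, `prior = "alphamax"`) is the
#' PA2DE (V2.0) configuration: a second-order averaged dependence estimator
#' whose class prior comes from the AlphaMax estimator. The same model with
#' `prior = "elkan-noto"` is plain PA2DE.
#'
#' @param family `"pande"`, `"paode"`, `"pnb"` or `"ptan"`.
#' @param n dependence order (pande only).
#' @param prior prior estimation method, or `"fixed"` with `alpha` given.
#' @param alpha fixed prior (only for `prior = "fixed"`).
#' @return a list understood by [randomization_protocol()] and
#'   [cross_validation()].
#' @export
learner_spec <- function(family = "pande", n = 2L,
                         prior = c("alphamax", "elkan-noto", "fixed"),
                         alpha = NULL) {
  prior <- match.arg(prior)
  list(family = family, n = n, prior = prior, alpha = alpha)
}

## fit preprocessing (discretizer + mRMR) on training rows, fit/estimate the
## prior on a validation split, fit the learner, and score a test split
fit_learner <- function(spec, Xd_train, s_train, prior_est, m = 1) {
  alpha <- switch(spec$prior,
                  fixed = spec$alpha,
                  prior_est$alpha)
  alpha <- clamp_prior(alpha)
  alpha <- min(alpha, 1 - 1e-9)
  pu_fit(pu_dataset(Xd_train, s_train), family = spec$family, n = spec$n,
         prior = alpha, m = m)
}

#' Repeated-randomization evaluation protocol
#'
#' Per repeat: an equal number of unlabelled rows is drawn to match the
#' positives; the resulting set is split 50/20/30 (train/validation/test),
#' stratified by the labelling indicator `s`; the discretizer and mRMR
#' selection are fit on the training split; the nontraditional scorer is fit
#' on the training split and the class prior estimated on the validation
#' split; training and validation are then merged ("trainingV") and each
#' learner refit before evaluation on the test split. Metrics are aggregated
#' as mean and SD over repeats.
#'
#' @param features numeric matrix (rows = sites).
#' @param s 0/1 labelling indicator per row.
#' @param learners named list of learner specs, each a list with `family`
#'   (`"pande"`, `"paode"`, `"pnb"`, `"ptan"`), `n`, `prior` (`"alphamax"`,
#'   `"elkan-noto"` or `"fixed"`) and optional `alpha`.
#' @param n_repeats number of randomization repeats (paper protocol: 100).
#' @param seed base seed; repeat r uses `seed + r`.
#' @param n_bins discretization bins.
#' @param mrmr_k number of mRMR-selected features (default 100, capped at
#'   the feature count).
#' @param m smoothing weight for the Bayes learners.
#' @return an `eval_report`.
#' @export
randomization_protocol <- function(features, s,
                                   learners = list(
                                     `PA2DE(V2.0)` = learner_spec()),
                                   n_repeats = 100L, seed = 1L,
                                   n_bins = 5L, mrmr_k = 100L, m = 1) {
  s <- as.integer(s)
  idx_pos <- which(s == 1L); idx_unl <- which(s == 0L)
  if (length(idx_unl) < length(idx_pos))
    stop("unlabelled pool smaller than the positive set")
  mrmr_k <- min(mrmr_k, ncol(features))
  rows <- list()
  for (r in seq_len(n_repeats)) {
    rows[[r]] <- local_seed(seed + r, {
      take <- c(idx_pos, sample(idx_unl, length(idx_pos)))
      Xr <- features[take, , drop = FALSE]
      sr <- s[take]
      part <- stratified_split(sr)
      disc <- fit_discretizer(Xr[part == 1L, , drop = FALSE], n_bins)
      Xd <- discretize(disc, Xr)
      sel <- mrmr_select(Xd[part == 1L, , drop = FALSE], sr[part == 1L],
                         mrmr_k)$feature
      Xd <- Xd[, sel, drop = FALSE]
      scorer <- fit_nontraditional_scorer(
        pu_dataset(Xd[part == 1L, , drop = FALSE], sr[part == 1L]), m = m)
      sc <- score_set(scorer, pu_dataset(Xd[part == 2L, , drop = FALSE],
                                         sr[part == 2L]))
      frac_lab <- mean(sr == 1L)
      priors <- list(
        `elkan-noto` = elkan_noto_estimate(sc, frac_lab),
        alphamax = alphamax_estimate(sc))
      trainV <- part %in% c(1L, 2L)
      out <- lapply(names(learners), function(nm) {
        spec <- learners[[nm]]
        pe <- if (spec$prior == "fixed") NULL else priors[[spec$prior]]
        model <- fit_learner(spec, Xd[trainV, , drop = FALSE], sr[trainV],
                             pe, m = m)
        pred <- predict(model, Xd[part == 3L, , drop = FALSE])
        truth <- sr[part == 3L]
        met <- f1_acc(confusion_counts(truth, pred$label))
        data.frame(repeat_id = r, learner = nm, F1 = met$F1, ACC = met$ACC,
                   AUC = auc_score(pred$posterior_positive, truth),
                   alpha = model$alpha, stringsAsFactors = FALSE)
      })
      do.call(rbind, out)
    })
  }
  new_eval_report(do.call(rbind, rows),
                  list(name = "randomization 50/20/30",
                       n_repeats = n_repeats, seed = seed,
                       mrmr_k = mrmr_k, n_bins = n_bins))
}

#' Stratified k-fold cross-validation
#'
#' Folds are stratified by the labelling indicator. Within each fold's
#' training part an internal 75/25 split provides the held-out scores for
#' prior estimation before the learner is refit on the full training part.
#'
#' @inheritParams randomization_protocol
#' @param learner a single learner spec (see [randomization_protocol()]).
#' @param k_folds number of folds (default 5).
#' @return an `eval_report` (one row per fold).
#' @export
cross_validation <- function(features, s, learner = learner_spec(),
                             k_folds = 5L, seed = 1L, n_bins = 5L,
                             mrmr_k = 100L, m = 1) {
  s <- as.integer(s)
  stopifnot(k_folds >= 2L)
  mrmr_k <- min(mrmr_k, ncol(features))
  fold <- local_seed(seed, {
    f <- integer(length(s))
    for (cls in unique(s)) {
      idx <- sample(which(s == cls))
      f[idx] <- rep_len(seq_len(k_folds), length(idx))
    }
    f
  })
  if (any(tapply(s == 1L, fold, sum) == 0))
    stop("a fold has no positive rows; reduce k_folds")
  rows <- lapply(seq_len(k_folds), function(fi) {
    local_seed(seed + fi, {
      tr <- fold != fi
      disc <- fit_discretizer(features[tr, , drop = FALSE], n_bins)
      Xd <- discretize(disc, features)
      sel <- mrmr_select(Xd[tr, , drop = FALSE], s[tr], mrmr_k)$feature
      Xd <- Xd[, sel, drop = FALSE]
      inner <- stratified_split(s[tr], c(0.75, 0.25, 0))
      tr_idx <- which(tr)
      scorer <- fit_nontraditional_scorer(
        pu_dataset(Xd[tr_idx[inner == 1L], , drop = FALSE],
                   s[tr_idx[inner == 1L]]), m = m)
      sc <- score_set(scorer,
                      pu_dataset(Xd[tr_idx[inner == 2L], , drop = FALSE],
                                 s[tr_idx[inner == 2L]]))
      pe <- if (learner$prior == "elkan-noto")
        elkan_noto_estimate(sc, mean(s[tr] == 1L))
      else if (learner$prior == "alphamax") alphamax_estimate(sc)
      else NULL
      model <- fit_learner(learner, Xd[tr, , drop = FALSE], s[tr], pe, m = m)
      pred <- predict(model, Xd[!tr, , drop = FALSE])
      truth <- s[!tr]
      met <- f1_acc(confusion_counts(truth, pred$label))
      data.frame(repeat_id = fi, learner = learner$family, F1 = met$F1,
                 ACC = met$ACC,
                 AUC = auc_score(pred$posterior_positive, truth),
                 alpha = model$alpha, stringsAsFactors = FALSE)
    })
  })
  new_eval_report(do.call(rbind, rows),
                  list(name = sprintf("%d-fold cross-validation", k_folds),
                       n_repeats = k_folds, seed = seed, mrmr_k = mrmr_k,
                       n_bins = n_bins))
}

#' Paired comparison of two learners over repeats
#'
#' Two-sided paired Student's t-test on a per-repeat metric; the
#' conventional significance threshold in this setting is p <= 0.01.
#'
#' @param report an `eval_report` containing both learners.
#' @param a,b learner names.
#' @param metric `"F1"`, `"ACC"` or `"AUC"`.
#' @return htest object.
#' @export
compare_learners <- function(report, a, b, metric = "F1") {
  pr <- report$per_repeat
  xa <- pr[pr$learner == a, metric]
  xb <- pr[pr$learner == b, metric]
  if (!length(xa) || !length(xb)) stop("learner not present in report")
  stats::t.test(xa, xb, paired = TRUE)
}

#' Baseline learner adapters
#'
#' Thin adapters around external supervised / one-class learners, used only
#' for comparison: `"rf"` and `"svm"` train with the labelling indicator as
#' the class; `"one-class-svm"` trains on the labelled positives only and
#' maps rejected ('?') outputs to negative. The PU pipeline has no
#' dependency on these backends: when the backing package
#' (randomForest / e1071) is not installed the adapter fails with a clear
#' error and everything else is unaffected.
#'
#' @param name `"rf"`, `"svm"` or `"one-class-svm"`.
#' @param train,test [pu_dataset()] objects.
#' @return list with `scores` (numeric) and `labels`
#'   (`"positive"`/`"negative"`).
#' @export
baseline_adapter <- function(name = c("rf", "svm", "one-class-svm"),
                             train, test) {
  name <- match.arg(name)
  backend <- switch(name, rf = "randomForest", "e1071")
  if (!requireNamespace(backend, quietly = TRUE))
    stop("baseline adapter '", name, "' requires the optional package '",
         backend, "', which is not installed; the PU learning pipeline ",
         "does not depend on it")
  Xtr <- as.data.frame(train$X); Xte <- as.data.frame(test$X)
  if (name == "rf") {
    fit <- randomForest::randomForest(Xtr, factor(train$s, levels = 0:1))
    sc <- stats::predict(fit, Xte, type = "prob")[, "1"]
  } else if (name == "svm") {
    fit <- e1071::svm(Xtr, factor(train$s, levels = 0:1), probability = TRUE)
    pr <- stats::predict(fit, Xte, probability = TRUE)
    sc <- attr(pr, "probabilities")[, "1"]
  } else {
    fit <- e1071::svm(Xtr[train$s == 1L, , drop = FALSE], y = NULL,
                      type = "one-classification")
    sc <- as.numeric(stats::predict(fit, Xte))  # TRUE -> 1, '?' -> 0
  }
  list(scores = sc,
       labels = ifelse(sc >= 0.5, "positive", "negative"))
}
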