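test_that("confusion_counts and f1_acc implement the definitions", {
  truth <- c(rep("positive", 5), rep("negative", 5))
  cc <- confusion_counts(truth, truth)
  expect_equal(unlist(cc[c("TP", "TN", "FP", "FN")]),
               c(TP = 5, TN = 5, FP = 0, FN = 0))
  m <- f1_acc(cc)
  expect_equal(m$F1, 1); expect_equal(m$ACC, 1)

  pred <- rep("positive", 10)
  truth <- c(rep("positive", 4), rep("negative", 6))
  cc <- confusion_counts(truth, pred)
  expect_equal(unlist(cc[c("TP", "FP", "TN", "FN")]),
               c(TP = 4, FP = 6, TN = 0, FN = 0))
  m <- f1_acc(cc)
  expect_equal(m$Precision, 0.4)
  expect_equal(m$Recall, 1)
  expect_equal(m$F1, 2 * 0.4 / 1.4, tolerance = 1e-12)
  expect_equal(m$ACC, 0.4)

  m0 <- f1_acc(confusion_counts(c(1, 1), c(0, 0)))
  expect_equal(m0$Precision, 0)
  expect_true(m0$degenerate)

  expect_error(confusion_counts(1:3, 1:2), "equal length")

  # random case vs hand tally
  set.seed(41)
  yt <- rbinom(50, 1, 0.5); yp <- rbinom(50, 1, 0.5)
  cc <- confusion_counts(yt, yp)
  expect_equal(cc$TP, sum(yt == 1 & yp == 1))
  expect_equal(cc$TN, sum(yt == 0 & yp == 0))
  expect_equal(cc$TP + cc$TN + cc$FP + cc$FN, 50)
})

test_that("F1/ACC structural properties hold", {
  set.seed(42)
  for (i in 1:20) {
    cc <- structure(as.list(rpois(4, 10) + 1), class = "confusion_counts")
    names(cc) <- c("TP", "TN", "FP", "FN")
    m <- f1_acc(cc)
    expect_equal(m$F1, 2 / (1 / m$Precision + 1 / m$Recall),
                 tolerance = 1e-12)
    swapped <- structure(list(TP = cc$TN, TN = cc$TP, FP = cc$FN,
                              FN = cc$FP), class = "confusion_counts")
    expect_equal(f1_acc(swapped)$ACC, m$ACC, tolerance = 1e-12)
  }
})

test_that("auc_score is the midrank Mann-Whitney statistic", {
  expect_equal(auc_score(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(auc_score(rep(0.5, 10), c(1, 1, 1, 0, 0, 0, 1, 0, 1, 0)), 0.5)
  expect_error(auc_score(1:3, c(1, 1, 1)), "both classes")

  set.seed(43)
  for (i in 1:10) {
    sc <- round(runif(20), 1)   # ties likely
    y <- rbinom(20, 1, 0.5); y[1] <- 1; y[2] <- 0
    expect_equal(auc_score(sc, y), bf_auc(sc, y == 1), tolerance = 1e-12)
    # invariance under strictly monotone transforms
    expect_equal(auc_score(exp(3 * sc), y), auc_score(sc, y),
                 tolerance = 1e-12)
  }
})

test_that("stratified splitting respects the 50/20/30 fractions", {
  s <- rep(c(1L, 0L), each = 50)
  part <- glycopu:::local_seed(1, glycopu:::stratified_split(s))
  expect_equal(sum(part == 1L), 50)
  expect_equal(sum(part == 2L), 20)
  expect_equal(sum(part == 3L), 30)
  # stratified: each class split at the same rates
  expect_equal(sum(part == 1L & s == 1L), 25)
  expect_equal(sum(part == 2L & s == 0L), 10)
})

test_that("randomization_protocol is deterministic and performs on
           separable synthetic data", {
  sim <- generate_scar(scar_spec(n = 800, alpha = 0.5, c = 0.8,
                                 separation = 3, seed = 51))
  feats <- sim$dataset$X + 0   # discrete features as numeric
  s <- sim$dataset$s
  learners <- list(`PA2DE(V2.0)` = learner_spec(),
                   PNB = learner_spec(family = "pnb",
                                      prior = "elkan-noto"))
  r1 <- randomization_protocol(feats, s, learners, n_repeats = 3, seed = 9,
                               mrmr_k = 10)
  r2 <- randomization_protocol(feats, s, learners, n_repeats = 3, seed = 9,
                               mrmr_k = 10)
  expect_identical(r1$per_repeat, r2$per_repeat)
  expect_equal(nrow(r1$per_repeat), 6)
  expect_gte(r1$summary$AUC_mean[r1$summary$learner == "PA2DE(V2.0)"], 0.9)
  expect_true(all(r1$summary$F1_sd >= 0))
  expect_match(paste(capture.output(print(r1)), collapse = "\n"), "±")
  expect_error(randomization_protocol(feats, rep(1L, nrow(feats))),
               "pool")
})

test_that("cross_validation builds stratified folds and is seeded", {
  sim <- generate_scar(scar_spec(n = 400, alpha = 0.5, c = 1, seed = 52,
                                 separation = 2))
  feats <- sim$dataset$X + 0
  s <- sim$dataset$s
  r <- cross_validation(feats, s, learner_spec(family = "pnb",
                                               prior = "elkan-noto"),
                        k_folds = 5, seed = 2, mrmr_k = 10)
  expect_equal(nrow(r$per_repeat), 5)
  r2 <- cross_validation(feats, s, learner_spec(family = "pnb",
                                                prior = "elkan-noto"),
                         k_folds = 5, seed = 2, mrmr_k = 10)
  expect_identical(r$per_repeat, r2$per_repeat)

  s_few <- c(rep(1L, 4), rep(0L, 96))
  expect_error(cross_validation(matrix(rnorm(600), 100, 6), s_few,
                                learner_spec(family = "pnb",
                                             prior = "fixed", alpha = 0.1),
                                k_folds = 5, seed = 1, mrmr_k = 3),
               "fold")
})

test_that("compare_learners runs a paired t-test over repeats", {
  sim <- generate_scar(scar_spec(n = 600, alpha = 0.5, c = 0.8,
                                 separation = 2, seed = 53))
  r <- randomization_protocol(sim$dataset$X + 0, sim$dataset$s,
                              list(a = learner_spec(family = "pnb",
                                                    prior = "elkan-noto"),
                                   b = learner_spec()),
                              n_repeats = 3, seed = 4, mrmr_k = 8)
  ht <- compare_learners(r, "a", "b", "F1")
  expect_true(is.numeric(ht$p.value))
  expect_error(compare_learners(r, "a", "zzz"), "not present")
})

test_that("baseline adapters fail cleanly without their backends and the
           PU pipeline is unaffected", {
  sim <- generate_scar(scar_spec(n = 200, alpha = 0.5, c = 1, seed = 54))
  tr <- pu_dataset(sim$dataset$X[1:150, ], sim$dataset$s[1:150])
  te <- pu_dataset(sim$dataset$X[151:200, ], sim$dataset$s[151:200])
  for (nm in c("rf", "svm", "one-class-svm")) {
    backend <- if (nm == "rf") "randomForest" else "e1071"
    if (requireNamespace(backend, quietly = TRUE)) {
      out <- baseline_adapter(nm, tr, te)
      expect_true(all(out$labels %in% c("positive", "negative")))
    } else {
      expect_error(baseline_adapter(nm, tr, te), "not installed")
    }
  }
  # isolation: the PU learner still runs end to end
  m <- pu_fit(tr, "pnb", prior = 0.5)
  expect_length(predict(m, te$X)$posterior_positive, 50)
})

test_that("report serialization writes JSON and TSV", {
  sim <- generate_scar(scar_spec(n = 300, alpha = 0.5, c = 1,
                                 separation = 2, seed = 55))
  r <- cross_validation(sim$dataset$X + 0, sim$dataset$s,
                        learner_spec(family = "pnb", prior = "elkan-noto"),
                        k_folds = 3, seed = 1, mrmr_k = 5)
  pj <- tempfile(fileext = ".json"); pt <- tempfile(fileext = ".tsv")
  report_to_json(r, pj, pt)
  expect_true(file.exists(pj) && file.exists(pt))
  js <- jsonlite::fromJSON(pj)
  expect_equal(nrow(js$per_repeat), 3)
})
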