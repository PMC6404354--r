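make_split_scores <- function(alpha, cc, n = 4000, seed = 1,
                              separation = 0.73) {
  sim <- generate_scar(scar_spec(n = n, alpha = alpha, c = cc,
                                 separation = separation, seed = seed))
  ds <- sim$dataset
  part <- glycopu:::local_seed(seed + 5000,
                               glycopu:::stratified_split(ds$s,
                                                          c(0.6, 0.4, 0)))
  tr <- pu_dataset(ds$X[part == 1, , drop = FALSE], ds$s[part == 1])
  va <- pu_dataset(ds$X[part == 2, , drop = FALSE], ds$s[part == 2])
  sc <- score_set(fit_nontraditional_scorer(tr), va)
  list(scores = sc, frac = mean(ds$s), sim = sim)
}

test_that("nontraditional scorer is calibrated at the extremes", {
  # separable data: labelled validation scores near 1
  x <- make_split_scores(0.4, 1, n = 3000, seed = 2, separation = 6)
  expect_gt(mean(x$scores$scores_labelled), 0.9)

  # identical feature distributions: scores approximate the base rate
  set.seed(3)
  X <- matrix(sample(1:3, 2000 * 5, TRUE), 2000, 5)
  s <- rbinom(2000, 1, 0.3)
  sc <- score_set(fit_nontraditional_scorer(pu_dataset(X[1:1500, ],
                                                       s[1:1500])),
                  pu_dataset(X[1501:2000, ], s[1501:2000]))
  expect_equal(mean(c(sc$scores_labelled, sc$scores_unlabelled)), 0.3,
               tolerance = 0.08)

  # deterministic refit
  s1 <- fit_nontraditional_scorer(pu_dataset(X, s))
  s2 <- fit_nontraditional_scorer(pu_dataset(X, s))
  expect_identical(predict(s1, X[1:10, ]), predict(s2, X[1:10, ]))

  expect_error(fit_nontraditional_scorer(
    pu_dataset(X[s == 1, ][1:10, ], rep(1L, 10))), "labelled and unlabelled")
})

test_that("elkan_noto_estimate implements the e1 estimator", {
  sc <- structure(list(scores_labelled = rep(1, 50),
                       scores_unlabelled = runif(50)), class = "score_set")
  pe <- elkan_noto_estimate(sc, 0.2)
  expect_equal(pe$c, 1)
  expect_equal(pe$alpha, 0.2)

  sc$scores_labelled <- rep(0.5, 50)
  pe <- elkan_noto_estimate(sc, 0.2)
  expect_equal(pe$alpha, 0.4)
  expect_equal(pe$method, "elkan-noto")

  # alpha >= frac_labelled always (c <= 1 by construction of scores)
  set.seed(6)
  for (i in 1:10) {
    sc$scores_labelled <- runif(50)
    frac <- runif(1, 0.05, 0.5)
    expect_gte(elkan_noto_estimate(sc, frac)$alpha, frac - 1e-12)
  }

  sc$scores_labelled <- rep(0, 10)
  expect_error(elkan_noto_estimate(sc, 0.2), "c is 0")
})

test_that("alphamax_estimate hits the grid bounds in the pure limits", {
  set.seed(7)
  # unlabelled drawn from the positive score distribution
  pos <- rbeta(500, 8, 2)
  sc <- structure(list(scores_labelled = pos,
                       scores_unlabelled = rbeta(500, 8, 2)),
                  class = "score_set")
  am <- alphamax_estimate(sc)
  expect_gte(am$diagnostics$alpha_star, 0.9)

  # unlabelled from a disjoint null distribution
  sc$scores_unlabelled <- rbeta(500, 1, 30)
  am <- alphamax_estimate(sc)
  expect_lte(am$diagnostics$alpha_star, 0.05)
})

test_that("alphamax profile likelihood is nonincreasing after its maximum", {
  x <- make_split_scores(0.3, 0.5, seed = 9)
  am <- alphamax_estimate(x$scores)
  ll <- am$diagnostics$loglik
  i_max <- which.max(ll)
  expect_true(all(diff(ll[i_max:length(ll)]) <= 1e-6))
})

test_that("alphamax recovers a known mixture proportion", {
  # direct mixture on the score scale: contamination 0.3
  errs <- sapply(1:10, function(seed) {
    set.seed(seed)
    pos <- rbeta(2500, 6, 2)
    neg <- rbeta(2500, 2, 6)
    unl <- ifelse(runif(2500) < 0.3, rbeta(2500, 6, 2), rbeta(2500, 2, 6))
    sc <- structure(list(scores_labelled = pos, scores_unlabelled = unl),
                    class = "score_set")
    alphamax_estimate(sc)$diagnostics$alpha_star - 0.3
  })
  expect_lte(median(abs(errs)), 0.1)
})

test_that("both estimators overestimate (or match) the true prior on
           average, and alphamax is closer", {
  settings <- expand.grid(alpha = c(0.2, 0.3), cc = c(0.5, 1.0))
  res <- do.call(rbind, lapply(seq_len(nrow(settings)), function(i) {
    t(sapply(1:12, function(seed) {
      x <- make_split_scores(settings$alpha[i], settings$cc[i], seed = seed)
      c(alpha = settings$alpha[i],
        en = elkan_noto_estimate(x$scores, x$frac)$alpha,
        am = alphamax_estimate(x$scores)$alpha)
    }))
  }))
  expect_gte(mean(res[, "en"] - res[, "alpha"]), 0)
  expect_gte(mean(res[, "am"] - res[, "alpha"]), 0)
  expect_lte(median(abs(res[, "am"] - res[, "alpha"])),
             median(abs(res[, "en"] - res[, "alpha"])))
})

test_that("clamp_prior applies the low-prior floor", {
  expect_warning(a <- clamp_prior(1e-6), "clamped")
  expect_equal(a, 1e-4)
  expect_equal(clamp_prior(0.2), 0.2)
  pe <- prior_estimate("fixed", 0.1)
  expect_match(as.character(prior_to_json(pe)), "fixed")
})
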