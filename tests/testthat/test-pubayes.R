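test_that("derive_negative_conditionals inverts the mixture and clips", {
  r <- derive_negative_conditionals(c(0.8, 0.2), c(0.5, 0.5), 0.5)
  expect_equal(r$conditionals, c(0.2, 0.8), tolerance = 1e-12)
  expect_equal(r$n_clipped, 0)

  # raw -0.2 at the first value: clipped to eps and renormalized
  r <- derive_negative_conditionals(c(0.8, 0.2), c(0.3, 0.7), 0.5)
  expect_equal(r$n_clipped, 1)
  expect_equal(sum(r$conditionals), 1)
  expect_lt(r$conditionals[1], 1e-5)

  # alpha -> 0 limit: negative conditionals approach the marginal
  r <- derive_negative_conditionals(c(0.8, 0.2), c(0.5, 0.5), 1e-9)
  expect_equal(r$conditionals, c(0.5, 0.5), tolerance = 1e-8)

  expect_error(derive_negative_conditionals(c(1, 0), c(0.5, 0.5), 1),
               "alpha")
})

test_that("PNB on a hand-countable dataset matches manual computation", {
  # 8 rows, 2 binary attributes, 4 labelled positives; alpha = 0.5, m = 1
  X <- rbind(c(1, 1), c(1, 1), c(1, 2), c(2, 1),
             c(2, 2), c(2, 2), c(1, 2), c(2, 2))
  s <- c(1, 1, 1, 1, 0, 0, 0, 0)
  m <- pu_fit(pu_dataset(X, s), "pnb", prior = 0.5, m = 1)
  # hand computation (m-estimate smoothing, uniform base):
  #   x1: P(x1=1|1) = (3 + .5)/(4 + 1) = 0.7
  #       raw P(x1=1) = 4/8, raw P(x1=1|1) = 3/4
  #       raw P(x1=1|0) = (0.5 - 0.5*0.75)/0.5 = 0.25
  #       smoothed, n0 = 8*(1-alpha) = 4: (4*0.25 + 0.5)/(4 + 1) = 0.3
  #   x2: P(x2=1|1) = 0.7; raw P(x2=1) = 3/8 -> raw P(x2=1|0) = 0
  #       smoothed: (4*0 + 0.5)/5 = 0.1
  #   posterior(1,1) = .5*.7*.7 / (.5*.7*.7 + .5*.3*.1) = 0.245/0.260
  p <- predict(m, rbind(c(1, 1)))$posterior_positive
  expect_equal(p, 0.245 / 0.260, tolerance = 1e-12)
})

test_that("pande with n = 1 is definitionally identical to paode", {
  set.seed(21)
  X <- matrix(sample(1:3, 300 * 6, TRUE), 300, 6)
  s <- rbinom(300, 1, 0.4); s[1] <- 1L
  ds <- pu_dataset(X, s)
  Xt <- matrix(sample(1:3, 40 * 6, TRUE), 40, 6)
  p1 <- predict(pu_fit(ds, "pande", n = 1, prior = 0.3), Xt)
  p2 <- predict(pu_fit(ds, "paode", prior = 0.3), Xt)
  expect_equal(p1$posterior_positive, p2$posterior_positive,
               tolerance = 1e-12)
  expect_error(pu_fit(ds, "pande", n = 6, prior = 0.3), "exceeds")
  expect_error(pu_fit(ds, "pande", n = 2, prior = NULL), "prior")
})

test_that("classification matches the brute-force score transcription", {
  set.seed(22)
  for (rep in 1:25) {
    k <- sample(2:4, 1); n <- sample(15:40, 1)
    arity <- sample(2:3, k, replace = TRUE)
    X <- sapply(seq_len(k), function(j) sample.int(arity[j], n, TRUE))
    s <- rbinom(n, 1, 0.4); if (sum(s) == 0) s[1] <- 1L
    norder <- sample(0:min(2, k - 1), 1)
    alpha <- runif(1, 0.1, 0.9)
    xt <- X[sample(n, 1), ]   # training row: every parent tuple occurs
    bf <- bf_pande_posterior(X, s, xt, arity, norder, alpha)
    model <- pu_fit(pu_dataset(X, s), if (norder == 0) "pnb" else "pande",
                    n = norder, prior = alpha)
    got <- predict(model, matrix(xt, 1))
    expect_equal(got$posterior_positive, bf$posterior, tolerance = 1e-12)
    expect_equal(got$fallback_depth, 0L)
  }
})

test_that("degenerate parent tuples trigger the order-reduction fallback", {
  X <- rbind(c(1, 1, 1), c(2, 2, 2), c(3, 3, 3), c(1, 1, 1))
  s <- c(1, 1, 0, 0)
  arity <- c(4L, 4L, 4L)
  ds <- pu_dataset(X, s)
  m2 <- pu_fit(ds, "pande", n = 2, prior = 0.5, arity = arity)
  m1 <- pu_fit(ds, "paode", prior = 0.5, arity = arity)
  m0 <- pu_fit(ds, "pnb", prior = 0.5, arity = arity)

  # (1,2,3): every attribute value occurs, no pair co-occurs
  p2 <- predict(m2, rbind(c(1, 2, 3)))
  p1 <- predict(m1, rbind(c(1, 2, 3)))
  expect_equal(p2$fallback_depth, 1L)
  expect_identical(p2$posterior_positive, p1$posterior_positive)

  # (4,4,4): nothing occurs; chain bottoms out at PNB
  p2b <- predict(m2, rbind(c(4, 4, 4)))
  p0 <- predict(m0, rbind(c(4, 4, 4)))
  expect_equal(p2b$fallback_depth, 2L)
  expect_identical(p2b$posterior_positive, p0$posterior_positive)

  # unseen attribute values never crash (smoothed pseudo-count path)
  expect_silent(predict(m0, rbind(c(4, 4, 4))))
})

test_that("posterior on a dominant positive pattern exceeds 0.5", {
  X <- rbind(matrix(1L, 20, 3), matrix(2L, 20, 3))
  s <- c(rep(1L, 20), rep(0L, 20))
  m <- pu_fit(pu_dataset(X, s), "pande", n = 2, prior = 0.5)
  expect_gt(predict(m, rbind(c(1, 1, 1)))$posterior_positive, 0.5)
  expect_lt(predict(m, rbind(c(2, 2, 2)))$posterior_positive, 0.5)
})

test_that("predict_batch preserves order and scales", {
  set.seed(23)
  X <- matrix(sample(1:4, 500 * 8, TRUE), 500, 8)
  s <- rbinom(500, 1, 0.3); s[1] <- 1L
  m <- pu_fit(pu_dataset(X, s), "pande", n = 2, prior = 0.3)
  Xt <- matrix(sample(1:4, 1000 * 8, TRUE), 1000, 8)
  out <- predict_batch(m, Xt)
  expect_length(out$scores, 1000)
  expect_true(all(out$scores >= 0 & out$scores <= 1))

  one <- predict_batch(m, Xt[5, , drop = FALSE])
  expect_equal(one$scores, out$scores[5])

  perm <- sample(1000)
  expect_equal(predict_batch(m, Xt[perm, ])$scores, out$scores[perm])

  expect_error(predict(m, Xt[, 1:5]), "attributes")
})

test_that("posteriors are duplication-invariant without smoothing and the
           smoothing effect shrinks", {
  set.seed(24)
  X <- matrix(sample(1:3, 150 * 5, TRUE), 150, 5)
  s <- rbinom(150, 1, 0.4); s[1] <- 1L
  Xt <- X[1:25, ]
  fit_at <- function(f, m) predict(
    pu_fit(pu_dataset(X[rep(1:150, f), ], rep(s, f)), "pande", n = 2,
           prior = 0.4, m = m), Xt)$posterior_positive

  # without smoothing all estimates are count ratios: exactly invariant
  expect_equal(fit_at(1, 0), fit_at(10, 0), tolerance = 1e-9)

  # with m = 1 duplication converges monotonically to the unsmoothed limit
  p_inf <- fit_at(1, 0)
  expect_lt(mean(abs(fit_at(10, 1) - p_inf)),
            mean(abs(fit_at(2, 1) - p_inf)))
  expect_lt(mean(abs(fit_at(2, 1) - p_inf)),
            mean(abs(fit_at(1, 1) - p_inf)))
})

test_that("PA2DE recovers signal on separable SCAR data and the true prior
           is not worse than badly misspecified ones (up to noise)", {
  res <- t(sapply(1:25, function(seed) {
    sim <- generate_scar(scar_spec(n = 2000, alpha = 0.3, c = 0.5,
                                   separation = 3, seed = seed))
    tr <- 1:1400; te <- 1401:2000
    ds <- pu_dataset(sim$dataset$X[tr, ], sim$dataset$s[tr])
    auc_at <- function(a) {
      m <- pu_fit(ds, "pande", n = 2, prior = a)
      auc_score(predict(m, sim$dataset$X[te, ])$posterior_positive,
                sim$y[te])
    }
    c(true = auc_at(0.3), lo = auc_at(0.15), hi = auc_at(0.45))
  }))
  expect_gte(median(res[, "true"]), 0.95)
  # alpha-misspecification is nearly AUC-neutral for this family; allow a
  # small noise margin (see the methods vignette)
  expect_gte(median(res[, "true"]), median(res[, "lo"]) - 0.002)
  expect_gte(median(res[, "true"]), median(res[, "hi"]) - 0.002)
})

test_that("PTAN learns a pairwise-dependence structure and classifies", {
  sim <- generate_scar(scar_spec(n = 3000, alpha = 0.3, c = 0.7,
                                 dependence = TRUE, seed = 31))
  tr <- 1:2000; te <- 2001:3000
  m <- pu_fit(pu_dataset(sim$dataset$X[tr, ], sim$dataset$s[tr]), "ptan",
              prior = 0.3)
  expect_equal(m$tan$parent[1], 0L)           # root = attribute 1
  expect_equal(sum(m$tan$parent == 0L), 1L)   # exactly one root
  # dependent pairs (2j-1, 2j) should mostly be tree edges
  pairs_linked <- sum(sapply(seq(2, 10, 2), function(j)
    m$tan$parent[j] == j - 1 || m$tan$parent[j - 1] == j))
  expect_gte(pairs_linked, 3)
  auc <- auc_score(predict(m, sim$dataset$X[te, ])$posterior_positive,
                   sim$y[te])
  expect_gt(auc, 0.75)
  # deterministic refit
  m2 <- pu_fit(pu_dataset(sim$dataset$X[tr, ], sim$dataset$s[tr]), "ptan",
               prior = 0.3)
  expect_identical(m$tan$parent, m2$tan$parent)
})

test_that("model JSON round trip reproduces predictions bit-for-bit", {
  set.seed(25)
  X <- matrix(sample(1:3, 200 * 4, TRUE), 200, 4,
              dimnames = list(NULL, paste0("f", 1:4)))
  s <- rbinom(200, 1, 0.4); s[1] <- 1L
  m <- pu_fit(pu_dataset(X, s), "pande", n = 2, prior = 0.35)
  path <- tempfile(fileext = ".json")
  model_to_json(m, path)
  m2 <- model_from_json(path)
  Xt <- matrix(sample(1:3, 50 * 4, TRUE), 50, 4,
               dimnames = list(NULL, paste0("f", 1:4)))
  expect_identical(predict(m, Xt)$posterior_positive,
                   predict(m2, Xt)$posterior_positive)
})
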