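## Class-prior (mixture proportion) estimation from positive and unlabelled
## data: the Elkan-Noto estimator and a score-space AlphaMax estimator.

#' Construct a prior estimate
#'
#' @param method `"fixed"`, `"elkan-noto"` or `"alphamax"`.
#' @param alpha positive-class prior in (0, 1].
#' @param c labelling frequency `P(s = 1 | y = 1)` in (0, 1].
#' @param diagnostics optional list (e.g. the AlphaMax likelihood curve).
#' @return object of class `prior_estimate`.
#' @export
prior_estimate <- function(method, alpha, c = NA_real_, diagnostics = NULL) {
  stopifnot(alpha > 0, alpha <= 1)
  structure(list(method = method, alpha = alpha, c = c,
                 diagnostics = diagnostics), class = "prior_estimate")
}

#' @export
print.prior_estimate <- function(x, ...) {
  cat(sprintf("Prior estimate [%s]: alpha = %.4f, c = %.4f\n",
              x$method, x$alpha, x$c))
  invisible(x)
}

#' Fit the nontraditional scorer g(x) = P(s = 1 | x)
#'
#' A naive Bayes classifier of the labelling indicator `s` against the
#' attributes (no external learner dependency); outputs are probabilities in
#' `[0, 1]`. Deterministic given the data (the seed argument is kept for
#' interface stability).
#'
#' @param train a [pu_dataset()].
#' @param m smoothing weight.
#' @param seed unused placeholder (the fit is deterministic).
#' @return an `nb_model` scorer.
#' @export
fit_nontraditional_scorer <- function(train, m = 1, seed = NULL) {
  if (length(unique(train$s)) < 2L)
    stop("scorer training data must contain labelled and unlabelled rows")
  nb_fit(train$X, train$s, m = m)
}

#' Score a held-out set with the nontraditional scorer
#'
#' @param scorer an `nb_model` from [fit_nontraditional_scorer()].
#' @param dataset a [pu_dataset()] (typically a held-out validation split).
#' @return object of class `score_set`: list with `scores_labelled` and
#'   `scores_unlabelled`.
#' @export
score_set <- function(scorer, dataset) {
  g <- predict(scorer, dataset$X)
  structure(list(scores_labelled = g[dataset$s == 1L],
                 scores_unlabelled = g[dataset$s == 0L]),
            class = "score_set")
}

#' Elkan-Noto class-prior estimate
#'
#' Uses the e1 estimator of the labelling frequency: `c` is the mean
#' nontraditional-classifier score over held-out labelled positives, and the
#' class prior is `alpha = frac_labelled / c`, clipped to (0, 1].
#'
#' @param scores a [score_set()] from a held-out validation split.
#' @param frac_labelled fraction of labelled rows in the full dataset.
#' @return a [prior_estimate()].
#' @export
elkan_noto_estimate <- function(scores, frac_labelled) {
  if (!length(scores$scores_labelled))
    stop("no labelled scores available for the Elkan-Noto estimator")
  c_hat <- mean(scores$scores_labelled)
  if (c_hat <= 0) stop("estimated labelling frequency c is 0")
  alpha <- min(frac_labelled / c_hat, 1)
  prior_estimate("elkan-noto", alpha = alpha, c = c_hat)
}

## Constrained maximum of sum_b n_b log(alpha f1_b + (1 - alpha) f0_b) over
## probability vectors f0 >= 0 (the free negative component), by KKT
## water-filling: bins enter the zero set when the positive component alone
## explains them.
alphamax_profile_ll <- function(n_b, f1, alpha) {
  stopifnot(length(n_b) == length(f1))
  active <- n_b > 0                      # bins with f0_b > 0
  repeat {
    NZ <- sum(n_b[active])
    F1Z <- sum(f1[active])
    if (NZ == 0) break
    lambda <- NZ * (1 - alpha) / ((1 - alpha) + alpha * F1Z)
    # a bin keeps free negative mass only while its water level exceeds the
    # positive-component floor alpha f1_b
    keep <- active & (n_b * (1 - alpha) > lambda * alpha * f1)
    if (identical(keep, active)) break
    active <- keep
  }
  NZ <- sum(n_b[active]); F1Z <- sum(f1[active])
  lambda <- if (NZ > 0) NZ * (1 - alpha) / ((1 - alpha) + alpha * F1Z)
            else 1
  mix <- alpha * f1
  mix[active] <- n_b[active] * (1 - alpha) / lambda
  f0 <- pmax((mix - alpha * f1) / (1 - alpha), 0)
  ll <- sum(n_b[mix > 0] * log(mix[mix > 0]))
  if (any(n_b > 0 & mix == 0)) ll <- -Inf
  list(ll = ll, f0 = f0)
}

#' AlphaMax class-prior estimate (score-space variant)
#'
#' Models the held-out unlabelled scores as the mixture
#' `alpha* f1 + (1 - alpha*) f0` on the 1-D score scale, where `f1` is the
#' histogram density of the labelled-positive scores (fixed bins on
#' `[0, 1]`) and `f0` is a free per-bin nonnegative normalized density. For
#' each `alpha*` on the grid the profile log-likelihood is maximized in
#' closed form over `f0`; the estimate is the inflection point of the
#' normalized log-likelihood curve (the grid point with the most negative
#' second difference, i.e. the largest `alpha*` before the curve bends
#' down). The in-mixture proportion `alpha*` (fraction of positives among
#' unlabelled) is then rescaled to the full dataset composition:
#' `alpha = (n_labelled + alpha* n_unlabelled) / n`.
#'
#' @param scores a [score_set()]; at least 50 scores per set recommended.
#' @param grid grid of candidate mixture proportions.
#' @param bins number of fixed histogram bins on `[0, 1]` (default 25).
#' @return a [prior_estimate()] whose `diagnostics` carries the grid, the
#'   normalized log-likelihood curve and `alpha_star`.
#' @export
alphamax_estimate <- function(scores, grid = seq(0.01, 0.99, by = 0.01),
                              bins = 25L) {
  gl <- scores$scores_labelled; gu <- scores$scores_unlabelled
  if (length(gl) < 2L || length(gu) < 2L)
    stop("alphamax_estimate needs labelled and unlabelled scores")
  edges <- seq(0, 1, length.out = bins + 1L)
  bin_of <- function(x) pmin(pmax(findInterval(x, edges, left.open = TRUE),
                                  1L), bins)
  n_b <- tabulate(bin_of(gu), bins)
  c1 <- tabulate(bin_of(gl), bins)
  if (sum(n_b) == 0 || sum(c1) == 0) stop("degenerate score histograms")
  # unsmoothed positive component: the free negative density covers any bin
  # with unlabelled mass, so the profile likelihood is always finite for
  # alpha < 1; smoothing f1 into empty bins would destroy the flat plateau
  # of the curve whose bend is the estimate
  f1 <- c1 / sum(c1)
  ll <- vapply(grid, function(a) alphamax_profile_ll(n_b, f1, a)$ll,
               numeric(1))
  if (all(!is.finite(ll))) stop("degenerate likelihood curve")
  rng <- range(ll[is.finite(ll)])
  cn <- (ll - rng[1]) / max(rng[2] - rng[1], .Machine$double.eps)
  # inflection rule: the profile curve is (up to noise) flat while the
  # mixture proportion is feasible and bends downwards beyond it; the
  # estimate is the largest alpha before the local slope of the normalized
  # curve exceeds 10% of the curve's mean decline rate
  G <- length(grid)
  # statistically flat curve (total decline within likelihood-ratio noise
  # for the histogram df): the unlabelled set is indistinguishable from the
  # positive component, so the proportion estimate is the upper bound
  total_drop <- max(ll[is.finite(ll)]) - ll[G]
  if (!is.finite(total_drop) ||
      total_drop <= stats::qchisq(0.99, df = bins - 1L) / 2) {
    alpha_star <- grid[G]
  } else {
    slope <- diff(cn) / diff(grid)
    overall <- (cn[G] - cn[1]) / (grid[G] - grid[1])
    crossing <- which(slope < 0.1 * overall)   # decline beyond 10% of mean
    alpha_star <- if (!length(crossing)) grid[G] else grid[crossing[1L]]
  }
  nL <- length(gl); nU <- length(gu)
  alpha <- (nL + alpha_star * nU) / (nL + nU)
  c_hat <- min(nL / (nL + nU) / alpha, 1)
  prior_estimate("alphamax", alpha = alpha, c = c_hat,
                 diagnostics = list(grid = grid, loglik = ll,
                                    normalized = cn,
                                    alpha_star = alpha_star))
}

#' Clamp a class prior at the low-prior floor
#'
#' Highly imbalanced candidate pools push estimated priors toward zero; the
#' pipeline clamps the working prior at a small floor (default `1e-4`) so
#' the mixture inversion stays defined, warning when the clamp fires.
#'
#' @param alpha estimated prior.
#' @param floor lower bound (default 1e-4).
#' @return clamped alpha.
#' @export
clamp_prior <- function(alpha, floor = 1e-4) {
  if (alpha < floor) {
    warning("class prior ", signif(alpha, 4), " below floor ", floor,
            "; clamped")
    return(floor)
  }
  alpha
}

#' Serialize a prior estimate (with diagnostics) to JSON
#' @param x a `prior_estimate`.
#' @param path optional output path.
#' @export
prior_to_json <- function(x, path = NULL) {
  js <- jsonlite::toJSON(unclass(x), auto_unbox = TRUE, digits = NA,
                         null = "null")
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}
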