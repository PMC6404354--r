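## Positive-unlabelled Bayesian classifiers: PNB, PAODE (= PA1DE),
## PAnDE (default n = 2, i.e. PA2DE) and PTAN.

#' Construct a PU dataset
#'
#' A discrete attribute matrix together with the observed labelling
#' indicator `s` (1 = labelled positive, 0 = unlabelled) under the
#' selected-completely-at-random assumption.
#'
#' @param X integer matrix of discrete attribute values (1-based bin ids).
#' @param s integer vector of 0/1 labels.
#' @param keys optional row keys (`protein_id:position`).
#' @return object of class `pu_dataset`.
#' @export
pu_dataset <- function(X, s, keys = rownames(X)) {
  X <- as.matrix(X)
  storage.mode(X) <- "integer"
  s <- as.integer(s)
  if (length(s) != nrow(X)) stop("length(s) must equal nrow(X)")
  if (anyNA(X) || anyNA(s)) stop("pu_dataset cannot contain missing cells")
  if (!all(s %in% c(0L, 1L))) stop("s must be 0/1")
  if (sum(s) < 1L) stop("pu_dataset needs at least one labelled positive")
  if (any(X < 1L)) stop("attribute values must be positive integers")
  if (is.null(keys)) keys <- as.character(seq_len(nrow(X)))
  structure(list(X = X, s = s, keys = keys), class = "pu_dataset")
}

#' Derive negative-class conditionals by mixture inversion
#'
#' Under the selected-completely-at-random assumption the marginal
#' distribution of an attribute is the mixture
#' `P(v) = alpha P(v|y=1) + (1 - alpha) P(v|y=0)`, so the unobservable
#' negative-class conditional is recovered as
#' `P(v|y=0) = (P(v) - alpha P(v|y=1)) / (1 - alpha)`. Sampling noise can
#' push entries negative; those are clipped to `eps` and the distribution
#' renormalized, with clip events counted.
#'
#' @param positive_conditionals numeric vector (a probability distribution
#'   over attribute values) `P(v|y=1)`.
#' @param marginals numeric vector `P(v)` of the same length.
#' @param alpha positive-class prior in (0, 1).
#' @param eps clip value for negative entries (default 1e-6).
#' @return list with `conditionals` (the renormalized `P(v|y=0)`) and
#'   `n_clipped`.
#' @examples
#' derive_negative_conditionals(c(0.8, 0.2), c(0.5, 0.5), 0.5)
#' @export
derive_negative_conditionals <- function(positive_conditionals, marginals,
                                         alpha, eps = 1e-6) {
  if (alpha >= 1) stop("alpha must be < 1 for mixture inversion")
  if (alpha <= 0) stop("alpha must be > 0")
  raw <- (marginals - alpha * positive_conditionals) / (1 - alpha)
  clipped <- raw < 0
  raw[clipped] <- eps
  list(conditionals = raw / sum(raw), n_clipped = sum(clipped))
}

#' Fit a PU Bayesian classifier
#'
#' Families: `"pnb"` (naive Bayes), `"paode"` (averaged one-dependence,
#' = PAnDE with n = 1), `"pande"` (averaged n-dependence, default n = 2) and
#' `"ptan"` (tree-augmented naive Bayes with structure from conditional
#' mutual information). Positive-class tables are estimated from labelled
#' rows with m-estimate smoothing (uniform base, default m = 1); marginals
#' from all rows; negative-class tables by per-context mixture inversion
#' (see [derive_negative_conditionals()]).
#'
#' For the averaged families the smoothed tables are derived inside the
#' scoring kernel from the stored sufficient statistics (the discrete
#' training matrix), deterministically; the PTAN tree and conditional
#' probability tables are materialized at fit time.
#'
#' @param dataset a [pu_dataset()].
#' @param family one of `"pande"`, `"paode"`, `"pnb"`, `"ptan"`.
#' @param n dependence order for `"pande"` (default 2; `n = 1` is
#'   definitionally identical to `"paode"`, `n = 0` to `"pnb"`).
#' @param prior a [prior_estimate()] or a bare numeric alpha in (0, 1).
#' @param m m-estimate smoothing weight (default 1).
#' @param eps clipping epsilon for derived negative conditionals.
#' @param arity optional per-attribute arity (defaults to observed maxima;
#'   supply when test data may contain larger values).
#' @return object of class `pu_bayes`.
#' @export
pu_fit <- function(dataset, family = c("pande", "paode", "pnb", "ptan"),
                   n = 2L, prior, m = 1, eps = 1e-6, arity = NULL) {
  family <- match.arg(family)
  if (missing(prior) || is.null(prior)) stop("a class prior must be supplied")
  alpha <- if (inherits(prior, "prior_estimate")) prior$alpha
           else as.numeric(prior)
  if (is.na(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must lie strictly in (0, 1); got ", alpha)
  X <- dataset$X
  k <- ncol(X)
  n <- switch(family, pnb = 0L, paode = 1L, ptan = 1L, pande = as.integer(n))
  if (family == "pande" && n > k - 1L)
    stop("dependence order n = ", n, " exceeds k - 1 = ", k - 1L)
  if (is.null(arity)) arity <- apply(X, 2L, max)
  arity <- pmax(as.integer(arity), apply(X, 2L, max))
  model <- structure(list(
    family = family, n = n, alpha = alpha, m = m, eps = eps,
    arity = arity, features = colnames(X),
    X = X, s = dataset$s,
    prior = if (inherits(prior, "prior_estimate")) prior else NULL),
    class = "pu_bayes")
  if (family == "ptan") model$tan <- fit_tan_structure(model)
  model
}

#' @export
print.pu_bayes <- function(x, ...) {
  cat(sprintf("PU Bayes classifier [%s%s], k = %d attributes, alpha = %.4g\n",
              toupper(x$family),
              if (x$family == "pande") paste0(" n=", x$n) else "",
              ncol(x$X), x$alpha))
  invisible(x)
}

#' Classify instances with a PU Bayes model
#'
#' Implements the averaged n-dependence score with the degeneracy fallback:
#' if for an instance every size-n parent tuple is unseen in training
#' (all `delta(x_S) = 0`), the order-(n-1) model is used, recursing down to
#' naive Bayes. The reported `fallback_depth` counts how many orders were
#' skipped for the instance.
#'
#' @param object a [pu_fit()] model.
#' @param newdata integer matrix of attribute values (or a `pu_dataset`).
#' @param threshold decision threshold on the positive posterior
#'   (default 0.5; exact ties predict positive).
#' @param ... unused.
#' @return data.frame with `posterior_positive`, `label` and
#'   `fallback_depth`.
#' @export
predict.pu_bayes <- function(object, newdata, threshold = 0.5, ...) {
  Xt <- if (inherits(newdata, "pu_dataset")) newdata$X else as.matrix(newdata)
  storage.mode(Xt) <- "integer"
  if (ncol(Xt) != ncol(object$X))
    stop("newdata has ", ncol(Xt), " attributes; model expects ",
         ncol(object$X))
  if (!is.null(object$features) && !is.null(colnames(Xt)) &&
      !identical(colnames(Xt), object$features))
    stop("newdata attribute names do not match the model schema")
  arity <- pmax(object$arity, apply(Xt, 2L, max))
  t_ <- nrow(Xt)
  if (object$family == "ptan") {
    logs <- tan_logscores(object, Xt)
    fallback <- rep(0L, t_)
  } else {
    logs <- matrix(NA_real_, t_, 2L)
    fallback <- rep(NA_integer_, t_)
    pending <- seq_len(t_)
    order_now <- object$n
    while (length(pending)) {
      res <- pande_kernel(object$X, object$s,
                          Xt[pending, , drop = FALSE],
                          as.integer(arity), as.integer(order_now),
                          object$alpha, object$m, object$eps)
      ok <- res$ndelta > 0L | order_now == 0L
      logs[pending[ok], ] <- res$logs[ok, , drop = FALSE]
      fallback[pending[ok]] <- object$n - order_now
      pending <- pending[!ok]
      order_now <- order_now - 1L
    }
  }
  post <- posterior_from_logs(logs)
  data.frame(
    posterior_positive = post,
    label = ifelse(post >= threshold, "positive", "negative"),
    fallback_depth = fallback,
    row.names = rownames(Xt))
}

posterior_from_logs <- function(logs) {
  mx <- pmax(logs[, 1L], logs[, 2L])
  e0 <- exp(logs[, 1L] - mx); e1 <- exp(logs[, 2L] - mx)
  e1 / (e0 + e1)
}

#' Batch prediction with posterior scores
#'
#' Row-wise classification preserving input order; the posterior vector is
#' suitable for AUC computation.
#'
#' @param model a [pu_fit()] model.
#' @param dataset a [pu_dataset()] or integer matrix.
#' @param threshold decision threshold.
#' @return list with `predictions` (data.frame) and `scores` (numeric).
#' @export
predict_batch <- function(model, dataset, threshold = 0.5) {
  pred <- predict(model, dataset, threshold = threshold)
  list(predictions = pred, scores = pred$posterior_positive)
}

## -- PTAN ---------------------------------------------------------------------

## Pairwise joint tables (positive via labelled rows, negative via mixture
## inversion) for every attribute pair, computed with one indicator-matrix
## cross-product; used for both the Chow-Liu structure and the CPTs.
pair_counts <- function(X, s, arity) {
  n <- nrow(X); k <- ncol(X)
  off <- c(0L, cumsum(arity))
  Z <- Matrix::sparseMatrix(
    i = rep(seq_len(n), k),
    j = as.integer(sweep(X, 2L, off[seq_len(k)], "+")),
    x = 1, dims = c(n, off[k + 1L]))
  list(all = as.matrix(Matrix::crossprod(Z)),
       pos = as.matrix(Matrix::crossprod(Z[s == 1L, , drop = FALSE])),
       off = off)
}

## Smoothed class-conditional joint of attributes (i, j) for y = 1 and y = 0.
pair_joint_y <- function(counts, i, j, arity, n, n1, alpha, m, eps) {
  off <- counts$off
  bi <- arity[i]; bj <- arity[j]
  blk <- function(M) M[(off[i] + 1L):(off[i] + bi),
                       (off[j] + 1L):(off[j] + bj), drop = FALSE]
  c_all <- blk(counts$all); c_pos <- blk(counts$pos)
  p1_raw <- c_pos / n1
  p_raw <- c_all / n
  inv <- derive_negative_conditionals(as.vector(p1_raw), as.vector(p_raw),
                                      alpha, eps)
  p0_raw <- matrix(inv$conditionals, bi, bj)
  n0 <- n * (1 - alpha)
  ncell <- bi * bj
  list(
    p1 = (c_pos + m / ncell) / (n1 + m),
    p0 = (n0 * p0_raw + m / ncell) / (n0 + m),
    n_clipped = inv$n_clipped)
}

## Chow-Liu structure: maximum spanning tree over conditional mutual
## information I(X_i; X_j | Y), computed from the derived class-conditional
## pair tables; Kruskal with deterministic tie-breaks, root = attribute 1.
fit_tan_structure <- function(model) {
  X <- model$X; s <- model$s; arity <- model$arity
  n <- nrow(X); k <- ncol(X); n1 <- sum(s)
  alpha <- model$alpha; m <- model$m; eps <- model$eps
  counts <- pair_counts(X, s, arity)
  cmi <- function(jt) {
    val <- 0
    for (y in 1:2) {
      p <- if (y == 1) jt$p1 else jt$p0
      w <- if (y == 1) alpha else 1 - alpha
      p <- p / sum(p)
      pr <- rowSums(p); pc <- colSums(p)
      tt <- p * (log(p) - outer(log(pr), log(pc), "+"))
      val <- val + w * sum(tt[p > 0])
    }
    val
  }
  edges <- utils::combn(k, 2L)
  wts <- apply(edges, 2L, function(e)
    cmi(pair_joint_y(counts, e[1], e[2], arity, n, n1, alpha, m, eps)))
  ord <- order(-wts, edges[1L, ], edges[2L, ])
  parent <- rep(NA_integer_, k)
  comp <- seq_len(k)
  adj <- vector("list", k)
  n_edges <- 0L
  for (e in ord) {
    i <- edges[1L, e]; j <- edges[2L, e]
    if (comp[i] != comp[j]) {
      adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
      comp[comp == comp[j]] <- comp[i]
      n_edges <- n_edges + 1L
      if (n_edges == k - 1L) break
    }
  }
  # orient away from the root (attribute 1)
  parent[1L] <- 0L
  queue <- 1L
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    for (u in adj[[v]]) if (is.na(parent[u])) {
      parent[u] <- v
      queue <- c(queue, u)
    }
  }
  # conditional probability tables: root P(x|y); others P(x_m | y, x_parent)
  cpt <- vector("list", k)
  n_clip <- 0L
  for (j in seq_len(k)) {
    if (parent[j] == 0L) {
      # univariate table from the diagonal of the indicator cross-product
      off <- counts$off
      c_all <- diag(counts$all)[(off[j] + 1L):(off[j] + arity[j])]
      c_pos <- diag(counts$pos)[(off[j] + 1L):(off[j] + arity[j])]
      inv <- derive_negative_conditionals(c_pos / n1, c_all / n, alpha, eps)
      n0 <- n * (1 - alpha)
      cpt[[j]] <- list(
        l1 = log((c_pos + m / arity[j]) / (n1 + m)),
        l0 = log((n0 * inv$conditionals + m / arity[j]) / (n0 + m)))
      n_clip <- n_clip + inv$n_clipped
    } else {
      p <- parent[j]
      off <- counts$off
      bi <- arity[j]; bp <- arity[p]
      blk_all <- counts$all[(off[j] + 1L):(off[j] + bi),
                            (off[p] + 1L):(off[p] + bp), drop = FALSE]
      blk_pos <- counts$pos[(off[j] + 1L):(off[j] + bi),
                            (off[p] + 1L):(off[p] + bp), drop = FALSE]
      l1 <- l0 <- matrix(NA_real_, bi, bp)
      for (v in seq_len(bp)) {
        nallc <- sum(blk_all[, v]); n1c <- sum(blk_pos[, v])
        a_c <- if (nallc > 0) alpha * (n1c / n1) / (nallc / n) else 0
        a_c <- min(max(a_c, 0), 1 - 1e-9)
        q1 <- if (n1c > 0) blk_pos[, v] / n1c else rep(0, bi)
        q  <- if (nallc > 0) blk_all[, v] / nallc else rep(1 / bi, bi)
        raw <- (q - a_c * q1) / (1 - a_c)
        n_clip <- n_clip + sum(raw < 0)
        raw[raw < 0] <- eps
        q0n <- raw / sum(raw)
        n0c <- nallc * (1 - a_c)
        l1[, v] <- log((blk_pos[, v] + m / bi) / (n1c + m))
        l0[, v] <- log((n0c * q0n + m / bi) / (n0c + m))
      }
      cpt[[j]] <- list(l1 = l1, l0 = l0)
    }
  }
  list(parent = parent, cpt = cpt, n_clipped = n_clip)
}

tan_logscores <- function(model, Xt) {
  k <- ncol(Xt); t_ <- nrow(Xt)
  parent <- model$tan$parent
  l1 <- rep(log(model$alpha), t_)
  l0 <- rep(log(1 - model$alpha), t_)
  for (j in seq_len(k)) {
    cpt <- model$tan$cpt[[j]]
    v <- Xt[, j]
    if (parent[j] == 0L) {
      l1 <- l1 + cpt$l1[v]
      l0 <- l0 + cpt$l0[v]
    } else {
      pv <- Xt[, parent[j]]
      idx <- cbind(v, pv)
      l1 <- l1 + cpt$l1[idx]
      l0 <- l0 + cpt$l0[idx]
    }
  }
  cbind(l0, l1)
}

## -- Model serialization ------------------------------------------------------

#' Serialize a PU Bayes model to JSON
#'
#' The stored object contains the sufficient statistics (the discrete
#' training matrix and labels), configuration and prior; refitting from it
#' is deterministic, so a train/predict round trip through JSON is
#' bit-stable.
#'
#' @param model a `pu_bayes` model.
#' @param path optional output path.
#' @param extra optional named list stored alongside (e.g. discretizer).
#' @return JSON string (invisibly when written to a file).
#' @export
model_to_json <- function(model, path = NULL, extra = NULL) {
  obj <- list(family = model$family, n = model$n, alpha = model$alpha,
              m = model$m, eps = model$eps, arity = model$arity,
              features = model$features, X = model$X, s = model$s,
              extra = extra)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}

#' @rdname model_to_json
#' @param json JSON string or file path produced by [model_to_json()].
#' @return `model_from_json`: a `pu_bayes` model (with `$extra` attached).
#' @export
model_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json)
  X <- as.matrix(obj$X)
  storage.mode(X) <- "integer"
  colnames(X) <- obj$features
  ds <- pu_dataset(X, obj$s)
  model <- pu_fit(ds, family = obj$family,
                  n = if (obj$family == "pande") obj$n else 2L,
                  prior = obj$alpha, m = obj$m, eps = obj$eps,
                  arity = obj$arity)
  model$extra <- obj$extra
  model
}
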