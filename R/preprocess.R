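## Discretization, mutual information, mRMR feature selection and
## unlabelled-site sampling.

#' Fit an equal-frequency discretizer
#'
#' Bin edges are placed at midpoints between consecutive order statistics of
#' the training rows so that bins hold (as nearly as possible) equal counts.
#' Features with fewer distinct values than `n_bins` get fewer bins; constant
#' features collapse to a single bin with a warning. The boundary convention
#' is "value <= edge falls in the lower bin".
#'
#' @param x numeric matrix (rows = training instances) or vector.
#' @param n_bins target number of bins (default 5).
#' @return object of class `discretizer`: list with `edges` (per-feature
#'   numeric vectors, possibly empty) and `n_bins`.
#' @export
fit_discretizer <- function(x, n_bins = 5L) {
  if (is.vector(x)) x <- matrix(x, ncol = 1L)
  n_bins <- as.integer(n_bins)
  stopifnot(n_bins >= 1L)
  n <- nrow(x)
  any_constant <- FALSE
  edges <- lapply(seq_len(ncol(x)), function(j) {
    v <- sort(x[, j])
    if (v[1] == v[n]) { any_constant <<- TRUE; return(numeric(0)) }
    cut_at <- floor(seq_len(n_bins - 1L) * n / n_bins)
    cut_at <- cut_at[cut_at >= 1L & cut_at < n]
    e <- (v[cut_at] + v[cut_at + 1L]) / 2
    unique(e[!duplicated(e)])
  })
  names(edges) <- colnames(x)
  if (any_constant)
    warning("fit_discretizer: constant feature(s) collapsed to a single bin")
  structure(list(edges = edges, n_bins = n_bins), class = "discretizer")
}

#' Apply a discretizer
#'
#' Maps every real value to a bin id in `[1, n_bins]`; values at or below an
#' edge go to the lower bin. The transform is total (any real maps to a bin)
#' and idempotent on bin representatives.
#'
#' @param disc a [fit_discretizer()] model.
#' @param x numeric matrix or vector with the same columns as the fit data.
#' @return integer matrix of bin ids.
#' @export
discretize <- function(disc, x) {
  if (is.vector(x)) x <- matrix(x, ncol = 1L)
  if (ncol(x) != length(disc$edges))
    stop("discretizer was fit on ", length(disc$edges),
         " features but given ", ncol(x))
  out <- vapply(seq_len(ncol(x)), function(j) {
    e <- disc$edges[[j]]
    if (!length(e)) return(rep(1L, nrow(x)))
    findInterval(x[, j], e, left.open = FALSE) + 1L
  }, integer(nrow(x)))
  out <- matrix(out, nrow = nrow(x),
                dimnames = list(rownames(x), names(disc$edges)))
  storage.mode(out) <- "integer"
  out
}

#' Serialize / restore a discretizer as JSON
#' @param disc a `discretizer`.
#' @param path optional file.
#' @return JSON string, or (for `discretizer_from_json`) a `discretizer`.
#' @export
discretizer_to_json <- function(disc, path = NULL) {
  js <- jsonlite::toJSON(unclass(disc), auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}

#' @rdname discretizer_to_json
#' @param json JSON string or path produced by [discretizer_to_json()].
#' @export
discretizer_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json, simplifyDataFrame = FALSE,
                            simplifyMatrix = FALSE)
  edges <- lapply(obj$edges, as.numeric)
  structure(list(edges = edges, n_bins = as.integer(obj$n_bins)),
            class = "discretizer")
}

#' Plug-in mutual information between two discrete columns
#'
#' `I(x, y) = sum p(x, y) log[p(x, y) / (p(x) p(y))]` with natural logarithm
#' and the convention `0 log 0 = 0`, using empirical plug-in probabilities.
#' Always nonnegative (up to floating point) and symmetric; `I(x, x)` equals
#' the empirical entropy of `x`.
#'
#' @param x,y vectors of equal length (coerced to factors).
#' @return nonnegative numeric scalar (nats).
#' @export
mutual_information <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  tab <- table(x, y)
  n <- sum(tab)
  pxy <- tab / n
  px <- rowSums(pxy); py <- colSums(pxy)
  terms <- pxy * (log(pxy) - outer(log(px), log(py), "+"))
  max(sum(terms[pxy > 0]), 0)
}

## One-hot indicator of a discrete matrix (built once, reused across the
## greedy mRMR steps).
onehot_indicator <- function(X) {
  n <- nrow(X)
  arity <- apply(X, 2L, max)
  offsets <- c(0L, cumsum(arity))[seq_len(ncol(X))]
  Z <- Matrix::sparseMatrix(
    i = rep(seq_len(n), ncol(X)),
    j = as.integer(sweep(X, 2L, offsets, "+")),
    x = 1, dims = c(n, sum(arity)))
  list(Z = Z, arity = arity, offsets = offsets, n = n)
}

## MI of every encoded column block against a discrete vector, from one
## sparse cross-product; fully vectorized across feature blocks.
mi_vs_vector <- function(oh, y) {
  y <- as.integer(factor(y))
  by <- max(y)
  Zy <- Matrix::sparseMatrix(i = seq_len(oh$n), j = y, x = 1,
                             dims = c(oh$n, by))
  P <- as.matrix(Matrix::crossprod(Zy, oh$Z)) / oh$n   # by x total arity
  grp <- rep(seq_along(oh$arity), oh$arity)
  pc <- colSums(P)                                     # p(x) per encoded value
  PR <- t(rowsum(t(P), grp))                           # p(y) per (y, feature)
  terms <- P * (log(P) - log(PR)[, grp, drop = FALSE] -
                  matrix(log(pc), by, length(pc), byrow = TRUE))
  terms[P == 0] <- 0
  pmax(as.numeric(rowsum(colSums(terms), grp)), 0)
}

## Vectorized MI of every column of a discrete matrix against a target.
mi_columns <- function(X, y) mi_vs_vector(onehot_indicator(X), y)

#' Greedy mRMR feature selection (MID scheme)
#'
#' Minimum-redundancy maximum-relevance selection with the difference (MID)
#' criterion: the first feature maximizes `I(f; label)`; each subsequent
#' feature maximizes `I(f; label) - mean_{g in selected} I(f; g)`. Mutual
#' information is the plug-in estimate on discrete columns (natural log).
#' Ties are broken deterministically by ascending feature name. In the PU
#' setting the label argument is the observed labelled/unlabelled indicator
#' `s`, used as a proxy for the class.
#'
#' @param X discrete integer matrix with column names (e.g. from
#'   [discretize()]).
#' @param label discrete target vector (length `nrow(X)`).
#' @param k number of features to select (default 100).
#' @return data.frame with columns `rank`, `feature`, `relevance` (MI with
#'   the label) and `score` (mRMR score at selection time), in selection
#'   order.
#' @export
mrmr_select <- function(X, label, k = 100L) {
  k <- as.integer(k)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  if (k > ncol(X))
    stop("k = ", k, " exceeds the number of features (", ncol(X), ")")
  nms <- colnames(X)
  oh <- onehot_indicator(X)
  relevance <- mi_vs_vector(oh, label)
  redundancy_sum <- numeric(ncol(X))
  selected <- integer(0)
  ranks <- data.frame(rank = seq_len(k), feature = character(k),
                      relevance = numeric(k), score = numeric(k),
                      stringsAsFactors = FALSE)
  remaining <- seq_len(ncol(X))
  for (step in seq_len(k)) {
    score <- if (length(selected) == 0L) relevance[remaining]
             else relevance[remaining] -
                  redundancy_sum[remaining] / length(selected)
    ord <- order(-score, nms[remaining])
    pick <- remaining[ord[1L]]
    ranks$feature[step] <- nms[pick]
    ranks$relevance[step] <- relevance[pick]
    ranks$score[step] <- score[ord[1L]]
    selected <- c(selected, pick)
    remaining <- remaining[remaining != pick]
    if (length(remaining))
      redundancy_sum <- redundancy_sum + mi_vs_vector(oh, X[, pick])
  }
  ranks
}

#' Write an mRMR ranking as TSV
#' @param ranking data.frame from [mrmr_select()].
#' @param path output path.
#' @export
write_ranking <- function(ranking, path) {
  utils::write.table(ranking, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Sample unlabelled candidate sites
#'
#' Implements the two-stage unlabelled sampling protocol: from each
#' glycosylated protein (one carrying at least one positive site), up to
#' `per_protein` candidate sites of the given type that are not annotated
#' positive are drawn uniformly without replacement; the pooled draw is then
#' uniformly subsampled to at most `cap` sites. If fewer candidates are
#' available than either limit, all are kept. All randomness flows from
#' `seed`.
#'
#' @param proteins named character vector of sequences.
#' @param positives data.frame of positive annotations (protein_id,
#'   position, glyco_type).
#' @param glyco_type glycosylation type.
#' @param per_protein per-protein draw (default 20).
#' @param cap global cap (default 10000).
#' @param seed integer seed.
#' @return data.frame of sampled candidates (as [enumerate_candidates()]).
#' @export
sample_unlabelled <- function(proteins, positives, glyco_type,
                              per_protein = 20L, cap = 10000L, seed = 1L) {
  stopifnot(per_protein >= 0L, cap >= 0L)
  glyc_ids <- unique(positives$protein_id)
  cand <- enumerate_candidates(proteins[names(proteins) %in% glyc_ids],
                               glyco_type, positives)
  out <- local_seed(seed, {
    picked <- lapply(split(seq_len(nrow(cand)), cand$protein_id),
                     function(idx) {
      if (length(idx) <= per_protein) idx
      else sample(idx, per_protein)
    })
    idx <- sort(unlist(picked, use.names = FALSE))
    if (length(idx) > cap) idx <- sort(sample(idx, cap))
    cand[idx, , drop = FALSE]
  })
  rownames(out) <- NULL
  out
}

## Evaluate an expression under a temporary RNG state seeded with `seed`,
## restoring the caller's RNG afterwards.
local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
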