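## Plain (fully supervised) discrete naive Bayes with m-estimate smoothing.
## Used as the nontraditional scorer g(x) = P(s = 1 | x) for class-prior
## estimation, and as the supervised reference model that PNB must reproduce
## when the data are fully labelled.

#' Fit a discrete naive Bayes classifier
#'
#' @param X integer matrix of discrete attribute values (1-based).
#' @param y 0/1 class vector (for the PU scorer this is the labelling
#'   indicator `s`).
#' @param m m-estimate smoothing weight (default 1, uniform base).
#' @param arity optional per-attribute arity.
#' @return object of class `nb_model`.
#' @export
nb_fit <- function(X, y, m = 1, arity = NULL) {
  X <- as.matrix(X); storage.mode(X) <- "integer"
  y <- as.integer(y)
  if (length(unique(y)) < 2L) stop("nb_fit requires both classes present")
  if (is.null(arity)) arity <- apply(X, 2L, max)
  arity <- pmax(as.integer(arity), apply(X, 2L, max))
  n <- nrow(X)
  n1 <- sum(y == 1L); n0 <- n - n1
  cpt <- lapply(seq_len(ncol(X)), function(j) {
    b <- arity[j]
    c1 <- tabulate(X[y == 1L, j], b)
    c0 <- tabulate(X[y == 0L, j], b)
    list(l1 = log((c1 + m / b) / (n1 + m)),
         l0 = log((c0 + m / b) / (n0 + m)))
  })
  structure(list(cpt = cpt, log_prior = c(log(n0 / n), log(n1 / n)),
                 arity = arity, m = m, features = colnames(X)),
            class = "nb_model")
}

#' Posterior P(y = 1 | x) from a naive Bayes model
#'
#' @param object an [nb_fit()] model.
#' @param newdata integer matrix.
#' @param ... unused.
#' @return numeric vector of posteriors in `[0, 1]`.
#' @export
predict.nb_model <- function(object, newdata, ...) {
  Xt <- as.matrix(newdata); storage.mode(Xt) <- "integer"
  t_ <- nrow(Xt)
  l1 <- rep(object$log_prior[2L], t_)
  l0 <- rep(object$log_prior[1L], t_)
  for (j in seq_len(ncol(Xt))) {
    v <- pmin(Xt[, j], object$arity[j])
    l1 <- l1 + object$cpt[[j]]$l1[v]
    l0 <- l0 + object$cpt[[j]]$l0[v]
  }
  posterior_from_logs(cbind(l0, l1))
}
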