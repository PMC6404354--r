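# Independent brute-force oracles used by the property and acceptance tests.
# These deliberately share no code with the package implementation: plain
# double loops and direct formula transcriptions.

random_window <- function(with_x = FALSE) {
  pool <- if (with_x) c(glycopu:::AA20, "X", "X") else glycopu:::AA20
  sample(pool, 15, replace = TRUE)
}

## --- descriptor oracles ------------------------------------------------------

bf_autocorrelation <- function(window, kind, pt, nlag) {
  v <- unname(pt[window])
  L <- length(v)
  out <- numeric(nlag)
  for (d in seq_len(nlag)) {
    if (d >= L) next
    if (kind == "moreau-broto") {
      acc <- 0
      for (i in 1:(L - d)) acc <- acc + v[i] * v[i + d]
      out[d] <- acc / (L - d)
    } else if (kind == "moran") {
      m <- sum(v) / L
      num <- 0
      for (i in 1:(L - d)) num <- num + (v[i] - m) * (v[i + d] - m)
      den <- sum((v - m)^2) / L
      out[d] <- if (den == 0) 0 else (num / (L - d)) / den
    } else {
      m <- sum(v) / L
      num <- 0
      for (i in 1:(L - d)) num <- num + (v[i] - v[i + d])^2
      den <- sum((v - m)^2) / (L - 1)
      out[d] <- if (den == 0) 0 else (num / (2 * (L - d))) / den
    }
  }
  out
}

# distribution-percentile block of CTD for one attribute, computed directly
bf_ctd_distribution <- function(window, groups) {
  seq2 <- window[window != "X"]
  L <- length(seq2)
  out <- numeric(15)
  for (g in 1:3) {
    occ <- which(seq2 %in% groups[[g]])
    vals <- numeric(5)
    if (length(occ) > 0) {
      nc <- length(occ)
      targets <- c(1, ceiling(0.25 * nc), ceiling(0.5 * nc),
                   ceiling(0.75 * nc), nc)
      targets[targets < 1] <- 1
      for (qi in 1:5) vals[qi] <- occ[targets[qi]] / L
    }
    out[(g - 1) * 5 + 1:5] <- vals
  }
  out
}

bf_socn <- function(window, dm, maxlag) {
  L <- length(window)
  out <- numeric(maxlag)
  for (d in seq_len(maxlag)) {
    if (d >= L) next
    acc <- 0
    for (i in 1:(L - d)) acc <- acc + dm[window[i], window[i + d]]^2
    out[d] <- acc
  }
  out
}

bf_pseaac1 <- function(window, props, lambda, w) {
  L <- length(window)
  z <- lapply(props, function(pt) unname(pt[window]))
  theta <- numeric(lambda)
  for (d in seq_len(lambda)) {
    if (d >= L) next
    acc <- 0
    for (i in 1:(L - d)) {
      corr <- 0
      for (p in seq_along(z)) corr <- corr + (z[[p]][i] - z[[p]][i + d])^2
      acc <- acc + corr / length(z)
    }
    theta[d] <- acc / (L - d)
  }
  f <- numeric(20)
  for (r in seq_along(glycopu:::AA20))
    f[r] <- sum(window == glycopu:::AA20[r])
  den <- sum(f) + w * sum(theta)
  c(f / den, w * theta / den)
}

bf_pseaac2 <- function(window, props, lambda, w) {
  L <- length(window)
  z <- lapply(props, function(pt) unname(pt[window]))
  tau <- numeric(2 * lambda)
  for (d in seq_len(lambda)) {
    if (d >= L) next
    a1 <- 0; a2 <- 0
    for (i in 1:(L - d)) {
      a1 <- a1 + z[[1]][i] * z[[1]][i + d]
      a2 <- a2 + z[[2]][i] * z[[2]][i + d]
    }
    tau[2 * d - 1] <- a1 / (L - d)
    tau[2 * d] <- a2 / (L - d)
  }
  f <- numeric(20)
  for (r in seq_along(glycopu:::AA20))
    f[r] <- sum(window == glycopu:::AA20[r])
  den <- sum(f) + w * sum(tau)
  c(f / den, w * tau / den)
}

## --- information / selection oracles ----------------------------------------

bf_mutual_information <- function(x, y) {
  xs <- unique(x); ys <- unique(y)
  n <- length(x)
  mi <- 0
  for (a in xs) for (b in ys) {
    pab <- sum(x == a & y == b) / n
    if (pab > 0) {
      pa <- sum(x == a) / n; pb <- sum(y == b) / n
      mi <- mi + pab * log(pab / (pa * pb))
    }
  }
  mi
}

bf_mrmr <- function(X, label, k) {
  nms <- colnames(X)
  selected <- character(0)
  remaining <- nms
  for (step in seq_len(k)) {
    best <- NULL; best_score <- -Inf
    for (f in sort(remaining)) {
      rel <- bf_mutual_information(X[, f], label)
      red <- if (length(selected) == 0) 0
             else mean(sapply(selected,
                              function(g) bf_mutual_information(X[, f],
                                                                X[, g])))
      sc <- rel - red
      if (sc > best_score + 1e-12) { best <- f; best_score <- sc }
    }
    selected <- c(selected, best)
    remaining <- setdiff(remaining, best)
  }
  selected
}

bf_auc <- function(scores, pos) {
  ip <- which(pos); iq <- which(!pos)
  tot <- 0
  for (i in ip) for (j in iq)
    tot <- tot + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
  tot / (length(ip) * length(iq))
}

## --- averaged n-dependence score: brute-force transcription ------------------

bf_pande_posterior <- function(X, s, xt, arity, norder, alpha, m = 1,
                               eps = 1e-6) {
  n <- nrow(X); k <- ncol(X); n1 <- sum(s)
  subsets <- if (norder == 0) list(integer(0)) else {
    cmb <- utils::combn(k, norder)
    lapply(seq_len(ncol(cmb)), function(i) cmb[, i])
  }
  score <- c(0, 0)
  ndelta <- 0
  for (S in subsets) {
    in_ctx <- rep(TRUE, n)
    for (j in S) in_ctx <- in_ctx & X[, j] == xt[j]
    cAll <- sum(in_ctx); cPos <- sum(in_ctx & s == 1)
    if (norder > 0 && cAll == 0) next
    ndelta <- ndelta + 1
    CS <- prod(arity[S])
    if (norder == 0) { p1S <- 1; p0S <- 1 } else {
      p1S <- (cPos + m / CS) / (n1 + m)
      ctx_vals <- expand.grid(lapply(S, function(j) seq_len(arity[j])))
      raw <- apply(ctx_vals, 1, function(cv) {
        inc <- rep(TRUE, n)
        for (jj in seq_along(S)) inc <- inc & X[, S[jj]] == cv[jj]
        r <- (sum(inc) / n - alpha * sum(inc & s == 1) / n1) / (1 - alpha)
        if (r < 0) eps else r
      })
      this_raw <- {
        inc <- rep(TRUE, n)
        for (jj in seq_along(S)) inc <- inc & X[, S[jj]] == xt[S[jj]]
        r <- (sum(inc) / n - alpha * sum(inc & s == 1) / n1) / (1 - alpha)
        if (r < 0) eps else r
      }
      n0 <- n * (1 - alpha)
      p0S <- (n0 * this_raw / sum(raw) + m / CS) / (n0 + m)
    }
    t1 <- alpha * p1S; t0 <- (1 - alpha) * p0S
    n1c <- sum(in_ctx & s == 1)
    a_c <- if (cAll > 0) alpha * (cPos / n1) / (cAll / n) else 0
    a_c <- min(max(a_c, 0), 1 - 1e-9)
    n0c <- cAll * (1 - a_c)
    for (mm in setdiff(seq_len(k), S)) {
      b <- arity[mm]
      c1v <- sapply(seq_len(b), function(v) sum(in_ctx & s == 1 & X[, mm] == v))
      cav <- sapply(seq_len(b), function(v) sum(in_ctx & X[, mm] == v))
      q1 <- if (n1c > 0) c1v / n1c else rep(0, b)
      q <- cav / cAll
      raw <- (q - a_c * q1) / (1 - a_c)
      raw[raw < 0] <- eps
      q0n <- raw / sum(raw)
      t1 <- t1 * (c1v[xt[mm]] + m / b) / (n1c + m)
      t0 <- t0 * (n0c * q0n[xt[mm]] + m / b) / (n0c + m)
    }
    score[2] <- score[2] + t1
    score[1] <- score[1] + t0
  }
  list(posterior = score[2] / sum(score), ndelta = ndelta)
}

## --- small fixture builders --------------------------------------------------

write_tmp_fasta <- function(records) {
  path <- tempfile(fileext = ".fasta")
  writeLines(unlist(lapply(names(records), function(id)
    c(paste0(">", id), records[[id]]))), path)
  path
}

write_tmp_sites <- function(df) {
  path <- tempfile(fileext = ".tsv")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# snapshot data.frames with the given composition; keys are synthetic
make_snapshot <- function(n_pos, n_unl, prefix = "P") {
  data.frame(
    protein_id = prefix,
    position = seq_len(n_pos + n_unl),
    label = c(rep("positive", n_pos), rep("unlabelled", n_unl)),
    stringsAsFactors = FALSE)
}
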