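## Synthetic data: SCAR-labelled discrete PU datasets with known ground
## truth, and motif-bearing synthetic proteins so the whole pipeline runs
## without downloads.

#' Specification for a SCAR PU dataset
#'
#' The generated world: true class `y ~ Bernoulli(alpha)`; attributes drawn
#' independently (given `y`) from per-attribute categorical tables; the
#' labelling indicator `s = 1` with probability `c` for positives only
#' (selected completely at random), `s = 0` otherwise. Negative-class tables
#' are uniform; positive-class tables are exponentially tilted,
#' `p1(v) ~ exp(separation * z_v * dir_j)` with `z` equally spaced on
#' `[-1, 1]` and the tilt direction alternating across attributes.
#'
#' The default `separation = 0.73` was calibrated once (by simulating the
#' log-likelihood-ratio AUC of the two classes at k = 10, arity = 3) so the
#' Bayes-optimal AUC of the default world is ~0.90 - hard enough that
#' recovery tests are meaningful, but learnable.
#'
#' @param n sample count.
#' @param k number of attributes.
#' @param arity values per attribute.
#' @param alpha true positive-class prior in (0, 1).
#' @param c true labelling frequency in (0, 1].
#' @param separation exponential tilt of the positive class.
#' @param dependence if TRUE, each even attribute copies its predecessor
#'   with probability 1/2 (pairwise dependence for exercising n >= 1
#'   learners).
#' @param seed integer seed.
#' @return list of class `scar_spec`.
#' @export
scar_spec <- function(n = 5000L, k = 10L, arity = 3L, alpha = 0.3,
                      c = 0.5, separation = 0.73, dependence = FALSE,
                      seed = 1L) {
  stopifnot(alpha > 0, alpha < 1, c > 0, c <= 1, n >= 1, k >= 1, arity >= 2)
  structure(list(n = as.integer(n), k = as.integer(k),
                 arity = as.integer(arity), alpha = alpha, c = c,
                 separation = separation, dependence = dependence,
                 seed = as.integer(seed)), class = "scar_spec")
}

scar_tables <- function(spec) {
  z <- seq(-1, 1, length.out = spec$arity)
  lapply(seq_len(spec$k), function(j) {
    dir <- if (j %% 2L == 0L) -1 else 1
    p1 <- exp(spec$separation * z * dir); p1 <- p1 / sum(p1)
    p0 <- rep(1 / spec$arity, spec$arity)
    list(p1 = p1, p0 = p0)
  })
}

#' Generate a SCAR PU dataset with known ground truth
#'
#' @param spec a [scar_spec()].
#' @return list with `dataset` (a [pu_dataset()]), `y` (true classes) and
#'   `spec`. Deterministic given the spec (byte-identical for equal seeds).
#' @export
generate_scar <- function(spec) {
  stopifnot(inherits(spec, "scar_spec"))
  tabs <- scar_tables(spec)
  local_seed(spec$seed, {
    y <- stats::rbinom(spec$n, 1L, spec$alpha)
    X <- matrix(0L, spec$n, spec$k)
    for (j in seq_len(spec$k)) {
      p <- tabs[[j]]
      X[, j] <- ifelse(y == 1L,
                       sample.int(spec$arity, spec$n, TRUE, p$p1),
                       sample.int(spec$arity, spec$n, TRUE, p$p0))
    }
    if (spec$dependence) {
      for (j in seq(2L, spec$k, by = 2L)) {
        copy <- stats::runif(spec$n) < 0.5
        X[copy, j] <- X[copy, j - 1L]
      }
    }
    colnames(X) <- sprintf("attr%02d", seq_len(spec$k))
    s <- ifelse(y == 1L, stats::rbinom(spec$n, 1L, spec$c), 0L)
    list(dataset = pu_dataset(X, s), y = y, spec = spec)
  })
}

#' Specification for synthetic motif-bearing proteins
#'
#' Proteins are i.i.d. draws from background amino-acid frequencies with
#' `implants` N-linked sequons (`N[!P][ST][!P]`) written in at random
#' positions. A fraction `site_rate` of all sequon occurrences is annotated
#' as positive; for those sites the flanking window positions (offsets
#' -7..-1 and +4..+7 around the motif) are redrawn with probability
#' `flank_bias` from an enriched residue set, so that sequence descriptors
#' carry class signal ("constructed separable setting" when the bias is
#' high). Real glycosylation data differ in many ways (no such clean
#' positional enrichment, correlated sites, homology structure); the
#' generator only emulates the structural interface of the problem.
#'
#' @param n_proteins number of proteins.
#' @param length_mean mean protein length (Poisson, floored at 50).
#' @param site_rate fraction of sequon occurrences annotated positive.
#' @param implants expected implanted sequons per protein (Poisson).
#' @param flank_bias probability that a flank residue of a positive site is
#'   drawn from the enriched set `{D, E, K, R, G}`.
#' @param seed integer seed.
#' @return list of class `sequence_spec`.
#' @export
sequence_spec <- function(n_proteins = 200L, length_mean = 150L,
                          site_rate = 0.5, implants = 2L,
                          flank_bias = 0.6, seed = 1L) {
  stopifnot(site_rate >= 0, site_rate <= 1, flank_bias >= 0, flank_bias <= 1)
  structure(list(n_proteins = as.integer(n_proteins),
                 length_mean = as.integer(length_mean),
                 site_rate = site_rate, implants = implants,
                 flank_bias = flank_bias, seed = as.integer(seed)),
            class = "sequence_spec")
}

#' Generate synthetic proteins with motif-embedded positive sites
#'
#' @param spec a [sequence_spec()].
#' @return list with `proteins` (named character vector), `sites`
#'   (data.frame of positive annotations: protein_id, position, residue,
#'   glyco_type, label) and `spec`.
#' @export
generate_proteins <- function(spec) {
  stopifnot(inherits(spec, "sequence_spec"))
  enriched <- c("D", "E", "K", "R", "G")
  local_seed(spec$seed, {
    proteins <- character(spec$n_proteins)
    names(proteins) <- sprintf("SYN%04d", seq_len(spec$n_proteins))
    for (i in seq_len(spec$n_proteins)) {
      L <- max(50L, stats::rpois(1L, spec$length_mean))
      chars <- sample(AA20, L, TRUE, prob = AA_BACKGROUND_FREQ)
      n_imp <- stats::rpois(1L, spec$implants)
      if (n_imp > 0L) {
        starts <- sample(seq_len(L - 3L), min(n_imp, floor((L - 3L) / 4L)))
        for (st in starts) {
          chars[st] <- "N"
          chars[st + 1L] <- sample(setdiff(AA20, "P"), 1L)
          chars[st + 2L] <- sample(c("S", "T"), 1L)
          chars[st + 3L] <- sample(setdiff(AA20, "P"), 1L)
        }
      }
      proteins[i] <- paste(chars, collapse = "")
    }
    occ <- enumerate_candidates(proteins, "N")
    occ <- occ[occ$motif, , drop = FALSE]
    if (nrow(occ) == 0L) {
      warning("no sequon occurrences generated; empty annotation set")
      sites <- occ[, c("protein_id", "position", "residue", "glyco_type",
                       "label")]
      return(list(proteins = proteins, sites = sites, spec = spec))
    }
    n_pos <- round(spec$site_rate * nrow(occ))
    pos_idx <- if (n_pos > 0L) sort(sample(nrow(occ), n_pos)) else integer(0)
    sites <- occ[pos_idx, , drop = FALSE]
    sites$label <- rep("positive", nrow(sites))
    # enrich the flanks of positive sites so descriptors carry signal;
    # the motif spans (p..p+3) of all positive sites are protected so the
    # annotations stay consistent with the sequences
    if (nrow(sites) && spec$flank_bias > 0) {
      split_chars <- strsplit(proteins, "")
      protected <- lapply(split(sites$position, sites$protein_id),
                          function(p) unique(as.vector(outer(p, 0:3, "+"))))
      for (r in seq_len(nrow(sites))) {
        id <- sites$protein_id[r]; p <- sites$position[r]
        chars <- split_chars[[id]]
        flanks <- c(p - 7:1, p + 4:7)
        flanks <- flanks[flanks >= 1L & flanks <= length(chars)]
        flanks <- setdiff(flanks, protected[[id]])
        redraw <- flanks[stats::runif(length(flanks)) < spec$flank_bias]
        chars[redraw] <- sample(enriched, length(redraw), TRUE)
        split_chars[[id]] <- chars
      }
      proteins <- vapply(split_chars, paste, character(1), collapse = "")
    }
    sites <- sites[, c("protein_id", "position", "residue", "glyco_type",
                       "label")]
    rownames(sites) <- NULL
    list(proteins = proteins, sites = sites, spec = spec)
  })
}

#' Read or write generator specs as YAML
#' @param spec a `scar_spec` or `sequence_spec`.
#' @param path output path.
#' @export
spec_to_yaml <- function(spec, path) {
  obj <- unclass(spec)
  obj$.class <- class(spec)[1]
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname spec_to_yaml
#' @export
spec_from_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  cls <- obj$.class
  obj$.class <- NULL
  do.call(switch(cls, scar_spec = scar_spec, sequence_spec = sequence_spec),
          obj)
}
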