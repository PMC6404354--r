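## Sequence-derived descriptors for 15-residue peptide windows.
##
## All descriptors depend only on the 15 window symbols. The padding/unknown
## symbol 'X' is excluded from composition counts and maps to 0 (the mean) in
## z-scored property encodings, and to distance 0 in the distance-matrix
## based features.

as_window <- function(window) {
  if (length(window) == 1L && nchar(window) > 1L)
    window <- strsplit(window, "")[[1]]
  if (!all(window %in% c(AA20, "X")))
    stop("window contains invalid symbols: ",
         paste(setdiff(window, c(AA20, "X")), collapse = ", "))
  window
}

prop_values <- function(pt, window) unname(pt[window])

#' Amino acid composition (20 features)
#'
#' Frequency of each of the 20 amino acids among the non-`'X'` symbols of the
#' window; sums to 1 whenever at least one real residue is present.
#'
#' @param window character vector of window symbols (or a single string).
#' @return named numeric vector of length 20 (names `AAC.<aa>`).
#' @export
aac <- function(window) {
  window <- as_window(window)
  real <- window[window != "X"]
  counts <- tabulate(match(real, AA20), nbins = 20L)
  if (!length(real)) {
    warning("aac: window contains no standard residues; returning zeros")
    v <- numeric(20L)
  } else v <- counts / length(real)
  setNames(v, paste0("AAC.", AA20))
}

#' Dipeptide composition (400 features)
#'
#' Frequencies of ordered amino-acid pairs over adjacent window positions;
#' pairs involving `'X'` are excluded. Sums to 1 when at least one valid
#' adjacent pair exists.
#'
#' @inheritParams aac
#' @return named numeric vector of length 400 (names `DPC.<aa1><aa2>`).
#' @export
dpc <- function(window) {
  window <- as_window(window)
  L <- length(window)
  nm <- paste0("DPC.", rep(AA20, each = 20L), rep(AA20, times = 20L))
  if (L < 2L || sum(window != "X") < 2L) {
    warning("dpc: fewer than 2 standard residues; returning zeros")
    return(setNames(numeric(400L), nm))
  }
  a <- window[-L]; b <- window[-1L]
  ok <- a != "X" & b != "X"
  if (!any(ok)) {
    warning("dpc: no valid adjacent pairs; returning zeros")
    return(setNames(numeric(400L), nm))
  }
  idx <- (match(a[ok], AA20) - 1L) * 20L + match(b[ok], AA20)
  counts <- tabulate(idx, nbins = 400L)
  setNames(counts / sum(ok), nm)
}

#' Autocorrelation descriptors (normalized Moreau-Broto, Moran, Geary)
#'
#' For a z-scored property encoding `P_1..P_L` of the window (with `'X'`
#' imputed at the property mean, i.e. 0) and lag `d`:
#' * normalized Moreau-Broto: `AC(d) = sum_i P_i P_{i+d} / (L - d)`
#' * Moran: `I(d) = [sum_i (P_i - Pbar)(P_{i+d} - Pbar)/(L - d)] /
#'   [sum_i (P_i - Pbar)^2 / L]`
#' * Geary: `C(d) = [sum_i (P_i - P_{i+d})^2 / (2(L - d))] /
#'   [sum_i (P_i - Pbar)^2 / (L - 1)]`
#'
#' Lags `d >= L` emit 0 so the output dimensionality is fixed at
#' `length(properties) * nlag` regardless of window content; with the default
#' 8 properties and `nlag = 30` each kind contributes 240 features. Moran and
#' Geary denominators of 0 (property constant over the window) also emit 0,
#' with a warning.
#'
#' @inheritParams aac
#' @param kind `"moreau-broto"`, `"moran"` or `"geary"`.
#' @param properties list of z-scored [property_table()] objects.
#' @param nlag maximum lag (default 30).
#' @return named numeric vector of length `length(properties) * nlag`.
#' @export
autocorrelation <- function(window, kind = c("moreau-broto", "moran", "geary"),
                            properties = default_autocorr_properties(),
                            nlag = 30L) {
  kind <- match.arg(kind)
  window <- as_window(window)
  L <- length(window)
  tag <- switch(kind, "moreau-broto" = "NMB", "moran" = "MORAN",
                "geary" = "GEARY")
  degenerate <- FALSE
  out <- lapply(properties, function(pt) {
    v <- prop_values(pt, window)
    m <- mean(v)
    ss <- sum((v - m)^2)
    vapply(seq_len(nlag), function(d) {
      if (d >= L) return(0)
      if (kind == "moreau-broto")
        return(sum(v[1:(L - d)] * v[(1 + d):L]) / (L - d))
      if (ss == 0) { degenerate <<- TRUE; return(0) }
      if (kind == "moran")
        sum((v[1:(L - d)] - m) * (v[(1 + d):L] - m)) / (L - d) / (ss / L)
      else
        sum((v[1:(L - d)] - v[(1 + d):L])^2) / (2 * (L - d)) / (ss / (L - 1))
    }, numeric(1))
  })
  if (degenerate)
    warning("autocorrelation: constant property over window; emitting zeros")
  nms <- unlist(lapply(properties, function(pt)
    paste0(tag, ".", attr(pt, "name"), ".d", seq_len(nlag))))
  setNames(unlist(out), nms)
}

#' Composition-Transition-Distribution descriptors (147 features)
#'
#' Seven physicochemical attributes each partition the amino acids into three
#' classes. Per attribute the descriptor emits 3 class fractions
#' (composition), 3 unordered class-pair transition frequencies over adjacent
#' residues, and 5 distribution values per class (the normalized position of
#' the first, 25%, 50%, 75% and last occurrence). `'X'` symbols are removed
#' before computation; positions and lengths refer to the X-stripped window.
#' A class absent from the window yields 0 for its distribution features.
#'
#' @inheritParams aac
#' @return named numeric vector of length 147 (7 x (3 + 3 + 15)).
#' @export
ctd <- function(window) {
  window <- as_window(window)
  seq2 <- window[window != "X"]
  L <- length(seq2)
  qs <- c(first = 0, q25 = 0.25, q50 = 0.5, q75 = 0.75, q100 = 1)
  out <- numeric(0)
  for (attr_name in names(CTD_GROUPS)) {
    groups <- CTD_GROUPS[[attr_name]]
    cls <- integer(L)
    for (g in 1:3) cls[seq2 %in% groups[[g]]] <- g
    comp <- if (L > 0) tabulate(cls, 3L) / L else numeric(3L)
    names(comp) <- paste0("CTD.", attr_name, ".C", 1:3)
    trans <- numeric(3L)
    names(trans) <- paste0("CTD.", attr_name, ".T",
                           c("12", "13", "23"))
    if (L >= 2L) {
      a <- cls[-L]; b <- cls[-1L]
      pair_id <- paste0(pmin(a, b), pmax(a, b))
      trans[1] <- sum(pair_id == "12") / (L - 1L)
      trans[2] <- sum(pair_id == "13") / (L - 1L)
      trans[3] <- sum(pair_id == "23") / (L - 1L)
    }
    dist <- numeric(15L)
    names(dist) <- paste0("CTD.", attr_name, ".D", rep(1:3, each = 5L),
                          ".", rep(names(qs), times = 3L))
    for (g in 1:3) {
      at <- which(cls == g)
      if (length(at)) {
        r <- pmax(1L, ceiling(qs * length(at)))
        dist[(g - 1L) * 5L + 1:5] <- at[r] / L
      }
    }
    out <- c(out, comp, trans, dist)
  }
  out
}

#' Sequence-order-coupling numbers and quasi-sequence-order (60 + 100)
#'
#' For each amino-acid distance matrix, the sequence-order-coupling number of
#' lag `d` is `tau_d = sum_i dist(p_i, p_{i+d})^2`; lags `d >= L` emit 0.
#' The quasi-sequence-order block contains 20 composition-type terms
#' `f_r / (sum f + w sum tau)` and `maxlag` order terms
#' `w tau_d / (sum f + w sum tau)`. Distances to `'X'` are 0 and `'X'` is
#' excluded from the composition counts. With the default two matrices and
#' `maxlag = 30` this yields 60 coupling-number and 100 quasi-sequence-order
#' features.
#'
#' @inheritParams aac
#' @param maxlag maximum lag (default 30).
#' @param w weighting factor for the order terms (default 0.1).
#' @param matrices named list of 21 x 21 distance matrices
#'   (default: Grantham and the synthetic physicochemical distance).
#' @return named numeric vector: `SOCN.*` then `QSO.*` blocks.
#' @export
sequence_order <- function(window, maxlag = 30L, w = 0.1,
                           matrices = default_distance_matrices()) {
  window <- as_window(window)
  L <- length(window)
  real <- window[window != "X"]
  f <- setNames(tabulate(match(real, AA20), 20L), AA20)
  socn <- numeric(0); qso <- numeric(0)
  for (mn in names(matrices)) {
    dm <- matrices[[mn]]
    tau <- vapply(seq_len(maxlag), function(d) {
      if (d >= L) return(0)
      i <- 1:(L - d)
      sum(dm[cbind(window[i], window[i + d])]^2)
    }, numeric(1))
    names(tau) <- paste0("SOCN.", mn, ".d", seq_len(maxlag))
    socn <- c(socn, tau)
    denom <- sum(f) + w * sum(tau)
    comp <- setNames(f / denom, paste0("QSO.", mn, ".", AA20))
    ord <- setNames(w * tau / denom,
                    paste0("QSO.", mn, ".d", seq_len(maxlag)))
    qso <- c(qso, comp, ord)
  }
  c(socn, qso)
}

#' Pseudo amino acid composition (type I and type II, 50 features each)
#'
#' Type I uses three z-scored properties (hydrophobicity, hydrophilicity,
#' side-chain mass); the tier-`d` correlation factor is
#' `theta_d = mean_i mean_prop (z(p_i) - z(p_{i+d}))^2` and the feature
#' vector is `f_r / D` for the 20 amino acids followed by
#' `w theta_d / D` for `d = 1..lambda`, with `D = sum f + w sum theta`.
#' Type II (amphiphilic) uses hydrophobicity and hydrophilicity; tier `d`
#' contributes two factors `tau_{2d-1} = mean_i z1(p_i) z1(p_{i+d})` and
#' `tau_{2d} = mean_i z2(p_i) z2(p_{i+d})`, giving `20 + 2 lambda` features.
#' Tiers with `d >= L` emit 0, so defaults `lambda = 30` (type I) and
#' `lambda = 15` (type II) both give 50 features on any window.
#'
#' @inheritParams aac
#' @param type 1 or 2.
#' @param lambda number of correlation tiers (default 30 for type I, 15 for
#'   type II).
#' @param w weighting factor (default 0.05).
#' @return named numeric vector of length `20 + lambda` (type I) or
#'   `20 + 2 lambda` (type II).
#' @export
pseaac <- function(window, type = 1L, lambda = if (type == 1L) 30L else 15L,
                   w = 0.05) {
  window <- as_window(window)
  L <- length(window)
  type <- as.integer(type)
  stopifnot(type %in% c(1L, 2L))
  props <- if (type == 1L)
    list(property_table("hydrophobicity", AA_HYDROPHOBICITY),
         property_table("hydrophilicity", AA_HYDROPHILICITY),
         property_table("sidechain_mass", AA_SIDECHAIN_MASS))
  else
    list(property_table("hydrophobicity", AA_HYDROPHOBICITY),
         property_table("hydrophilicity", AA_HYDROPHILICITY))
  z <- lapply(props, prop_values, window = window)
  real <- window[window != "X"]
  f <- setNames(tabulate(match(real, AA20), 20L), AA20)
  if (type == 1L) {
    theta <- vapply(seq_len(lambda), function(d) {
      if (d >= L) return(0)
      i <- 1:(L - d)
      mean(vapply(z, function(v) mean((v[i] - v[i + d])^2), numeric(1)))
    }, numeric(1))
    denom <- sum(f) + w * sum(theta)
    out <- c(setNames(f / denom, paste0("PSE1.", AA20)),
             setNames(w * theta / denom, paste0("PSE1.theta", seq_len(lambda))))
  } else {
    tau <- numeric(2L * lambda)
    for (d in seq_len(lambda)) {
      if (d < L) {
        i <- 1:(L - d)
        tau[2L * d - 1L] <- mean(z[[1]][i] * z[[1]][i + d])
        tau[2L * d]      <- mean(z[[2]][i] * z[[2]][i + d])
      }
    }
    denom <- sum(f) + w * sum(tau)
    out <- c(setNames(f / denom, paste0("PSE2.", AA20)),
             setNames(w * tau / denom, paste0("PSE2.tau", seq_len(2L * lambda))))
  }
  out
}

#' Positional AAindex encoding
#'
#' One feature per (window position, index): the z-scored property value of
#' the residue at that position, with `'X'` encoded as 0 (the post-z-score
#' mean). With `n` complete indices the block has `15 n` features.
#'
#' @inheritParams aac
#' @param tables named list of z-scored [property_table()] objects
#'   (e.g. from [read_aaindex()]).
#' @return named numeric vector of length `15 * length(tables)`
#'   (names `AAIDX.<accession>.p<position>`).
#' @export
aaindex_encode <- function(window, tables = default_aaindex_tables()) {
  window <- as_window(window)
  out <- unlist(lapply(tables, prop_values, window = window))
  nms <- unlist(lapply(names(tables), function(acc)
    paste0("AAIDX.", acc, ".p", seq_along(window))))
  setNames(out, nms)
}

#' Descriptor configuration
#'
#' Collects the tunable descriptor parameters. Defaults mirror the full
#' descriptor set: all groups enabled, autocorrelation over 8 properties and
#' 30 lags (3 x 240 features), 30 sequence-order lags (60 + 100 features),
#' pseudo-composition tiers of 30 (type I) and 15 (type II) (50 + 50), and
#' the vendored AAindex snapshot (15 features per index).
#'
#' @param groups character vector of enabled groups, a subset of
#'   `c("AAC","DPC","NMB","MORAN","GEARY","CTD","SOCN","QSO","PSE1","PSE2",
#'   "AAIDX")`.
#' @param nlag_auto,maxlag_so lag bounds (>= 1).
#' @param lambda1,lambda2 pseudo-composition tier counts (>= 1).
#' @param w_qso,w_pse1,w_pse2 weighting factors in `[0, 1]`.
#' @param aaindex_path optional path to an AAindex1 file replacing the
#'   vendored snapshot.
#' @param aaindex_ids optional accession subset of the AAindex tables.
#' @param autocorr_properties list of z-scored property tables.
#' @return list of class `descriptor_config`.
#' @export
descriptor_config <- function(groups = c("AAC", "DPC", "NMB", "MORAN",
                                         "GEARY", "CTD", "SOCN", "QSO",
                                         "PSE1", "PSE2", "AAIDX"),
                              nlag_auto = 30L, maxlag_so = 30L,
                              lambda1 = 30L, lambda2 = 15L,
                              w_qso = 0.1, w_pse1 = 0.05, w_pse2 = 0.05,
                              aaindex_path = NULL, aaindex_ids = NULL,
                              autocorr_properties = NULL) {
  all_groups <- c("AAC", "DPC", "NMB", "MORAN", "GEARY", "CTD", "SOCN",
                  "QSO", "PSE1", "PSE2", "AAIDX")
  groups <- match.arg(groups, all_groups, several.ok = TRUE)
  stopifnot(nlag_auto >= 1L, maxlag_so >= 1L, lambda1 >= 1L, lambda2 >= 1L,
            w_qso >= 0, w_qso <= 1, w_pse1 >= 0, w_pse1 <= 1,
            w_pse2 >= 0, w_pse2 <= 1)
  cfg <- list(groups = groups, nlag_auto = as.integer(nlag_auto),
              maxlag_so = as.integer(maxlag_so),
              lambda1 = as.integer(lambda1), lambda2 = as.integer(lambda2),
              w_qso = w_qso, w_pse1 = w_pse1, w_pse2 = w_pse2,
              aaindex_path = aaindex_path, aaindex_ids = aaindex_ids,
              autocorr_properties = autocorr_properties)
  class(cfg) <- "descriptor_config"
  cfg
}

config_tables <- function(config) {
  props <- config$autocorr_properties
  if (is.null(props)) props <- default_autocorr_properties()
  tabs <- NULL
  if ("AAIDX" %in% config$groups) {
    tabs <- if (is.null(config$aaindex_path)) default_aaindex_tables()
            else read_aaindex(config$aaindex_path)
    if (!is.null(config$aaindex_ids)) {
      missing <- setdiff(config$aaindex_ids, names(tabs))
      if (length(missing))
        stop("aaindex_ids not present in the AAindex file: ",
             paste(missing, collapse = ", "))
      tabs <- tabs[config$aaindex_ids]
    }
  }
  list(properties = props, aaindex = tabs,
       distances = default_distance_matrices())
}

#' Full descriptor vector for one window
#'
#' Concatenates the enabled groups in the fixed order AAC, DPC, NMB, MORAN,
#' GEARY, CTD, SOCN, QSO, PSE1, PSE2, AAIDX with deterministic feature names.
#'
#' @inheritParams aac
#' @param config a [descriptor_config()].
#' @param tables internal: precomputed property/AAindex tables (to avoid
#'   re-reading them per window).
#' @return named numeric vector.
#' @export
extract_all <- function(window, config = descriptor_config(),
                        tables = config_tables(config)) {
  window <- as_window(window)
  out <- list()
  g <- config$groups
  if ("AAC" %in% g) out$aac <- aac(window)
  if ("DPC" %in% g) out$dpc <- dpc(window)
  for (kind in c("NMB", "MORAN", "GEARY")) {
    if (kind %in% g)
      out[[kind]] <- autocorrelation(
        window,
        switch(kind, NMB = "moreau-broto", MORAN = "moran", GEARY = "geary"),
        properties = tables$properties, nlag = config$nlag_auto)
  }
  if ("CTD" %in% g) out$ctd <- ctd(window)
  if (any(c("SOCN", "QSO") %in% g)) {
    so <- sequence_order(window, maxlag = config$maxlag_so, w = config$w_qso,
                         matrices = tables$distances)
    if ("SOCN" %in% g) out$socn <- so[startsWith(names(so), "SOCN.")]
    if ("QSO" %in% g) out$qso <- so[startsWith(names(so), "QSO.")]
  }
  if ("PSE1" %in% g)
    out$pse1 <- pseaac(window, 1L, config$lambda1, config$w_pse1)
  if ("PSE2" %in% g)
    out$pse2 <- pseaac(window, 2L, config$lambda2, config$w_pse2)
  if ("AAIDX" %in% g) out$aaidx <- aaindex_encode(window, tables$aaindex)
  v <- unlist(unname(out))
  if (any(!is.finite(v))) stop("non-finite descriptor values produced")
  v
}

#' Feature matrix for a table of sites
#'
#' @param proteins named character vector of sequences.
#' @param sites data.frame with protein_id and position.
#' @param config a [descriptor_config()].
#' @return numeric matrix, rows keyed `protein_id:position`.
#' @export
extract_features <- function(proteins, sites, config = descriptor_config()) {
  tables <- config_tables(config)
  wins <- site_windows(proteins, sites)
  rows <- lapply(seq_len(nrow(wins)), function(i)
    extract_all(wins[i, ], config, tables))
  m <- do.call(rbind, rows)
  rownames(m) <- rownames(wins)
  m
}

#' Write a feature matrix with a sidecar config
#'
#' The matrix is written as TSV (first column `key`) and the descriptor
#' configuration as JSON next to it (`<path>.config.json`).
#'
#' @param features numeric matrix with rownames.
#' @param path output TSV path.
#' @param config the [descriptor_config()] used (optional).
#' @param extra optional data.frame of site metadata columns (label etc.)
#'   bound before the features.
#' @export
write_features <- function(features, path, config = NULL, extra = NULL) {
  df <- data.frame(key = rownames(features), check.names = FALSE)
  if (!is.null(extra)) df <- cbind(df, extra)
  df <- cbind(df, as.data.frame(features, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(config)) {
    cfg <- config
    cfg$autocorr_properties <- NULL
    writeLines(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, null = "null"),
               paste0(path, ".config.json"))
  }
  invisible(path)
}
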