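#' @useDynLib glycopu, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats sd quantile rbinom rpois runif setNames t.test chisq.test
#' @importFrom utils read.delim write.table combn head
NULL

## The 20-letter amino-acid alphabet, in the conventional alphabetical
## one-letter order used for composition features.
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "W", "Y", "V")
AA20 <- sort(AA20)

## Symbols accepted in input sequences but mapped to the unknown symbol 'X'.
NONSTANDARD_AA <- c("B", "Z", "U", "O", "J", "*")

aa_named <- function(values) setNames(as.numeric(values), AA20)

## -- Physicochemical property scales -----------------------------------------
## All scales are stored in AA20 (alphabetical) order. Sources are the
## standard literature scales; values feed the autocorrelation, sequence-order
## and pseudo-composition descriptors and the vendored AAindex snapshot.

# Kyte-Doolittle hydropathy
AA_HYDROPHOBICITY <- aa_named(c(
  A = 1.8,  C = 2.5,  D = -3.5, E = -3.5, F = 2.8,
  G = -0.4, H = -3.2, I = 4.5,  K = -3.9, L = 3.8,
  M = 1.9,  N = -3.5, P = -1.6, Q = -3.5, R = -4.5,
  S = -0.8, T = -0.7, V = 4.2,  W = -0.9, Y = -1.3)[AA20])

# Hopp-Woods hydrophilicity
AA_HYDROPHILICITY <- aa_named(c(
  A = -0.5, C = -1.0, D = 3.0,  E = 3.0,  F = -2.5,
  G = 0.0,  H = -0.5, I = -1.8, K = 3.0,  L = -1.8,
  M = -1.3, N = 0.2,  P = 0.0,  Q = 0.2,  R = 3.0,
  S = 0.3,  T = -0.4, V = -1.5, W = -3.4, Y = -2.3)[AA20])

# Side-chain mass (Da)
AA_SIDECHAIN_MASS <- aa_named(c(
  A = 15,  C = 47,  D = 59,  E = 73,  F = 91,
  G = 1,   H = 82,  I = 57,  K = 73,  L = 57,
  M = 75,  N = 58,  P = 42,  Q = 72,  R = 101,
  S = 31,  T = 45,  V = 43,  W = 130, Y = 107)[AA20])

# Grantham (1974) side-chain composition, polarity and volume
AA_GRANTHAM_COMPOSITION <- aa_named(c(
  A = 0,    C = 2.75, D = 1.38, E = 0.92, F = 0,
  G = 0.74, H = 0.58, I = 0,    K = 0.33, L = 0,
  M = 0,    N = 1.33, P = 0.39, Q = 0.89, R = 0.65,
  S = 1.42, T = 0.71, V = 0,    W = 0.13, Y = 0.20)[AA20])

AA_GRANTHAM_POLARITY <- aa_named(c(
  A = 8.1,  C = 5.5,  D = 13.0, E = 12.3, F = 5.2,
  G = 9.0,  H = 10.4, I = 5.2,  K = 11.3, L = 4.9,
  M = 5.7,  N = 11.6, P = 8.0,  Q = 10.5, R = 10.5,
  S = 9.2,  T = 8.6,  V = 5.9,  W = 5.4,  Y = 6.2)[AA20])

AA_GRANTHAM_VOLUME <- aa_named(c(
  A = 31,   C = 55,  D = 54,  E = 83,  F = 132,
  G = 3,    H = 96,  I = 111, K = 119, L = 111,
  M = 105,  N = 56,  P = 32.5, Q = 85, R = 124,
  S = 32,   T = 61,  V = 84,  W = 170, Y = 136)[AA20])

# Zimmerman isoelectric point
AA_ISOELECTRIC <- aa_named(c(
  A = 6.00, C = 5.05, D = 2.77, E = 3.22, F = 5.48,
  G = 5.97, H = 7.59, I = 6.02, K = 9.74, L = 5.98,
  M = 5.74, N = 5.41, P = 6.30, Q = 5.65, R = 10.76,
  S = 5.68, T = 5.66, V = 5.96, W = 5.89, Y = 5.66)[AA20])

# Charton-Charton polarizability
AA_POLARIZABILITY <- aa_named(c(
  A = 0.046, C = 0.128, D = 0.105, E = 0.151, F = 0.290,
  G = 0.000, H = 0.230, I = 0.186, K = 0.219, L = 0.186,
  M = 0.221, N = 0.134, P = 0.131, Q = 0.180, R = 0.291,
  S = 0.062, T = 0.108, V = 0.140, W = 0.409, Y = 0.298)[AA20])

# UniProt/Swiss-Prot average amino-acid background frequencies (approximate),
# used by the synthetic protein generator.
AA_BACKGROUND_FREQ <- local({
  f <- aa_named(c(
    A = 8.25, C = 1.37, D = 5.45, E = 6.75, F = 3.86,
    G = 7.07, H = 2.27, I = 5.96, K = 5.84, L = 9.66,
    M = 2.42, N = 4.06, P = 4.70, Q = 3.93, R = 5.53,
    S = 6.56, T = 5.34, V = 6.87, W = 1.08, Y = 2.92)[AA20])
  f / sum(f)
})

## -- PropertyTable ------------------------------------------------------------

#' Build an amino-acid property table
#'
#' A property table maps each of the 20 standard amino acids to a numeric
#' value. Tables can be z-score normalized over the 20 values, in which case
#' the unknown symbol `'X'` maps to 0 (the mean after normalization), the
#' neutral imputation used by all property-based descriptors.
#'
#' @param name identifier for the table (e.g. an AAindex accession).
#' @param values named numeric vector covering all 20 amino acids.
#' @param normalization `"none"` or `"zscore"`.
#' @return An object of class `property_table`: a named numeric vector over
#'   the 20 amino acids plus `'X'`, with attributes `name` and
#'   `normalization`.
#' @examples
#' pt <- property_table("kd", c(
#'   A = 1.8, C = 2.5, D = -3.5, E = -3.5, F = 2.8, G = -0.4, H = -3.2,
#'   I = 4.5, K = -3.9, L = 3.8, M = 1.9, N = -3.5, P = -1.6, Q = -3.5,
#'   R = -4.5, S = -0.8, T = -0.7, V = 4.2, W = -0.9, Y = -1.3))
#' round(mean(pt[names(pt) != "X"]), 12)  # 0 after z-scoring
#' @export
property_table <- function(name, values, normalization = "zscore") {
  normalization <- match.arg(normalization, c("zscore", "none"))
  if (!all(AA20 %in% names(values)))
    stop("property table '", name, "' must cover all 20 amino acids; missing: ",
         paste(setdiff(AA20, names(values)), collapse = ", "))
  v <- as.numeric(values[AA20])
  if (anyNA(v))
    stop("property table '", name, "' contains missing values")
  if (normalization == "zscore") {
    s <- stats::sd(v)
    if (s == 0) stop("property table '", name, "' is constant; cannot z-score")
    v <- (v - mean(v)) / s
    x_val <- 0
  } else {
    x_val <- mean(v)
  }
  out <- c(setNames(v, AA20), X = x_val)
  structure(out, name = name, normalization = normalization,
            class = "property_table")
}

## Default 8-property set for the autocorrelation descriptors (z-scored).
default_autocorr_properties <- function() {
  raw <- list(
    hydrophobicity  = AA_HYDROPHOBICITY,
    hydrophilicity  = AA_HYDROPHILICITY,
    sidechain_mass  = AA_SIDECHAIN_MASS,
    polarity        = AA_GRANTHAM_POLARITY,
    volume          = AA_GRANTHAM_VOLUME,
    composition     = AA_GRANTHAM_COMPOSITION,
    isoelectric     = AA_ISOELECTRIC,
    polarizability  = AA_POLARIZABILITY)
  lapply(names(raw), function(nm) property_table(nm, raw[[nm]]))
}

## -- Amino-acid distance matrices (sequence-order descriptors) ---------------

#' Grantham chemical distance matrix
#'
#' Computed from Grantham's side-chain composition, polarity and volume with
#' the published quadratic form and scaled so that the mean off-diagonal
#' distance is 100 (sanity anchors: D(Leu, Ile) = 5, D(Cys, Trp) = 215).
#'
#' @return a symmetric 21 x 21 matrix (20 amino acids plus `'X'`; distances
#'   to `'X'` are 0, the neutral convention for padded window positions).
#' @export
grantham_distance <- function() {
  c_ <- AA_GRANTHAM_COMPOSITION; p <- AA_GRANTHAM_POLARITY
  v <- AA_GRANTHAM_VOLUME
  alpha <- 1.833; beta <- 0.1018; gamma <- 0.000399
  d <- sqrt(alpha * outer(c_, c_, "-")^2 +
            beta  * outer(p, p, "-")^2 +
            gamma * outer(v, v, "-")^2)
  off <- d[upper.tri(d)]
  d <- d * (100 / mean(off))
  pad_distance_matrix(d, "grantham")
}

#' Synthetic physicochemical distance matrix
#'
#' A stand-in for the Schneider-Wrede physicochemical distance (whose exact
#' published values are not vendored): the Euclidean distance between amino
#' acids in the z-scored (hydrophobicity, hydrophilicity, side-chain mass)
#' space, scaled to `[0, 1]`. It plays the same structural role (a second,
#' physicochemically motivated distance for the sequence-order descriptors)
#' and is clearly labelled as synthetic.
#'
#' @return a symmetric 21 x 21 matrix as in [grantham_distance()].
#' @export
physchem_synthetic_distance <- function() {
  z <- sapply(list(AA_HYDROPHOBICITY, AA_HYDROPHILICITY, AA_SIDECHAIN_MASS),
              function(v) (v - mean(v)) / stats::sd(v))
  d <- as.matrix(stats::dist(z))
  d <- d / max(d)
  pad_distance_matrix(d, "physchem_synthetic")
}

pad_distance_matrix <- function(d, name) {
  m <- matrix(0, 21, 21, dimnames = list(c(AA20, "X"), c(AA20, "X")))
  m[AA20, AA20] <- d[AA20, AA20]
  attr(m, "name") <- name
  m
}

default_distance_matrices <- function() {
  list(grantham = grantham_distance(),
       physchem_synthetic = physchem_synthetic_distance())
}

## -- CTD class partitions -----------------------------------------------------
## Seven 3-class physicochemical partitions of the amino acids (the standard
## composition/transition/distribution scheme).
CTD_GROUPS <- list(
  hydrophobicity = list(
    c("R", "K", "E", "D", "Q", "N"),
    c("G", "A", "S", "T", "P", "H", "Y"),
    c("C", "L", "V", "I", "M", "F", "W")),
  vdw_volume = list(
    c("G", "A", "S", "T", "P", "D"),
    c("N", "V", "E", "Q", "I", "L"),
    c("M", "H", "K", "F", "R", "Y", "W")),
  polarity = list(
    c("L", "I", "F", "W", "C", "M", "V", "Y"),
    c("P", "A", "T", "G", "S"),
    c("H", "Q", "R", "K", "N", "E", "D")),
  polarizability = list(
    c("G", "A", "S", "D", "T"),
    c("C", "P", "N", "V", "E", "Q", "I", "L"),
    c("K", "M", "H", "F", "R", "Y", "W")),
  charge = list(
    c("K", "R"),
    c("A", "N", "C", "Q", "G", "H", "I", "L", "M", "F", "P", "S", "T",
      "W", "Y", "V"),
    c("D", "E")),
  secondary_structure = list(
    c("E", "A", "L", "M", "Q", "K", "R", "H"),
    c("V", "I", "Y", "C", "W", "F", "T"),
    c("G", "N", "P", "S", "D")),
  solvent_accessibility = list(
    c("A", "L", "F", "C", "G", "I", "V", "W"),
    c("R", "K", "Q", "E", "N", "D"),
    c("M", "S", "P", "T", "H", "Y")))

## -- AAindex1 flat-file reader ------------------------------------------------

#' Read amino-acid property tables from an AAindex1-format file
#'
#' Parses the AAindex1 flat-file format (entries delimited by `//`, with the
#' accession on the `H` line and two rows of ten values following the `I`
#' line, in the order A R N D C Q E G H I / L K M F P S T W Y V). Indices
#' containing any missing (`NA`) value are dropped with a warning, since the
#' positional encoding requires a complete table.
#'
#' @param path path to an AAindex1-format text file.
#' @param normalization passed to [property_table()] (default z-score).
#' @return named list of [property_table()] objects keyed by accession.
#' @export
read_aaindex <- function(path, normalization = "zscore") {
  if (!file.exists(path)) stop("AAindex file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  order1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I")
  order2 <- c("L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  out <- list()
  dropped <- character()
  i <- 1L
  acc <- NULL
  while (i <= length(lines)) {
    ln <- lines[[i]]
    if (startsWith(ln, "H ")) {
      acc <- trimws(sub("^H ", "", ln))
    } else if (startsWith(ln, "I ")) {
      if (is.null(acc)) stop("malformed AAindex entry: I line before H line ",
                             "at line ", i)
      v1 <- suppressWarnings(as.numeric(strsplit(trimws(lines[[i + 1L]]),
                                                 "\\s+")[[1]]))
      v2 <- suppressWarnings(as.numeric(strsplit(trimws(lines[[i + 2L]]),
                                                 "\\s+")[[1]]))
      if (length(v1) != 10L || length(v2) != 10L)
        stop("malformed AAindex value rows for ", acc, " near line ", i)
      vals <- setNames(c(v1, v2), c(order1, order2))
      if (anyNA(vals)) {
        dropped <- c(dropped, acc)
      } else {
        out[[acc]] <- property_table(acc, vals, normalization)
      }
      i <- i + 2L
    }
    i <- i + 1L
  }
  if (length(dropped))
    warning("dropped ", length(dropped),
            " AAindex entries with missing values: ",
            paste(dropped, collapse = ", "))
  out
}

default_aaindex_tables <- function() {
  path <- system.file("extdata", "aaindex1_subset.txt", package = "glycopu")
  read_aaindex(path)
}
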