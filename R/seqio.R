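## Sequence and site-annotation I/O, window extraction and annotation
## snapshot comparison.

GLYCO_TYPES <- c("C", "N", "O-S", "O-T")

#' Residue targeted by a glycosylation type
#'
#' C-linked glycans attach to tryptophan, N-linked to asparagine and O-linked
#' to serine (`O-S`) or threonine (`O-T`).
#'
#' @param glyco_type one of `"C"`, `"N"`, `"O-S"`, `"O-T"`.
#' @return single amino-acid symbol.
#' @export
glyco_residue <- function(glyco_type) {
  glyco_type <- match.arg(glyco_type, GLYCO_TYPES)
  switch(glyco_type, "C" = "W", "N" = "N", "O-S" = "S", "O-T" = "T")
}

#' Read protein sequences from a FASTA file
#'
#' Sequences are uppercased and the non-standard symbols B, Z, U, O, J and
#' `*` are mapped to the unknown symbol `'X'`; the number of substitutions is
#' reported via a message and stored in the `"substitutions"` attribute.
#'
#' @param path path to a (multi-record) FASTA file.
#' @return named character vector of sequences (names are the record ids, the
#'   first whitespace-delimited token of each header).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  first <- which(nzchar(trimws(lines)))[1]
  if (is.na(first) || !startsWith(lines[[first]], ">"))
    stop("malformed FASTA (", path, "): expected '>' header at line ",
         if (is.na(first)) 1 else first)
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    stop("duplicate FASTA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  if (any(nchar(seqs) < 1)) stop("empty sequence in FASTA: ",
                                 paste(ids[nchar(seqs) < 1], collapse = ", "))
  pattern <- paste0("[", paste(sub("\\*", "\\\\*", NONSTANDARD_AA),
                               collapse = ""), "]")
  n_sub <- sum(vapply(seqs, function(s)
    sum(strsplit(s, "")[[1]] %in% NONSTANDARD_AA), integer(1)))
  if (n_sub > 0) {
    seqs <- gsub(pattern, "X", seqs)
    message("read_fasta: mapped ", n_sub, " non-standard symbol(s) to 'X'")
  }
  attr(seqs, "substitutions") <- n_sub
  seqs
}

#' Write sequences to FASTA
#' @param proteins named character vector of sequences.
#' @param path output path.
#' @export
write_fasta <- function(proteins, path) {
  set <- Biostrings::BStringSet(unclass(proteins))
  names(set) <- names(proteins)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read site annotations from a tab-separated table
#'
#' The table must have a header with columns `protein_id`, `position`,
#' `glyco_type` and `label` (`positive` or `unlabelled`). The residue column
#' is filled in from the sequences. Rows whose position is out of range or
#' whose residue does not match the glycosylation type (C->W, N->N, O-S->S,
#' O-T->T) are rejected; the rejected rows are attached as the `"rejected"`
#' attribute and reported via a message.
#'
#' @param path path to the TSV file.
#' @param proteins named character vector of sequences (e.g. [read_fasta()]).
#' @return data.frame with columns protein_id, position, residue, glyco_type,
#'   label (accepted rows only).
#' @export
read_sites <- function(path, proteins) {
  if (!file.exists(path)) stop("site table not found: ", path)
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  required <- c("protein_id", "position", "glyco_type", "label")
  missing <- setdiff(required, names(tab))
  if (length(missing))
    stop("site table is missing column(s): ", paste(missing, collapse = ", "))
  tab$protein_id <- as.character(tab$protein_id)
  tab$position <- as.integer(tab$position)
  unknown <- setdiff(unique(tab$protein_id), names(proteins))
  if (length(unknown))
    stop("site table references unknown protein id(s): ",
         paste(unknown, collapse = ", "))
  if (!all(tab$glyco_type %in% GLYCO_TYPES))
    stop("invalid glyco_type value(s): ",
         paste(setdiff(unique(tab$glyco_type), GLYCO_TYPES), collapse = ", "))
  if (!all(tab$label %in% c("positive", "unlabelled")))
    stop("invalid label value(s): ",
         paste(setdiff(unique(tab$label), c("positive", "unlabelled")),
               collapse = ", "))
  len <- nchar(proteins)[tab$protein_id]
  in_range <- !is.na(tab$position) & tab$position >= 1L & tab$position <= len
  residue <- rep(NA_character_, nrow(tab))
  residue[in_range] <- substr(proteins[tab$protein_id[in_range]],
                              tab$position[in_range], tab$position[in_range])
  expected <- vapply(tab$glyco_type, glyco_residue, character(1))
  ok <- in_range & residue == expected
  tab$residue <- residue
  accepted <- tab[ok, c("protein_id", "position", "residue", "glyco_type",
                        "label")]
  rownames(accepted) <- NULL
  rejected <- tab[!ok, , drop = FALSE]
  if (nrow(rejected) > 0)
    message("read_sites: rejected ", nrow(rejected),
            " row(s) with out-of-range positions or residue/type mismatch")
  attr(accepted, "rejected") <- rejected
  accepted
}

#' Write a site annotation table
#' @param sites data.frame as returned by [read_sites()].
#' @param path output path.
#' @export
write_sites <- function(sites, path) {
  utils::write.table(sites, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Extract the 15-residue peptide window centred on a site
#'
#' The window covers positions `position - 7 ... position + 7`; positions
#' beyond either terminus are padded with `'X'` so the window length is
#' always exactly 15 and the candidate site sits at index 8.
#'
#' @param protein a single sequence (character scalar).
#' @param position 1-based position of the candidate site.
#' @return character vector of 15 symbols.
#' @export
extract_window <- function(protein, position) {
  protein <- as.character(protein)
  L <- nchar(protein)
  position <- as.integer(position)
  if (is.na(position) || position < 1L || position > L)
    stop("position ", position, " out of range for sequence of length ", L)
  chars <- strsplit(protein, "")[[1]]
  idx <- (position - 7L):(position + 7L)
  out <- rep("X", 15L)
  keep <- idx >= 1L & idx <= L
  out[keep] <- chars[idx[keep]]
  out
}

#' Windows for a table of sites
#'
#' @param proteins named character vector of sequences.
#' @param sites data.frame with protein_id and position columns.
#' @return character matrix (rows = sites, 15 columns), rownames
#'   `protein_id:position`.
#' @export
site_windows <- function(proteins, sites) {
  w <- t(mapply(function(p, pos) extract_window(proteins[[p]], pos),
                sites$protein_id, sites$position))
  rownames(w) <- paste0(sites$protein_id, ":", sites$position)
  colnames(w) <- paste0("p", 1:15)
  w
}

#' Check the N-linked sequon at a position
#'
#' The sequon requires residues (i, i+1, i+2, i+3) = N, not-P, S-or-T, not-P.
#' Positions too close to the C-terminus to evaluate the full motif are
#' treated as non-motif.
#'
#' @param protein a single sequence.
#' @param position 1-based position (must hold an N for a true result).
#' @return logical scalar.
#' @export
matches_sequon <- function(protein, position) {
  L <- nchar(protein)
  if (position + 3L > L) return(FALSE)
  quad <- substring(protein, position:(position + 3L), position:(position + 3L))
  quad[1] == "N" && quad[2] != "P" && quad[3] %in% c("S", "T") && quad[4] != "P"
}

#' Enumerate candidate (unlabelled) sites of a glycosylation type
#'
#' All positions carrying the residue targeted by `glyco_type` and not listed
#' as positive are returned as unlabelled candidates. For N-linked sites the
#' `motif` column records whether the position lies in an `N[!P][ST][!P]`
#' sequon; the motif and non-motif subsets partition the candidates.
#'
#' @param proteins named character vector of sequences.
#' @param glyco_type one of `"C"`, `"N"`, `"O-S"`, `"O-T"`.
#' @param positives optional data.frame of positive annotations
#'   (protein_id, position) to exclude.
#' @return data.frame: protein_id, position, residue, glyco_type, label
#'   (`"unlabelled"`), motif (logical; meaningful for type `"N"`).
#' @export
enumerate_candidates <- function(proteins, glyco_type, positives = NULL) {
  glyco_type <- match.arg(glyco_type, GLYCO_TYPES)
  target <- glyco_residue(glyco_type)
  pos_keys <- if (!is.null(positives) && nrow(positives))
    paste0(positives$protein_id, ":", positives$position) else character()
  res <- lapply(names(proteins), function(id) {
    chars <- strsplit(proteins[[id]], "")[[1]]
    at <- which(chars == target)
    if (!length(at)) return(NULL)
    data.frame(protein_id = id, position = at, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    return(data.frame(protein_id = character(), position = integer(),
                      residue = character(), glyco_type = character(),
                      label = character(), motif = logical()))
  out <- out[!(paste0(out$protein_id, ":", out$position) %in% pos_keys), ,
             drop = FALSE]
  out$residue <- target
  out$glyco_type <- glyco_type
  out$label <- "unlabelled"
  out$motif <- if (glyco_type == "N") {
    mapply(function(p, i) matches_sequon(proteins[[p]], i),
           out$protein_id, out$position)
  } else FALSE
  rownames(out) <- NULL
  out
}

#' Compare two annotation snapshots of the same glycosylation type
#'
#' Computes the relabelling summary between an earlier and a later snapshot:
#' `N1` is the number of sites annotated positive in the later snapshot that
#' were present as unlabelled in the earlier one; `pct_mislabelled` is
#' `N1 / (later positives - earlier positives)` (the fraction of newly added
#' positives that were previously mislabelled); `actual_prior` is
#' `(N1 + earlier positives) / (earlier unlabelled + earlier positives)`,
#' i.e. the class prior of the earlier collection in hindsight.
#'
#' @param earlier,later data.frames with protein_id, position, label columns
#'   (the full earlier/later snapshots: positives plus unlabelled candidates).
#' @return object of class `relabelling_summary`: a list with
#'   `n_new_positive`, `n_previously_unlabelled` (N1), `pct_mislabelled`,
#'   `actual_prior` and `degenerate` (TRUE when no positives were added, in
#'   which case the percentage is reported as 0).
#' @export
compare_snapshots <- function(earlier, later) {
  key <- function(df) paste0(df$protein_id, ":", df$position)
  e_pos <- key(earlier[earlier$label == "positive", , drop = FALSE])
  e_unl <- key(earlier[earlier$label == "unlabelled", , drop = FALSE])
  l_pos <- key(later[later$label == "positive", , drop = FALSE])
  if (length(l_pos) < length(e_pos))
    stop("snapshots out of order: later has fewer positives (",
         length(l_pos), ") than earlier (", length(e_pos), ")")
  new_pos <- setdiff(l_pos, e_pos)
  n1 <- sum(new_pos %in% e_unl)
  added <- length(l_pos) - length(e_pos)
  degenerate <- added == 0L
  pct <- if (degenerate) 0 else n1 / added
  prior <- (n1 + length(e_pos)) / (length(e_unl) + length(e_pos))
  structure(list(
    n_new_positive = length(new_pos),
    n_previously_unlabelled = n1,
    pct_mislabelled = pct,
    actual_prior = prior,
    degenerate = degenerate), class = "relabelling_summary")
}

#' @export
print.relabelling_summary <- function(x, ...) {
  cat("Relabelling summary\n")
  cat(sprintf("  newly positive sites:        %d\n", x$n_new_positive))
  cat(sprintf("  previously unlabelled (N1):  %d\n",
              x$n_previously_unlabelled))
  cat(sprintf("  %% mislabelled among added:   %.2f%%%s\n",
              100 * x$pct_mislabelled,
              if (x$degenerate) " (degenerate: no positives added)" else ""))
  cat(sprintf("  actual prior (earlier data): %.2f%%\n",
              100 * x$actual_prior))
  invisible(x)
}

#' Serialize a relabelling summary to JSON
#' @param x a `relabelling_summary`.
#' @param path optional output file.
#' @return JSON string (invisibly if written to file).
#' @export
relabelling_to_json <- function(x, path = NULL) {
  js <- jsonlite::toJSON(unclass(x), auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}
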