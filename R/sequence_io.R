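# Sequence sets are plain named character vectors: names are record ids,
# values are validated RNA residue strings over {A,C,G,U}. Labelled data are
# held in the lightweight `orn_dataset` container below.

#' Normalize a raw sequence string to the RNA alphabet
#'
#' Uppercases the input and converts T to U, so DNA-form input (as commonly
#' pasted for siRNAs) is accepted transparently. Any character outside
#' `{A,C,G,U,T}` (either case), including IUPAC ambiguity codes, is rejected.
#'
#' @param raw A non-empty character scalar.
#' @return A string over `{A,C,G,U}`.
#' @examples
#' normalize_to_rna("acgt")  # "ACGU"
#' @export
normalize_to_rna <- function(raw) {
  stopifnot(is.character(raw), length(raw) == 1L)
  if (!nzchar(raw)) stop("sequence is empty", call. = FALSE)
  up <- chartr("acgut", "ACGUT", raw)
  up <- gsub("T", "U", up, fixed = TRUE)
  bad <- regexpr("[^ACGU]", up)
  if (bad > 0L) {
    stop(sprintf("invalid character '%s' at position %d (expected A/C/G/U/T)",
                 substr(raw, bad, bad), bad), call. = FALSE)
  }
  up
}

#' Read an RNA FASTA file
#'
#' Reads a (multi-record, wrapped or unwrapped) FASTA file and returns a named
#' character vector of normalized RNA sequences (see [normalize_to_rna()]).
#' Record ids are the first whitespace-delimited token of each header line.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of RNA residue strings; empty for an empty
#'   file. Record order is preserved.
#' @seealso [write_fasta()]
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  validate_fasta_lines(path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) return(stats::setNames(character(0), character(0)))
  ids <- sub("\\s.*$", "", names(set))
  seqs <- as.character(set)
  out <- vapply(seq_along(seqs), function(i) {
    tryCatch(normalize_to_rna(seqs[[i]]),
             error = function(e) stop(sprintf("record '%s': %s", ids[[i]],
                                              conditionMessage(e)), call. = FALSE))
  }, character(1))
  stats::setNames(out, ids)
}

# Pre-scan for structural faults so errors can name the offending line;
# content-level validation happens per record in read_fasta().
validate_fasta_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) return(invisible(TRUE))
  if (!startsWith(lines[nonblank[1L]], ">")) {
    stop(sprintf("%s: line %d: sequence data before first FASTA header",
                 path, nonblank[1L]), call. = FALSE)
  }
  headers <- which(startsWith(lines, ">"))
  for (h in headers) {
    id <- sub("\\s.*$", "", sub("^>", "", lines[h]))
    if (!nzchar(id)) {
      stop(sprintf("%s: line %d: FASTA header with empty id", path, h), call. = FALSE)
    }
    body_end <- if (any(headers > h)) min(headers[headers > h]) - 1L else length(lines)
    body <- lines[seq.int(h + 1L, length.out = max(0L, body_end - h))]
    if (sum(nchar(trimws(body))) == 0L) {
      stop(sprintf("%s: line %d: record '%s' has an empty sequence", path, h, id),
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of RNA sequences.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  set <- Biostrings::RNAStringSet(unname(as.character(seqs)))
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Keep sequences within a length range
#'
#' Retains records whose length is within `[min_len, max_len]` inclusive
#' (default 17-27 nt, the modelling range). Order is preserved and an empty
#' result is allowed.
#'
#' @param seqs Named character vector of RNA sequences.
#' @param min_len,max_len Inclusive length bounds.
#' @return Filtered named character vector.
#' @export
filter_by_length <- function(seqs, min_len = 17L, max_len = 27L) {
  stopifnot(min_len <= max_len)
  seqs[nchar(seqs) >= min_len & nchar(seqs) <= max_len]
}

#' Drop duplicate sequences
#'
#' Removes records whose residue string has already been seen, keeping the
#' first occurrence. Ids are ignored in the comparison: two records with
#' different ids but identical residues count as duplicates.
#'
#' @param seqs Named character vector of RNA sequences.
#' @return De-duplicated named character vector, order of survivors preserved.
#' @export
deduplicate <- function(seqs) {
  seqs[!duplicated(unname(seqs))]
}

#' Build a labelled oligonucleotide dataset
#'
#' Combines a positive (IMORN, label +1) and a negative (non-IMORN, label -1)
#' sequence set into an `orn_dataset`. Ids must be unique across the combined
#' set, and a residue string occurring in both classes is reported as an error
#' (a cross-class duplicate has no well-defined label).
#'
#' @param positive,negative Named character vectors of RNA sequences.
#' @param name Dataset name used in printing.
#' @param min_len,max_len Optional inclusive length bounds enforced on every
#'   record; `NULL` (default) skips the check.
#' @return An object of class `orn_dataset`: a list with elements `id`, `seq`
#'   (character vectors) and `label` (integer, +1/-1), plus a `name`.
#' @examples
#' ds <- orn_dataset(c(p1 = "AAAAAAAAAAAAAAAAA"), c(n1 = "GGGGGGGGGGGGGGGGG"))
#' ds
#' @export
orn_dataset <- function(positive, negative, name = "dataset",
                        min_len = NULL, max_len = NULL) {
  stopifnot(is.character(positive), is.character(negative))
  if (length(positive) && is.null(names(positive)))
    names(positive) <- paste0("pos_", seq_along(positive))
  if (length(negative) && is.null(names(negative)))
    names(negative) <- paste0("neg_", seq_along(negative))
  id <- c(names(positive), names(negative))
  seq <- c(unname(positive), unname(negative))
  label <- rep(c(1L, -1L), c(length(positive), length(negative)))
  if (anyDuplicated(id)) {
    stop(sprintf("duplicate ids across the dataset: %s",
                 paste(unique(id[duplicated(id)])[1:min(3, sum(duplicated(id)))],
                       collapse = ", ")), call. = FALSE)
  }
  cross <- intersect(unname(positive), unname(negative))
  if (length(cross)) {
    stop(sprintf("%d sequence(s) occur in both classes (first: %s); resolve before modelling",
                 length(cross), cross[[1L]]), call. = FALSE)
  }
  if (!is.null(min_len) || !is.null(max_len)) {
    lo <- min_len %||% 1L
    hi <- max_len %||% Inf
    bad <- which(nchar(seq) < lo | nchar(seq) > hi)
    if (length(bad)) {
      stop(sprintf("%d record(s) outside length bounds [%s, %s] (first: %s, length %d)",
                   length(bad), lo, hi, id[bad[1L]], nchar(seq[bad[1L]])), call. = FALSE)
    }
  }
  structure(list(id = id, seq = seq, label = label, name = name),
            class = "orn_dataset")
}

#' Read a labelled dataset from two FASTA files
#'
#' @param positive_path FASTA of positive (IMORN) sequences.
#' @param negative_path FASTA of negative (non-IMORN) sequences.
#' @inheritParams orn_dataset
#' @return An [orn_dataset()].
#' @export
read_labeled_fasta <- function(positive_path, negative_path, name = "dataset",
                               min_len = NULL, max_len = NULL) {
  orn_dataset(read_fasta(positive_path), read_fasta(negative_path),
              name = name, min_len = min_len, max_len = max_len)
}

#' Read a labelled dataset from one FASTA plus a label table
#'
#' The table is two-column TSV (id, label) with labels in `{1, -1}` and no
#' header. Every FASTA record must be labelled.
#'
#' @param fasta_path FASTA of all sequences.
#' @param label_path Two-column TSV path.
#' @inheritParams orn_dataset
#' @return An [orn_dataset()].
#' @export
read_label_table <- function(fasta_path, label_path, name = "dataset",
                             min_len = NULL, max_len = NULL) {
  seqs <- read_fasta(fasta_path)
  tab <- utils::read.table(label_path, sep = "\t", header = FALSE,
                           col.names = c("id", "label"),
                           colClasses = c("character", "integer"))
  if (!all(tab$label %in% c(1L, -1L)))
    stop("labels must be 1 or -1", call. = FALSE)
  missing <- setdiff(names(seqs), tab$id)
  if (length(missing))
    stop(sprintf("no label for id(s): %s", paste(utils::head(missing, 3), collapse = ", ")),
         call. = FALSE)
  lab <- tab$label[match(names(seqs), tab$id)]
  orn_dataset(seqs[lab == 1L], seqs[lab == -1L], name = name,
              min_len = min_len, max_len = max_len)
}

#' @export
print.orn_dataset <- function(x, ...) {
  cat(sprintf("orn_dataset '%s': %d sequences (%d positive / %d negative), lengths %d-%d\n",
              x$name, length(x$seq), sum(x$label == 1L), sum(x$label == -1L),
              if (length(x$seq)) min(nchar(x$seq)) else 0L,
              if (length(x$seq)) max(nchar(x$seq)) else 0L))
  invisible(x)
}

#' Extract the positive or negative class of a dataset
#'
#' @param ds An [orn_dataset()].
#' @param class `+1` for positives, `-1` for negatives.
#' @return Named character vector of sequences.
#' @export
dataset_class <- function(ds, class = 1L) {
  stopifnot(inherits(ds, "orn_dataset"), class %in% c(1L, -1L))
  stats::setNames(ds$seq[ds$label == class], ds$id[ds$label == class])
}
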