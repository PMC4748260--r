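# Secondary-structure analysis of short ssRNA: dot-bracket parsing, folding
# (external RNAfold when available, otherwise a maximum-pairing Nussinov
# dynamic program), extended-linear vs stem-loop classification, hairpin-loop
# detection, and the length-binned class summary. All coordinates are 1-based
# inclusive.

#' Parse a dot-bracket secondary structure
#'
#' Validates that the structure string has the same length as the sequence
#' and that parentheses are balanced and properly nested, and computes the
#' base-pair partner map by stack matching.
#'
#' @param seq RNA residue string.
#' @param structure String over `. ( )` of the same length.
#' @param mfe Optional minimum free energy (kcal/mol) to record.
#' @return An object of class `dot_bracket`: list with `seq`, `structure`,
#'   `partner` (integer vector, `NA` where unpaired), `n_pairs`, `mfe`.
#' @examples
#' parse_dot_bracket("GGGAAAACCC", "(((....)))")
#' @export
parse_dot_bracket <- function(seq, structure, mfe = NULL) {
  if (nchar(seq) != nchar(structure))
    stop(sprintf("sequence length %d != structure length %d",
                 nchar(seq), nchar(structure)), call. = FALSE)
  chars <- strsplit(structure, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% c(".", "(", ")"))
  if (length(bad))
    stop(sprintf("invalid structure character '%s' at position %d",
                 chars[bad[1L]], bad[1L]), call. = FALSE)
  partner <- rep(NA_integer_, length(chars))
  stack <- integer(0)
  for (i in seq_along(chars)) {
    if (chars[i] == "(") stack <- c(stack, i)
    else if (chars[i] == ")") {
      if (!length(stack))
        stop(sprintf("unbalanced ')' at position %d", i), call. = FALSE)
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      partner[i] <- j; partner[j] <- i
    }
  }
  if (length(stack))
    stop(sprintf("unbalanced '(' at position %d", stack[1L]), call. = FALSE)
  structure(list(seq = seq, structure = structure, partner = partner,
                 n_pairs = as.integer(sum(!is.na(partner)) / 2L), mfe = mfe),
            class = "dot_bracket")
}

#' @export
print.dot_bracket <- function(x, ...) {
  cat(x$seq, "\n", x$structure, sep = "")
  if (!is.null(x$mfe)) cat(sprintf(" (%.2f)", x$mfe))
  cat(sprintf("\n%d base pair(s), %s\n", x$n_pairs, classify_structure(x)))
  invisible(x)
}

#' Is the external RNAfold backend available?
#'
#' @return `TRUE` when the `RNAfold` executable (ViennaRNA) is on the PATH.
#' @export
rnafold_available <- function() nzchar(Sys.which("RNAfold"))

#' Fold sequences with the external RNAfold program
#'
#' Runs ViennaRNA's `RNAfold` and parses the minimum-free-energy dot-bracket
#' structure and energy for each sequence.
#'
#' @param seqs Named character vector of RNA sequences.
#' @return Named list of [parse_dot_bracket()] objects (with `mfe` set).
#' @seealso [fold_nussinov()] for the offline fallback.
#' @export
fold_rnafold <- function(seqs) {
  if (!rnafold_available())
    stop(paste("RNAfold backend unavailable: install ViennaRNA, supply",
               "dot-bracket structures directly, or use fold_nussinov()"),
         call. = FALSE)
  if (!length(seqs)) return(list())
  ids <- names(seqs) %||% paste0("seq_", seq_along(seqs))
  input <- as.vector(rbind(paste0(">", ids), unname(seqs)))
  out <- system2("RNAfold", args = c("--noPS"), input = input, stdout = TRUE)
  res <- list()
  i <- 1L
  while (i <= length(out)) {
    if (startsWith(out[i], ">")) {
      id <- sub("^>\\s*", "", out[i])
      seq <- chartr("T", "U", toupper(out[i + 1L]))
      line <- out[i + 2L]
      db <- sub("^([.()]+).*$", "\\1", line)
      mfe <- as.numeric(sub("^.*\\(\\s*(-?[0-9.]+)\\)\\s*$", "\\1", line))
      res[[id]] <- parse_dot_bracket(seq, db, mfe = mfe)
      i <- i + 3L
    } else i <- i + 1L
  }
  res
}

can_pair <- function(a, b) {
  paste0(a, b) %in% c("AU", "UA", "GC", "CG", "GU", "UG")
}

#' Maximum base-pairing fold (Nussinov dynamic program)
#'
#' Computes a structure with the maximum number of nested Watson-Crick or
#' wobble pairs (`AU, UA, GC, CG, GU, UG`) subject to a minimum hairpin loop
#' of `min_loop` unpaired residues. This is a maximum-pairing approximation,
#' not a thermodynamic (MFE) fold; results carry no energy. Traceback is
#' deterministic: leaving the rightmost position unpaired is preferred when it
#' ties the optimum, otherwise the smallest partner index is chosen.
#'
#' @param seq RNA residue string.
#' @param min_loop Minimum unpaired residues enclosed by a pair (default 3).
#' @return A [parse_dot_bracket()] object (with `mfe = NULL`).
#' @examples
#' fold_nussinov("GGGAAAACCC")$structure  # "(((....)))"
#' @export
fold_nussinov <- function(seq, min_loop = 3L) {
  n <- nchar(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  if (n == 0L) stop("empty sequence", call. = FALSE)
  N <- matrix(0L, n, n)
  if (n > min_loop + 1L) {
    for (span in (min_loop + 1L):(n - 1L)) {
      for (i in 1:(n - span)) {
        j <- i + span
        best <- N[i, j - 1L]
        for (k in i:(j - min_loop - 1L)) {
          if (can_pair(chars[k], chars[j])) {
            v <- 1L + (if (k > i) N[i, k - 1L] else 0L) +
              (if (k + 1L <= j - 1L) N[k + 1L, j - 1L] else 0L)
            if (v > best) best <- v
          }
        }
        N[i, j] <- best
      }
    }
  }
  db <- rep(".", n)
  stack <- list(c(1L, n))
  while (length(stack)) {
    ij <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- ij[1L]; j <- ij[2L]
    if (i >= j || j - i <= min_loop) next
    if (N[i, j] == N[i, j - 1L]) {
      stack[[length(stack) + 1L]] <- c(i, j - 1L)
      next
    }
    for (k in i:(j - min_loop - 1L)) {
      if (can_pair(chars[k], chars[j])) {
        v <- 1L + (if (k > i) N[i, k - 1L] else 0L) +
          (if (k + 1L <= j - 1L) N[k + 1L, j - 1L] else 0L)
        if (v == N[i, j]) {
          db[k] <- "("; db[j] <- ")"
          if (k > i) stack[[length(stack) + 1L]] <- c(i, k - 1L)
          stack[[length(stack) + 1L]] <- c(k + 1L, j - 1L)
          break
        }
      }
    }
  }
  parse_dot_bracket(seq, paste(db, collapse = ""))
}

#' Fold a set of sequences with a chosen backend
#'
#' @param seqs Named character vector of RNA sequences.
#' @param backend `"rnafold"` (external, MFE) or `"nussinov"` (built-in,
#'   maximum pairing). The two are never mixed within one call.
#' @return Named list of `dot_bracket` objects, with the backend recorded in
#'   `attr(, "backend")`.
#' @export
fold_sequences <- function(seqs, backend = c("rnafold", "nussinov")) {
  backend <- match.arg(backend)
  res <- if (backend == "rnafold") fold_rnafold(seqs)
         else lapply(stats::setNames(as.character(seqs),
                                     names(seqs) %||% paste0("seq_", seq_along(seqs))),
                     fold_nussinov)
  attr(res, "backend") <- backend
  res
}

#' Classify a structure as extended linear or stem-loop
#'
#' "Linear" means the predicted structure has no base pairs at all (an
#' extended open structure); any paired structure counts as stem-loop.
#'
#' @param db A `dot_bracket` object.
#' @return `"linear"` or `"stem_loop"`.
#' @export
classify_structure <- function(db) {
  stopifnot(inherits(db, "dot_bracket"))
  if (db$n_pairs == 0L) "linear" else "stem_loop"
}

#' Locate hairpin loops
#'
#' A hairpin loop is a maximal run of unpaired positions whose immediate
#' flanking positions pair with each other. Internal loops and bulges are not
#' counted. A structure may contain several hairpin loops.
#'
#' @param db A `dot_bracket` object.
#' @return Data frame with columns `start`, `end` (1-based inclusive unpaired
#'   run) and `close_i`, `close_j` (the enclosing pair); zero rows when there
#'   is no hairpin.
#' @export
hairpin_loops <- function(db) {
  stopifnot(inherits(db, "dot_bracket"))
  unpaired <- is.na(db$partner)
  n <- length(unpaired)
  r <- rle(unpaired)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- data.frame(start = integer(0), end = integer(0),
                    close_i = integer(0), close_j = integer(0))
  for (q in which(r$values)) {
    s <- starts[q]; e <- ends[q]
    if (s > 1L && e < n && !is.na(db$partner[s - 1L]) &&
        db$partner[s - 1L] == e + 1L) {
      out <- rbind(out, data.frame(start = s, end = e,
                                   close_i = s - 1L, close_j = e + 1L))
    }
  }
  out
}

#' Does a hairpin loop contain a uridine?
#'
#' @param loop One row of [hairpin_loops()] output (or a list with `start`
#'   and `end`).
#' @param db The `dot_bracket` object the loop came from.
#' @return `TRUE` iff any residue in `[start, end]` is `U`.
#' @export
loop_contains_uridine <- function(loop, db) {
  stopifnot(inherits(db, "dot_bracket"))
  grepl("U", substr(db$seq, loop$start, loop$end), fixed = TRUE)
}

#' Length-binned structure summary for two classes
#'
#' Splits each class into length bins (17-20, 21-23, 24-27 nt by default) and
#' tabulates, per bin and overall: sequence counts, extended-linear vs
#' stem-loop counts, hairpin-loop counts, and hairpin loops containing at
#' least one uridine. Percentages are half-up rounded to 2 decimals
#' (353/602 -> 58.64).
#'
#' @param pos_structs,neg_structs Lists of `dot_bracket` objects (one class
#'   each), e.g. from [fold_sequences()].
#' @param bins List of `c(min, max)` inclusive length bins.
#' @return Data frame with one row per class x (bin + total): columns
#'   `class`, `bin`, `n_sequences`, `n_linear`, `pct_linear`, `n_stem_loop`,
#'   `pct_stem_loop`, `n_loops`, `n_loops_with_uridine`,
#'   `pct_loops_with_uridine`.
#' @export
summarize_by_length_bins <- function(pos_structs, neg_structs,
                                     bins = list(c(17L, 20L), c(21L, 23L),
                                                 c(24L, 27L))) {
  bin_label <- vapply(bins, function(b) sprintf("%d-%d", b[1L], b[2L]), character(1))
  per_struct <- function(db) {
    loops <- hairpin_loops(db)
    with_u <- if (nrow(loops)) sum(vapply(seq_len(nrow(loops)), function(i)
      loop_contains_uridine(loops[i, ], db), logical(1))) else 0L
    c(len = nchar(db$seq), linear = as.integer(classify_structure(db) == "linear"),
      n_loops = nrow(loops), loops_u = with_u)
  }
  summarise_class <- function(structs, class_name) {
    if (!length(structs)) {
      tab <- matrix(0L, nrow = 0, ncol = 4,
                    dimnames = list(NULL, c("len", "linear", "n_loops", "loops_u")))
    } else {
      tab <- t(vapply(structs, per_struct, numeric(4)))
    }
    which_bin <- function(len) {
      for (q in seq_along(bins)) if (len >= bins[[q]][1L] && len <= bins[[q]][2L]) return(q)
      stop(sprintf("sequence length %d falls outside all bins", len), call. = FALSE)
    }
    bin_of <- if (nrow(tab)) vapply(tab[, "len"], which_bin, integer(1)) else integer(0)
    one <- function(rows, label) {
      n <- length(rows)
      n_lin <- sum(tab[rows, "linear"])
      n_loops <- sum(tab[rows, "n_loops"])
      loops_u <- sum(tab[rows, "loops_u"])
      data.frame(class = class_name, bin = label, n_sequences = n,
                 n_linear = n_lin, pct_linear = percentage(n_lin, n),
                 n_stem_loop = n - n_lin, pct_stem_loop = percentage(n - n_lin, n),
                 n_loops = n_loops, n_loops_with_uridine = loops_u,
                 pct_loops_with_uridine = percentage(loops_u, n_loops))
    }
    rows <- lapply(seq_along(bins), function(q) one(which(bin_of == q), bin_label[q]))
    do.call(rbind, c(rows, list(one(seq_len(nrow(tab)), "total"))))
  }
  out <- rbind(summarise_class(pos_structs, "IMORN"),
               summarise_class(neg_structs, "non-IMORN"))
  rownames(out) <- NULL
  out
}
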