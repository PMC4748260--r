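# Oligonucleotide design utilities built on a fitted classifier: virtual
# screening of libraries, exhaustive single-site analog design,
# immunomodulatory-region scanning of longer RNAs, and per-strand siRNA
# immunotoxicity screening.

class_label <- function(pred) ifelse(pred == 1L, "IMORN", "non-IMORN")

#' All single-site substitution analogs of a sequence
#'
#' Generates every sequence at Hamming distance 1 from the parent: `3 * L`
#' analogs for a length-L sequence, ordered by position (ascending) and
#' substituted nucleotide (A < C < G < U). The parent itself is excluded.
#'
#' @param seq RNA residue string.
#' @return Data frame with columns `position`, `original_nt`,
#'   `substituted_nt`, `analog`.
#' @examples
#' nrow(generate_analogs("AUGCAUGCAUGCAUGCA"))  # 51
#' @export
generate_analogs <- function(seq) {
  seq <- normalize_to_rna(seq)
  L <- nchar(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  rows <- lapply(seq_len(L), function(p) {
    subs <- setdiff(RNA_ALPHABET, chars[p])
    analogs <- vapply(subs, function(nt) {
      s <- seq; substr(s, p, p) <- nt; s
    }, character(1))
    data.frame(position = p, original_nt = chars[p], substituted_nt = subs,
               analog = unname(analogs))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Score and classify all single-site analogs of a sequence
#'
#' Scores every analog from [generate_analogs()] with a fitted classifier,
#' and includes the parent's own record (flagged `is_parent`) for reference.
#'
#' @param seq RNA residue string (length within the model's feature spec).
#' @param fit An [imorn_fit()].
#' @param parent_id Id used in the output (default `"parent"`).
#' @return Data frame with columns `parent_id`, `position`, `original_nt`,
#'   `substituted_nt`, `analog`, `score`, `predicted_class`, `is_parent`
#'   (3L + 1 rows).
#' @export
predict_analogs <- function(seq, fit, parent_id = "parent") {
  seq <- normalize_to_rna(seq)
  an <- generate_analogs(seq)
  seqs <- stats::setNames(c(seq, an$analog),
                          c(parent_id, paste0(parent_id, "_p", an$position, an$substituted_nt)))
  scores <- decision_scores(fit, seqs)
  pred <- classify_at_threshold(scores, fit$threshold)
  data.frame(parent_id = parent_id,
             position = c(NA_integer_, an$position),
             original_nt = c(NA_character_, an$original_nt),
             substituted_nt = c(NA_character_, an$substituted_nt),
             analog = c(seq, an$analog),
             score = unname(scores), predicted_class = class_label(pred),
             is_parent = c(TRUE, rep(FALSE, nrow(an))))
}

#' Scan a long RNA for immunomodulatory regions
#'
#' Slides windows of each requested length along the sequence (step 1) and
#' scores every window with the classifier. Window lengths longer than the
#' sequence are skipped with a message.
#'
#' @param seq RNA residue string.
#' @param fit An [imorn_fit()].
#' @param window_lengths Integer vector of window lengths (default 17:27,
#'   the modelling range).
#' @param parent_id Id used in the output.
#' @return Data frame with columns `parent_id`, `start`, `end` (1-based
#'   inclusive), `window_length`, `subsequence`, `score`, `predicted_class`.
#' @export
scan_regions <- function(seq, fit, window_lengths = 17:27, parent_id = "query") {
  seq <- normalize_to_rna(seq)
  L <- nchar(seq)
  window_lengths <- sort(unique(as.integer(window_lengths)))
  usable <- window_lengths[window_lengths <= L]
  skipped <- setdiff(window_lengths, usable)
  if (length(skipped))
    message(sprintf("skipping window length(s) longer than the sequence (%d nt): %s",
                    L, paste(skipped, collapse = ", ")))
  if (!length(usable))
    stop(sprintf("no requested window fits in a sequence of length %d", L),
         call. = FALSE)
  rows <- lapply(usable, function(w) {
    starts <- seq_len(L - w + 1L)
    data.frame(parent_id = parent_id, start = starts, end = starts + w - 1L,
               window_length = w,
               subsequence = substring(seq, starts, starts + w - 1L))
  })
  out <- do.call(rbind, rows)
  scores <- decision_scores(fit, stats::setNames(out$subsequence, NULL))
  out$score <- unname(scores)
  out$predicted_class <- class_label(classify_at_threshold(scores, fit$threshold))
  rownames(out) <- NULL
  out
}

#' Virtually screen an oligonucleotide library
#'
#' Scores and classifies every sequence of a library and ranks it by
#' decision score (descending), ties broken by id.
#'
#' @param seqs Named character vector of RNA sequences.
#' @param fit An [imorn_fit()].
#' @return Data frame with columns `id`, `score`, `predicted_class`, `rank`
#'   (1 = highest score), sorted by rank.
#' @export
screen_library <- function(seqs, fit) {
  if (is.null(names(seqs))) names(seqs) <- paste0("seq_", seq_along(seqs))
  scores <- decision_scores(fit, seqs)
  pred <- classify_at_threshold(scores, fit$threshold)
  out <- data.frame(id = names(seqs), score = unname(scores),
                    predicted_class = class_label(pred))
  out <- out[order(-out$score, out$id), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Screen siRNA duplexes for immunotoxicity
#'
#' Scores the sense and antisense strand of each duplex independently as
#' single-stranded RNA; a duplex is flagged immunotoxic when either strand is
#' predicted immunomodulatory (the strands are what the endosomal sensors
#' see, so the verdict is symmetric in strand order). The output reserves an
#' `efficacy` column filled by an optional silencing-efficacy scorer.
#'
#' @param sense,antisense Character vectors of equal length (paired strands).
#' @param fit An [imorn_fit()].
#' @param ids Optional duplex ids.
#' @param efficacy_scorer Optional `function(sense, antisense)` returning a
#'   numeric efficacy per duplex; `NULL` leaves the column `NA`.
#' @return Data frame with one row per duplex: `id`, `sense_score`,
#'   `sense_class`, `antisense_score`, `antisense_class`, `immunotoxic`
#'   (logical), `efficacy`.
#' @export
sirna_immunotoxicity <- function(sense, antisense, fit, ids = NULL,
                                 efficacy_scorer = NULL) {
  if (length(sense) != length(antisense))
    stop("sense and antisense must have equal length", call. = FALSE)
  ids <- ids %||% paste0("duplex_", seq_along(sense))
  s_scores <- decision_scores(fit, stats::setNames(as.character(sense), NULL))
  a_scores <- decision_scores(fit, stats::setNames(as.character(antisense), NULL))
  s_pred <- classify_at_threshold(s_scores, fit$threshold)
  a_pred <- classify_at_threshold(a_scores, fit$threshold)
  eff <- if (is.null(efficacy_scorer)) rep(NA_real_, length(sense))
         else as.numeric(efficacy_scorer(sense, antisense))
  data.frame(id = ids,
             sense_score = unname(s_scores), sense_class = class_label(s_pred),
             antisense_score = unname(a_scores), antisense_class = class_label(a_pred),
             immunotoxic = s_pred == 1L | a_pred == 1L,
             efficacy = eff)
}
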