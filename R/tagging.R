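# IOB2 encoding: every entity-initial token gets B-<cat>, the remaining
# tokens of the entity I-<cat>, everything else O. Label order is fixed:
# O first, then B-/I- pairs in category order NANO, EXPO, TOXIC, TARGET.

#' Canonical BIO label set
#'
#' @return Character vector of the 9 labels in canonical order: `O`,
#'   then `B-`/`I-` pairs for NANO, EXPO, TOXIC, TARGET.
#' @export
#' @examples
#' bio_labels()
bio_labels <- function() {
  c("O", as.vector(rbind(paste0("B-", NANO_CATEGORIES),
                         paste0("I-", NANO_CATEGORIES))))
}

#' Construct a labeled token sequence
#'
#' The conditional random field's native view of a sentence: tokens plus a
#' per-token BIO tag.
#'
#' @param tokens Token data frame (as from [tokenize()]).
#' @param tags Character vector of BIO tags, one per token.
#' @param text The underlying sentence string.
#' @return An object of class `nano_sequence`.
#' @export
labeled_sequence <- function(tokens, tags, text) {
  stopifnot(nrow(tokens) == length(tags), all(tags %in% bio_labels()))
  structure(list(tokens = tokens, tags = as.character(tags), text = text),
            class = "nano_sequence")
}

#' Encode entity spans as a BIO tag sequence
#'
#' @param sentence A `nano_sentence`.
#' @return A [labeled_sequence()]: the first token of each entity is tagged
#'   `B-<category>`, remaining entity tokens `I-<category>`, all others `O`.
#' @export
#' @examples
#' spans_to_bio(parse_annotated("<NANO>titanium dioxide particles</NANO>"))$tags
spans_to_bio <- function(sentence) {
  stopifnot(inherits(sentence, "nano_sentence"))
  tags <- rep("O", nrow(sentence$tokens))
  ents <- sentence$entities
  for (i in seq_len(nrow(ents))) {
    rng <- (ents$tok_start[i] + 1L):ents$tok_end[i]
    if (any(tags[rng] != "O")) compute_error("overlapping entity spans")
    tags[rng[1]] <- paste0("B-", ents$category[i])
    if (length(rng) > 1L) tags[rng[-1]] <- paste0("I-", ents$category[i])
  }
  labeled_sequence(sentence$tokens, tags, sentence$text)
}

#' Decode a BIO tag sequence to entity spans
#'
#' Accepts possibly ill-formed decoder output: an `I-X` not preceded by
#' `B-X`/`I-X` (an orphan) is repaired as `B-X`, so every non-`O` token ends
#' up inside exactly one span. On well-formed sequences this is the exact
#' inverse of [spans_to_bio()].
#'
#' @param seq A `nano_sequence` (tags need not be well-formed).
#' @return A `nano_sentence` with the decoded entities.
#' @export
bio_to_spans <- function(seq) {
  stopifnot(inherits(seq, "nano_sequence"))
  tags <- seq$tags
  ents <- list()
  open_cat <- NULL
  open_start <- NA_integer_
  close_open <- function(end_idx) {
    if (!is.null(open_cat)) {
      ents[[length(ents) + 1L]] <<- data.frame(
        category = open_cat, tok_start = open_start, tok_end = end_idx,
        stringsAsFactors = FALSE)
    }
    open_cat <<- NULL
  }
  for (t in seq_along(tags)) {
    tag <- tags[t]
    if (tag == "O") {
      close_open(t - 1L)
    } else {
      kind <- substr(tag, 1L, 1L)
      cat_name <- substr(tag, 3L, nchar(tag))
      if (kind == "B" || is.null(open_cat) || cat_name != open_cat) {
        close_open(t - 1L)           # orphan I-X starts a new span
        open_cat <- cat_name
        open_start <- t - 1L
      }
    }
  }
  close_open(length(tags))
  annotated_sentence(seq$text, do.call(rbind, ents))
}

#' Export / import a corpus in two-column CoNLL form
#'
#' One `token<TAB>tag` line per token, a blank line between sentences.
#' Reading joins tokens with single spaces, so round trips preserve tokens
#' and tags but not the original inter-token spacing.
#'
#' @param corpus A `nano_corpus`.
#' @param path File path.
#' @export
write_conll <- function(corpus, path) {
  stopifnot(inherits(corpus, "nano_corpus"))
  blocks <- vapply(corpus, function(s) {
    b <- spans_to_bio(s)
    paste(paste(b$tokens$text, b$tags, sep = "\t"), collapse = "\n")
  }, character(1))
  writeLines(paste(blocks, collapse = "\n\n"), path)
  invisible(path)
}

#' @rdname write_conll
#' @export
read_conll <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  groups <- split(lines, cumsum(lines == ""))
  groups <- lapply(groups, function(g) g[g != ""])
  groups <- groups[vapply(groups, length, integer(1)) > 0L]
  as_corpus(lapply(groups, function(g) {
    parts <- strsplit(g, "\t", fixed = TRUE)
    toks <- vapply(parts, `[`, character(1), 1L)
    tags <- vapply(parts, `[`, character(1), 2L)
    text <- paste(toks, collapse = " ")
    bio_to_spans(labeled_sequence(tokenize(text), tags, text))
  }))
}
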