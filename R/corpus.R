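# Annotated-corpus format: one sentence per line, entities enclosed in
# inline tags <NANO>...</NANO>, <EXPO>...</EXPO>, <TOXIC>...</TOXIC>,
# <TARGET>...</TARGET>. Tags never split tokens. Offsets are 0-based,
# half-open, for both characters and tokens.

# Token pattern, one regular-expression pass:
#   1. chemical formulas: letter+digit runs, e.g. TiO2, C60, Fe3O4
#   2. maximal runs of word characters
#   3. any other non-space character as a single token (hyphens split words)
TOKEN_PATTERN <- "(?:\\p{L}+\\p{N}+)+\\p{L}*|[\\p{L}\\p{N}_]+|[^\\p{L}\\p{N}_\\s]"

#' Tokenize a sentence
#'
#' Splits on whitespace and punctuation while keeping chemical formulas
#' (letter runs immediately followed by digits, possibly repeated: `TiO2`,
#' `C60`, `Fe3O4`) as single tokens. Hyphenated words are split, with the
#' hyphen kept as its own token. Concatenating the token texts with the
#' original gaps reconstructs the input exactly.
#'
#' @param text A single sentence (character scalar, any Unicode).
#' @return A data frame with one row per token and columns `text`, `start`,
#'   `end` (0-based half-open character offsets into `text`). Empty or
#'   whitespace-only input yields zero rows.
#' @export
#' @examples
#' tokenize("TiO2 induced apoptosis.")$text
tokenize <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  m <- gregexpr(TOKEN_PATTERN, text, perl = TRUE)[[1]]
  if (m[1] == -1L) {
    return(data.frame(text = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  }
  start <- as.integer(m) - 1L
  end <- start + attr(m, "match.length")
  data.frame(text = substring(text, start + 1L, end),
             start = start, end = end, stringsAsFactors = FALSE)
}

#' Construct an annotated sentence
#'
#' The gold-standard unit: a sentence string, its tokenization, and a set of
#' non-overlapping, non-nested entity spans given as half-open token ranges.
#'
#' @param text Sentence string (no inline tags).
#' @param entities Data frame with columns `category` (one of
#'   [entity_categories()]), `tok_start`, `tok_end` (0-based half-open token
#'   indices). May be `NULL` or empty for an unannotated sentence.
#' @return An object of class `nano_sentence`: a list with elements `text`,
#'   `tokens` (as from [tokenize()]) and `entities` (with a derived
#'   `surface` column, the whitespace-joined covered tokens), entities
#'   sorted by `tok_start`.
#' @export
annotated_sentence <- function(text, entities = NULL) {
  tokens <- tokenize(text)
  if (is.null(entities) || NROW(entities) == 0L) {
    entities <- data.frame(category = character(0), tok_start = integer(0),
                           tok_end = integer(0), surface = character(0),
                           stringsAsFactors = FALSE)
  } else {
    entities <- data.frame(category = as.character(entities$category),
                           tok_start = as.integer(entities$tok_start),
                           tok_end = as.integer(entities$tok_end),
                           stringsAsFactors = FALSE)
    entities <- entities[order(entities$tok_start), , drop = FALSE]
    rownames(entities) <- NULL
    bad <- !entities$category %in% NANO_CATEGORIES
    if (any(bad)) {
      format_error(sprintf("unknown entity category '%s'",
                           entities$category[which(bad)[1]]))
    }
    if (any(entities$tok_start >= entities$tok_end) ||
        any(entities$tok_start < 0L) ||
        any(entities$tok_end > nrow(tokens))) {
      format_error("entity token range out of bounds or empty")
    }
    if (nrow(entities) > 1L &&
        any(entities$tok_start[-1L] < entities$tok_end[-nrow(entities)])) {
      format_error("overlapping or nested entity spans")
    }
    entities$surface <- vapply(seq_len(nrow(entities)), function(i) {
      paste(tokens$text[(entities$tok_start[i] + 1L):entities$tok_end[i]],
            collapse = " ")
    }, character(1))
  }
  structure(list(text = text, tokens = tokens, entities = entities),
            class = "nano_sentence")
}

#' @export
print.nano_sentence <- function(x, ...) {
  cat(serialize_annotated(x), "\n", sep = "")
  invisible(x)
}

TAG_PATTERN <- "</?([A-Za-z]+)>"

#' Parse one annotated line
#'
#' Reads a sentence in the inline-tag dialect: each entity is enclosed
#' between an opening and a closing tag naming its category, e.g.
#' `<NANO>titanium dioxide particles</NANO>`. Tags must be balanced,
#' non-nested, name a known category, and must not split tokens.
#'
#' @param line Annotated sentence (character scalar).
#' @param line_number Optional line number used in error messages.
#' @return A [annotated_sentence()] whose `text` is the line with tags
#'   stripped.
#' @export
#' @examples
#' s <- parse_annotated("<NANO>TiO2</NANO> induced <TOXIC>apoptosis</TOXIC> .")
#' s$entities
parse_annotated <- function(line, line_number = NULL) {
  stopifnot(is.character(line), length(line) == 1L, !is.na(line))
  m <- gregexpr(TAG_PATTERN, line, perl = TRUE)[[1]]
  if (m[1] == -1L) {
    return(annotated_sentence(line))
  }
  tag_start <- as.integer(m)
  tag_len <- attr(m, "match.length")
  text <- ""
  cursor <- 1L                       # 1-based position in `line`
  open_cat <- NULL
  open_at <- NA_integer_             # char offset in stripped text
  ents <- list()
  for (k in seq_along(tag_start)) {
    text <- paste0(text, substr(line, cursor, tag_start[k] - 1L))
    tag <- substr(line, tag_start[k], tag_start[k] + tag_len[k] - 1L)
    closing <- substr(tag, 2L, 2L) == "/"
    cat_name <- gsub("[</>]", "", tag)
    if (!cat_name %in% NANO_CATEGORIES) {
      format_error(sprintf("unknown category tag '%s'", tag),
                   line = line_number, offset = tag_start[k])
    }
    if (closing) {
      if (is.null(open_cat)) {
        format_error(sprintf("closing tag '%s' without opening tag", tag),
                     line = line_number, offset = tag_start[k])
      }
      if (cat_name != open_cat) {
        format_error(sprintf("closing tag '%s' does not match open <%s>",
                             tag, open_cat),
                     line = line_number, offset = tag_start[k])
      }
      if (nchar(text) == open_at) {
        format_error(sprintf("empty <%s> annotation", open_cat),
                     line = line_number, offset = tag_start[k])
      }
      ents[[length(ents) + 1L]] <- list(category = open_cat,
                                        char_start = open_at,
                                        char_end = nchar(text))
      open_cat <- NULL
    } else {
      if (!is.null(open_cat)) {
        format_error(sprintf("nested tag '%s' inside <%s>", tag, open_cat),
                     line = line_number, offset = tag_start[k])
      }
      open_cat <- cat_name
      open_at <- nchar(text)
    }
    cursor <- tag_start[k] + tag_len[k]
  }
  if (!is.null(open_cat)) {
    format_error(sprintf("unclosed tag <%s>", open_cat), line = line_number)
  }
  text <- paste0(text, substr(line, cursor, nchar(line)))
  tokens <- tokenize(text)
  entities <- do.call(rbind, lapply(ents, function(e) {
    inside <- which(tokens$start >= e$char_start & tokens$end <= e$char_end)
    straddle <- which((tokens$start < e$char_start & tokens$end > e$char_start) |
                      (tokens$start < e$char_end & tokens$end > e$char_end))
    if (length(straddle) > 0L) {
      format_error(sprintf("<%s> tag splits token '%s'", e$category,
                           tokens$text[straddle[1]]), line = line_number)
    }
    if (length(inside) == 0L) {
      format_error(sprintf("<%s> annotation covers no token", e$category),
                   line = line_number)
    }
    data.frame(category = e$category, tok_start = inside[1] - 1L,
               tok_end = inside[length(inside)], stringsAsFactors = FALSE)
  }))
  annotated_sentence(text, entities)
}

#' Serialize an annotated sentence to one line
#'
#' Inverse of [parse_annotated()]: inserts the inline category tags around
#' each entity's token character range, leaving the rest of the sentence
#' byte-identical.
#'
#' @param sentence A `nano_sentence`.
#' @return A single annotated line; `parse_annotated(serialize_annotated(s))`
#'   reproduces `s`.
#' @export
serialize_annotated <- function(sentence) {
  stopifnot(inherits(sentence, "nano_sentence"))
  text <- sentence$text
  ents <- sentence$entities
  if (nrow(ents) == 0L) return(text)
  out <- ""
  cursor <- 0L                       # 0-based char position consumed
  for (i in seq_len(nrow(ents))) {
    cs <- sentence$tokens$start[ents$tok_start[i] + 1L]
    ce <- sentence$tokens$end[ents$tok_end[i]]
    out <- paste0(out, substr(text, cursor + 1L, cs),
                  "<", ents$category[i], ">",
                  substr(text, cs + 1L, ce),
                  "</", ents$category[i], ">")
    cursor <- ce
  }
  paste0(out, substr(text, cursor + 1L, nchar(text)))
}

#' Build a corpus from a list of sentences
#'
#' @param sentences List of `nano_sentence` objects.
#' @return An object of class `nano_corpus` (a list of sentences).
#' @export
as_corpus <- function(sentences) {
  stopifnot(is.list(sentences),
            all(vapply(sentences, inherits, logical(1), "nano_sentence")))
  structure(sentences, class = "nano_corpus")
}

#' @export
`[.nano_corpus` <- function(x, i) as_corpus(unclass(x)[i])

#' @export
print.nano_corpus <- function(x, n = 5L, ...) {
  cat(sprintf("<nano_corpus> %d sentences, %d entities\n", length(x),
              sum(vapply(x, function(s) nrow(s$entities), integer(1)))))
  for (s in head(x, n)) cat("  ", serialize_annotated(s), "\n", sep = "")
  if (length(x) > n) cat(sprintf("  ... and %d more\n", length(x) - n))
  invisible(x)
}

#' Read / write an annotated corpus file
#'
#' Corpus files are UTF-8 text with one annotated sentence per line in the
#' inline-tag dialect; line i becomes sentence i. Reading then writing a
#' canonical file is the identity.
#'
#' @param path File path.
#' @return `read_corpus()` returns a `nano_corpus`; a malformed line raises
#'   an error naming the line and offset.
#' @export
read_corpus <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  as_corpus(lapply(seq_along(lines), function(i) {
    parse_annotated(lines[i], line_number = i)
  }))
}

#' @param corpus A `nano_corpus` to write.
#' @rdname read_corpus
#' @export
write_corpus <- function(corpus, path) {
  stopifnot(inherits(corpus, "nano_corpus"))
  writeLines(vapply(corpus, serialize_annotated, character(1)), path,
             useBytes = FALSE)
  invisible(path)
}
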