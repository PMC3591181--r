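# Hybrid dictionary + TF-IDF baseline annotator.
#
# Candidate terms are all single tokens (stop words excluded) plus n-grams
# of sizes 2..6 occurring in the corpus. Each term is scored by TF-IDF with
# one corpus sentence playing the role of a document: tf is the occurrence
# count in the document where the term is most frequent, idf = ln(N / df)
# with no smoothing. Terms scoring below the threshold (default 0.1) are
# discarded; the survivors are matched exactly (after normalization)
# against a NANO lexicon and a TARGET lexicon. The baseline never emits
# EXPO or TOXIC entities: no controlled vocabulary covers those categories.

#' Bundled English stop-word list
#'
#' The fixed list used when building baseline candidate terms; shipped as
#' `inst/extdata/stopwords_en.txt`.
#'
#' @return Character vector of stop words.
#' @export
stopwords_en <- function() {
  readLines(system.file("extdata", "stopwords_en.txt", package = "nanoner"),
            warn = FALSE)
}

#' Normalize a term for dictionary matching
#'
#' Lowercases, strips surrounding punctuation from each token, and
#' collapses whitespace to single spaces. Matching is exact on the
#' normalized strings; no stemming.
#'
#' @param x Character vector of terms.
#' @return Normalized character vector (may contain `""` for
#'   punctuation-only input).
#' @export
normalize_term <- function(x) {
  x <- tolower(x)
  x <- gsub("^[[:punct:]]+|[[:punct:]]+$", "", x)
  x <- gsub("\\s+", " ", x)
  trimws(x)
}

#' Contiguous token n-grams
#'
#' All windows of `nmin..nmax` consecutive tokens, lowercased and joined
#' with single spaces, in order of size then position.
#'
#' @param tokens Token data frame from [tokenize()] or character vector.
#' @param nmin,nmax Window size range (defaults 2 and 6).
#' @return Character vector of n-gram surfaces (empty when the sentence is
#'   shorter than `nmin`).
#' @export
#' @examples
#' extract_ngrams(tokenize("Gold nanoparticles have the potential to"), 2, 2)
extract_ngrams <- function(tokens, nmin = 2L, nmax = 6L) {
  stopifnot(nmin >= 1L, nmin <= nmax)
  words <- if (is.data.frame(tokens)) tokens$text else as.character(tokens)
  words <- tolower(words)
  out <- character(0)
  for (n in nmin:nmax) {
    if (length(words) < n) break
    idx <- seq_len(length(words) - n + 1L)
    out <- c(out, vapply(idx, function(i) {
      paste(words[i:(i + n - 1L)], collapse = " ")
    }, character(1)))
  }
  out
}

# Normalized token vector of a sentence (punctuation-only tokens -> "").
norm_tokens <- function(sentence) normalize_term(sentence$tokens$text)

# Occurrence count of a normalized term (n tokens) in one sentence.
count_occurrences <- function(nt, term_tokens) {
  n <- length(term_tokens)
  if (length(nt) < n) return(0L)
  hits <- 0L
  for (i in seq_len(length(nt) - n + 1L)) {
    if (all(nt[i:(i + n - 1L)] == term_tokens)) hits <- hits + 1L
  }
  hits
}

#' TF-IDF score of a term over a sentence corpus
#'
#' Each sentence is a document. `tf` is the term's occurrence count in the
#' document containing it most often; `idf = ln(N / df)` where `N` is the
#' number of documents and `df` the number containing the term; the score
#' is `tf * idf`. A term absent from the corpus (or present in every
#' document) scores 0.
#'
#' @param term Term string (normalized with [normalize_term()]).
#' @param corpus A nonempty `nano_corpus`.
#' @return A single non-negative number.
#' @export
tfidf_score <- function(term, corpus) {
  stopifnot(inherits(corpus, "nano_corpus"), length(corpus) > 0L)
  term_tokens <- strsplit(normalize_term(term), " ", fixed = TRUE)[[1]]
  if (length(term_tokens) == 0L) return(0)
  counts <- vapply(corpus, function(s) {
    count_occurrences(norm_tokens(s), term_tokens)
  }, integer(1))
  df <- sum(counts > 0L)
  if (df == 0L) return(0)
  max(counts) * log(length(corpus) / df)
}

#' Build the scored candidate-term dictionary
#'
#' Candidates are all single tokens excluding stop words, plus n-grams of
#' sizes `nmin..nmax`; each unique candidate is TF-IDF scored over the
#' corpus.
#'
#' @param corpus A nonempty `nano_corpus`.
#' @param nmin,nmax n-gram size range (defaults 2 and 6).
#' @param stopwords Stop-word list used to exclude single-token candidates
#'   (n-grams may still contain stop words internally).
#' @return Data frame with columns `term` (normalized surface), `n` (token
#'   length) and `score`.
#' @export
build_tfidf_dictionary <- function(corpus, nmin = 2L, nmax = 6L,
                                   stopwords = stopwords_en()) {
  stopifnot(inherits(corpus, "nano_corpus"), length(corpus) > 0L)
  per_doc <- lapply(corpus, function(s) {
    nt <- norm_tokens(s)
    uni <- nt[nzchar(nt) & !nt %in% stopwords]
    grams <- character(0)
    for (n in nmin:nmax) {
      if (length(nt) < n) break
      idx <- seq_len(length(nt) - n + 1L)
      win <- vapply(idx, function(i) {
        paste(nt[i:(i + n - 1L)], collapse = " ")
      }, character(1))
      # windows touching punctuation-only tokens cannot match a dictionary
      keep <- vapply(idx, function(i) all(nzchar(nt[i:(i + n - 1L)])),
                     logical(1))
      grams <- c(grams, win[keep])
    }
    table(c(uni, grams))
  })
  term <- unlist(lapply(per_doc, names), use.names = FALSE)
  count <- unlist(lapply(per_doc, as.integer), use.names = FALSE)
  if (length(term) == 0L) {
    return(data.frame(term = character(0), n = integer(0),
                      score = numeric(0), stringsAsFactors = FALSE))
  }
  tf <- tapply(count, term, max)
  df <- tapply(count, term, length)
  terms <- names(tf)
  score <- as.numeric(tf) * log(length(corpus) / as.numeric(df))
  data.frame(term = terms,
             n = lengths(strsplit(terms, " ", fixed = TRUE)),
             score = score, stringsAsFactors = FALSE, row.names = NULL)
}

#' Filter and rank candidate terms by TF-IDF score
#'
#' Keeps candidates whose score is at least `threshold` (default 0.1, i.e.
#' scores smaller than 0.1 are discarded) and sorts them in descending
#' score order.
#'
#' @param candidates Data frame as from [build_tfidf_dictionary()].
#' @param threshold Minimum retained score.
#' @return The filtered, score-sorted data frame.
#' @export
select_terms <- function(candidates, threshold = 0.1) {
  keep <- candidates[candidates$score >= threshold, , drop = FALSE]
  keep <- keep[order(-keep$score, keep$term), , drop = FALSE]
  rownames(keep) <- NULL
  keep
}

#' Read a lexicon file
#'
#' UTF-8 text, one term per line, `#` starts a comment; terms are
#' normalized with [normalize_term()].
#'
#' @param path File path.
#' @param category The category the lexicon stands for (`"NANO"` or
#'   `"TARGET"` for the baseline).
#' @return An object of class `nano_lexicon`: list with `name`, `category`
#'   and the normalized `terms` set.
#' @export
read_lexicon <- function(path, category) {
  stopifnot(category %in% NANO_CATEGORIES)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- sub("#.*$", "", lines)
  terms <- unique(normalize_term(lines[nzchar(trimws(lines))]))
  terms <- terms[nzchar(terms)]
  if (length(terms) == 0L) {
    config_error(sprintf("lexicon '%s' is empty", path))
  }
  structure(list(name = basename(path), category = category, terms = terms),
            class = "nano_lexicon")
}

#' Construct a lexicon from a character vector
#'
#' @param terms Character vector of terms (normalized internally).
#' @param category Entity category the lexicon labels.
#' @param name Optional lexicon name.
#' @return A `nano_lexicon`.
#' @export
lexicon <- function(terms, category, name = category) {
  stopifnot(category %in% NANO_CATEGORIES)
  terms <- unique(normalize_term(terms))
  terms <- terms[nzchar(terms)]
  if (length(terms) == 0L) config_error("lexicon has no usable terms")
  structure(list(name = name, category = category, terms = terms),
            class = "nano_lexicon")
}

#' Dictionary + TF-IDF baseline annotator
#'
#' Builds the TF-IDF dictionary over the corpus, keeps terms scoring at
#' least `threshold`, and marks every occurrence of a surviving term that
#' exactly matches a lexicon entry as an entity of that lexicon's category.
#' Overlaps are resolved longest-match-first, then leftmost; when a term is
#' in both lexicons the NANO lexicon wins. Only NANO and TARGET entities
#' are ever emitted.
#'
#' @param corpus A `nano_corpus` (its annotations are ignored; only the
#'   text is used).
#' @param nano_lex,target_lex `nano_lexicon` objects for the NANO and
#'   TARGET categories.
#' @param threshold TF-IDF cutoff (default 0.1).
#' @param nmin,nmax n-gram size range for candidate terms.
#' @return A `nano_corpus` of the same sentences re-annotated by the
#'   baseline.
#' @export
baseline_annotate <- function(corpus, nano_lex, target_lex, threshold = 0.1,
                              nmin = 2L, nmax = 6L) {
  stopifnot(inherits(corpus, "nano_corpus"),
            inherits(nano_lex, "nano_lexicon"),
            inherits(target_lex, "nano_lexicon"))
  if (length(nano_lex$terms) == 0L || length(target_lex$terms) == 0L) {
    config_error("baseline lexicons must be nonempty")
  }
  dict <- select_terms(build_tfidf_dictionary(corpus, nmin, nmax), threshold)
  selected <- dict$term
  max_len <- max(nmax, 1L)
  as_corpus(lapply(corpus, function(s) {
    nt <- norm_tokens(s)
    claimed <- rep(FALSE, length(nt))
    ents <- list()
    for (n in seq.int(max_len, 1L)) {
      if (length(nt) < n) next
      for (i in seq_len(length(nt) - n + 1L)) {
        rng <- i:(i + n - 1L)
        if (any(claimed[rng]) || !all(nzchar(nt[rng]))) next
        surface <- paste(nt[rng], collapse = " ")
        if (!surface %in% selected) next
        category <- if (surface %in% nano_lex$terms) {
          "NANO"
        } else if (surface %in% target_lex$terms) {
          "TARGET"
        } else {
          next
        }
        claimed[rng] <- TRUE
        ents[[length(ents) + 1L]] <- data.frame(
          category = category, tok_start = i - 1L, tok_end = i + n - 1L,
          stringsAsFactors = FALSE)
      }
    }
    annotated_sentence(s$text, do.call(rbind, ents))
  }))
}
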