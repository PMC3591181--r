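# Per-position binary features: word identity, word shape, affixes,
# orthographic predicates, and the neighbors' word/shape within a window.
# The inventory is fixed and closed so feature spaces are reproducible.

GREEK_LETTERS <- c("alpha", "beta", "gamma", "delta", "epsilon", "zeta",
                   "eta", "theta", "iota", "kappa", "lambda", "mu", "nu",
                   "xi", "omicron", "pi", "rho", "sigma", "tau", "upsilon",
                   "phi", "chi", "psi", "omega")

ORTHO_PREDICATES <- list(
  INITCAPS     = function(w) grepl("^[A-Z]", w),
  ALLCAPS      = function(w) grepl("^[A-Z]+$", w),
  CAPSMIX      = function(w) grepl("[A-Z]", w) && grepl("[a-z]", w),
  HASDIGIT     = function(w) grepl("[0-9]", w),
  ALLDIGITS    = function(w) grepl("^[0-9]+$", w),
  ALPHANUMERIC = function(w) grepl("[A-Za-z]", w) && grepl("[0-9]", w),
  HASDASH      = function(w) grepl("-", w, fixed = TRUE),
  PUNCTUATION  = function(w) grepl("^[[:punct:]]+$", w),
  GREEKLETTER  = function(w) tolower(w) %in% GREEK_LETTERS,
  ROMANNUMERAL = function(w) grepl("^[IVXLCDM]+$", w),
  CHEMFORMULA  = function(w) grepl("^(?:[A-Za-z]+[0-9]+)+[A-Za-z]*$", w)
)

#' Feature extraction configuration
#'
#' @param window Non-negative integer: neighbor word/shape features are
#'   added for offsets -window..+window (0 = no context features).
#' @param affix_lengths Integer vector of character prefix/suffix lengths.
#' @param predicates Character vector of enabled orthographic predicate
#'   names (subset of the built-in inventory).
#' @return An object of class `nano_featcfg`.
#' @export
feature_config <- function(window = 1L, affix_lengths = c(1L, 2L, 3L),
                           predicates = names(ORTHO_PREDICATES)) {
  window <- as.integer(window)
  affix_lengths <- as.integer(affix_lengths)
  if (is.na(window) || window < 0L) config_error("window must be >= 0")
  if (length(affix_lengths) > 0L && any(affix_lengths < 1L)) {
    config_error("affix lengths must be >= 1")
  }
  unknown <- setdiff(predicates, names(ORTHO_PREDICATES))
  if (length(unknown) > 0L) {
    config_error(paste("unknown orthographic predicate:",
                       paste(unknown, collapse = ", ")))
  }
  structure(list(window = window, affix_lengths = affix_lengths,
                 predicates = predicates), class = "nano_featcfg")
}

# Word shape: uppercase -> X, lowercase -> x, digit -> 0, other characters
# kept; adjacent identical shape characters collapsed ("IL" -> "X").
word_shape <- function(w) {
  s <- gsub("[A-Z]", "X", w)
  s <- gsub("[a-z]", "x", s)
  s <- gsub("[0-9]", "0", s)
  gsub("(.)\\1+", "\\1", s)
}

token_local_features <- function(w, cfg) {
  feats <- c("BIAS", paste0("W=", tolower(w)), paste0("SHAPE=", word_shape(w)))
  for (k in cfg$affix_lengths) {
    if (nchar(w) >= k) {
      feats <- c(feats,
                 paste0("P", k, "=", tolower(substr(w, 1L, k))),
                 paste0("S", k, "=", tolower(substr(w, nchar(w) - k + 1L,
                                                    nchar(w)))))
    }
  }
  fired <- vapply(cfg$predicates, function(p) ORTHO_PREDICATES[[p]](w),
                  logical(1))
  c(feats, cfg$predicates[fired])
}

#' Extract features at one token position
#'
#' Returns the binary feature set for position `i`: word identity
#' (lowercased), collapsed word shape, character prefixes/suffixes,
#' orthographic predicates (INITCAPS, ALLCAPS, CAPSMIX, HASDIGIT,
#' ALLDIGITS, ALPHANUMERIC, HASDASH, PUNCTUATION, GREEKLETTER,
#' ROMANNUMERAL, CHEMFORMULA), neighbor word/shape features at offsets up
#' to `cfg$window` (prefixed with the signed offset), and a constant bias.
#' Deterministic in (tokens, i, cfg) and local to the window.
#'
#' @param tokens Token data frame from [tokenize()], or a character vector
#'   of token texts.
#' @param i Position, 1-based.
#' @param cfg A [feature_config()].
#' @return Character vector of feature names (a set: no duplicates).
#' @export
#' @examples
#' extract_features(tokenize("TiO2 induced apoptosis ."), 1)
extract_features <- function(tokens, i, cfg = feature_config()) {
  words <- if (is.data.frame(tokens)) tokens$text else as.character(tokens)
  if (length(i) != 1L || is.na(i) || i < 1L || i > length(words)) {
    compute_error(sprintf("feature position %s out of range 1..%d",
                          toString(i), length(words)))
  }
  feats <- token_local_features(words[i], cfg)
  if (cfg$window > 0L) {
    for (o in setdiff(seq.int(-cfg$window, cfg$window), 0L)) {
      j <- i + o
      if (j >= 1L && j <= length(words)) {
        feats <- c(feats,
                   paste0("W@", o, "=", tolower(words[j])),
                   paste0("SHAPE@", o, "=", word_shape(words[j])))
      }
    }
  }
  unique(feats)
}

# Feature sets for every position of a sentence.
sentence_features <- function(tokens, cfg = feature_config()) {
  n <- if (is.data.frame(tokens)) nrow(tokens) else length(tokens)
  lapply(seq_len(n), function(i) extract_features(tokens, i, cfg))
}

#' Read / write a feature configuration file
#'
#' Plain `key = value` text with keys `window`, `affix_lengths`
#' (comma-separated) and `predicates` (comma-separated).
#'
#' @param cfg A [feature_config()].
#' @param path File path.
#' @export
write_feature_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "nano_featcfg"))
  writeLines(c(paste("window =", cfg$window),
               paste("affix_lengths =", paste(cfg$affix_lengths,
                                              collapse = ",")),
               paste("predicates =", paste(cfg$predicates, collapse = ","))),
             path)
  invisible(path)
}

#' @rdname write_feature_config
#' @export
read_feature_config <- function(path) {
  lines <- grep("=", readLines(path, warn = FALSE), fixed = TRUE,
                value = TRUE)
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, character(1), 1L))
  vals <- trimws(vapply(kv, function(x) paste(x[-1], collapse = "="),
                        character(1)))
  get <- function(key, default) if (key %in% keys) vals[match(key, keys)] else default
  split_csv <- function(x) trimws(strsplit(x, ",", fixed = TRUE)[[1]])
  feature_config(
    window = as.integer(get("window", "1")),
    affix_lengths = as.integer(split_csv(get("affix_lengths", "1,2,3"))),
    predicates = split_csv(get("predicates",
                               paste(names(ORTHO_PREDICATES),
                                     collapse = ","))))
}
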