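# Seeded generator of annotated corpora with the statistical shape of the
# 300-sentence nanotoxicology gold standard: ~4.8 entities per sentence,
# category proportions NANO:EXPO:TOXIC:TARGET = 426:144:485:385, and mean
# tokens per entity (1.68, 1.29, 1.31, 1.83). Sentences come from a small
# template grammar whose entity slots are filled from bundled per-category
# term lists (disjoint across categories by construction); 10% of sentences
# are entity-free distractors so the model has to learn O.

# Sentence frames; {E} marks an entity slot whose category is drawn from
# the configured weights.
SENTENCE_TEMPLATES <- c(
  "Delivery of {E} by {E} induced {E} and {E} in the {E} of {E} .",
  "{E} administered via {E} caused {E} in {E} and {E} .",
  "Treatment with {E} and {E} resulted in {E} and {E} in treated {E} .",
  "Following {E} , {E} produced marked {E} in the {E} and {E} of {E} .",
  "{E} induced {E} and {E} in {E} after {E} .",
  "The effects of {E} on {E} and {E} were assessed after {E} .",
  "{E} delivered by {E} led to {E} , {E} and {E} in {E} .",
  "Studies show that {E} and {E} trigger {E} in the {E} of treated {E} .",
  "After {E} of {E} , significant {E} was observed in {E} .",
  "{E} uptake following {E} elicited {E} and {E} in {E} and {E} ."
)

DISTRACTOR_TEMPLATES <- c(
  "The experimental protocol was approved by the institutional committee .",
  "Samples were collected at regular intervals during the study period .",
  "Statistical analysis was performed using standard methods .",
  "The results were consistent across all replicate experiments .",
  "Further research is needed to confirm these preliminary findings .",
  "All measurements were carried out in triplicate under controlled conditions ."
)

DISTRACTOR_FRACTION <- 0.1

read_gen_lexicons <- function() {
  files <- c(NANO = "gen_nano.txt", EXPO = "gen_expo.txt",
             TOXIC = "gen_toxic.txt", TARGET = "gen_target.txt")
  lapply(files, function(f) {
    path <- system.file("extdata", f, package = "nanoner")
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- trimws(sub("#.*$", "", lines))
    lines[nzchar(lines)]
  })
}

#' Synthetic-corpus generator configuration
#'
#' The defaults reproduce the shape of the 300-sentence gold standard:
#' category entity weights proportional to `(426, 144, 485, 385)` (which
#' normalize to about 0.296, 0.100, 0.337, 0.267) and mean tokens per
#' entity `(717/426, 186/144, 637/485, 705/385)`, i.e. about
#' `(1.68, 1.29, 1.31, 1.83)`.
#'
#' @param n_sentences Number of sentences (default 300).
#' @param category_weights Non-negative relative entity frequencies, in
#'   NANO, EXPO, TOXIC, TARGET order (normalized internally).
#' @param mean_entity_tokens Mean tokens per entity per category; entity
#'   lengths are drawn as `1 + Poisson(mean - 1)` truncated to the lengths
#'   available in the lexicon.
#' @param label_noise Fraction in `[0, 1)` of entities silently dropped
#'   from the annotations (the text keeps the term), simulating imperfect
#'   gold annotation.
#' @param seed Generator seed (default 42).
#' @param lexicons Named list (NANO, EXPO, TOXIC, TARGET) of term vectors;
#'   defaults to the bundled lists, which are disjoint across categories.
#' @return An object of class `nano_gencfg`.
#' @export
generator_config <- function(n_sentences = 300L,
                             category_weights = c(426, 144, 485, 385),
                             mean_entity_tokens = c(717 / 426, 186 / 144,
                                                    637 / 485, 705 / 385),
                             label_noise = 0,
                             seed = 42L,
                             lexicons = read_gen_lexicons()) {
  stopifnot(n_sentences >= 1L, length(category_weights) == 4L,
            all(category_weights >= 0), sum(category_weights) > 0,
            length(mean_entity_tokens) == 4L, all(mean_entity_tokens >= 1),
            label_noise >= 0, label_noise < 1)
  names(category_weights) <- NANO_CATEGORIES
  names(mean_entity_tokens) <- NANO_CATEGORIES
  stopifnot(setequal(names(lexicons), NANO_CATEGORIES))
  structure(list(n_sentences = as.integer(n_sentences),
                 category_weights = category_weights / sum(category_weights),
                 mean_entity_tokens = mean_entity_tokens,
                 label_noise = label_noise, seed = as.integer(seed),
                 lexicons = lexicons[NANO_CATEGORIES]),
            class = "nano_gencfg")
}

# Index lexicon terms by token length once per generation run.
index_lexicon_lengths <- function(terms, category) {
  lens <- vapply(terms, function(t) nrow(tokenize(t)), integer(1))
  if (length(terms) == 0L) {
    compute_error(sprintf("generator lexicon for %s is empty", category))
  }
  split(terms, lens)
}

# Draw an entity length: 1 + Poisson(mean - 1), truncated to the lengths
# available in the lexicon (nearest available length not below the draw,
# else the largest available).
draw_length <- function(mean_tokens, available) {
  want <- 1L + rpois(1L, mean_tokens - 1)
  at_least <- available[available >= want]
  if (length(at_least) > 0L) min(at_least) else max(available)
}

#' Generate a synthetic annotated corpus
#'
#' Builds `cfg$n_sentences` sentences from the template grammar: each
#' non-distractor sentence's entity slots get a category drawn from
#' `cfg$category_weights` and a term of sampled length from that category's
#' lexicon. Deterministic given `cfg$seed`; a fixed 10% of sentences are
#' entity-free distractors.
#'
#' @param cfg A [generator_config()].
#' @return List with elements `corpus` (a `nano_corpus`) and `report`
#'   (data frame of realized per-category entity and token counts, exactly
#'   matching the emitted corpus).
#' @export
#' @examples
#' gen <- generate_corpus(generator_config(n_sentences = 5))
#' gen$report
generate_corpus <- function(cfg = generator_config()) {
  stopifnot(inherits(cfg, "nano_gencfg"))
  by_len <- mapply(index_lexicon_lengths, cfg$lexicons, NANO_CATEGORIES,
                   SIMPLIFY = FALSE)
  avail <- lapply(by_len, function(b) as.integer(names(b)))
  set.seed(cfg$seed)
  lines <- vapply(seq_len(cfg$n_sentences), function(i) {
    if (runif(1) < DISTRACTOR_FRACTION) {
      return(sample(DISTRACTOR_TEMPLATES, 1L))
    }
    template <- sample(SENTENCE_TEMPLATES, 1L)
    parts <- strsplit(template, "{E}", fixed = TRUE)[[1]]
    n_slots <- length(parts) - 1L
    filled <- parts[1]
    for (s in seq_len(n_slots)) {
      cat_name <- sample(NANO_CATEGORIES, 1L, prob = cfg$category_weights)
      len <- draw_length(cfg$mean_entity_tokens[[cat_name]],
                         avail[[cat_name]])
      pool <- by_len[[cat_name]][[as.character(len)]]
      term <- pool[sample.int(length(pool), 1L)]
      piece <- if (cfg$label_noise > 0 && runif(1) < cfg$label_noise) {
        term
      } else {
        paste0("<", cat_name, ">", term, "</", cat_name, ">")
      }
      filled <- paste0(filled, piece, parts[s + 1L])
    }
    filled
  }, character(1))
  corpus <- as_corpus(lapply(seq_along(lines), function(i) {
    parse_annotated(lines[i], line_number = i)
  }))
  list(corpus = corpus, report = generation_report(corpus))
}

#' Realized per-category entity and token counts
#'
#' @param corpus A `nano_corpus`.
#' @return Data frame with one row per category plus a total row, columns
#'   `entities` and `tokens`.
#' @export
generation_report <- function(corpus) {
  stopifnot(inherits(corpus, "nano_corpus"))
  ents <- do.call(rbind, lapply(corpus, function(s) s$entities))
  counts <- lapply(NANO_CATEGORIES, function(cat) {
    e <- ents[ents$category == cat, , drop = FALSE]
    data.frame(category = cat,
               entities = NROW(e),
               tokens = if (NROW(e)) sum(e$tok_end - e$tok_start) else 0L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, counts)
  rbind(out, data.frame(category = "Total",
                        entities = sum(out$entities),
                        tokens = sum(out$tokens)))
}

#' Perturb gold annotations into a synthetic "system output"
#'
#' Drops each entity independently with probability `flip_rate` and, among
#' the survivors with at least two tokens, shrinks a fraction
#' `shrink_rate` by one boundary token (first or last, at random). With
#' `shrink_rate = 0` the expected entity recall is `1 - flip_rate` and
#' entity precision is exactly 1; shrunk entities score 0 at entity level
#' but still credit tokens at token level.
#'
#' @param corpus A `nano_corpus`.
#' @param flip_rate Drop probability in `[0, 1)`.
#' @param shrink_rate Boundary-shrink probability in `[0, 1]` (default 0).
#' @param seed Seed.
#' @return A `nano_corpus` over the same sentences.
#' @export
perturb_annotations <- function(corpus, flip_rate, shrink_rate = 0,
                                seed = 1L) {
  stopifnot(inherits(corpus, "nano_corpus"),
            flip_rate >= 0, flip_rate < 1,
            shrink_rate >= 0, shrink_rate <= 1)
  set.seed(seed)
  as_corpus(lapply(corpus, function(s) {
    e <- s$entities
    if (nrow(e) > 0L) {
      e <- e[runif(nrow(e)) >= flip_rate, , drop = FALSE]
    }
    if (nrow(e) > 0L && shrink_rate > 0) {
      for (i in seq_len(nrow(e))) {
        if (e$tok_end[i] - e$tok_start[i] >= 2L &&
            runif(1) < shrink_rate) {
          if (runif(1) < 0.5) {
            e$tok_start[i] <- e$tok_start[i] + 1L
          } else {
            e$tok_end[i] <- e$tok_end[i] - 1L
          }
        }
      }
    }
    annotated_sentence(s$text, e)
  }))
}
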