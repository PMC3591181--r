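# Entity-level and token-level precision/recall/F per category.
#
# Entity level: a predicted entity is correct only if both its category and
# its exact token boundaries match a gold entity. Token level: tokens inside
# category entities are compared individually, crediting partial matches
# ("metallic nickel nanoparticles" predicted as "nickel nanoparticles"
# scores 0 at entity level but 2/3 recall at token level). Counts are
# micro-averaged (pooled) across sentences and cross-validation folds.

check_aligned <- function(gold, pred) {
  stopifnot(inherits(gold, "nano_corpus"), inherits(pred, "nano_corpus"))
  if (length(gold) != length(pred)) {
    stop(errorCondition(
      sprintf("corpora are misaligned: %d vs %d sentences",
              length(gold), length(pred)),
      class = c("nanoner_alignment_error", "nanoner_error")))
  }
  for (i in seq_along(gold)) {
    if (!identical(gold[[i]]$tokens$text, pred[[i]]$tokens$text)) {
      stop(errorCondition(
        sprintf("corpora are misaligned: tokenizations differ at sentence %d",
                i),
        class = c("nanoner_alignment_error", "nanoner_error")))
    }
  }
  invisible(TRUE)
}

cat_entities <- function(sentence, cat) {
  e <- sentence$entities
  e[e$category == cat, , drop = FALSE]
}

#' Entity-level counts for one category
#'
#' An entity is counted correct only when category and token boundaries
#' both match exactly.
#'
#' @param gold,pred Sentence-aligned `nano_corpus` objects with identical
#'   tokenizations.
#' @param cat One of [entity_categories()].
#' @return Named integer vector `c(correct, returned, in_gold)`.
#' @export
entity_counts <- function(gold, pred, cat) {
  check_aligned(gold, pred)
  correct <- returned <- in_gold <- 0L
  for (i in seq_along(gold)) {
    g <- cat_entities(gold[[i]], cat)
    p <- cat_entities(pred[[i]], cat)
    gk <- paste(g$tok_start, g$tok_end)
    pk <- paste(p$tok_start, p$tok_end)
    correct <- correct + sum(pk %in% gk)
    returned <- returned + nrow(p)
    in_gold <- in_gold + nrow(g)
  }
  c(correct = correct, returned = returned, in_gold = in_gold)
}

cat_token_idx <- function(sentence, cat) {
  e <- cat_entities(sentence, cat)
  if (nrow(e) == 0L) return(integer(0))
  unlist(lapply(seq_len(nrow(e)), function(i) {
    (e$tok_start[i] + 1L):e$tok_end[i]
  }))
}

#' Token-level counts for one category
#'
#' Counts tokens lying inside entities of the category; a token is correct
#' when it is inside a category entity in both gold and prediction. Tokens
#' outside any predicted entity are never counted as returned.
#'
#' @inheritParams entity_counts
#' @return Named integer vector `c(correct, returned, in_gold)`.
#' @export
token_counts <- function(gold, pred, cat) {
  check_aligned(gold, pred)
  correct <- returned <- in_gold <- 0L
  for (i in seq_along(gold)) {
    g <- cat_token_idx(gold[[i]], cat)
    p <- cat_token_idx(pred[[i]], cat)
    correct <- correct + length(intersect(g, p))
    returned <- returned + length(p)
    in_gold <- in_gold + length(g)
  }
  c(correct = correct, returned = returned, in_gold = in_gold)
}

#' Precision, recall and F from a count triple
#'
#' `P = correct / returned`, `R = correct / in_gold`,
#' `F = 2 P R / (P + R)`. Any 0/0 is taken as 0 (with a warning), so a
#' category with no predictions scores zero rather than NA.
#'
#' @param counts Numeric triple `(correct, returned, in_gold)` (as from
#'   [entity_counts()] or [token_counts()]).
#' @return Named numeric vector `c(precision, recall, f)`.
#' @export
#' @examples
#' compute_metrics(c(2, 2, 3))  # the partial-match token example: P=1, R=2/3
compute_metrics <- function(counts) {
  counts <- as.numeric(counts)
  stopifnot(length(counts) == 3L, all(counts >= 0),
            counts[1] <= min(counts[2], counts[3]))
  ratio0 <- function(num, den, what) {
    if (den == 0) {
      if (num == 0) {
        warning(sprintf("0/0 in %s taken as 0", what), call. = FALSE)
        return(0)
      }
      compute_error("count numerator exceeds zero denominator")
    }
    num / den
  }
  p <- ratio0(counts[1], counts[2], "precision")
  r <- ratio0(counts[1], counts[3], "recall")
  f <- if (p + r == 0) 0 else 2 * p * r / (p + r)
  c(precision = p, recall = r, f = f)
}

report_from_counts <- function(ec, tc) {
  rows <- lapply(NANO_CATEGORIES, function(cat) {
    em <- suppressWarnings(compute_metrics(ec[[cat]]))
    tm <- suppressWarnings(compute_metrics(tc[[cat]]))
    data.frame(category = cat,
               EP = em["precision"], ER = em["recall"], EF = em["f"],
               TP = tm["precision"], TR = tm["recall"], TF = tm["f"],
               stringsAsFactors = FALSE, row.names = NULL)
  })
  report <- do.call(rbind, rows)
  structure(list(metrics = report, entity_counts = ec, token_counts = tc),
            class = "nano_eval")
}

#' @export
print.nano_eval <- function(x, digits = 3, ...) {
  m <- x$metrics
  cat("            Entity-level             Token-level\n")
  cat(sprintf("%-8s %6s %6s %6s   %6s %6s %6s\n",
              "", "EP", "ER", "EF", "TP", "TR", "TF"))
  for (i in seq_len(nrow(m))) {
    cat(sprintf("%-8s %6.3f %6.3f %6.3f   %6.3f %6.3f %6.3f\n",
                m$category[i], m$EP[i], m$ER[i], m$EF[i],
                m$TP[i], m$TR[i], m$TF[i]))
  }
  invisible(x)
}

#' Evaluate a predicted corpus against a gold standard
#'
#' Computes entity-level and token-level precision, recall and F for each
#' of the four categories (24 metric cells), from pooled counts over all
#' sentences.
#'
#' @inheritParams entity_counts
#' @return An object of class `nano_eval`: a list with `metrics` (a 4-row
#'   data frame with columns EP, ER, EF, TP, TR, TF) and the underlying
#'   `entity_counts` / `token_counts` per category, from which the metrics
#'   are recomputable.
#' @export
evaluate_corpus <- function(gold, pred) {
  check_aligned(gold, pred)
  ec <- lapply(stats::setNames(NANO_CATEGORIES, NANO_CATEGORIES),
               function(cat) entity_counts(gold, pred, cat))
  tc <- lapply(stats::setNames(NANO_CATEGORIES, NANO_CATEGORIES),
               function(cat) token_counts(gold, pred, cat))
  report_from_counts(ec, tc)
}

#' k-fold cross-validation of the CRF recognizer
#'
#' Shuffles sentences with the given seed, partitions them into `k` folds
#' whose sizes differ by at most one, trains on the complement of each fold,
#' predicts the held-out sentences, and pools (micro-averages) the counts
#' across folds before computing the metrics.
#'
#' @param corpus A `nano_corpus` with at least `k` sentences.
#' @param k Number of folds (default 10).
#' @param seed Seed for the fold permutation.
#' @param featcfg A [feature_config()].
#' @param traincfg A [train_config()].
#' @return A `nano_eval` report; its `"folds"` attribute records the fold
#'   assignment (sentence index -> fold id).
#' @export
cross_validate <- function(corpus, k = 10L, seed = 1L,
                           featcfg = feature_config(),
                           traincfg = train_config()) {
  stopifnot(inherits(corpus, "nano_corpus"))
  n <- length(corpus)
  k <- as.integer(k)
  if (k < 2L || k > n) {
    config_error(sprintf("k must be between 2 and the corpus size (%d)", n))
  }
  set.seed(seed)
  fold <- integer(n)
  fold[sample.int(n)] <- rep_len(seq_len(k), n)
  zero <- c(correct = 0L, returned = 0L, in_gold = 0L)
  ec <- lapply(stats::setNames(NANO_CATEGORIES, NANO_CATEGORIES),
               function(cat) zero)
  tc <- ec
  for (f in seq_len(k)) {
    test_idx <- which(fold == f)
    model <- crf_train(corpus[-test_idx], featcfg, traincfg)
    gold_f <- corpus[test_idx]
    pred_f <- as_corpus(lapply(gold_f, function(s) {
      crf_predict(model, s$text)
    }))
    for (cat in NANO_CATEGORIES) {
      ec[[cat]] <- ec[[cat]] + entity_counts(gold_f, pred_f, cat)
      tc[[cat]] <- tc[[cat]] + token_counts(gold_f, pred_f, cat)
    }
  }
  report <- report_from_counts(ec, tc)
  attr(report, "folds") <- fold
  attr(report, "k") <- k
  report
}
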