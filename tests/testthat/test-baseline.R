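toy_baseline_corpus <- function() {
  as_corpus(lapply(c(
    "Gold nanoparticles accumulate in the liver of mice .",
    "Gold nanoparticles have the potential to reach the brain .",
    "Exposure to fullerene damaged the liver in treated animals .",
    "The committee reviewed the study design in detail .",
    "Fullerene was detected again in the liver tissue of mice .",
    "The protocol was approved before the study began .",
    "Gold nanoparticles were stable in suspension for weeks .",
    "Animals were housed under standard laboratory conditions .",
    "The brain showed no changes after saline control injections .",
    "Saline control groups were included in every experiment ."
  ), parse_annotated))
}

test_that("n-grams enumerate contiguous windows in order", {
  tok <- tokenize("Gold nanoparticles have the potential to")
  expect_equal(extract_ngrams(tok, 2, 2),
               c("gold nanoparticles", "nanoparticles have", "have the",
                 "the potential", "potential to"))
  g3 <- extract_ngrams(tok, 3, 3)
  expect_true(all(c("gold nanoparticles have", "nanoparticles have the")
                  %in% g3))
  expect_equal(extract_ngrams(tokenize("one"), 2, 6), character(0))
  expect_error(extract_ngrams(tok, 0, 2))
  expect_error(extract_ngrams(tok, 3, 2))
})

test_that("TF-IDF uses the maximum-occurrence document and ln(N/df)", {
  corpus <- toy_baseline_corpus()
  # "liver" occurs in 3 of 10 documents, once each
  expect_equal(tfidf_score("liver", corpus), log(10 / 3), tolerance = 1e-12)
  # a term present in every document scores 0 (idf = 0)
  everywhere <- as_corpus(lapply(rep("the cat sat", 4), parse_annotated))
  expect_equal(tfidf_score("cat", everywhere), 0)
  expect_equal(tfidf_score("absent", corpus), 0)
  # 3 occurrences in one document of a 10-document corpus -> 3 ln(10)
  docs <- c("spike spike spike here .", rep("nothing to see .", 9))
  spiked <- as_corpus(lapply(docs, parse_annotated))
  expect_equal(tfidf_score("spike", spiked), 3 * log(10), tolerance = 1e-12)
})

test_that("the candidate dictionary excludes stop-word unigrams but not n-gram interiors", {
  dict <- build_tfidf_dictionary(toy_baseline_corpus())
  expect_false("the" %in% dict$term[dict$n == 1])
  expect_true("have the" %in% dict$term)
  expect_true(all(dict$n >= 1 & dict$n <= 6))
  # scores agree with the standalone scorer
  for (term in c("gold nanoparticles", "fullerene", "liver")) {
    expect_equal(dict$score[dict$term == term],
                 tfidf_score(term, toy_baseline_corpus()), tolerance = 1e-12)
  }
})

test_that("term selection applies the threshold inclusively and sorts by score", {
  cand <- data.frame(term = c("a b", "c d", "e f", "g h"),
                     n = c(2L, 2L, 2L, 2L),
                     score = c(0.0999, 0.1, 2.5, 0.7))
  kept <- select_terms(cand, 0.1)
  expect_equal(kept$term, c("e f", "g h", "c d"))
  expect_identical(kept$score, sort(kept$score, decreasing = TRUE))
  expect_equal(nrow(select_terms(cand[0, ], 0.1)), 0L)
})

test_that("the baseline emits exactly the lexicon-covered spans above threshold", {
  corpus <- toy_baseline_corpus()
  nano <- lexicon(c("gold nanoparticles", "fullerene", "quantum dots"), "NANO")
  target <- lexicon(c("liver", "brain", "kidney"), "TARGET")
  ann <- baseline_annotate(corpus, nano, target)
  ents <- do.call(rbind, lapply(ann, function(s) s$entities))
  expect_true(all(ents$category %in% c("NANO", "TARGET")))
  expect_true(all(normalize_term(ents$surface) %in%
                    c(nano$terms, target$terms)))
  expect_setequal(unique(normalize_term(ents$surface)),
                  c("gold nanoparticles", "fullerene", "liver", "brain"))
  # every surface occurrence of a matched term is annotated
  expect_equal(sum(normalize_term(ents$surface) == "liver"), 3L)
  # sentence-level sanity: first sentence has one NANO and one TARGET span
  expect_equal(ann[[1]]$entities$category, c("NANO", "TARGET"))
})

test_that("raising the threshold is monotone non-increasing in emitted entities", {
  corpus <- toy_baseline_corpus()
  nano <- lexicon(c("gold nanoparticles", "fullerene"), "NANO")
  target <- lexicon(c("liver", "brain"), "TARGET")
  n_ent <- vapply(c(0, 0.5, 1, 2, 5), function(th) {
    ann <- baseline_annotate(corpus, nano, target, threshold = th)
    sum(vapply(ann, function(s) nrow(s$entities), integer(1)))
  }, integer(1))
  expect_true(all(diff(n_ent) <= 0))
})

test_that("NANO wins when a term is in both lexicons; no EXPO or TOXIC ever", {
  corpus <- toy_baseline_corpus()
  nano <- lexicon(c("fullerene", "liver"), "NANO")
  target <- lexicon(c("liver", "brain"), "TARGET")
  ann <- baseline_annotate(corpus, nano, target)
  ents <- do.call(rbind, lapply(ann, function(s) s$entities))
  expect_true(all(ents$category[normalize_term(ents$surface) == "liver"]
                  == "NANO"))
  expect_false(any(ents$category %in% c("EXPO", "TOXIC")))
})

test_that("bundled synthetic lexicon files load and drive the baseline", {
  nano <- read_lexicon(system.file("extdata", "npo_synthetic_lexicon.txt",
                                   package = "nanoner"), "NANO")
  target <- read_lexicon(system.file("extdata", "fma_synthetic_lexicon.txt",
                                     package = "nanoner"), "TARGET")
  expect_gte(length(nano$terms), 40L)
  expect_gte(length(target$terms), 40L)
  gen <- generate_corpus(generator_config(n_sentences = 50L, seed = 31L))
  ann <- baseline_annotate(gen$corpus, nano, target)
  rep <- suppressWarnings(evaluate_corpus(gen$corpus, ann))
  # two-row behavior: nothing returned outside NANO and TARGET
  expect_equal(unname(rep$entity_counts$EXPO["returned"]), 0L)
  expect_equal(unname(rep$entity_counts$TOXIC["returned"]), 0L)
  expect_gt(rep$metrics$ER[rep$metrics$category == "NANO"], 0)
  # empty lexicon is a configuration error
  expect_error(lexicon(character(0), "NANO"), class = "nanoner_config_error")
  expect_error(read_lexicon(withr::local_tempfile(lines = "# only comments"),
                            "NANO"),
               class = "nanoner_config_error")
})
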