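zero_model <- function(features = c("f1", "f2")) {
  crf_model(features, matrix(0, length(features), 9), matrix(0, 9, 9))
}

test_that("sequence_score sums state and transition terms explicitly", {
  m0 <- zero_model()
  featseq <- list(c("f1"), c("f1", "f2"), c("f2"))
  expect_equal(sequence_score(m0, featseq, c("O", "B-NANO", "I-NANO")), 0)
  # single state feature firing once contributes exactly its weight
  W <- matrix(0, 2, 9)
  W[1, 2] <- 1.75
  m1 <- crf_model(c("f1", "f2"), W, matrix(0, 9, 9))
  expect_equal(sequence_score(m1, list("f1"), "B-NANO"), 1.75)
  expect_equal(sequence_score(m1, list("f2"), "B-NANO"), 0)
  # unknown feature names are ignored with zero weight
  expect_equal(sequence_score(m1, list(c("f1", "unseen")), "B-NANO"), 1.75)
  # random models match the explicit-summation oracle
  for (seed in 1:20) {
    rm <- random_model_and_seq(seed)
    tags <- sample(bio_labels(), rm$T_, replace = TRUE)
    S <- oracle_state_scores(rm$model, rm$featseq)
    y <- match(tags, bio_labels())
    want <- sum(S[cbind(seq_len(rm$T_), y)])
    if (rm$T_ > 1L) {
      want <- want + sum(rm$model$trans[cbind(y[-rm$T_], y[-1L])])
    }
    expect_equal(sequence_score(rm$model, rm$featseq, tags), want)
  }
})

test_that("log partition equals T*ln(9) for the uniform model and dominates any score", {
  m0 <- zero_model()
  for (T_ in c(1, 3, 7)) {
    featseq <- replicate(T_, "f1", simplify = FALSE)
    expect_equal(log_partition(m0, featseq), T_ * log(9))
  }
  rm <- random_model_and_seq(99, T_ = 3L)
  lz <- log_partition(rm$model, rm$featseq)
  for (i in 1:10) {
    tags <- sample(bio_labels(), 3, replace = TRUE)
    expect_gt(lz, sequence_score(rm$model, rm$featseq, tags))
  }
})

test_that("forward recursion matches brute-force enumeration at T = 3", {
  for (seed in 1:10) {
    rm <- random_model_and_seq(seed, T_ = 3L)
    S <- oracle_state_scores(rm$model, rm$featseq)
    expect_equal(log_partition(rm$model, rm$featseq),
                 oracle_logZ(S, rm$model$trans), tolerance = 1e-10)
  }
})

test_that("marginals are proper distributions and match enumeration", {
  for (seed in 1:10) {
    rm <- random_model_and_seq(seed + 100)
    P <- posterior_marginals(rm$model, rm$featseq)
    expect_true(all(P >= 0))
    expect_equal(rowSums(P), rep(1, rm$T_), tolerance = 1e-8)
    S <- oracle_state_scores(rm$model, rm$featseq)
    expect_equal(unname(P), oracle_marginals(S, rm$model$trans),
                 tolerance = 1e-8)
  }
})

test_that("Viterbi decodes the enumeration argmax with lowest-index ties", {
  # all-zero weights: everything ties, O (index 1) wins everywhere
  m0 <- zero_model()
  expect_equal(viterbi_decode(m0, replicate(4, "f1", simplify = FALSE)),
               rep("O", 4))
  for (seed in 1:15) {
    rm <- random_model_and_seq(seed + 200)
    tags <- viterbi_decode(rm$model, rm$featseq)
    S <- oracle_state_scores(rm$model, rm$featseq)
    expect_equal(sequence_score(rm$model, rm$featseq, tags),
                 oracle_best_score(S, rm$model$trans), tolerance = 1e-10)
  }
  expect_error(viterbi_decode(m0, list()), class = "nanoner_compute_error")
})

test_that("decoding is invariant to a constant shift of one position's state scores", {
  rm <- random_model_and_seq(7, T_ = 4L)
  shifted <- rm$model
  shifted$W[2, ] <- shifted$W[2, ] + 3.7  # feature f2, same shift for all labels
  featseq <- lapply(1:4, function(t) if (t == 2) c("f2", "f1") else "f1")
  expect_identical(viterbi_decode(rm$model, featseq),
                   viterbi_decode(shifted, featseq))
})

test_that("nll and gradient match the uniform closed form and finite differences", {
  m0 <- zero_model()
  pair <- list(list(features = replicate(4, "f1", simplify = FALSE),
                    tags = c("O", "B-NANO", "I-NANO", "O")))
  expect_equal(nll_and_gradient(m0, pair)$value, 4 * log(9))
  # gradient of the prior term alone is w / sigma^2: compare a model against
  # itself on no likelihood change by zero features
  for (seed in 1:20) {
    set.seed(seed)
    nf <- 3L
    feats <- paste0("g", 1:nf)
    model <- crf_model(feats, matrix(rnorm(nf * 9, sd = 0.5), nf, 9),
                       matrix(rnorm(81, sd = 0.5), 9, 9), sigma = 5)
    data <- lapply(1:2, function(s) {
      T_ <- sample(2:3, 1)
      list(features = lapply(seq_len(T_), function(t) {
        sample(feats, sample.int(nf, 1))
      }),
      tags = sample(bio_labels(), T_, replace = TRUE))
    })
    got <- nll_and_gradient(model, data)
    theta <- c(as.vector(model$W), as.vector(model$trans))
    eps <- 1e-5
    num <- vapply(seq_along(theta), function(k) {
      up <- theta; up[k] <- up[k] + eps
      dn <- theta; dn[k] <- dn[k] - eps
      mk <- function(v) {
        crf_model(feats, matrix(v[seq_len(nf * 9)], nf, 9),
                  matrix(v[nf * 9 + seq_len(81)], 9, 9), sigma = 5)
      }
      (nll_and_gradient(mk(up), data)$value -
         nll_and_gradient(mk(dn), data)$value) / (2 * eps)
    }, numeric(1))
    expect_equal(got$gradient, num, tolerance = 1e-5)
  }
})

test_that("the prior contributes w/sigma^2 to the gradient", {
  set.seed(1)
  feats <- c("h1", "h2")
  W <- matrix(rnorm(18), 2, 9)
  trans <- matrix(rnorm(81), 9, 9)
  data <- list(list(features = list("h1", "h2"), tags = c("O", "O")))
  g5 <- nll_and_gradient(crf_model(feats, W, trans, sigma = 5), data)
  ginf <- nll_and_gradient(crf_model(feats, W, trans, sigma = 1e8), data)
  expect_equal(g5$gradient - ginf$gradient,
               c(as.vector(W), as.vector(trans)) / 25, tolerance = 1e-6)
})

test_that("training fits a word-determined corpus and is deterministic", {
  corpus <- toy_training_corpus()
  cfg <- train_config(max_iterations = 80)
  model <- crf_train(corpus, traincfg = cfg)
  # final penalized NLL no worse than the zero-weight start
  data <- lapply(corpus[seq_along(corpus)], function(s) {
    b <- spans_to_bio(s)
    list(features = lapply(seq_len(nrow(b$tokens)), function(i) {
      extract_features(b$tokens, i)
    }), tags = b$tags)
  })
  zero <- crf_model(model$features, 0 * model$W, 0 * model$trans)
  expect_lte(model$value, nll_and_gradient(zero, data)$value)
  # held-in decoding recovers the word-to-tag mapping
  pred <- crf_predict(model, "Exposure by inhalation to TiO2 harmed lung .")
  expect_equal(pred$entities$category, c("EXPO", "NANO", "TARGET"))
  expect_equal(pred$entities$surface, c("inhalation", "TiO2", "lung"))
  model2 <- crf_train(corpus, traincfg = cfg)
  expect_identical(model$W, model2$W)
  expect_identical(model$trans, model2$trans)
})

test_that("the penalized objective is convex: random restarts agree", {
  corpus <- toy_training_corpus()[1:4]
  vals <- vapply(c(2, 3, 4), function(seed) {
    crf_train(corpus, traincfg = train_config(max_iterations = 400,
                                              tolerance = 1e-9,
                                              seed = seed,
                                              init_sd = 0.5))$value
  }, numeric(1))
  expect_lt(max(vals) - min(vals), 1e-4)
})

test_that("prediction is pure and handles empty input", {
  model <- crf_train(toy_training_corpus(),
                     traincfg = train_config(max_iterations = 40))
  empty <- crf_predict(model, "")
  expect_equal(nrow(empty$tokens), 0L)
  expect_equal(nrow(empty$entities), 0L)
  p1 <- crf_predict(model, "ZnO caused necrosis in liver .")
  p2 <- crf_predict(model, "ZnO caused necrosis in liver .")
  expect_identical(p1, p2)
  # a sentence of unseen filler words typically yields no entities
  p3 <- crf_predict(model, "the committee reviewed the annual budget report")
  expect_equal(nrow(p3$entities), 0L)
})

test_that("models survive the save/load round trip", {
  model <- crf_train(toy_training_corpus(),
                     traincfg = train_config(max_iterations = 40))
  path <- withr::local_tempfile(fileext = ".json")
  write_crf(model, path)
  back <- read_crf(path)
  expect_identical(back$features, model$features)
  expect_equal(back$W, model$W)
  expect_equal(back$trans, model$trans, ignore_attr = TRUE)
  txt <- "Exposure by ingestion to ZnO harmed lung ."
  expect_identical(crf_predict(back, txt)$entities,
                   crf_predict(model, txt)$entities)
  expect_error(read_crf(withr::local_tempfile(lines = "{}",
                                              fileext = ".json")),
               class = "nanoner_format_error")
})
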