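# Independent oracles for the chain model, used only by tests: explicit
# summation for sequence scores and exhaustive enumeration over all L^T
# taggings for the partition function, marginals and the best path.

lse <- function(v) {
  m <- max(v)
  m + log(sum(exp(v - m)))
}

# State-score matrix computed by explicit per-feature summation,
# independently of the package's matrix path.
oracle_state_scores <- function(model, featseq) {
  L <- length(model$labels)
  S <- matrix(0, length(featseq), L)
  for (t in seq_along(featseq)) {
    for (f in featseq[[t]]) {
      k <- which(model$features == f)
      if (length(k) == 1L) {
        for (l in seq_len(L)) S[t, l] <- S[t, l] + model$W[k, l]
      }
    }
  }
  S
}

# Scores of every one of the L^T taggings.
oracle_all_scores <- function(S, trans) {
  T_ <- nrow(S)
  L <- ncol(S)
  grid <- as.matrix(expand.grid(rep(list(seq_len(L)), T_)))
  sc <- numeric(nrow(grid))
  for (t in seq_len(T_)) sc <- sc + S[t, ][grid[, t]]
  if (T_ > 1L) {
    for (t in 2:T_) sc <- sc + trans[cbind(grid[, t - 1L], grid[, t])]
  }
  list(grid = grid, scores = sc)
}

oracle_logZ <- function(S, trans) lse(oracle_all_scores(S, trans)$scores)

oracle_marginals <- function(S, trans) {
  e <- oracle_all_scores(S, trans)
  logZ <- lse(e$scores)
  p <- exp(e$scores - logZ)
  out <- matrix(0, nrow(S), ncol(S))
  for (t in seq_len(nrow(S))) {
    for (l in seq_len(ncol(S))) out[t, l] <- sum(p[e$grid[, t] == l])
  }
  out
}

oracle_best_score <- function(S, trans) max(oracle_all_scores(S, trans)$scores)

# Small random model plus a random feature sequence of length T.
random_model_and_seq <- function(seed, T_ = NULL, nfeat = 5L) {
  set.seed(seed)
  if (is.null(T_)) T_ <- sample(1:4, 1L)
  feats <- paste0("f", seq_len(nfeat))
  model <- crf_model(feats,
                     matrix(rnorm(nfeat * 9), nfeat, 9),
                     matrix(rnorm(81), 9, 9))
  featseq <- lapply(seq_len(T_), function(t) {
    sample(feats, sample.int(nfeat, 1L))
  })
  list(model = model, featseq = featseq, T_ = T_)
}

# Cached default synthetic corpus shared by the heavier tests.
.fixture_env <- new.env(parent = emptyenv())

default_generated <- function() {
  if (is.null(.fixture_env$gen)) {
    .fixture_env$gen <- generate_corpus(generator_config())
  }
  .fixture_env$gen
}

# A tiny hand-written training corpus where word identity determines the
# tag: quick to fit, used by several training tests.
toy_training_corpus <- function() {
  as_corpus(lapply(c(
    "<NANO>TiO2</NANO> caused <TOXIC>apoptosis</TOXIC> in <TARGET>lung</TARGET> .",
    "<NANO>ZnO</NANO> caused <TOXIC>necrosis</TOXIC> in <TARGET>liver</TARGET> .",
    "<NANO>TiO2</NANO> induced <TOXIC>necrosis</TOXIC> in <TARGET>lung</TARGET> .",
    "Exposure by <EXPO>inhalation</EXPO> to <NANO>ZnO</NANO> harmed <TARGET>liver</TARGET> .",
    "Exposure by <EXPO>ingestion</EXPO> to <NANO>TiO2</NANO> harmed <TARGET>lung</TARGET> .",
    "No entities occur in this sentence at all ."
  ), parse_annotated))
}
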