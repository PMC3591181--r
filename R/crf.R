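# Linear-chain conditional random field over the 9 BIO labels.
#
# The score of a tagging y for a sentence with per-position feature sets
# x_1..x_T is sum_t w_state[x_t, y_t] + sum_{t>1} w_trans[y_{t-1}, y_t];
# the model is normalized globally per sentence. Transitions are plain
# label-pair weights (not feature-conjoined), the classic linear-chain
# formulation. Training minimizes the negative log-likelihood plus a
# Gaussian prior ||w||^2 / (2 sigma^2) with L-BFGS. All dynamic programs
# run in log space (compiled, see src/crf_dp.cpp). Illegal transitions
# such as O -> I-X are not hard-masked; decoder output is repaired by
# bio_to_spans().

#' Construct a CRF model
#'
#' @param features Character vector of feature names; its order is the
#'   feature index.
#' @param state_weights Numeric matrix, `length(features)` x 9 (feature,
#'   label).
#' @param transition_weights Numeric 9 x 9 matrix (from-label, to-label).
#' @param sigma Positive Gaussian prior scale.
#' @param featcfg The [feature_config()] the model expects at prediction
#'   time.
#' @return An object of class `nano_crf`.
#' @export
crf_model <- function(features, state_weights, transition_weights,
                      sigma = 10, featcfg = feature_config()) {
  labels <- bio_labels()
  L <- length(labels)
  state_weights <- as.matrix(state_weights)
  transition_weights <- as.matrix(transition_weights)
  stopifnot(is.character(features), !anyDuplicated(features),
            nrow(state_weights) == length(features),
            ncol(state_weights) == L,
            all(dim(transition_weights) == c(L, L)),
            all(is.finite(state_weights)), all(is.finite(transition_weights)))
  if (!is.numeric(sigma) || sigma <= 0) config_error("sigma must be > 0")
  dimnames(transition_weights) <- list(labels, labels)
  structure(list(labels = labels, features = features, W = state_weights,
                 trans = transition_weights, sigma = sigma,
                 featcfg = featcfg),
            class = "nano_crf")
}

#' @export
print.nano_crf <- function(x, ...) {
  cat(sprintf("<nano_crf> %d labels, %d features, sigma = %g\n",
              length(x$labels), length(x$features), x$sigma))
  if (!is.null(x$value)) {
    cat(sprintf("  penalized NLL %.4f after %d objective evaluations\n",
                x$value, x$evaluations))
  }
  invisible(x)
}

#' Training configuration
#'
#' @param sigma Gaussian prior scale (default 10).
#' @param max_iterations L-BFGS iteration cap (default 200).
#' @param tolerance Relative objective-change stopping tolerance
#'   (default 1e-6).
#' @param seed Seed used only when `init_sd > 0` to draw the random start.
#' @param init_sd Standard deviation of the random weight initialization;
#'   0 (the default) starts from the zero vector.
#' @return An object of class `nano_traincfg`.
#' @export
train_config <- function(sigma = 10, max_iterations = 200L,
                         tolerance = 1e-6, seed = 1L, init_sd = 0) {
  if (sigma <= 0) config_error("sigma must be > 0")
  if (tolerance <= 0) config_error("tolerance must be > 0")
  if (max_iterations < 1L) config_error("max_iterations must be >= 1")
  structure(list(sigma = sigma, max_iterations = as.integer(max_iterations),
                 tolerance = tolerance, seed = as.integer(seed),
                 init_sd = init_sd),
            class = "nano_traincfg")
}

# T x L matrix of state scores; unknown feature names get zero weight.
state_score_matrix <- function(model, featseq) {
  L <- length(model$labels)
  S <- matrix(0, nrow = length(featseq), ncol = L)
  for (t in seq_along(featseq)) {
    idx <- match(featseq[[t]], model$features)
    idx <- idx[!is.na(idx)]
    if (length(idx) > 0L) S[t, ] <- colSums(model$W[idx, , drop = FALSE])
  }
  S
}

check_featseq <- function(featseq) {
  if (!is.list(featseq) || length(featseq) < 1L) {
    compute_error("feature sequence must be a nonempty list of feature sets")
  }
}

#' Unnormalized log-linear score of one tagging
#'
#' `sum_t` state score of `tags[t]` given `featseq[[t]]` plus `sum_{t>1}`
#' transition score `tags[t-1] -> tags[t]`. Feature names absent from the
#' model are silently ignored (zero weight).
#'
#' @param model A `nano_crf`.
#' @param featseq List (length T >= 1) of character vectors of feature
#'   names.
#' @param tags Character vector of T BIO tags.
#' @return A single numeric score.
#' @export
sequence_score <- function(model, featseq, tags) {
  check_featseq(featseq)
  stopifnot(length(tags) == length(featseq), all(tags %in% model$labels))
  S <- state_score_matrix(model, featseq)
  y <- match(tags, model$labels)
  score <- sum(S[cbind(seq_along(y), y)])
  if (length(y) > 1L) {
    score <- score + sum(model$trans[cbind(y[-length(y)], y[-1L])])
  }
  score
}

#' Log-partition function of a sentence
#'
#' `log` of the sum over all `9^T` taggings of `exp(sequence_score)`,
#' computed by the forward recursion in log space.
#'
#' @inheritParams sequence_score
#' @return A single numeric value; always `>= sequence_score(model,
#'   featseq, tags)` for any tagging.
#' @export
log_partition <- function(model, featseq) {
  check_featseq(featseq)
  crf_logZ_cpp(state_score_matrix(model, featseq), model$trans)
}

#' Per-position posterior label marginals
#'
#' Forward-backward marginals `P(y_t = l | x)`; each row is non-negative
#' and sums to 1.
#'
#' @inheritParams sequence_score
#' @return T x 9 numeric matrix with label column names.
#' @export
posterior_marginals <- function(model, featseq) {
  check_featseq(featseq)
  P <- crf_marginals_cpp(state_score_matrix(model, featseq), model$trans)
  colnames(P) <- model$labels
  P
}

#' Viterbi decoding
#'
#' Returns an argmax tagging of [sequence_score()]; ties are broken toward
#' the lowest label index at every backtrace step, so the all-zero model
#' decodes everything to `O`.
#'
#' @inheritParams sequence_score
#' @return Character vector of T BIO tags.
#' @export
viterbi_decode <- function(model, featseq) {
  check_featseq(featseq)
  v <- crf_viterbi_cpp(state_score_matrix(model, featseq), model$trans)
  model$labels[v$path + 1L]
}

# ---- training internals -------------------------------------------------

# Stack a list of (featseq, tags) pairs into the sparse design used by the
# objective: Phi (total tokens x features), one-hot Y, sentence offsets,
# 0-based observed labels, and observed transition counts.
build_design <- function(data, features) {
  labels <- bio_labels()
  L <- length(labels)
  lens <- vapply(data, function(d) length(d$features), integer(1))
  if (any(lens == 0L)) compute_error("cannot train on an empty sentence")
  starts <- cumsum(c(0L, lens[-length(lens)]))
  n_tok <- sum(lens)
  ii <- vector("list", length(data))
  jj <- vector("list", length(data))
  y <- integer(n_tok)
  obs_trans <- matrix(0, L, L)
  for (s in seq_along(data)) {
    fs <- data[[s]]$features
    idx <- lapply(fs, function(f) {
      m <- match(f, features)
      m[!is.na(m)]
    })
    nf <- lengths(idx)
    ii[[s]] <- rep(starts[s] + seq_along(fs), nf)
    jj[[s]] <- unlist(idx, use.names = FALSE)
    ys <- match(data[[s]]$tags, labels)
    if (anyNA(ys)) compute_error("unknown BIO tag in training data")
    y[starts[s] + seq_along(ys)] <- ys - 1L
    if (length(ys) > 1L) {
      for (t in 2:length(ys)) {
        obs_trans[ys[t - 1L], ys[t]] <- obs_trans[ys[t - 1L], ys[t]] + 1
      }
    }
  }
  Phi <- sparseMatrix(i = unlist(ii, use.names = FALSE),
                      j = unlist(jj, use.names = FALSE),
                      x = 1, dims = c(n_tok, length(features)))
  Y <- sparseMatrix(i = seq_len(n_tok), j = y + 1L, x = 1,
                    dims = c(n_tok, L))
  list(Phi = Phi, Y = Y, starts = starts, lens = lens, y = y,
       obs_trans = obs_trans)
}

# Penalized NLL and gradient given unpacked weights and a design.
crf_objective_parts <- function(W, trans, design, sigma) {
  S <- as.matrix(design$Phi %*% W)
  res <- crf_batch_infer_cpp(S, trans, design$starts, design$lens, design$y)
  value <- res$nll + (sum(W^2) + sum(trans^2)) / (2 * sigma^2)
  gW <- as.matrix(crossprod(design$Phi, res$post - design$Y)) + W / sigma^2
  gT <- res$trans_expected - design$obs_trans + trans / sigma^2
  list(value = value, gradient = c(as.vector(gW), as.vector(gT)))
}

as_crf_data <- function(corpus, featcfg) {
  seqs <- lapply(corpus, spans_to_bio)
  seqs <- seqs[vapply(seqs, function(b) nrow(b$tokens) > 0L, logical(1))]
  lapply(seqs, function(b) {
    list(features = sentence_features(b$tokens, featcfg), tags = b$tags)
  })
}

#' Penalized negative log-likelihood and gradient
#'
#' `value = -sum_s [score(y_s) - logZ_s] + ||w||^2 / (2 sigma^2)`;
#' `gradient = (expected - observed feature counts) + w / sigma^2`, with
#' expectations from forward-backward marginals. The gradient is packed as
#' `c(state weights column-major (features x 9), transition weights
#' column-major (9 x 9))`.
#'
#' @param model A `nano_crf`.
#' @param data List of training pairs, each a list with elements
#'   `features` (list of per-position feature-name vectors) and `tags`
#'   (BIO tag vector of the same length).
#' @return List with elements `value` and `gradient`.
#' @export
nll_and_gradient <- function(model, data) {
  stopifnot(is.list(data), length(data) > 0L)
  design <- build_design(data, model$features)
  crf_objective_parts(model$W, model$trans, design, model$sigma)
}

#' Train a CRF on an annotated corpus
#'
#' Extracts features over the corpus vocabulary, encodes entities as IOB2
#' tags, and minimizes the Gaussian-prior-penalized negative log-likelihood
#' with L-BFGS run to `traincfg$tolerance` (relative objective change) or
#' `traincfg$max_iterations`. The objective is convex, so the optimum does
#' not depend on the (zero, by default) starting point.
#'
#' @param corpus A nonempty `nano_corpus`.
#' @param featcfg A [feature_config()].
#' @param traincfg A [train_config()].
#' @return A fitted `nano_crf`; its final penalized NLL never exceeds the
#'   zero-weight objective.
#' @export
crf_train <- function(corpus, featcfg = feature_config(),
                      traincfg = train_config()) {
  stopifnot(inherits(corpus, "nano_corpus"))
  if (length(corpus) == 0L) config_error("cannot train on an empty corpus")
  data <- as_crf_data(corpus, featcfg)
  if (length(data) == 0L) config_error("corpus has no non-empty sentences")
  features <- sort(unique(unlist(lapply(data, function(d) d$features),
                                 use.names = FALSE)))
  design <- build_design(data, features)
  L <- length(bio_labels())
  nf <- length(features)
  npar <- nf * L + L * L
  eval_env <- new.env(parent = emptyenv())
  eval_env$count <- 0L
  eval_env$par <- NULL
  calc <- function(par) {
    if (!is.null(eval_env$par) && identical(par, eval_env$par)) {
      return(eval_env$res)
    }
    eval_env$count <- eval_env$count + 1L
    W <- matrix(par[seq_len(nf * L)], nf, L)
    trans <- matrix(par[nf * L + seq_len(L * L)], L, L)
    res <- crf_objective_parts(W, trans, design, traincfg$sigma)
    if (!is.finite(res$value) || anyNA(res$gradient)) {
      compute_error(sprintf(
        "training failed: non-finite objective at evaluation %d",
        eval_env$count))
    }
    eval_env$par <- par
    eval_env$res <- res
    res
  }
  par0 <- if (traincfg$init_sd > 0) {
    set.seed(traincfg$seed)
    stats::rnorm(npar, sd = traincfg$init_sd)
  } else {
    numeric(npar)
  }
  opt <- optim(par0, fn = function(p) calc(p)$value,
               gr = function(p) calc(p)$gradient,
               method = "L-BFGS-B",
               control = list(maxit = traincfg$max_iterations,
                              factr = traincfg$tolerance /
                                .Machine$double.eps))
  model <- crf_model(features,
                     matrix(opt$par[seq_len(nf * L)], nf, L),
                     matrix(opt$par[nf * L + seq_len(L * L)], L, L),
                     sigma = traincfg$sigma, featcfg = featcfg)
  model$value <- opt$value
  model$evaluations <- eval_env$count
  model$convergence <- opt$convergence
  model
}

#' Annotate raw text with a trained CRF
#'
#' Tokenizes, extracts features with the model's stored configuration,
#' Viterbi-decodes and converts the BIO tags back to entity spans
#' (repairing any ill-formed tag runs). Pure and deterministic.
#'
#' @param model A trained `nano_crf`.
#' @param text Sentence string.
#' @return A `nano_sentence` with predicted entities.
#' @export
crf_predict <- function(model, text) {
  stopifnot(inherits(model, "nano_crf"))
  tokens <- tokenize(text)
  if (nrow(tokens) == 0L) return(annotated_sentence(text))
  featseq <- sentence_features(tokens, model$featcfg)
  tags <- viterbi_decode(model, featseq)
  bio_to_spans(labeled_sequence(tokens, tags, text))
}

#' Save / load a CRF model
#'
#' Single self-describing JSON container (format `nanoner-crf`, version 1)
#' holding the label set, feature index, weights, prior scale and feature
#' configuration. The feature index is stable across save/load.
#'
#' @param model A `nano_crf`.
#' @param path File path.
#' @export
write_crf <- function(model, path) {
  stopifnot(inherits(model, "nano_crf"))
  payload <- list(format = "nanoner-crf", version = 1L,
                  labels = model$labels, features = model$features,
                  state_weights = as.vector(model$W),
                  transition_weights = as.vector(model$trans),
                  sigma = model$sigma,
                  featcfg = list(window = model$featcfg$window,
                                 affix_lengths = model$featcfg$affix_lengths,
                                 predicates = model$featcfg$predicates))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_crf
#' @export
read_crf <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "nanoner-crf") || p$version != 1L) {
    format_error("not a nanoner-crf version 1 model file")
  }
  if (!identical(p$labels, bio_labels())) {
    format_error("model file label set does not match this package")
  }
  L <- length(p$labels)
  crf_model(p$features,
            matrix(p$state_weights, length(p$features), L),
            matrix(p$transition_weights, L, L),
            sigma = p$sigma,
            featcfg = feature_config(window = p$featcfg$window,
                                     affix_lengths = p$featcfg$affix_lengths,
                                     predicates = p$featcfg$predicates))
}
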