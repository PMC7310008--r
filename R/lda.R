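#' LDA sampler configuration
#'
#' Hyper-parameters and run lengths for the collapsed Gibbs sampler. Each
#' patient is a document; genes or microbes are the word dictionary, and a
#' cell's scaled count is the number of tokens of that word in the document.
#'
#' Defaults: 10 topics, symmetric Dirichlet smoothing `alpha = 0.5` over
#' topics and `beta = 0.1` over words, 1000 sweeps with a 500-sweep burn-in,
#' and point estimates taken from the final state (set
#' `average_samples = TRUE` to average the post-burn-in estimates instead).
#'
#' @param n_topics Number of topics (>= 2).
#' @param alpha Symmetric document-topic Dirichlet hyper-parameter (> 0).
#' @param beta Symmetric topic-word Dirichlet hyper-parameter (> 0).
#' @param n_sweeps Total Gibbs sweeps.
#' @param burn_in Sweeps discarded before estimation (< `n_sweeps`).
#' @param seed RNG seed for initialization and sampling.
#' @param average_samples Average post-burn-in estimates rather than using
#'   the final state.
#' @return A list of class `lda_config`.
#' @export
lda_config <- function(n_topics = 10L, alpha = 0.5, beta = 0.1,
                       n_sweeps = 1000L, burn_in = 500L, seed = 1L,
                       average_samples = FALSE) {
  if (n_topics < 2) abort("n_topics must be >= 2")
  if (alpha <= 0 || beta <= 0) abort("alpha and beta must be positive")
  if (burn_in >= n_sweeps) abort("burn_in must be smaller than n_sweeps")
  structure(list(n_topics = as.integer(n_topics), alpha = alpha, beta = beta,
                 n_sweeps = as.integer(n_sweeps), burn_in = as.integer(burn_in),
                 seed = as.integer(seed), average_samples = isTRUE(average_samples)),
            class = "lda_config")
}

#' Expand scaled counts into a tokenized sampler state
#'
#' Each unit of count becomes one word token; topic assignments are drawn
#' uniformly at random from the seeded generator and the count matrices are
#' built to match. Documents with zero tokens are dropped with a warning.
#'
#' @param counts Integer abundance tibble (see [scale_counts()]).
#' @param config An [lda_config()].
#' @return A list of class `lda_state` with token vectors `z`, `doc`, `word`,
#'   count matrices `n_doc_topic` (docs x topics), `n_topic_word`
#'   (topics x words), `n_topic_total`, plus `doc_ids`, `vocab`,
#'   `doc_tokens`.
#' @export
init_lda_state <- function(counts, config) {
  m <- abund_matrix(counts)
  if (any(m < 0) || any(m != floor(m))) abort("counts must be non-negative integers")
  keep <- rowSums(m) > 0
  if (!any(keep)) abort("empty corpus: every document has zero tokens")
  if (!all(keep)) {
    warn(sprintf("dropping %d all-zero document(s): %s", sum(!keep),
                 paste(head(rownames(m)[!keep], 5), collapse = ", ")))
    m <- m[keep, , drop = FALSE]
  }
  storage.mode(m) <- "integer"
  np <- nrow(m); nv <- ncol(m); nk <- config$n_topics
  # token expansion in document-major, word-index-minor order
  idx <- which(t(m) > 0, arr.ind = TRUE)  # rows of t(m): words; cols: docs
  reps <- t(m)[t(m) > 0]
  doc <- rep.int(idx[, "col"], reps)
  word <- rep.int(idx[, "row"], reps)
  o <- order(doc, word)
  doc <- as.integer(doc[o]); word <- as.integer(word[o])
  n_tok <- length(doc)
  z <- withr::with_seed(config$seed, sample.int(nk, n_tok, replace = TRUE))
  ndk <- matrix(tabulate(doc + (z - 1L) * np, nbins = np * nk), np, nk)
  nkw <- matrix(tabulate(z + (word - 1L) * nk, nbins = nk * nv), nk, nv)
  storage.mode(ndk) <- "integer"
  storage.mode(nkw) <- "integer"
  structure(list(z = z, doc = doc, word = word,
                 n_doc_topic = ndk, n_topic_word = nkw,
                 n_topic_total = as.integer(rowSums(nkw)),
                 doc_tokens = as.integer(rowSums(ndk)),
                 doc_ids = rownames(m), vocab = colnames(m),
                 sweeps_done = 0L, loglik = numeric(0)),
            class = "lda_state")
}

check_lda_state <- function(state) {
  stopifnot(identical(as.integer(rowSums(state$n_doc_topic)), state$doc_tokens),
            identical(as.integer(rowSums(state$n_topic_word)), state$n_topic_total),
            sum(state$n_doc_topic) == length(state$z),
            all(state$n_doc_topic >= 0), all(state$n_topic_word >= 0))
  invisible(state)
}

#' Run collapsed Gibbs sweeps over a sampler state
#'
#' Every token is resampled once per sweep from its full conditional with its
#' own count excluded; the conditional is proportional to
#' `(n_topic_word + beta) / (n_topic_total + Nv * beta) * (n_doc_topic + alpha)`.
#' Tokens are visited document-major, token-minor. Counts are updated
#' incrementally. Uses R's RNG stream (seed it with `set.seed()` or rely on
#' [fit_lda()]).
#'
#' @param state An `lda_state`.
#' @param config An [lda_config()].
#' @param n_sweeps Number of sweeps to run (default 1).
#' @return The updated `lda_state`, with the per-sweep token log-likelihood
#'   appended to `state$loglik`.
#' @export
gibbs_sweep <- function(state, config, n_sweeps = 1L) {
  z <- state$z + 0L
  ndk <- state$n_doc_topic + 0L
  nkw <- state$n_topic_word + 0L
  ntot <- state$n_topic_total + 0L
  ll <- lda_gibbs_sweeps(z, state$doc, state$word, ndk, nkw, ntot,
                         state$doc_tokens, config$alpha, config$beta,
                         as.integer(n_sweeps))
  state$z <- z
  state$n_doc_topic <- ndk
  state$n_topic_word <- nkw
  state$n_topic_total <- ntot
  state$sweeps_done <- state$sweeps_done + as.integer(n_sweeps)
  state$loglik <- c(state$loglik, ll)
  check_lda_state(state)
}

#' Per-token full conditional of the sampler
#'
#' Returns the normalized probability over topics for one token, with that
#' token's own counts removed from the state — exactly the distribution the
#' sweep samples from.
#'
#' @param state An `lda_state`.
#' @param token_index Index into the token vectors.
#' @param config An [lda_config()].
#' @return Numeric vector of length `n_topics` summing to 1.
#' @export
token_conditional <- function(state, token_index, config) {
  lda_token_conditional(state$n_doc_topic, state$n_topic_word,
                        state$n_topic_total,
                        state$doc[token_index], state$word[token_index],
                        state$z[token_index], config$alpha, config$beta)
}

#' Posterior-mean topic matrices from a sampler state
#'
#' Smoothed point estimates from the current counts:
#' `theta[p,k] = (n[p,k] + alpha) / (N_p_tokens + K * alpha)` and
#' `phi[k,v] = (n[k,v] + beta) / (n[k] + V * beta)`.
#'
#' @param state An `lda_state`.
#' @param config An [lda_config()].
#' @return A list of class `lda_model`: `theta` (patients x topics), `phi`
#'   (topics x words), `config`, `loglik`.
#' @export
estimate_lda <- function(state, config) {
  K <- ncol(state$n_doc_topic)
  V <- ncol(state$n_topic_word)
  theta <- (state$n_doc_topic + config$alpha) /
    (rowSums(state$n_doc_topic) + K * config$alpha)
  phi <- (state$n_topic_word + config$beta) /
    (rowSums(state$n_topic_word) + V * config$beta)
  dimnames(theta) <- list(state$doc_ids, paste0("topic_", seq_len(K)))
  dimnames(phi) <- list(paste0("topic_", seq_len(K)), state$vocab)
  structure(list(theta = theta, phi = phi, config = config,
                 loglik = state$loglik, n_tokens = length(state$z)),
            class = "lda_model")
}

#' Fit an LDA topic model by collapsed Gibbs sampling
#'
#' Initializes a tokenized state from scaled counts, runs `n_sweeps` sweeps,
#' and estimates `theta` (patient -> topic) and `phi` (topic -> word) from
#' the final state (or from the average of post-burn-in states when
#' `config$average_samples` is set). Topics are relabeled in descending
#' order of total token mass so runs are comparable; the whole fit is
#' deterministic given `config$seed`.
#'
#' @param counts Integer abundance tibble (see [scale_counts()]).
#' @param config An [lda_config()].
#' @return An `lda_model` (see [estimate_lda()]).
#' @export
fit_lda <- function(counts, config = lda_config()) {
  state <- init_lda_state(counts, config)
  model <- withr::with_seed(config$seed, {
    if (!config$average_samples) {
      state <- gibbs_sweep(state, config, n_sweeps = config$n_sweeps)
      estimate_lda(state, config)
    } else {
      state <- gibbs_sweep(state, config, n_sweeps = config$burn_in)
      acc_theta <- 0; acc_phi <- 0; kept <- 0L
      template <- NULL
      for (s in seq_len(config$n_sweeps - config$burn_in)) {
        state <- gibbs_sweep(state, config, n_sweeps = 1L)
        est <- estimate_lda(state, config)
        acc_theta <- acc_theta + est$theta
        acc_phi <- acc_phi + est$phi
        kept <- kept + 1L
        template <- est
      }
      template$theta <- acc_theta / kept
      template$phi <- acc_phi / kept
      template$loglik <- state$loglik
      template
    }
  })
  # canonical topic order: descending total mass
  mass <- colSums(model$theta)
  ord <- order(mass, decreasing = TRUE)
  model$theta <- model$theta[, ord, drop = FALSE]
  model$phi <- model$phi[ord, , drop = FALSE]
  colnames(model$theta) <- paste0("topic_", seq_along(ord))
  rownames(model$phi) <- paste0("topic_", seq_along(ord))
  model
}

#' @export
print.lda_model <- function(x, ...) {
  cat(sprintf("LDA model: %d patients x %d topics over %d words (%d tokens, %d sweeps)\n",
              nrow(x$theta), ncol(x$theta), ncol(x$phi), x$n_tokens,
              length(x$loglik)))
  invisible(x)
}

#' Per-token perplexity of the training corpus under a state
#'
#' @param state An `lda_state` that has run at least one sweep.
#' @return `exp(-loglik / n_tokens)` for the most recent sweep.
#' @export
lda_perplexity <- function(state) {
  if (!length(state$loglik)) abort("run at least one sweep first")
  exp(-utils::tail(state$loglik, 1) / length(state$z))
}

#' Tidy an LDA model into a long tibble
#'
#' @param x An `lda_model`.
#' @param matrix `"phi"` (topic-word weights, default) or `"theta"`
#'   (patient-topic proportions).
#' @param ... Unused.
#' @return Long tibble: `(topic, term, phi)` or `(patient_id, topic, theta)`.
#' @export
tidy.lda_model <- function(x, matrix = c("phi", "theta"), ...) {
  matrix <- match.arg(matrix)
  if (matrix == "phi") {
    tibble::as_tibble(x$phi, rownames = "topic") |>
      tidyr::pivot_longer(-"topic", names_to = "term", values_to = "phi")
  } else {
    tibble::as_tibble(x$theta, rownames = "patient_id") |>
      tidyr::pivot_longer(-"patient_id", names_to = "topic", values_to = "theta")
  }
}

#' One-row summary of an LDA fit
#'
#' @param x An `lda_model`.
#' @param ... Unused.
#' @return Tibble with topic count, dimensions, final log-likelihood and
#'   training perplexity.
#' @export
glance.lda_model <- function(x, ...) {
  ll <- if (length(x$loglik)) utils::tail(x$loglik, 1) else NA_real_
  tibble::tibble(n_topics = ncol(x$theta), n_patients = nrow(x$theta),
                 n_terms = ncol(x$phi), n_tokens = x$n_tokens,
                 log_likelihood = ll,
                 perplexity = exp(-ll / x$n_tokens))
}

#' Plot the Gibbs log-likelihood trace of an LDA fit
#'
#' @param object An `lda_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lda_model <- function(object, ...) {
  df <- tibble::tibble(sweep = seq_along(object$loglik), loglik = object$loglik)
  ggplot2::ggplot(df, ggplot2::aes(.data$sweep, .data$loglik)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = "Gibbs sweep", y = "token log-likelihood",
                  title = "Collapsed Gibbs sampling trace") +
    ggplot2::theme_minimal()
}

#' Write theta/phi and a config sidecar to a directory
#'
#' @param model An `lda_model`.
#' @param dir Output directory (created if absent).
#' @param prefix File-name prefix (e.g. `"gene"`).
#' @return Invisibly, the paths written.
#' @export
write_lda <- function(model, dir, prefix = "lda") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p_theta <- file.path(dir, paste0(prefix, "_theta.tsv"))
  p_phi <- file.path(dir, paste0(prefix, "_phi.tsv"))
  p_json <- file.path(dir, paste0(prefix, "_lda.json"))
  write_table(tibble::as_tibble(model$theta, rownames = "patient_id"), p_theta)
  write_table(tibble::as_tibble(model$phi, rownames = "topic"), p_phi)
  jsonlite::write_json(list(config = unclass(model$config),
                            n_tokens = model$n_tokens,
                            loglik = model$loglik),
                       p_json, auto_unbox = TRUE, digits = NA)
  invisible(c(p_theta, p_phi, p_json))
}
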