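test_that("token expansion conserves counts and is deterministic under seed", {
  cfg <- lda_config(n_topics = 2, n_sweeps = 10, burn_in = 5, seed = 3)
  counts <- matrix(c(2, 0, 0, 3), 2, 2,
                   dimnames = list(c("d1", "d2"), c("w1", "w2")))
  st <- tiny_state(counts, cfg)
  expect_length(st$z, 5)
  expect_identical(rowSums(st$n_doc_topic), c(2, 3))
  expect_identical(sum(st$n_topic_word), 5L)

  st2 <- tiny_state(counts, cfg)
  expect_identical(st$z, st2$z)

  expect_error(init_lda_state(as_abundance_table(matrix(0, 1, 1,
    dimnames = list("d", "w")), "gene"), cfg), "empty corpus")
  expect_warning(init_lda_state(as_abundance_table(
    matrix(c(1, 2, 0, 0), 2, 2, byrow = TRUE,
           dimnames = list(c("d1", "d2"), c("w1", "w2"))), "gene"), cfg),
    "all-zero")
})

test_that("per-token conditional matches the brute-force collapsed-joint ratio", {
  # over several tiny corpora (<= 8 tokens, 2 topics) the sampler's
  # conditional must equal the normalized ratio of collapsed joints obtained
  # by enumerating the token's topic choices
  cfg <- lda_config(n_topics = 2, alpha = 0.7, beta = 0.3,
                    n_sweeps = 4, burn_in = 1, seed = 5)
  corpora <- list(
    matrix(c(2, 1, 0, 3), 2, 2),
    matrix(c(1, 1, 1, 1, 2, 1), 2, 3),
    matrix(c(3, 0, 1, 0, 2, 2), 3, 2)
  )
  for (cm in corpora) {
    dimnames(cm) <- list(paste0("d", seq_len(nrow(cm))),
                         paste0("w", seq_len(ncol(cm))))
    st <- tiny_state(cm, cfg)
    st <- gibbs_sweep(st, cfg, 2)
    V <- length(st$vocab)
    for (tok in seq_along(st$z)) {
      got <- token_conditional(st, tok, cfg)
      lj <- vapply(1:2, function(k) {
        z_try <- st$z
        z_try[tok] <- k
        collapsed_log_joint(z_try, st$doc, st$word, 2, V, cfg$alpha, cfg$beta)
      }, numeric(1))
      want <- exp(lj - max(lj))
      want <- want / sum(want)
      expect_equal(got, want, tolerance = 1e-10)
    }
  }
})

test_that("single-token corpus with symmetric priors has a uniform conditional", {
  cfg <- lda_config(n_topics = 2, alpha = 1, beta = 1, n_sweeps = 2,
                    burn_in = 1, seed = 1)
  st <- tiny_state(matrix(1, 1, 1, dimnames = list("d", "w")), cfg)
  expect_equal(token_conditional(st, 1, cfg), c(0.5, 0.5), tolerance = 1e-12)
})

test_that("sweeps conserve tokens and keep count matrices consistent", {
  cfg <- lda_config(n_topics = 3, n_sweeps = 10, burn_in = 2, seed = 8)
  withr::with_seed(2, {
    cm <- matrix(rpois(30, 3), 5, 6,
                 dimnames = list(paste0("d", 1:5), paste0("w", 1:6)))
  })
  cm[1, 1] <- cm[1, 1] + 1  # ensure non-zero doc
  st <- tiny_state(cm, cfg)
  total <- length(st$z)
  st2 <- withr::with_seed(1, gibbs_sweep(st, cfg, 5))
  expect_identical(length(st2$z), total)
  expect_identical(as.integer(rowSums(st2$n_doc_topic)), st2$doc_tokens)
  expect_identical(as.integer(rowSums(st2$n_topic_word)), st2$n_topic_total)
  expect_length(st2$loglik, 5)
})

test_that("estimate_lda implements the smoothed formulas exactly", {
  cfg <- lda_config(n_topics = 2, alpha = 0.5, beta = 0.25,
                    n_sweeps = 2, burn_in = 1, seed = 2)
  st <- tiny_state(matrix(c(3, 1, 0, 4), 2, 2,
                          dimnames = list(c("d1", "d2"), c("w1", "w2"))), cfg)
  # force a known count state: doc1 rows (3,1)
  st$n_doc_topic <- matrix(as.integer(c(3, 2, 1, 2)), 2, 2)
  st$doc_tokens <- c(4L, 4L)
  st$n_topic_word <- matrix(as.integer(c(2, 2, 2, 2)), 2, 2)
  st$n_topic_total <- c(4L, 4L)
  mod <- estimate_lda(st, cfg)
  # hand-computed: (3 + 0.5) / (4 + 2*0.5) = 0.7, (1 + 0.5)/5 = 0.3
  expect_equal(unname(mod$theta[1, ]), c(0.7, 0.3))
  expect_equal(rowSums(mod$theta), c(d1 = 1, d2 = 1), tolerance = 1e-12)
  expect_equal(unname(rowSums(mod$phi)), c(1, 1), tolerance = 1e-12)
  expect_true(all(mod$theta > 0) && all(mod$phi > 0))
})

test_that("fit_lda recovers planted topics and is seed-deterministic", {
  corp <- gen_lda_corpus(100, 50, 3, alpha_doc = 0.1, tokens_per_doc = 200,
                         seed = 7)
  cfg <- lda_config(n_topics = 3, n_sweeps = 200, burn_in = 100, seed = 11)
  fit <- fit_lda(corp$counts, cfg)
  expect_gte(best_perm_cosine(fit$phi, corp$truth$phi_true), 0.9)
  expect_identical(dim(fit$theta), c(100L, 3L))

  fit2 <- fit_lda(corp$counts, cfg)
  expect_identical(fit$theta, fit2$theta)
  expect_identical(fit$phi, fit2$phi)

  # log-likelihood improves from the random initialization
  expect_gt(mean(utils::tail(fit$loglik, 20)), mean(utils::head(fit$loglik, 5)))
})

test_that("tidy, glance and autoplot expose the fitted model", {
  corp <- gen_lda_corpus(12, 15, 2, tokens_per_doc = 60, seed = 3)
  cfg <- lda_config(n_topics = 2, n_sweeps = 30, burn_in = 10, seed = 4)
  fit <- fit_lda(corp$counts, cfg)
  td <- tidy(fit, "phi")
  expect_named(td, c("topic", "term", "phi"))
  expect_equal(nrow(td), 2 * 15)
  th <- tidy(fit, "theta")
  expect_equal(nrow(th), 12 * 2)
  gl <- glance(fit)
  expect_identical(gl$n_topics, 2L)
  expect_s3_class(autoplot(fit), "ggplot")
})
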