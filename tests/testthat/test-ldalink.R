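test_that("pseudo-gold selection applies the gates and balances classes", {
  fx <- link_benchmark()
  ts <- fx$ts
  expect_identical(sum(ts$label == "pos"), sum(ts$label == "neg"))
  key <- paste(fx$cor$entity_x, fx$cor$entity_y)
  pos_idx <- match(paste(ts$gene[ts$label == "pos"],
                         ts$microbe[ts$label == "pos"]), key)
  expect_true(all(abs(fx$cor$r[pos_idx]) > 0.4 & fx$cor$p[pos_idx] < 1e-5))
  neg_idx <- match(paste(ts$gene[ts$label == "neg"],
                         ts$microbe[ts$label == "neg"]), key)
  expect_true(all(abs(fx$cor$r[neg_idx]) < 0.05))

  # planted strong linear correlations are found
  lin <- fx$sim$truth$links[fx$sim$truth$links$mechanism == "linear", ]
  found <- paste(lin$gene, lin$microbe) %in%
    paste(ts$gene[ts$label == "pos"], ts$microbe[ts$label == "pos"])
  expect_gte(sum(found), 0.9 * nrow(lin))

  # determinism of the negative draw; empty-set and threshold errors
  ts2 <- build_pseudo_gold(fx$cor, seed = 103)
  expect_identical(ts$gene, ts2$gene)
  expect_error(build_pseudo_gold(fx$cor, r_pos = 1.0), "no positive pairs")
  expect_error(build_pseudo_gold(fx$cor, r_neg = 1e-9), "eligible negatives")
})

test_that("pair features concatenate the two topic columns", {
  fx <- link_benchmark()
  pair <- tibble::tibble(gene = "gene_0001", microbe = "microbe_0001")
  x <- make_features(fx$lda_g, fx$lda_m, pair)
  expect_identical(dim(x), c(1L, 10L))  # 2 * 5 topics
  expect_equal(sum(x[1, 1:5]), 1, tolerance = 1e-12)   # L1-normalized halves
  expect_equal(sum(x[1, 6:10]), 1, tolerance = 1e-12)
  # raw columns when normalization is off
  raw <- make_features(fx$lda_g, fx$lda_m, pair, normalize = FALSE)
  expect_equal(unname(raw[1, 1:5]), unname(fx$lda_g$phi[, "gene_0001"]))
  # swapping gene and microbe models swaps the halves exactly
  swapped <- make_features(fx$lda_m, fx$lda_g,
                           tibble::tibble(gene = "microbe_0001",
                                          microbe = "gene_0001"))
  expect_equal(unname(swapped[1, ]), unname(x[1, c(6:10, 1:5)]))
  expect_error(make_features(fx$lda_g, fx$lda_m,
                             tibble::tibble(gene = "nope",
                                            microbe = "microbe_0001")),
               "unknown gene")

  # degenerate column: a gene loading on one topic becomes an indicator
  phi_deg <- matrix(c(0, 1e-7, 0, 0.2, 0, 0.3), 3, 2,
                    dimnames = list(paste0("topic_", 1:3), c("gX", "gY")))
  xm <- make_features(phi_deg, fx$lda_m$phi,
                      tibble::tibble(gene = "gX", microbe = "microbe_0002"))
  expect_equal(unname(xm[1, 1:3]), c(0, 1, 0))
})

# sharply structured planted features shared by the classifier tests below
planted_features <- function(n_each = 60, K = 5, seed = 5) {
  withr::with_seed(seed, {
    mk_phi <- function(ids, hot_topic) {
      phi <- matrix(runif(K * length(ids), 0, 0.15), K,
                    dimnames = list(paste0("topic_", 1:K), ids))
      for (i in seq_along(ids)) phi[hot_topic[i], ids[i]] <- 2
      phi / rowSums(phi)
    }
    genes <- sprintf("g%03d", seq_len(2 * n_each))
    mics <- sprintf("m%03d", seq_len(2 * n_each))
    g_topic <- rep_len(1:K, 2 * n_each)
    m_topic <- c(g_topic[1:n_each],                       # matched: links
                 (g_topic[(n_each + 1):(2 * n_each)] %% K) + 1L)  # mismatched
    list(phiG = mk_phi(genes, g_topic), phiM = mk_phi(mics, m_topic),
         ts = structure(tibble::tibble(
           gene = genes, microbe = mics,
           label = factor(rep(c("pos", "neg"), each = n_each),
                          levels = c("neg", "pos"))),
           class = c("ldalink_training", class(tibble::tibble()))))
  })
}

test_that("the forest separates planted feature classes and ranks their topics", {
  pf <- planted_features()
  model <- train_link_model(pf$ts, pf$phiG, pf$phiM, n_trees = 300, seed = 6)
  acc <- mean(predict(model$rf, make_features(pf$phiG, pf$phiM, pf$ts)) ==
                pf$ts$label)
  expect_gte(acc, 0.95)
  expect_named(model$importance, c("feature", "half", "topic", "gini"))

  # same seed -> identical probabilities
  model2 <- train_link_model(pf$ts, pf$phiG, pf$phiM, n_trees = 300, seed = 6)
  expect_identical(
    predict(model$rf, make_features(pf$phiG, pf$phiM, pf$ts), type = "prob"),
    predict(model2$rf, make_features(pf$phiG, pf$phiM, pf$ts), type = "prob"))

  # shuffled labels carry no signal
  ts_null <- pf$ts
  ts_null$label <- withr::with_seed(8, sample(pf$ts$label))
  m_null <- train_link_model(ts_null, pf$phiG, pf$phiM, n_trees = 300, seed = 6)
  oob_acc <- 1 - m_null$rf$err.rate[300, "OOB"]
  expect_lt(abs(oob_acc - 0.5), 0.15)

  expect_error(train_link_model(pf$ts[pf$ts$label == "pos", ], pf$phiG, pf$phiM),
               "both classes")
})

test_that("predicted probabilities are bimodal on topic-pure planted data", {
  # when entities are strongly topic-pure the classifier's scores split into
  # a large mass near 0 and a clear mass near 1 with little in between
  sim <- gen_linked_tables(115, 200, 80, n_linear_links = 40,
                           affinity_purity = 1, noise_sd = 1.2, seed = 211)
  cg <- suppressWarnings(correlate_tables(sim$G, sim$M))
  ts <- build_pseudo_gold(cg, seed = 213)
  cfg <- lda_config(n_topics = 5, n_sweeps = 300, burn_in = 150, seed = 215,
                    average_samples = TRUE)
  lg <- fit_lda(scale_counts(sim$G), cfg)
  lm_ <- fit_lda(scale_counts(sim$M), cfg)
  model <- train_link_model(ts, lg, lm_, n_trees = 300, seed = 6)
  links <- predict_links(model)
  mid <- mean(links$probability >= 0.4 & links$probability <= 0.6)
  low <- mean(links$probability <= 0.1)
  expect_lt(mid, low)
  expect_gt(mean(links$probability >= 0.9), 0.01)  # a clear high mode exists
})

test_that("strict left-out CV keeps entities disjoint and discriminates planted links", {
  fx <- link_benchmark()
  cv <- strict_leftout_cv(fx$ts, fx$lda_g, fx$lda_m, n_repeats = 5,
                          n_trees = 300, seed = 7)
  expect_identical(nrow(cv$auc), 5L)
  expect_gte(mean(cv$auc$auc), 0.75)
  # entity removal leaves less than 90% of the labels
  expect_true(all(cv$auc$n_train < nrow(fx$ts) * 0.9))
  expect_error(strict_leftout_cv(fx$ts, fx$lda_g, fx$lda_m, test_frac = 0),
               "test_frac")
  expect_s3_class(autoplot(cv), "ggplot")
  expect_identical(glance(cv)$n_repeats, 5L)
})

test_that("predicted links exclude training pairs and rank planted links highly", {
  fx <- link_benchmark()
  model <- train_link_model(fx$ts, fx$lda_g, fx$lda_m, n_trees = 300, seed = 11)
  links <- predict_links(model)
  # training pairs absent
  expect_false(any(paste(links$gene, links$microbe) %in%
                     paste(fx$ts$gene, fx$ts$microbe)))
  # sorted by descending probability
  expect_true(all(diff(links$probability) <= 0))
  # strict > at the cut; hi_cut = 1 yields none
  expect_identical(links$is_high_confidence, links$probability > 0.95)
  expect_false(any(predict_links(model, hi_cut = 1)$is_high_confidence))
  # held-out planted couplings (entity-disjoint from training by
  # construction when not selected) concentrate in the top decile
  planted <- fx$sim$truth$links
  pk <- paste(planted$gene, planted$microbe)
  lk <- match(pk, paste(links$gene, links$microbe))
  in_pred <- !is.na(lk)
  if (any(in_pred)) {
    cut <- quantile(links$probability, 0.9)
    # held-out planted pairs are the weak threshold couplings; require
    # strong enrichment over the 10% baseline of the top decile
    expect_gte(mean(links$probability[lk[in_pred]] >= cut), 0.25)
  }
  expect_s3_class(autoplot(links), "ggplot")
})

test_that("topic features recover non-linear couplings the linear gate misses", {
  fx <- link_benchmark()
  model <- train_link_model(fx$ts, fx$lda_g, fx$lda_m, n_trees = 300, seed = 11)
  links <- predict_links(model)
  thr <- fx$sim$truth$links[fx$sim$truth$links$mechanism == "threshold", ]
  thr_key <- paste(thr$gene, thr$microbe)
  key <- paste(fx$cor$entity_x, fx$cor$entity_y)
  idx <- match(thr_key, key)
  gate_hits <- sum(abs(fx$cor$r[idx]) > 0.4 & fx$cor$p[idx] < 1e-5)
  cut <- quantile(links$probability, 0.9)
  lk <- match(thr_key, paste(links$gene, links$microbe))
  lda_hits <- sum(links$probability[lk] >= cut, na.rm = TRUE)
  expect_gt(lda_hits, gate_hits)
})
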