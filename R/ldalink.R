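#' Build a self-supervised pseudo-gold standard of gene-microbe links
#'
#' Labels are manufactured from the correlation structure itself: pairs with
#' `|r| > r_pos` and `p < p_pos` become positives (on the real cohort these
#' thresholds correspond to an FDR around 0.016), and an equal-sized seeded
#' uniform sample of near-zero pairs (`|r| < r_neg`) becomes negatives.
#'
#' @param cor_tbl Gene-microbe correlation result from [correlate_tables()]
#'   on harmonized `G` (as X) and `M` (as Y).
#' @param r_pos Absolute-correlation threshold for positives (default 0.4).
#' @param p_pos p-value threshold for positives (default 1e-5).
#' @param r_neg Absolute-correlation ceiling for negatives (default 0.05).
#' @param seed Seed for the negative sample.
#' @return Tibble of class `ldalink_training`: `(gene, microbe, label)` with
#'   `label` a factor `neg`/`pos`; thresholds kept as attribute
#'   `provenance`.
#' @export
build_pseudo_gold <- function(cor_tbl, r_pos = 0.4, p_pos = 1e-5,
                              r_neg = 0.05, seed = 1L) {
  ok <- !is.na(cor_tbl$r)
  pos <- cor_tbl[ok & abs(cor_tbl$r) > r_pos & cor_tbl$p < p_pos, ]
  if (nrow(pos) == 0) {
    abort("no positive pairs at these thresholds; review r_pos/p_pos")
  }
  neg_pool <- cor_tbl[ok & abs(cor_tbl$r) < r_neg, ]
  if (nrow(neg_pool) < nrow(pos)) {
    abort(sprintf("only %d eligible negatives for %d positives",
                  nrow(neg_pool), nrow(pos)))
  }
  neg <- withr::with_seed(seed,
    neg_pool[sample.int(nrow(neg_pool), nrow(pos)), ])
  out <- dplyr::bind_rows(
    tibble::tibble(gene = pos$entity_x, microbe = pos$entity_y, label = "pos"),
    tibble::tibble(gene = neg$entity_x, microbe = neg$entity_y, label = "neg")
  )
  out$label <- factor(out$label, levels = c("neg", "pos"))
  structure(out, class = c("ldalink_training", class(tibble::tibble())),
            provenance = list(r_pos = r_pos, p_pos = p_pos, r_neg = r_neg,
                              seed = seed))
}

#' Topic-feature vectors for gene-microbe pairs
#'
#' For each pair the feature vector is the gene's topic column of the gene
#' model's phi concatenated with the microbe's topic column of the microbe
#' model's phi — length `2 * n_topics` (20 at the default 10 topics). By
#' default each half is L1-normalized per entity so rare and abundant
#' entities are comparable; set `normalize = FALSE` for raw phi columns.
#'
#' @param phiG Gene `lda_model` (or its phi matrix).
#' @param phiM Microbe `lda_model` (or its phi matrix).
#' @param pairs Tibble/data frame with columns `gene`, `microbe`.
#' @param normalize L1-normalize each entity's topic column (default TRUE).
#' @return Numeric matrix, one row per pair, columns
#'   `gene_topic_1..K, microbe_topic_1..K`.
#' @export
make_features <- function(phiG, phiM, pairs, normalize = TRUE) {
  pg <- if (inherits(phiG, "lda_model")) phiG$phi else phiG
  pm <- if (inherits(phiM, "lda_model")) phiM$phi else phiM
  miss_g <- setdiff(unique(pairs$gene), colnames(pg))
  if (length(miss_g)) abort(paste0("unknown gene(s): ",
                                   paste(head(miss_g, 5), collapse = ", ")))
  miss_m <- setdiff(unique(pairs$microbe), colnames(pm))
  if (length(miss_m)) abort(paste0("unknown microbe(s): ",
                                   paste(head(miss_m, 5), collapse = ", ")))
  fg <- t(pg[, pairs$gene, drop = FALSE])
  fm <- t(pm[, pairs$microbe, drop = FALSE])
  if (normalize) {
    fg <- fg / rowSums(fg)
    fm <- fm / rowSums(fm)
  }
  colnames(fg) <- paste0("gene_topic_", seq_len(ncol(fg)))
  colnames(fm) <- paste0("microbe_topic_", seq_len(ncol(fm)))
  rownames(fg) <- NULL
  unname_rows <- cbind(fg, fm)
  rownames(unname_rows) <- NULL
  unname_rows
}

#' Train the random-forest link classifier
#'
#' Fits a binary random forest on the concatenated topic features of the
#' pseudo-gold pairs and reports per-feature Gini importances
#' (mean decrease in node impurity), labeled by topic half.
#'
#' @param ts Training tibble from [build_pseudo_gold()] (columns `gene`,
#'   `microbe`, `label`).
#' @param phiG,phiM Gene and microbe `lda_model`s.
#' @param n_trees Number of trees (default 500).
#' @param mtry Features tried per split (default: `sqrt(2 * n_topics)`,
#'   the randomForest classification default).
#' @param seed RNG seed.
#' @param normalize Passed to [make_features()].
#' @return List of class `link_model`: the fitted forest, `importance`
#'   tibble, the training set and feature settings.
#' @export
train_link_model <- function(ts, phiG, phiM, n_trees = 500L, mtry = NULL,
                             seed = 1L, normalize = TRUE) {
  if (length(unique(ts$label)) < 2) abort("training set must contain both classes")
  x <- make_features(phiG, phiM, ts, normalize = normalize)
  mtry <- mtry %||% max(1L, floor(sqrt(ncol(x))))
  rf <- withr::with_seed(seed,
    randomForest::randomForest(x = x, y = ts$label, ntree = n_trees,
                               mtry = mtry, importance = FALSE))
  imp <- randomForest::importance(rf, type = 2)
  importance <- tibble::tibble(
    feature = rownames(imp),
    half = ifelse(grepl("^gene_", rownames(imp)), "gene", "microbe"),
    topic = as.integer(sub(".*_topic_", "", rownames(imp))),
    gini = as.numeric(imp[, 1])
  ) |> dplyr::arrange(dplyr::desc(.data$gini))
  structure(list(rf = rf, importance = importance, training = ts,
                 phiG = if (inherits(phiG, "lda_model")) phiG$phi else phiG,
                 phiM = if (inherits(phiM, "lda_model")) phiM$phi else phiM,
                 normalize = normalize, n_trees = as.integer(n_trees),
                 seed = as.integer(seed)),
            class = "link_model")
}

#' @export
print.link_model <- function(x, ...) {
  cat(sprintf("Link classifier: %d trees, %d training pairs (%d positive)\n",
              x$n_trees, nrow(x$training), sum(x$training$label == "pos")))
  invisible(x)
}

#' Tidy the Gini importances of a link model
#'
#' @param x A `link_model`.
#' @param ... Unused.
#' @return Tibble `(feature, half, topic, gini)` sorted by importance.
#' @export
tidy.link_model <- function(x, ...) x$importance

#' Strict left-out cross-validation of the link classifier
#'
#' Per repeat: a fraction `test_frac` of the labeled pairs is held out, and
#' every remaining pair that shares a gene *or* a microbe with a held-out
#' pair is deleted from the training split (leaving slightly less than
#' `1 - test_frac` of the labels), so the model is always scored on entities
#' it has never seen. The entity-disjointness is asserted on every repeat.
#' Repeats whose entity removal empties a class are resampled (bounded
#' retries, logged).
#'
#' @param ts Training tibble from [build_pseudo_gold()].
#' @param phiG,phiM Gene and microbe `lda_model`s.
#' @param test_frac Held-out fraction per repeat (default 0.10).
#' @param n_repeats Number of repeats (default 10).
#' @param n_trees Trees per forest.
#' @param mtry Features tried per split (see [train_link_model()]).
#' @param seed Master seed.
#' @param normalize Passed to [make_features()].
#' @return List of class `link_cv`: `auc` tibble
#'   `(repeat, auc, n_train, n_test)`, pooled `roc` points tibble, and the
#'   settings.
#' @export
strict_leftout_cv <- function(ts, phiG, phiM, test_frac = 0.10,
                              n_repeats = 10L, n_trees = 500L, mtry = NULL,
                              seed = 1L, normalize = TRUE) {
  if (test_frac <= 0 || test_frac >= 1) abort("test_frac must lie in (0, 1)")
  n <- nrow(ts)
  n_test <- max(1L, round(test_frac * n))
  aucs <- vector("list", n_repeats)
  pooled <- vector("list", n_repeats)
  withr::with_seed(seed, {
    for (rep_i in seq_len(n_repeats)) {
      for (try_i in seq_len(25L)) {
        idx <- sample.int(n, n_test)
        test <- ts[idx, ]
        rest <- ts[-idx, ]
        keep <- !(rest$gene %in% test$gene | rest$microbe %in% test$microbe)
        train <- rest[keep, ]
        if (length(unique(train$label)) == 2 && length(unique(test$label)) == 2) break
        if (try_i == 25L) abort("could not draw a non-degenerate CV split")
        inform(sprintf("repeat %d: degenerate split, resampling", rep_i))
      }
      stopifnot(length(intersect(train$gene, test$gene)) == 0,
                length(intersect(train$microbe, test$microbe)) == 0)
      rf_seed <- sample.int(.Machine$integer.max, 1)
      model <- train_link_model(train, phiG, phiM, n_trees = n_trees,
                                mtry = mtry, seed = rf_seed,
                                normalize = normalize)
      xt <- make_features(phiG, phiM, test, normalize = normalize)
      prob <- predict(model$rf, xt, type = "prob")[, "pos"]
      lab <- test$label == "pos"
      aucs[[rep_i]] <- tibble::tibble(repeat_id = rep_i,
                                      auc = rank_auc(prob, lab),
                                      n_train = nrow(train),
                                      n_test = nrow(test))
      pooled[[rep_i]] <- tibble::tibble(repeat_id = rep_i, prob = prob,
                                        label = lab)
    }
  })
  scores <- dplyr::bind_rows(pooled)
  structure(list(auc = dplyr::bind_rows(aucs),
                 roc = roc_points(scores$prob, scores$label),
                 scores = scores,
                 settings = list(test_frac = test_frac, n_repeats = n_repeats,
                                 n_trees = n_trees, seed = seed)),
            class = "link_cv")
}

#' @export
print.link_cv <- function(x, ...) {
  cat(sprintf("Strict left-out CV: %d repeats, mean AUC %.3f (range %.3f-%.3f)\n",
              nrow(x$auc), mean(x$auc$auc), min(x$auc$auc), max(x$auc$auc)))
  invisible(x)
}

#' One-row CV summary
#'
#' @param x A `link_cv`.
#' @param ... Unused.
#' @return Tibble with repeat count and AUC summary statistics.
#' @export
glance.link_cv <- function(x, ...) {
  tibble::tibble(n_repeats = nrow(x$auc), mean_auc = mean(x$auc$auc),
                 sd_auc = sd(x$auc$auc), min_auc = min(x$auc$auc),
                 max_auc = max(x$auc$auc))
}

#' Pooled ROC curve of a strict left-out CV
#'
#' @param object A `link_cv`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.link_cv <- function(object, ...) {
  ggplot2::ggplot(object$roc, ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_path(colour = "steelblue") +
    ggplot2::geom_abline(linetype = "dashed", colour = "grey60") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false-positive rate", y = "true-positive rate",
                  title = sprintf("Pooled ROC, mean AUC = %.3f",
                                  mean(object$auc$auc))) +
    ggplot2::theme_minimal()
}

#' Score gene-microbe pairs with a trained link model
#'
#' Scores every (gene, microbe) pair in the two topic vocabularies,
#' excluding exact training pairs by default (set
#' `include_training = TRUE` to keep them, flagged). The probability is the
#' fraction of trees voting positive; `is_high_confidence` uses a strict
#' `probability > hi_cut` comparison. Rows are sorted by descending
#' probability, ties broken by (gene, microbe) lexicographic order.
#'
#' @param model A `link_model`.
#' @param hi_cut High-confidence probability cut (default 0.95, strict `>`).
#' @param include_training Keep training pairs in the output, flagged.
#' @param genes,microbes Optional subsets of the vocabularies to score.
#' @return Tibble of class `ldalink_links`:
#'   `(gene, microbe, probability, is_training, is_high_confidence)`.
#' @export
predict_links <- function(model, hi_cut = 0.95, include_training = FALSE,
                          genes = NULL, microbes = NULL) {
  genes <- genes %||% colnames(model$phiG)
  microbes <- microbes %||% colnames(model$phiM)
  pairs <- tidyr::expand_grid(gene = genes, microbe = microbes)
  key <- paste(pairs$gene, pairs$microbe, sep = "\r")
  tkey <- paste(model$training$gene, model$training$microbe, sep = "\r")
  is_tr <- key %in% tkey
  if (!include_training) {
    pairs <- pairs[!is_tr, ]
    is_tr <- is_tr[!is_tr]
  }
  x <- make_features(model$phiG, model$phiM, pairs, normalize = model$normalize)
  prob <- unname(predict(model$rf, x, type = "prob")[, "pos"])
  out <- tibble::tibble(gene = pairs$gene, microbe = pairs$microbe,
                        probability = as.numeric(prob),
                        is_training = is_tr,
                        is_high_confidence = !is_tr & prob > hi_cut)
  out <- dplyr::arrange(out, dplyr::desc(.data$probability), .data$gene,
                        .data$microbe)
  structure(out, class = c("ldalink_links", class(tibble::tibble())),
            hi_cut = hi_cut)
}

#' Histogram of predicted link probabilities
#'
#' The distribution is typically strongly bimodal: most pairs score near 0,
#' a clear mass near 1, and little in between.
#'
#' @param object Result of [predict_links()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ldalink_links <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$probability)) +
    ggplot2::geom_histogram(bins = 40, fill = "steelblue") +
    ggplot2::geom_vline(xintercept = attr(object, "hi_cut"),
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::labs(x = "link probability", y = "pairs") +
    ggplot2::theme_minimal()
}

#' Join predicted links with expanded cell-type expression
#'
#' Plumbing utility: annotates each predicted link with the linked gene's
#' inferred per-cell-type expression, so links can be read against the
#' cell-type composition.
#'
#' @param links Result of [predict_links()].
#' @param S_expanded Signature tibble from [expand_signatures()].
#' @return Links tibble with one `expr_<cell_type>` column per cell type.
#' @export
join_links_with_celltypes <- function(links, S_expanded) {
  S <- sig_matrix(S_expanded)
  shared <- intersect(unique(links$gene), colnames(S))
  expr <- tibble::as_tibble(t(S[, shared, drop = FALSE]), rownames = "gene")
  names(expr)[-1] <- paste0("expr_", names(expr)[-1])
  dplyr::left_join(tibble::as_tibble(links), expr, by = "gene")
}
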