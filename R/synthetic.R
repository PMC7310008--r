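#' Generate a planted-topic LDA corpus with retained truth
#'
#' Draws topic-word distributions with near-disjoint supports (each topic
#' concentrates its mass on its own vocabulary block), document-topic
#' proportions from a symmetric Dirichlet, and token counts from the
#' document-level multinomial `tokens_per_doc * (theta %*% phi)` — the
#' generative direction of the model the sampler inverts.
#'
#' `topic_sparsity` is the fraction of the vocabulary forming each topic's
#' exclusive support block (default `1 / n_topics`, a full partition);
#' `topic_overlap` spreads that fraction of each topic's mass uniformly over
#' the rest of the vocabulary.
#'
#' @param n_docs,n_vocab,n_topics Corpus dimensions.
#' @param alpha_doc Symmetric Dirichlet for document-topic draws.
#' @param topic_sparsity Support-block fraction per topic.
#' @param topic_overlap Off-support mass fraction per topic.
#' @param tokens_per_doc Tokens drawn per document.
#' @param seed RNG seed.
#' @return List: `counts` (gene-kind integer abundance tibble ready for
#'   [fit_lda()]) and `truth` (`theta_true`, `phi_true`, `seed`).
#' @export
gen_lda_corpus <- function(n_docs, n_vocab, n_topics, alpha_doc = 0.1,
                           topic_sparsity = NULL, topic_overlap = 0.02,
                           tokens_per_doc = 200L, seed = 1L) {
  if (n_topics > n_vocab) abort("need n_topics <= n_vocab")
  topic_sparsity <- topic_sparsity %||% (1 / n_topics)
  block <- max(1L, floor(topic_sparsity * n_vocab))
  if (block * n_topics > n_vocab) {
    abort("infeasible topic_sparsity: disjoint supports exceed the vocabulary")
  }
  withr::with_seed(seed, {
    phi <- matrix(0, n_topics, n_vocab)
    for (k in seq_len(n_topics)) {
      sup <- seq((k - 1) * block + 1, k * block)
      w <- rgamma(block, shape = 5)
      phi[k, sup] <- (1 - topic_overlap) * w / sum(w)
      if (topic_overlap > 0) {
        phi[k, -sup] <- topic_overlap / (n_vocab - block)
      }
    }
    theta <- rdirichlet(n_docs, rep(alpha_doc, n_topics))
    probs <- theta %*% phi
    counts <- t(vapply(seq_len(n_docs),
                       function(d) rmultinom(1, tokens_per_doc, probs[d, ])[, 1],
                       integer(n_vocab)))
    dimnames(counts) <- list(sprintf("doc_%03d", seq_len(n_docs)),
                             sprintf("word_%04d", seq_len(n_vocab)))
    dimnames(theta) <- list(rownames(counts), paste0("topic_", seq_len(n_topics)))
    dimnames(phi) <- list(paste0("topic_", seq_len(n_topics)), colnames(counts))
    list(counts = as_abundance_table(counts + 0.0, kind = "gene",
                                     id_col = "patient_id"),
         truth = list(theta_true = theta, phi_true = phi, seed = seed))
  })
}

#' Generate paired gene and microbe tables with planted links
#'
#' Latent patient topics drive both tables: every gene and every microbe
#' belongs to one latent topic and its abundance follows that topic's
#' per-patient weight with multiplicative log-normal noise. On top of the
#' baseline, two coupling mechanisms are planted between topic-matched
#' gene-microbe pairs:
#'
#' * `linear` — the gene tracks the microbe's abundance plus Gaussian noise
#'   calibrated so the pair's Pearson correlation is about `target_r`
#'   (default 0.8, comfortably past the pseudo-gold gate at ~115 patients);
#' * `threshold` — the gene is expressed at a high level only in patients
#'   where the microbe exceeds its 70th percentile, with noise calibrated to
#'   a point-biserial correlation of about `target_r_threshold` (default
#'   0.3, i.e. below the linear positive gate), a deliberately non-linear
#'   response such as an immune cell sensing a microbe.
#'
#' Unlinked entities are conditionally independent given the topics. Linked
#' entities are pairwise distinct, so entity-disjoint validation splits
#' exist by construction.
#'
#' @param n_patients Number of patients (default 115).
#' @param n_genes,n_microbes Table widths.
#' @param n_linear_links,n_threshold_links Planted couplings per mechanism.
#' @param n_topics Latent topic count.
#' @param affinity_purity Fraction of each entity's topic affinity placed on
#'   its main topic; the rest is an individual Dirichlet draw.
#' @param noise_sd Log-normal per-cell noise SD on baseline abundances.
#' @param target_r Pearson correlation aimed for by linear links.
#' @param target_r_threshold Correlation aimed for by threshold links.
#' @param seed RNG seed.
#' @return List: `G`, `M` (abundance tibbles) and `truth` (theta, per-entity
#'   topic assignments, and a `links` tibble
#'   `(gene, microbe, mechanism)`).
#' @export
gen_linked_tables <- function(n_patients = 115L, n_genes, n_microbes,
                              n_linear_links = 30L, n_threshold_links = 0L,
                              n_topics = 5L, affinity_purity = 0.3,
                              noise_sd = 0.8,
                              target_r = 0.8, target_r_threshold = 0.3,
                              seed = 1L) {
  n_links <- n_linear_links + n_threshold_links
  if (n_links > min(n_genes, n_microbes)) {
    abort("more planted links than distinct genes or microbes")
  }
  withr::with_seed(seed, {
    K <- n_topics
    theta <- rdirichlet(n_patients, rep(0.3, K))
    pid <- sprintf("patient_%03d", seq_len(n_patients))
    gene_topic <- rep_len(seq_len(K), n_genes)
    microbe_topic <- rep_len(seq_len(K), n_microbes)
    # each entity follows a mixed topic affinity: `affinity_purity` of its
    # mass on its main topic, the rest on an individual Dirichlet draw, so
    # two entities of one topic share only part of their driving signal
    mix_affinity <- function(mains) {
      d <- t(rdirichlet(length(mains), rep(0.3, K)))
      a <- (1 - affinity_purity) * d
      a[cbind(mains, seq_along(mains))] <-
        a[cbind(mains, seq_along(mains))] + affinity_purity
      a
    }
    Ag <- mix_affinity(gene_topic)        # K x n_genes
    Am <- mix_affinity(microbe_topic)     # K x n_microbes
    gmul <- runif(n_genes, 0.5, 1.5)
    mmul <- runif(n_microbes, 0.5, 1.5)
    G <- (theta %*% Ag) * rep(gmul, each = n_patients) * 100 *
      exp(matrix(rnorm(n_patients * n_genes, 0, noise_sd), n_patients))
    M <- (theta %*% Am) * rep(mmul, each = n_patients) * 100 *
      exp(matrix(rnorm(n_patients * n_microbes, 0, noise_sd), n_patients))
    gene_ids <- sprintf("gene_%04d", seq_len(n_genes))
    microbe_ids <- sprintf("microbe_%04d", seq_len(n_microbes))

    # pairwise-distinct linked entities, topic-matched within each pair;
    # pairs are allocated round-robin over topics within capacity
    shuffle <- function(x) if (length(x) > 1) sample(x) else x
    gene_pool <- lapply(split(seq_len(n_genes), gene_topic), shuffle)
    microbe_pool <- lapply(split(seq_len(n_microbes), microbe_topic), shuffle)
    caps <- pmin(lengths(gene_pool), lengths(microbe_pool))
    if (sum(caps) < n_links) {
      abort("not enough topic-matched gene-microbe pairs for the links")
    }
    pair_topic <- integer(0)
    left <- caps
    while (length(pair_topic) < n_links) {
      avail <- which(left > 0)
      take <- avail[seq_len(min(length(avail), n_links - length(pair_topic)))]
      pair_topic <- c(pair_topic, take)
      left[take] <- left[take] - 1L
    }
    rows <- vector("list", n_links)
    for (i in seq_len(n_links)) {
      k <- pair_topic[i]
      g <- gene_pool[[k]][1]
      gene_pool[[k]] <- gene_pool[[k]][-1]
      m <- microbe_pool[[k]][1]
      microbe_pool[[k]] <- microbe_pool[[k]][-1]
      mech <- if (i <= n_linear_links) "linear" else "threshold"
      mprof <- M[, m]
      if (mech == "linear") {
        sigma <- sd(mprof) * sqrt(1 / target_r^2 - 1)
        G[, g] <- pmax(0, mprof + rnorm(n_patients, 0, sigma) + 3 * sigma)
      } else {
        # step response: low baseline, high level above the 70th percentile,
        # log-normal noise solved so cor(gene, microbe) ~ target_r_threshold
        hi <- mprof > quantile(mprof, 0.7)
        base <- 5 + 30 * hi
        w <- (stats::cov(base, mprof)^2 /
                (target_r_threshold^2 * stats::var(mprof)) + mean(base)^2) /
          mean(base^2)
        tau <- sqrt(max(log(max(w, 1)), 0))
        # the planted property is a coupling the linear screen misses:
        # redraw the noise (bounded) if the realized |r| reaches the gate
        for (try_i in seq_len(20L)) {
          gprof <- base * exp(rnorm(n_patients, 0, tau))
          if (abs(cor(gprof, mprof)) < 0.4) break
        }
        G[, g] <- gprof
      }
      rows[[i]] <- tibble::tibble(gene = gene_ids[g], microbe = microbe_ids[m],
                                  mechanism = mech)
    }
    links <- dplyr::bind_rows(rows)
    dimnames(G) <- list(pid, gene_ids)
    dimnames(M) <- list(pid, microbe_ids)
    list(G = as_abundance_table(G, kind = "gene"),
         M = as_abundance_table(M, kind = "microbe"),
         truth = list(theta_true = theta,
                      gene_topics = setNames(gene_topic, gene_ids),
                      microbe_topics = setNames(microbe_topic, microbe_ids),
                      gene_affinity = `colnames<-`(Ag, gene_ids),
                      microbe_affinity = `colnames<-`(Am, microbe_ids),
                      links = links, seed = seed))
  })
}

#' Generate synthetic cell-type mixtures and a signature panel
#'
#' Builds a marker-block signature matrix (each cell type over-expresses its
#' own block of signature genes against a low common background), draws
#' mixing fractions from a Dirichlet, and emits the bulk profiles
#' `G = F S'` plus additive Gaussian noise scaled to `noise_sd` times the
#' mean signal.
#'
#' @param n_patients,n_cell_types,n_sig_genes Dimensions
#'   (`n_sig_genes >= 5 * n_cell_types` for conditioning).
#' @param noise_sd Noise level as a fraction of the mean signal.
#' @param alpha_frac Dirichlet concentration for the mixing fractions.
#' @param seed RNG seed.
#' @return List: `G` (gene abundance tibble over the signature genes),
#'   `signature` ([signature_matrix()]), `F_true` (matrix), and `truth`
#'   (includes the signature's condition number).
#' @export
gen_mixtures <- function(n_patients, n_cell_types, n_sig_genes,
                         noise_sd = 0.1, alpha_frac = 1, seed = 1L) {
  if (n_sig_genes < 5 * n_cell_types) {
    abort("need n_sig_genes >= 5 * n_cell_types for a well-conditioned panel")
  }
  withr::with_seed(seed, {
    block <- n_sig_genes %/% n_cell_types
    S <- matrix(runif(n_cell_types * n_sig_genes, 0, 0.5),
                n_cell_types, n_sig_genes)
    for (f in seq_len(n_cell_types)) {
      sup <- seq((f - 1) * block + 1, f * block)
      S[f, sup] <- S[f, sup] + 6 + rgamma(length(sup), shape = 2)
    }
    dimnames(S) <- list(sprintf("cell_%02d", seq_len(n_cell_types)),
                        sprintf("sig_gene_%04d", seq_len(n_sig_genes)))
    F_true <- rdirichlet(n_patients, rep(alpha_frac, n_cell_types))
    dimnames(F_true) <- list(sprintf("patient_%03d", seq_len(n_patients)),
                             rownames(S))
    G0 <- F_true %*% S
    G <- G0 + matrix(rnorm(length(G0), 0, noise_sd * mean(G0)), nrow(G0))
    G[G < 0] <- 0
    dimnames(G) <- dimnames(G0)
    list(G = as_abundance_table(G, kind = "gene"),
         signature = signature_matrix(tibble::as_tibble(S, rownames = "cell_type")),
         F_true = F_true,
         truth = list(F_true = F_true, S_true = S,
                      condition_number = kappa(S, exact = TRUE), seed = seed))
  })
}

#' Write a synthetic truth object as JSON (+ TSV link list)
#'
#' @param truth A `truth` list from one of the generators.
#' @param dir Output directory.
#' @param prefix File-name prefix.
#' @return Invisibly, the paths written.
#' @export
write_truth <- function(truth, dir, prefix = "truth") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p_json <- file.path(dir, paste0(prefix, ".json"))
  ser <- lapply(truth, function(x) if (is.matrix(x)) unclass(as.data.frame(x)) else x)
  jsonlite::write_json(ser, p_json, auto_unbox = TRUE, digits = NA)
  paths <- p_json
  if (!is.null(truth$links)) {
    p_links <- file.path(dir, paste0(prefix, "_links.tsv"))
    write_table(truth$links, p_links)
    paths <- c(paths, p_links)
  }
  invisible(paths)
}
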