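# Small programmatic fixtures shared across test files.

toy_table <- function(kind = "microbe", n = 4, m = 3, seed = 42, prefix = "t") {
  withr::with_seed(seed, {
    vals <- matrix(round(runif(n * m, 0, 50), 3), n, m,
                   dimnames = list(sprintf("p%02d", seq_len(n)),
                                   paste0(prefix, seq_len(m))))
    as_abundance_table(vals, kind = kind)
  })
}

# tiny deterministic sampler state for oracle checks
tiny_state <- function(counts_mat, config, seed = 1) {
  counts <- as_abundance_table(counts_mat + 0.0, kind = "gene")
  init_lda_state(counts, config)
}

# brute-force collapsed joint P(Z, W; alpha, beta) over an explicit token
# assignment, via the Dirichlet-multinomial Delta-function form
collapsed_log_joint <- function(z, doc, word, K, V, alpha, beta) {
  log_delta <- function(x) sum(lgamma(x)) - lgamma(sum(x))
  ll <- 0
  for (k in seq_len(K)) {
    nk <- vapply(seq_len(V), function(v) sum(z == k & word == v), numeric(1))
    ll <- ll + log_delta(nk + beta) - log_delta(rep(beta, V))
  }
  for (d in unique(doc)) {
    nd <- vapply(seq_len(K), function(k) sum(doc == d & z == k), numeric(1))
    ll <- ll + log_delta(nd + alpha) - log_delta(rep(alpha, K))
  }
  ll
}

# hand-rolled BH step-up (independent oracle for bh_adjust)
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  out <- numeric(m)
  out[o] <- pmin(q, 1)
  out
}

# direct evaluation of the product-moment correlation formula
pearson_oracle <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) /
    (sqrt(sum((x - mean(x))^2)) * sqrt(sum((y - mean(y))^2)))
}

best_perm_cosine <- function(phi_est, phi_true) {
  cos <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  K <- nrow(phi_true)
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out <- c(out, list(c(v[i], p)))
    }
    out
  }
  max(vapply(perms(seq_len(K)), function(p) {
    mean(vapply(seq_len(K), function(k) cos(phi_est[k, ], phi_true[p[k], ]),
                numeric(1)))
  }, numeric(1)))
}

# The link-prediction benchmark: 115 patients, 400 genes x 150 microbes,
# 120 linear + 20 threshold planted couplings, LDA fit at the latent
# dimension with posterior-averaged estimates. Built once per test run and
# shared across test files.
link_benchmark_env <- new.env(parent = emptyenv())
link_benchmark <- function() {
  if (is.null(link_benchmark_env$fix)) {
    sim <- gen_linked_tables(115, 400, 150, n_linear_links = 120,
                             n_threshold_links = 20, seed = 101)
    cg <- suppressWarnings(correlate_tables(sim$G, sim$M))
    cfg <- lda_config(n_topics = 5, n_sweeps = 500, burn_in = 250, seed = 9,
                      average_samples = TRUE)
    link_benchmark_env$fix <- list(
      sim = sim, cor = cg,
      ts = build_pseudo_gold(cg, seed = 103),
      lda_g = fit_lda(scale_counts(sim$G), cfg),
      lda_m = fit_lda(scale_counts(sim$M), cfg)
    )
  }
  link_benchmark_env$fix
}
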