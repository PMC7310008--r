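#' Pipeline configuration
#'
#' One structured object holds every stage's settings plus a single master
#' seed; each stage derives its own seed deterministically from
#' `(master_seed, stage name)`, so one integer reproduces the whole run.
#' Round-trips losslessly through YAML via [write_config()] /
#' [read_config()].
#'
#' @param gene_table,microbe_table Paths to input TSVs (`NULL` to simulate).
#' @param master_seed Master RNG seed.
#' @param lda_genes,lda_microbes Per-table [lda_config()] overrides (lists
#'   of fields).
#' @param cor_method Correlation method for the pseudo-gold standard.
#' @param r_pos,p_pos,r_neg Pseudo-gold thresholds.
#' @param n_trees Random-forest size.
#' @param test_frac,n_repeats Strict left-out CV settings.
#' @param hi_cut High-confidence probability cut.
#' @param net_cutoff_raw,net_cutoff_topic Co-abundance edge cutoffs for the
#'   raw-abundance and topic-space networks.
#' @param module_method Community-detection algorithm.
#' @param sim Simulation settings used when no input paths are given
#'   (passed to [gen_linked_tables()]).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(gene_table = NULL, microbe_table = NULL,
                            master_seed = 1L,
                            lda_genes = list(), lda_microbes = list(),
                            cor_method = "pearson",
                            r_pos = 0.4, p_pos = 1e-5, r_neg = 0.05,
                            n_trees = 500L, test_frac = 0.10, n_repeats = 10L,
                            hi_cut = 0.95,
                            net_cutoff_raw = 0.3, net_cutoff_topic = 0.8,
                            module_method = "edge_betweenness",
                            sim = list(n_patients = 115L, n_genes = 300L,
                                       n_microbes = 60L, n_linear_links = 30L,
                                       n_threshold_links = 10L)) {
  structure(list(gene_table = gene_table, microbe_table = microbe_table,
                 master_seed = as.integer(master_seed),
                 lda_genes = lda_genes, lda_microbes = lda_microbes,
                 cor_method = cor_method,
                 r_pos = r_pos, p_pos = p_pos, r_neg = r_neg,
                 n_trees = as.integer(n_trees), test_frac = test_frac,
                 n_repeats = as.integer(n_repeats), hi_cut = hi_cut,
                 net_cutoff_raw = net_cutoff_raw,
                 net_cutoff_topic = net_cutoff_topic,
                 module_method = module_method, sim = sim),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param path YAML path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

stage_lda_config <- function(overrides, seed) {
  defaults <- list(n_topics = 10L, alpha = 0.5, beta = 0.1,
                   n_sweeps = 1000L, burn_in = 500L)
  args <- utils::modifyList(defaults, overrides)
  args$seed <- seed
  do.call(lda_config, args)
}

#' Run the full pipeline
#'
#' Orchestrates simulate (when no input paths are configured) -> count
#' scaling -> LDA on genes and microbes -> gene-microbe correlation ->
#' pseudo-gold construction -> strict left-out CV -> link prediction ->
#' microbe networks (raw and topic space, with module detection), writing
#' every stage's TSV/JSON outputs plus a machine-readable run manifest into
#' `out_dir`. Fully deterministic given `config$master_seed`.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created).
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package_version = as.character(utils::packageVersion("ldalink")),
                   master_seed = config$master_seed, stages = list())
  note <- function(stage, files, rows) {
    manifest$stages[[stage]] <<- list(files = as.character(files),
                                      seed = derive_seed(config$master_seed, stage),
                                      rows = rows)
    message(sprintf("[%s] done (%s row(s))", stage,
                    paste(rows, collapse = "/")))
  }

  # stage 1: inputs
  if (is.null(config$gene_table)) {
    sim_args <- config$sim
    sim_args$seed <- derive_seed(config$master_seed, "simulate")
    sim <- do.call(gen_linked_tables, sim_args)
    G <- sim$G; M <- sim$M
    write_table(G, file.path(out_dir, "G.tsv"))
    write_table(M, file.path(out_dir, "M.tsv"))
    write_truth(sim$truth, out_dir, "truth")
    note("simulate", c("G.tsv", "M.tsv", "truth.json"), c(nrow(G), nrow(M)))
  } else {
    G <- load_table(config$gene_table, "gene")
    M <- load_table(config$microbe_table, "microbe")
    hm <- harmonize(list(G, M))
    G <- hm[[1]]; M <- hm[[2]]
    note("load", c(config$gene_table, config$microbe_table),
         c(nrow(G), nrow(M)))
  }

  # stage 2: LDA per table
  cfg_g <- stage_lda_config(config$lda_genes, derive_seed(config$master_seed, "lda_genes"))
  cfg_m <- stage_lda_config(config$lda_microbes, derive_seed(config$master_seed, "lda_microbes"))
  lda_g <- fit_lda(scale_counts(G), cfg_g)
  lda_m <- fit_lda(scale_counts(M), cfg_m)
  note("lda_genes", write_lda(lda_g, out_dir, "gene"), nrow(lda_g$theta))
  note("lda_microbes", write_lda(lda_m, out_dir, "microbe"), nrow(lda_m$theta))

  # stage 3: gene-microbe correlation
  cor_gm <- correlate_tables(G, M, method = config$cor_method)
  write_table(cor_gm, file.path(out_dir, "correlations.tsv"))
  note("correlate", "correlations.tsv", nrow(cor_gm))

  # stage 4: pseudo-gold standard
  ts <- build_pseudo_gold(cor_gm, r_pos = config$r_pos, p_pos = config$p_pos,
                          r_neg = config$r_neg,
                          seed = derive_seed(config$master_seed, "pseudo_gold"))
  write_table(ts, file.path(out_dir, "training_set.tsv"))
  note("pseudo_gold", "training_set.tsv", nrow(ts))

  # stage 5: strict left-out CV
  cv <- strict_leftout_cv(ts, lda_g, lda_m, test_frac = config$test_frac,
                          n_repeats = config$n_repeats,
                          n_trees = config$n_trees,
                          seed = derive_seed(config$master_seed, "cv"))
  write_table(cv$auc, file.path(out_dir, "cv_auc.tsv"))
  write_table(cv$roc, file.path(out_dir, "cv_roc.tsv"))
  note("cv", c("cv_auc.tsv", "cv_roc.tsv"), nrow(cv$auc))

  # stage 6: final model + link prediction
  model <- train_link_model(ts, lda_g, lda_m, n_trees = config$n_trees,
                            seed = derive_seed(config$master_seed, "train"))
  write_table(model$importance, file.path(out_dir, "importances.tsv"))
  note("train", "importances.tsv", nrow(model$importance))
  links <- predict_links(model, hi_cut = config$hi_cut)
  write_table(links, file.path(out_dir, "links.tsv"))
  note("predict", "links.tsv", nrow(links))

  # stage 7: co-abundance networks
  net_raw <- build_network(M, cutoff = config$net_cutoff_raw)
  net_raw <- detect_modules(net_raw, config$module_method,
                            seed = derive_seed(config$master_seed, "network_raw"))
  net_raw <- label_modules_with_topics(net_raw, lda_m)
  net_topic <- build_network(lda_m, cutoff = config$net_cutoff_topic)
  net_topic <- detect_modules(net_topic, config$module_method,
                              seed = derive_seed(config$master_seed, "network_topic"))
  net_topic <- label_modules_with_topics(net_topic, lda_m)
  note("network_raw", write_network(net_raw, out_dir, "network_raw"),
       nrow(net_raw$edges))
  note("network_topic", write_network(net_topic, out_dir, "network_topic"),
       nrow(net_topic$edges))

  manifest$config <- unclass(config)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(G = G, M = M, lda_genes = lda_g, lda_microbes = lda_m,
                 correlations = cor_gm, training = ts, cv = cv, model = model,
                 links = links, network_raw = net_raw,
                 network_topic = net_topic, manifest = manifest))
}
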