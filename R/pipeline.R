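# End-to-end orchestration: preprocess -> embeddings (gene, expression,
# co-expression network) -> VAE -> cell graph -> transformer branch -> GAT
# branch -> adaptive fusion -> evaluation.

#' Pipeline configuration
#'
#' Nested per-stage settings with desk-scale defaults (300 cells x 200
#' genes, 16-dimensional embeddings, 1 transformer block, 2 GAT layers).
#' Every stage derives its own seed from the global `seed`, so a rerun with
#' the same config reproduces the report exactly.
#'
#' @param seed global integer seed.
#' @param simulate a [synthetic_config()] used when no dataset is passed to
#'   [run_pipeline()]; its seed is overridden by the derived stage seed.
#' @param n_bins expression bin tokens (including the zero token).
#' @param embedding_dim shared dimension of the gene / expression /
#'   network embedding streams.
#' @param scale_per_cell per-cell depth scaling before the log transform.
#' @param gene_subset_n optional: restrict token sequences to the top-n
#'   most variable genes.
#' @param coexpr_neighbors per-gene neighbor budget of the co-expression
#'   network.
#' @param walk,skipgram,vae,graph,performer,gat,fusion stage option lists;
#'   see the field defaults in the function definition.
#' @param perf_metric metric behind the adaptive fusion weights:
#'   validation `"accuracy"` (default) or `"nmi"`.
#' @param validation_fraction stratified holdout fraction.
#' @param mode which views to run: `"full"` (alias
#'   `"cell_graph+spatiotemporal"`), `"temporal"` (transformer without the
#'   network embedding stream), `"cell_graph"` (GAT branch alone) or
#'   `"cell_graph+temporal"` (fusion, transformer without network stream).
#' @param output_dir optional directory for intermediate artifacts and the
#'   run manifest.
#' @param verbose print per-stage progress and timings.
#' @export
pipeline_config <- function(seed = 1,
                            simulate = synthetic_config(),
                            n_bins = 5,
                            embedding_dim = 16,
                            scale_per_cell = FALSE,
                            gene_subset_n = NULL,
                            coexpr_neighbors = 10,
                            walk = list(p = 2, q = 0.5, walk_length = 20,
                                        walks_per_node = 5),
                            skipgram = list(epochs = 5, negatives = 5,
                                            learning_rate = 0.05,
                                            max_pairs_per_gene = 20,
                                            window = 3,
                                            node_epochs = 3),
                            vae = list(hidden_dim = 128, latent_dim = 16,
                                       alpha_vae = 0.99, epochs = 600,
                                       learning_rate = 3e-3),
                            graph = list(K = 15, alpha = 0.25,
                                         prune_quantile = 0),
                            performer = list(layers = 1, heads = 2,
                                             feature_count = 32,
                                             hidden_dim = 32, epochs = 60,
                                             learning_rate = 8e-3,
                                             batch_size = 120),
                            gat = list(layers = 2, heads = 4,
                                       hidden_dim = 16, epochs = 150,
                                       learning_rate = 5e-3),
                            fusion = "adaptive",
                            perf_metric = c("accuracy", "nmi"),
                            validation_fraction = 0.2,
                            mode = "full",
                            output_dir = NULL,
                            verbose = FALSE) {
  mode <- match.arg(mode, c("full", "temporal", "cell_graph",
                            "cell_graph+temporal",
                            "cell_graph+spatiotemporal"))
  perf_metric <- match.arg(perf_metric)
  if (!fusion %in% c("adaptive", "mlp"))
    stop("fusion must be 'adaptive' or 'mlp'")
  structure(as.list(environment()), class = "PipelineConfig")
}

stage_msg <- function(verbose, t0, what) {
  if (verbose)
    message(sprintf("[%6.1fs] %s", as.numeric(Sys.time()) - t0, what))
}

#' Run the full multi-view pipeline
#'
#' Executes preprocessing, the embedding streams, the VAE and cell graph,
#' the transformer and GAT branches, adaptive fusion and evaluation on the
#' validation split. Which pieces run is controlled by `config$mode`.
#'
#' @param config a [pipeline_config()].
#' @param data optional `LabeledDataset` (or `RawCountMatrix` with labels);
#'   simulated from `config$simulate` when missing.
#' @return List of class `PipelineResult`: the validation
#'   `EvaluationReport`, fused and per-branch `ClassProbabilities`, branch
#'   validation accuracies, fusion weights, and the split.
#' @export
run_pipeline <- function(config, data = NULL) {
  stopifnot(inherits(config, "PipelineConfig"))
  t0 <- as.numeric(Sys.time())
  use_performer <- config$mode != "cell_graph"
  use_gat <- config$mode != "temporal"
  use_spatial <- config$mode %in% c("full", "cell_graph+spatiotemporal")

  if (is.null(data)) {
    sim <- config$simulate
    sim$seed <- derive_seed(config$seed, 1L)
    data <- simulate_counts(sim)
    stage_msg(config$verbose, t0, "simulated dataset")
  }
  raw <- if (inherits(data, "LabeledDataset")) data$raw else data
  labels <- if (inherits(data, "LabeledDataset")) data$labels else raw$labels
  if (is.null(labels)) stop("per-cell labels are required for training")

  norm <- log_normalize(raw, scale_per_cell = config$scale_per_cell)
  binned <- bin_expression(norm, n_bins = config$n_bins)
  split <- holdout_split(labels, config$validation_fraction,
                         seed = derive_seed(config$seed, 2L))
  stage_msg(config$verbose, t0, "preprocessed counts")

  A_fit <- NULL; B_fit <- NULL
  net <- NULL; spatial_tab <- NULL; vae_fit <- NULL; graph <- NULL

  if (use_performer) {
    net <- build_coexpression_network(norm, config$coexpr_neighbors)
    gene_subset <- if (!is.null(config$gene_subset_n))
      top_variable_genes(norm, config$gene_subset_n)
    corpus <- build_corpus(binned, net,
                           max_pairs_per_gene =
                             config$skipgram$max_pairs_per_gene,
                           seed = derive_seed(config$seed, 3L))
    gene_tab <- train_skipgram(corpus, dim = config$embedding_dim,
                               epochs = config$skipgram$epochs,
                               negatives = config$skipgram$negatives,
                               learning_rate =
                                 config$skipgram$learning_rate,
                               seed = derive_seed(config$seed, 4L))
    stage_msg(config$verbose, t0, "trained gene embeddings")
    if (use_spatial) {
      wcfg <- random_walk_config(p = config$walk$p, q = config$walk$q,
                                 walk_length = config$walk$walk_length,
                                 walks_per_node =
                                   config$walk$walks_per_node,
                                 seed = derive_seed(config$seed, 5L))
      walks <- generate_walks(net, wcfg)
      spatial_tab <- train_node_embeddings(
        walks, dim = config$embedding_dim,
        window = config$skipgram$window,
        epochs = config$skipgram$node_epochs,
        negatives = config$skipgram$negatives,
        learning_rate = config$skipgram$learning_rate,
        seed = derive_seed(config$seed, 6L),
        vocabulary = binned$gene_ids)
      stage_msg(config$verbose, t0, "trained network (spatial) embeddings")
    }
    expr_tab <- expression_embedding_table(config$n_bins,
                                           dim = config$embedding_dim,
                                           seed = derive_seed(config$seed,
                                                              7L))
    seqs <- assemble_token_sequences(binned, gene_tab, expr_tab,
                                     spatial_tab,
                                     gene_subset = gene_subset)
    pcfg <- performer_config(model_dim = config$embedding_dim,
                             layers = config$performer$layers,
                             heads = config$performer$heads,
                             feature_count = config$performer$feature_count,
                             hidden_dim = config$performer$hidden_dim,
                             epochs = config$performer$epochs,
                             learning_rate =
                               config$performer$learning_rate,
                             batch_size = config$performer$batch_size,
                             seed = derive_seed(config$seed, 8L))
    A_fit <- train_performer(seqs, labels, split, pcfg)
    stage_msg(config$verbose, t0,
              sprintf("trained transformer branch (val acc %.3f)",
                      A_fit$perf))
  }

  if (use_gat) {
    vcfg <- vae_config(input_dim = ncol(norm$values),
                       hidden_dim = config$vae$hidden_dim,
                       latent_dim = config$vae$latent_dim,
                       alpha_vae = config$vae$alpha_vae,
                       epochs = config$vae$epochs,
                       learning_rate = config$vae$learning_rate,
                       seed = derive_seed(config$seed, 9L))
    vae_fit <- train_vae(norm, vcfg)
    stage_msg(config$verbose, t0, "trained VAE")
    graph <- build_knn_graph(vae_fit$latent$mu, K = config$graph$K,
                             config = exp_mah_config(config$graph$alpha))
    graph <- prune_graph(graph, config$graph$prune_quantile)
    gcfg <- gat_config(layers = config$gat$layers, heads = config$gat$heads,
                       hidden_dim = config$gat$hidden_dim,
                       epochs = config$gat$epochs,
                       learning_rate = config$gat$learning_rate,
                       seed = derive_seed(config$seed, 10L))
    B_fit <- train_gat(graph, vae_fit$latent$mu, labels, split, gcfg)
    stage_msg(config$verbose, t0,
              sprintf("trained GAT branch (val acc %.3f)", B_fit$perf))
  }

  branch_perf <- function(fit) {
    if (config$perf_metric == "accuracy") return(fit$perf)
    nmi(predicted_labels(fit$probs)[split$validation],
        labels[split$validation])
  }
  if (use_performer && use_gat) {
    if (config$fusion == "adaptive") {
      w <- fusion_weights(branch_perf(A_fit), branch_perf(B_fit))
      fused <- fuse(A_fit$probs, B_fit$probs, w)
    } else {
      w <- NULL
      fused <- mlp_fuse(A_fit$probs, B_fit$probs, labels, split,
                        seed = derive_seed(config$seed, 11L))
    }
  } else {
    w <- NULL
    fused <- if (use_performer) A_fit$probs else B_fit$probs
  }
  pred <- predicted_labels(fused)
  report <- evaluate_labels(pred[split$validation],
                            labels[split$validation],
                            mode = "supervised")
  stage_msg(config$verbose, t0,
            sprintf("done: ACC %.3f NMI %.3f ARI %.3f",
                    report$acc, report$nmi, report$ari))

  result <- structure(
    list(report = report, fused = fused,
         performer = A_fit, gat = B_fit,
         perf_a = if (!is.null(A_fit)) A_fit$perf,
         perf_b = if (!is.null(B_fit)) B_fit$perf,
         weights = w, split = split, labels = labels,
         mode = config$mode, config = config),
    class = "PipelineResult")
  if (!is.null(config$output_dir))
    write_pipeline_artifacts(result, raw, net, vae_fit, graph,
                             config$output_dir)
  result
}

#' @export
print.PipelineResult <- function(x, ...) {
  cat("PipelineResult (mode:", x$mode, ")\n")
  print(x$report)
  if (!is.null(x$perf_a)) cat(sprintf("  transformer val acc: %.3f\n",
                                      x$perf_a))
  if (!is.null(x$perf_b)) cat(sprintf("  GAT val acc:         %.3f\n",
                                      x$perf_b))
  invisible(x)
}

write_pipeline_artifacts <- function(result, raw, net, vae_fit, graph,
                                     dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg_file <- file.path(dir, "config.txt")
  writeLines(deparse(result$config[setdiff(names(result$config),
                                           "output_dir")]), cfg_file)
  if (!is.null(net))
    write_coexpression_network(net, file.path(dir, "coexpression.tsv"))
  if (!is.null(vae_fit))
    write_latents(vae_fit, raw$cell_ids, file.path(dir, "latents.csv"))
  if (!is.null(graph))
    write_cell_graph(graph, file.path(dir, "cell_graph.tsv"))
  if (!is.null(result$performer))
    write_probabilities(result$performer$probs,
                        file.path(dir, "probs_transformer.csv"))
  if (!is.null(result$gat))
    write_probabilities(result$gat$probs, file.path(dir, "probs_gat.csv"))
  write_probabilities(result$fused, file.path(dir, "probs_fused.csv"))
  write_report(result$report, file.path(dir, "report.csv"))
  manifest <- list(seed = result$config$seed,
                   mode = result$mode,
                   config_md5 = unname(tools::md5sum(cfg_file)),
                   acc = result$report$acc, nmi = result$report$nmi,
                   ari = result$report$ari,
                   perf_a = result$perf_a, perf_b = result$perf_b,
                   r_version = as.character(getRversion()))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Ablation over data views
#'
#' Runs the pipeline on one shared dataset under several view combinations
#' and tabulates ACC / NMI / ARI per mode, preserving the requested order.
#'
#' @param config a [pipeline_config()].
#' @param modes subset of `c("temporal", "cell_graph",
#'   "cell_graph+temporal", "cell_graph+spatiotemporal")`.
#' @param data optional shared dataset (simulated once otherwise).
#' @return Data frame with one row per mode.
#' @export
ablate <- function(config,
                   modes = c("temporal", "cell_graph",
                             "cell_graph+temporal",
                             "cell_graph+spatiotemporal"),
                   data = NULL) {
  allowed <- c("temporal", "cell_graph", "cell_graph+temporal",
               "cell_graph+spatiotemporal")
  if (!all(modes %in% allowed))
    stop("unknown mode(s): ", paste(setdiff(modes, allowed), collapse = ", "))
  if (is.null(data)) {
    sim <- config$simulate
    sim$seed <- derive_seed(config$seed, 1L)
    data <- simulate_counts(sim)
  }
  rows <- lapply(modes, function(m) {
    cfg <- config
    cfg$mode <- m
    res <- run_pipeline(cfg, data = data)
    data.frame(mode = m, acc = res$report$acc, nmi = res$report$nmi,
               ari = res$report$ari, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Replicate the pipeline over seeds and summarize
#'
#' Runs the full pipeline once per seed and reports the per-replicate
#' metrics together with their mean and standard deviation.
#'
#' @param config a [pipeline_config()] (its `seed` is replaced per
#'   replicate).
#' @param n_reps number of replicates (>= 2).
#' @param seeds optional explicit seed vector of length `n_reps`.
#' @return List with `per_rep` (one row per replicate) and `summary`
#'   (mean and sd per metric).
#' @export
replicate_runs <- function(config, n_reps = 10, seeds = NULL) {
  if (n_reps < 2) stop("n_reps must be >= 2")
  seeds <- seeds %||% (config$seed + seq_len(n_reps) - 1L)
  if (length(seeds) != n_reps) stop("need one seed per replicate")
  rows <- lapply(seq_len(n_reps), function(i) {
    cfg <- config
    cfg$seed <- seeds[i]
    res <- tryCatch(run_pipeline(cfg), error = function(e)
      stop("replicate ", i, " (seed ", seeds[i], ") failed: ",
           conditionMessage(e)))
    data.frame(seed = seeds[i], acc = res$report$acc,
               nmi = res$report$nmi, ari = res$report$ari)
  })
  per_rep <- do.call(rbind, rows)
  summary <- data.frame(
    metric = c("acc", "nmi", "ari"),
    mean = c(mean(per_rep$acc), mean(per_rep$nmi), mean(per_rep$ari)),
    sd = c(stats::sd(per_rep$acc), stats::sd(per_rep$nmi),
           stats::sd(per_rep$ari)))
  list(per_rep = per_rep, summary = summary)
}
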