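#' Configuration for the synthetic count simulator
#'
#' Defaults describe the desk-scale study conditions used throughout the
#' package's experiments: 300 cells, 200 genes, 3 balanced cell types, a
#' marker program covering 15 percent of the genes per type at a
#' natural-log fold change of 1.5, four co-expressed gene modules of ten
#' genes, 60 percent dropout and moderate negative-binomial
#' overdispersion.
#'
#' @param n_cells,n_genes matrix dimensions.
#' @param n_types number of planted cell types.
#' @param type_proportions simplex vector of type frequencies (default
#'   balanced).
#' @param marker_fraction fraction of genes reserved as type markers,
#'   split evenly over types.
#' @param log_fold_change natural-log up-regulation of a type's markers.
#' @param module_count,module_size co-expressed gene blocks planted among the
#'   non-marker genes via a shared per-cell latent factor.
#' @param dropout_rate probability that an observed count is zeroed
#'   independently of its mean (technical dropout).
#' @param dispersion negative-binomial size parameter (smaller = noisier).
#' @param baseline_meanlog,baseline_sdlog log-normal distribution of
#'   per-gene baseline mean expression (shallow droplet-style depth by
#'   default).
#' @param module_factor_sd standard deviation of the shared per-cell latent
#'   factor driving each co-expression module.
#' @param seed integer seed; the draw is deterministic given it.
#' @return A list of class `SyntheticConfig`.
#' @export
synthetic_config <- function(n_cells = 300, n_genes = 200, n_types = 3,
                             type_proportions = NULL, marker_fraction = 0.45,
                             log_fold_change = 1.5, module_count = 4,
                             module_size = 10, dropout_rate = 0.6,
                             dispersion = 5, baseline_meanlog = log(1.5),
                             baseline_sdlog = 0.4, module_factor_sd = 0.5,
                             seed = 1) {
  if (is.null(type_proportions))
    type_proportions <- rep(1 / n_types, n_types)
  if (abs(sum(type_proportions) - 1) > 1e-8)
    stop("type_proportions must sum to 1")
  if (length(type_proportions) != n_types)
    stop("type_proportions length must equal n_types")
  if (marker_fraction <= 0 || marker_fraction >= 1)
    stop("marker_fraction must be in (0, 1)")
  if (floor(marker_fraction * n_genes) < n_types)
    stop("infeasible marker allocation: need at least one marker per type")
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop("dropout_rate must be in [0, 1)")
  if (dispersion <= 0) stop("dispersion must be positive")
  structure(list(n_cells = n_cells, n_genes = n_genes, n_types = n_types,
                 type_proportions = type_proportions,
                 marker_fraction = marker_fraction,
                 log_fold_change = log_fold_change,
                 module_count = module_count, module_size = module_size,
                 dropout_rate = dropout_rate, dispersion = dispersion,
                 baseline_meanlog = baseline_meanlog,
                 baseline_sdlog = baseline_sdlog,
                 module_factor_sd = module_factor_sd, seed = seed),
            class = "SyntheticConfig")
}

#' Simulate a labeled count matrix with planted structure
#'
#' Per-type mean profiles share a log-normal baseline; each type
#' up-regulates its own disjoint marker set by `exp(log_fold_change)`.
#' Module genes share a per-cell latent factor that induces positive
#' within-module correlation (recoverable by the co-expression network).
#' Counts are drawn negative-binomial around the cell/gene mean and then
#' zeroed independently with probability `dropout_rate`.
#'
#' @param config a [synthetic_config()].
#' @return A list of class `LabeledDataset` with fields `raw` (a
#'   [raw_count_matrix()] carrying the labels), `labels`, and `truth`
#'   (marker map, module map and the pre-noise mean matrix).
#' @export
simulate_counts <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "SyntheticConfig"))
  with_seed(config$seed, {
    n <- config$n_cells
    g <- config$n_genes
    k <- config$n_types
    gene_ids <- sprintf("g%03d", seq_len(g))
    cell_ids <- sprintf("c%04d", seq_len(n))
    types <- sample(seq_len(k), n, replace = TRUE,
                    prob = config$type_proportions)
    labels <- paste0("type", types)

    n_marker <- floor(config$marker_fraction * g)
    per_type <- n_marker %/% k
    marker_map <- stats::setNames(vector("list", k), paste0("type", seq_len(k)))
    idx <- 1L
    for (t in seq_len(k)) {
      marker_map[[t]] <- gene_ids[idx:(idx + per_type - 1L)]
      idx <- idx + per_type
    }
    # modules live among the non-marker genes
    module_map <- list()
    for (m in seq_len(config$module_count)) {
      hi <- idx + config$module_size - 1L
      if (hi > g) break
      module_map[[paste0("module", m)]] <- gene_ids[idx:hi]
      idx <- hi + 1L
    }

    base <- exp(stats::rnorm(g, mean = config$baseline_meanlog,
                             sd = config$baseline_sdlog))
    log_mu <- matrix(rep(log(base), each = n), n, g)
    for (t in seq_len(k)) {
      cols <- match(marker_map[[t]], gene_ids)
      rows <- which(types == t)
      log_mu[rows, cols] <- log_mu[rows, cols] + config$log_fold_change
    }
    for (mod in module_map) {
      f <- stats::rnorm(n, 0, config$module_factor_sd)  # shared factor
      cols <- match(mod, gene_ids)
      log_mu[, cols] <- log_mu[, cols] + f
    }
    mu <- exp(log_mu)
    counts <- matrix(stats::rnbinom(n * g, size = config$dispersion,
                                    mu = as.vector(mu)), n, g)
    if (config$dropout_rate > 0) {
      keep <- matrix(stats::runif(n * g) >= config$dropout_rate, n, g)
      counts <- counts * keep
    }
    raw <- raw_count_matrix(counts, cell_ids, gene_ids, labels = labels)
    structure(list(raw = raw, labels = labels,
                   truth = list(markers = marker_map, modules = module_map,
                                mean_matrix = mu, types = types)),
              class = "LabeledDataset")
  })
}

#' Stratified train/validation split
#'
#' Samples `validation_fraction` of each class into the validation set
#' (rounded per class); singleton classes stay in training with a warning.
#'
#' @param labels per-cell class labels.
#' @param validation_fraction fraction in (0, 1), default 0.2.
#' @param seed integer seed.
#' @return List with integer index vectors `train` and `validation`
#'   (disjoint, covering all cells).
#' @export
holdout_split <- function(labels, validation_fraction = 0.2, seed = 1) {
  if (validation_fraction <= 0 || validation_fraction >= 1)
    stop("validation_fraction must be in (0, 1)")
  with_seed(seed, {
    val <- integer(0)
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      if (length(idx) < 2) {
        warning("class ", cl, " has a single member; kept in train")
        next
      }
      n_val <- max(1L, round(validation_fraction * length(idx)))
      n_val <- min(n_val, length(idx) - 1L)
      val <- c(val, sample(idx, n_val))
    }
    val <- sort(val)
    list(train = setdiff(seq_along(labels), val), validation = val)
  })
}
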