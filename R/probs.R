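#' Row-stochastic class-probability container
#'
#' Shared output type of the transformer branch, the graph branch and the
#' fusion step.
#'
#' @param probs cells x classes matrix with non-negative entries and rows
#'   summing to 1 (within 1e-6).
#' @param class_ids class label vocabulary (column order).
#' @param cell_ids per-row cell identifiers.
#' @return An object of class `ClassProbabilities`.
#' @export
class_probabilities <- function(probs, class_ids, cell_ids = NULL) {
  probs <- as.matrix(probs)
  if (ncol(probs) != length(class_ids))
    stop("probs columns must match class_ids")
  if (any(probs < -1e-12) || any(abs(rowSums(probs) - 1) > 1e-6))
    stop("probs rows must be non-negative and sum to 1")
  colnames(probs) <- as.character(class_ids)
  if (!is.null(cell_ids)) rownames(probs) <- cell_ids
  structure(list(probs = probs, class_ids = as.character(class_ids),
                 cell_ids = cell_ids),
            class = "ClassProbabilities")
}

#' @export
print.ClassProbabilities <- function(x, ...) {
  cat("ClassProbabilities:", nrow(x$probs), "cells x",
      length(x$class_ids), "classes\n")
  invisible(x)
}

#' Hard labels from class probabilities
#' @param x a `ClassProbabilities`.
#' @return Character vector of argmax class labels (first class on ties).
#' @export
predicted_labels <- function(x) {
  x$class_ids[max.col(x$probs, ties.method = "first")]
}

#' Save / load a trained model checkpoint
#'
#' Single binary file carrying a format-version header alongside the
#' model object (transformer branch, GAT branch or any fit list).
#'
#' @param model object to persist.
#' @param path checkpoint path.
#' @return `path` (save) or the restored model (load).
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(format = "scMultiView-checkpoint", version = 1L,
               model = model), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "scMultiView-checkpoint"))
    stop("not a model checkpoint: ", path)
  if (obj$version > 1L)
    stop("checkpoint version ", obj$version, " is newer than this package")
  obj$model
}

#' Export class probabilities as CSV (cell id plus one column per class)
#' @param x a `ClassProbabilities`.
#' @param path output path.
#' @export
write_probabilities <- function(x, path) {
  df <- data.frame(cell_id = x$cell_ids %||% seq_len(nrow(x$probs)),
                   x$probs, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
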