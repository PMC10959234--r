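# Clustering agreement metrics: accuracy (supervised or after optimal
# cluster-to-class assignment), normalized mutual information and the
# adjusted Rand index, plus the evaluation report container.

# O(n^3) Hungarian algorithm (potentials + shortest augmenting paths) for a
# square cost matrix; returns the column assigned to each row.
solve_assignment <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n)
  u <- numeric(n + 1)
  v <- numeric(n + 1)
  p <- integer(n + 1)   # p[j+1]: row assigned to column j (0 = none)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(Inf, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]
      delta <- Inf
      j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j + 1]) {
          cur <- cost[i0, j] - u[i0 + 1] - v[j + 1]
          if (cur < minv[j + 1]) {
            minv[j + 1] <- cur
            way[j + 1] <- j0
          }
          if (minv[j + 1] < delta) {
            delta <- minv[j + 1]
            j1 <- j
          }
        }
      }
      for (j in 0:n) {
        if (used[j + 1]) {
          u[p[j + 1] + 1] <- u[p[j + 1] + 1] + delta
          v[j + 1] <- v[j + 1] - delta
        } else {
          minv[j + 1] <- minv[j + 1] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  assign <- integer(n)
  for (j in seq_len(n)) if (p[j + 1] > 0) assign[p[j + 1]] <- j
  assign
}

#' Clustering / classification accuracy
#'
#' `"supervised"` compares labels directly; `"hungarian"` maximizes the
#' matched fraction over one-to-one assignments of predicted clusters to
#' true classes (optimal assignment on the contingency matrix), making the
#' score invariant to cluster relabeling.
#'
#' @param pred_labels,true_labels equal-length label vectors.
#' @param mode `"supervised"` or `"hungarian"`.
#' @return Accuracy in `[0, 1]`.
#' @export
accuracy <- function(pred_labels, true_labels,
                     mode = c("supervised", "hungarian")) {
  mode <- match.arg(mode)
  if (length(pred_labels) != length(true_labels))
    stop("label vectors must have equal length")
  if (length(pred_labels) == 0) stop("empty labelings")
  if (mode == "supervised") return(mean(pred_labels == true_labels))
  tab <- table(pred_labels, true_labels)
  k <- max(dim(tab))
  counts <- matrix(0, k, k)
  counts[seq_len(nrow(tab)), seq_len(ncol(tab))] <- tab
  assign <- solve_assignment(max(counts) - counts)
  sum(counts[cbind(seq_len(k), assign)]) / length(pred_labels)
}

#' Normalized mutual information
#'
#' Mutual information of the two labelings normalized by the arithmetic
#' mean of their entropies; a degenerate pair in which both labelings have
#' zero entropy is defined as 0 with a warning.
#'
#' @param pred,true equal-length label vectors.
#' @return NMI in `[0, 1]`.
#' @export
nmi <- function(pred, true) {
  if (length(pred) != length(true))
    stop("label vectors must have equal length")
  n <- length(pred)
  tab <- table(pred, true)
  pij <- tab / n
  pi_ <- rowSums(pij)
  pj_ <- colSums(pij)
  nz <- pij > 0
  mi <- sum(pij[nz] * log(pij[nz] / outer(pi_, pj_)[nz]))
  h1 <- -sum(pi_[pi_ > 0] * log(pi_[pi_ > 0]))
  h2 <- -sum(pj_[pj_ > 0] * log(pj_[pj_ > 0]))
  if (h1 + h2 == 0) {
    warning("both labelings are single-cluster; NMI defined as 0")
    return(0)
  }
  mi / ((h1 + h2) / 2)
}

#' Adjusted Rand index
#'
#' Pair-counting contingency formula
#' `(RI - E[RI]) / (max RI - E[RI])`.
#'
#' @param pred,true equal-length label vectors (n >= 2).
#' @return ARI in `[-1, 1]`; 1 for identical partitions.
#' @export
ari <- function(pred, true) {
  if (length(pred) != length(true))
    stop("label vectors must have equal length")
  n <- length(pred)
  if (n < 2) stop("need at least 2 observations")
  tab <- table(pred, true)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_i <- sum(choose2(rowSums(tab)))
  sum_j <- sum(choose2(colSums(tab)))
  total <- choose2(n)
  expected <- sum_i * sum_j / total
  max_index <- (sum_i + sum_j) / 2
  if (max_index == expected) return(0)  # e.g. all-singleton vs one-cluster
  (sum_ij - expected) / (max_index - expected)
}

#' Score a labeling against ground truth
#'
#' @param pred_labels,true_labels equal-length label vectors.
#' @param mode accuracy mode, `"supervised"` (label-aware training) or
#'   `"hungarian"` (unsupervised comparisons).
#' @return List of class `EvaluationReport`: `acc`, `nmi`, `ari`,
#'   `confusion` (true x predicted counts) and `mode`.
#' @export
evaluate_labels <- function(pred_labels, true_labels,
                            mode = c("supervised", "hungarian")) {
  mode <- match.arg(mode)
  structure(list(acc = accuracy(pred_labels, true_labels, mode),
                 nmi = nmi(pred_labels, true_labels),
                 ari = ari(pred_labels, true_labels),
                 confusion = table(true = true_labels, pred = pred_labels),
                 mode = mode),
            class = "EvaluationReport")
}

#' @export
print.EvaluationReport <- function(x, ...) {
  cat(sprintf("EvaluationReport (%s): ACC %.3f  NMI %.3f  ARI %.3f\n",
              x$mode, x$acc, x$nmi, x$ari))
  invisible(x)
}

#' Write an evaluation report to CSV files
#' @param report an `EvaluationReport`.
#' @param path metrics CSV path; the confusion matrix goes to
#'   `<path stem>_confusion.csv`.
#' @export
write_report <- function(report, path) {
  utils::write.csv(data.frame(metric = c("acc", "nmi", "ari"),
                              value = c(report$acc, report$nmi, report$ari)),
                   path, row.names = FALSE)
  utils::write.csv(as.data.frame.matrix(report$confusion),
                   sub("(\\.[^.]+)?$", "_confusion.csv", path, perl = TRUE),
                   row.names = TRUE)
  invisible(path)
}
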