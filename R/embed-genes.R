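# Gene-identity embeddings: skip-gram over a co-expression corpus, the
# expression-bin embedding table, and assembly of per-cell token sequences.

new_embedding_table <- function(vectors, ids) {
  vectors <- as.matrix(vectors)
  rownames(vectors) <- ids
  structure(list(vectors = vectors, dim = ncol(vectors)),
            class = "EmbeddingTable")
}

#' @export
print.EmbeddingTable <- function(x, ...) {
  cat("EmbeddingTable:", nrow(x$vectors), "tokens x", x$dim, "dims\n")
  invisible(x)
}

#' Build a skip-gram corpus from a co-expression network
#'
#' Each gene contributes (center, context) pairs for its co-expression
#' neighbors, subsampled to at most `max_pairs_per_gene` with the given seed.
#' Isolated genes contribute no pairs.
#'
#' @param binned a `BinnedMatrix`; supplies the gene vocabulary.
#' @param coexpr a `CoexpressionNetwork` over the same genes.
#' @param max_pairs_per_gene cap on context pairs per center gene.
#' @param seed integer seed for the subsampling.
#' @return A list of class `GeneCorpus` with an integer `pairs` matrix
#'   (columns `center`, `context`) and a `vocabulary` map gene id -> token.
#' @export
build_corpus <- function(binned, coexpr, max_pairs_per_gene = 20, seed = 1) {
  vocab_ids <- binned$gene_ids
  vocab <- stats::setNames(seq_along(vocab_ids), vocab_ids)
  if (!all(names(coexpr$adjacency) %in% vocab_ids))
    stop("co-expression network genes not covered by the vocabulary")
  with_seed(seed, {
    pairs <- vector("list", length(vocab_ids))
    n_isolated <- 0L
    for (i in seq_along(vocab_ids)) {
      nb <- coexpr$adjacency[[vocab_ids[i]]]
      if (is.null(nb) || length(nb$ids) == 0) {
        n_isolated <- n_isolated + 1L
        next
      }
      ctx <- nb$ids
      if (length(ctx) > max_pairs_per_gene)
        ctx <- sample(ctx, max_pairs_per_gene)
      pairs[[i]] <- cbind(center = rep(vocab[[vocab_ids[i]]], length(ctx)),
                          context = unname(vocab[ctx]))
    }
    if (n_isolated > 0)
      warning(n_isolated, " isolated gene(s) contribute no pairs")
    pairs <- do.call(rbind, pairs)
    if (is.null(pairs) || nrow(pairs) == 0) stop("corpus is empty")
    structure(list(pairs = pairs, vocabulary = vocab), class = "GeneCorpus")
  })
}

#' Skip-gram conditional probability under the full softmax
#'
#' `P(c | w) = exp(v_c . v_w) / sum_{c'} exp(v_{c'} . v_w)` over the whole
#' vocabulary; used as the exact counterpart of the negative-sampling
#' objective on small vocabularies.
#'
#' @param w,c gene ids (or integer tokens) present in `table`.
#' @param table a `GeneEmbeddingTable` (context vectors default to the same
#'   table, matching the single-table softmax form).
#' @return Probability in (0, 1); sums to 1 over `c`.
#' @export
skipgram_prob <- function(w, c, table) {
  V <- table$vectors
  key_w <- if (is.character(w)) w else rownames(V)[w]
  key_c <- if (is.character(c)) c else rownames(V)[c]
  if (!(key_w %in% rownames(V)) || !(key_c %in% rownames(V)))
    stop("unknown token")
  s <- drop(V %*% V[key_w, ])
  s <- s - max(s)
  e <- exp(s)
  unname(e[key_c] / sum(e))
}

# Shared minibatch negative-sampling engine. pairs: integer matrix
# (center, context) over vocab 1..V. Gradients within a batch are
# aggregated by token before the update, so the result depends on the pair
# multiset and seed only, not the caller's pair order.
skipgram_engine <- function(pairs, n_vocab, dim, epochs, negatives,
                            learning_rate, seed, batch_size = 512L) {
  if (epochs <= 0) stop("epochs must be positive")
  if (dim < 2) stop("embedding dimension must be >= 2")
  ord <- order(pairs[, 1L], pairs[, 2L])
  pairs <- pairs[ord, , drop = FALSE]
  with_seed(seed, {
    W_in <- matrix(stats::runif(n_vocab * dim, -0.5, 0.5) / dim, n_vocab, dim)
    W_out <- matrix(0, n_vocab, dim)
    # unigram^(3/4) negative-sampling distribution over contexts
    cnt <- tabulate(pairs[, 2L], nbins = n_vocab)
    neg_prob <- (cnt + 1)^0.75
    neg_prob <- neg_prob / sum(neg_prob)
    n_pairs <- nrow(pairs)
    loss_trace <- numeric(epochs)
    for (ep in seq_len(epochs)) {
      perm <- sample.int(n_pairs)
      ep_loss <- 0
      for (start in seq(1L, n_pairs, by = batch_size)) {
        idx <- perm[start:min(start + batch_size - 1L, n_pairs)]
        w <- pairs[idx, 1L]
        tgt <- pairs[idx, 2L]
        B <- length(idx)
        vw <- W_in[w, , drop = FALSE]
        # positive pairs
        s_pos <- rowSums(vw * W_out[tgt, , drop = FALSE])
        g_pos <- sigmoid(s_pos) - 1
        d_in <- g_pos * W_out[tgt, , drop = FALSE]
        d_out_rows <- tgt
        d_out <- g_pos * vw
        ep_loss <- ep_loss - sum(log(pmax(sigmoid(s_pos), 1e-12)))
        # negatives
        neg <- matrix(sample.int(n_vocab, B * negatives, replace = TRUE,
                                 prob = neg_prob), B, negatives)
        for (k in seq_len(negatives)) {
          nk <- neg[, k]
          s_neg <- rowSums(vw * W_out[nk, , drop = FALSE])
          g_neg <- sigmoid(s_neg)
          d_in <- d_in + g_neg * W_out[nk, , drop = FALSE]
          d_out_rows <- c(d_out_rows, nk)
          d_out <- rbind(d_out, g_neg * vw)
          ep_loss <- ep_loss - sum(log(pmax(1 - sigmoid(s_neg), 1e-12)))
        }
        # per-token mean gradient within the batch keeps step sizes
        # bounded when a token recurs many times (small vocabularies)
        gi <- rowsum(d_in, group = w)
        gi <- gi / tabulate(w, nbins = n_vocab)[as.integer(rownames(gi))]
        W_in[as.integer(rownames(gi)), ] <-
          W_in[as.integer(rownames(gi)), ] - learning_rate * gi
        go <- rowsum(d_out, group = d_out_rows)
        go <- go / tabulate(d_out_rows,
                            nbins = n_vocab)[as.integer(rownames(go))]
        W_out[as.integer(rownames(go)), ] <-
          W_out[as.integer(rownames(go)), ] - learning_rate * go
      }
      loss_trace[ep] <- ep_loss / n_pairs
    }
    list(W_in = W_in, loss_trace = loss_trace)
  })
}

#' Train skip-gram gene embeddings with negative sampling
#'
#' Minimizes the negative-sampling surrogate of the full-softmax skip-gram
#' objective over the corpus pairs. Deterministic given `seed`, and
#' invariant to the order in which pairs are supplied.
#'
#' @param corpus a [build_corpus()] result.
#' @param dim embedding dimension (default 200; tests use 16).
#' @param epochs passes over the corpus.
#' @param negatives negative samples per positive pair.
#' @param learning_rate SGD step size.
#' @param seed integer seed.
#' @return A `GeneEmbeddingTable` over the full vocabulary, with the
#'   per-epoch mean loss attached as attribute `loss_trace`.
#' @export
train_skipgram <- function(corpus, dim = 200, epochs = 5, negatives = 5,
                           learning_rate = 0.05, seed = 1) {
  stopifnot(inherits(corpus, "GeneCorpus"))
  fit <- skipgram_engine(corpus$pairs, length(corpus$vocabulary), dim,
                         epochs, negatives, learning_rate, seed)
  tab <- new_embedding_table(fit$W_in, names(corpus$vocabulary))
  attr(tab, "loss_trace") <- fit$loss_trace
  tab
}

#' Random expression-bin embedding table
#'
#' One fixed Gaussian vector per bin token (`0 .. n_bins-1`), seeded for
#' reproducibility; these act as the discrete expression-token embeddings
#' added to the gene and co-expression-network streams.
#'
#' @param n_bins number of bin tokens.
#' @param dim embedding dimension (must match the gene table).
#' @param seed integer seed.
#' @return An `EmbeddingTable` keyed `"0" .. "n_bins-1"`.
#' @export
expression_embedding_table <- function(n_bins, dim = 200, seed = 1) {
  with_seed(seed, {
    V <- matrix(stats::rnorm(n_bins * dim, sd = 1 / sqrt(dim)), n_bins, dim)
    new_embedding_table(V, as.character(0:(n_bins - 1)))
  })
}

#' Write / read an embedding table as plain text
#'
#' One line per token: the token id followed by its coordinates,
#' whitespace-separated.
#' @param table an `EmbeddingTable`.
#' @param path output path.
#' @return `path` (write) or the reconstructed table (read).
#' @export
write_embedding_table <- function(table, path) {
  lines <- vapply(seq_len(nrow(table$vectors)), function(i) {
    paste(c(rownames(table$vectors)[i],
            format(table$vectors[i, ], digits = 17)), collapse = " ")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_embedding_table
#' @export
read_embedding_table <- function(path) {
  lines <- readLines(path)
  parts <- strsplit(trimws(lines), "\\s+")
  ids <- vapply(parts, `[[`, character(1), 1L)
  V <- t(vapply(parts, function(p) as.numeric(p[-1]),
                numeric(length(parts[[1]]) - 1L)))
  new_embedding_table(V, ids)
}

#' Assemble per-cell token embedding sequences
#'
#' For every cell, the ordered gene tokens (input gene-id order) each carry
#' the element-wise sum of their gene-identity, expression-bin and
#' co-expression-network ("spatial") embedding vectors.
#'
#' @param binned a `BinnedMatrix`.
#' @param gene_tab,expr_tab,spatial_tab `EmbeddingTable`s of equal dimension;
#'   `spatial_tab = NULL` uses zero spatial vectors (temporal-only view).
#' @param gene_subset optional character vector restricting (and ordering)
#'   the token sequence.
#' @return A list of class `TokenEmbeddingSequence` holding the `cells x
#'   tokens x dim` embedding array, the token (gene) order and bin tokens.
#' @export
assemble_token_sequences <- function(binned, gene_tab, expr_tab,
                                     spatial_tab = NULL, gene_subset = NULL) {
  genes <- gene_subset %||% binned$gene_ids
  if (!all(genes %in% binned$gene_ids)) stop("gene_subset outside matrix")
  d <- gene_tab$dim
  if (expr_tab$dim != d)
    stop("embedding dimension mismatch: gene ", d, " vs expression ",
         expr_tab$dim)
  if (!is.null(spatial_tab) && spatial_tab$dim != d)
    stop("embedding dimension mismatch: gene ", d, " vs spatial ",
         spatial_tab$dim)
  if (!all(genes %in% rownames(gene_tab$vectors)))
    stop("gene table does not cover all tokens")
  G <- gene_tab$vectors[genes, , drop = FALSE]
  if (!is.null(spatial_tab)) {
    covered <- genes %in% rownames(spatial_tab$vectors)
    S <- matrix(0, length(genes), d)
    S[covered, ] <- spatial_tab$vectors[genes[covered], , drop = FALSE]
    G <- G + S
  }
  tok <- binned$tokens[, genes, drop = FALSE]
  if (max(tok) > nrow(expr_tab$vectors) - 1L)
    stop("expression table does not cover all bin tokens")
  n <- nrow(tok)
  L <- length(genes)
  E <- expr_tab$vectors
  arr <- array(0, dim = c(n, L, d))
  for (i in seq_len(n)) {
    arr[i, , ] <- G + E[tok[i, ] + 1L, , drop = FALSE]
  }
  structure(list(cell_ids = binned$cell_ids, gene_ids = genes,
                 tokens = tok, embeddings = arr, dim = d,
                 labels = binned$labels),
            class = "TokenEmbeddingSequence")
}
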