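test_that("fusion weights are performance proportions", {
  w <- fusion_weights(0.8, 0.8)
  expect_equal(c(w$W1, w$W2), c(0.5, 0.5))
  w2 <- fusion_weights(0.9, 0.6)
  expect_equal(c(w2$W1, w2$W2), c(0.6, 0.4))
  set.seed(1)
  for (i in 1:20) {
    pa <- runif(1); pb <- runif(1)
    w3 <- fusion_weights(pa, pb)
    expect_equal(w3$W1 + w3$W2, 1, tolerance = 1e-12)
  }
  expect_error(fusion_weights(0, 0), "positive")
})

test_that("fusion is a row-stochastic convex combination", {
  set.seed(2)
  mk <- function() {
    m <- matrix(runif(12), 4, 3)
    class_probabilities(m / rowSums(m), c("a", "b", "c"), paste0("c", 1:4))
  }
  A <- mk(); B <- mk()
  expect_equal(fuse(A, A, fusion_weights(0.7, 0.3))$probs, A$probs)
  expect_equal(fuse(A, B, fusion_weights(1, 0))$probs, A$probs)
  P <- fuse(A, B, fusion_weights(0.6, 0.4))
  expect_equal(P$probs, 0.6 * A$probs + 0.4 * B$probs, tolerance = 1e-12)
  expect_equal(unname(rowSums(P$probs)), rep(1, 4), tolerance = 1e-12)
  Bad <- class_probabilities(matrix(1 / 2, 4, 2), c("a", "b"))
  expect_error(fuse(A, Bad, fusion_weights(0.5, 0.5)), "vocabularies")
})

test_that("MLP fusion dominates a pure-noise branch and is reproducible", {
  classes <- c("a", "b", "c")
  labels <- rep(classes, each = 20)
  hits <- 0
  for (s in 1:5) {
    set.seed(s)
    informative <- one_hot_m <- matrix(0.02, 60, 3)
    informative[cbind(1:60, match(labels, classes))] <- 0.96
    noise <- matrix(runif(180), 60, 3)
    noise <- noise / rowSums(noise)
    A <- class_probabilities(informative, classes)
    B <- class_probabilities(noise, classes)
    split <- holdout_split(labels, 0.3, seed = s)
    P <- mlp_fuse(A, B, labels, split, seed = s)
    expect_equal(rowSums(P$probs), rep(1, 60), tolerance = 1e-6)
    acc_fused <- mean(predicted_labels(P)[split$validation] ==
                        labels[split$validation])
    acc_b <- mean(predicted_labels(B)[split$validation] ==
                    labels[split$validation])
    if (acc_fused >= acc_b) hits <- hits + 1
    P2 <- mlp_fuse(A, B, labels, split, seed = s)
    expect_identical(P$probs, P2$probs)
  }
  expect_gte(hits, 5)
})

test_that("hungarian assignment matches brute-force enumeration", {
  set.seed(4)
  for (k in c(3, 4, 5)) {
    cost <- matrix(runif(k * k), k, k)
    got <- scMultiView:::solve_assignment(cost)
    perms <- gtools_perms <- function(v) {
      if (length(v) == 1) return(matrix(v, 1, 1))
      out <- NULL
      for (i in seq_along(v))
        out <- rbind(out, cbind(v[i], Recall(v[-i])))
      out
    }
    allp <- perms(seq_len(k))
    costs <- apply(allp, 1, function(p) sum(cost[cbind(seq_len(k), p)]))
    expect_equal(sum(cost[cbind(seq_len(k), got)]), min(costs),
                 tolerance = 1e-12)
  }
})

test_that("accuracy modes agree with definitions", {
  y <- c("a", "a", "b", "b", "c", "c")
  expect_equal(accuracy(y, y, "supervised"), 1)
  expect_equal(accuracy(y, y, "hungarian"), 1)
  perm <- c("b", "b", "c", "c", "a", "a")
  expect_equal(accuracy(perm, y, "hungarian"), 1)
  expect_lt(accuracy(perm, y, "supervised"), 1)
  # 3-class toy vs exhaustive search over the 6 assignments
  set.seed(5)
  pred <- sample(1:3, 30, TRUE)
  true <- sample(letters[1:3], 30, TRUE)
  tab <- table(pred, true)
  best <- 0
  for (p1 in 1:3) for (p2 in setdiff(1:3, p1)) {
    p3 <- setdiff(1:3, c(p1, p2))
    best <- max(best, tab[1, p1] + tab[2, p2] + tab[3, p3])
  }
  expect_equal(accuracy(pred, true, "hungarian"), best / 30)
  expect_gte(accuracy(pred, true, "hungarian"),
             accuracy(as.character(pred), as.character(true),
                      "supervised"))
  expect_error(accuracy(character(0), character(0)), "empty")
})

test_that("NMI matches hand entropy computation and oracles", {
  expect_equal(nmi(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  pred <- c(0, 0, 1, 1, 2, 2); true <- c(0, 0, 0, 1, 1, 1)
  # hand computation with the arithmetic-mean normalization
  tab <- table(pred, true) / 6
  mi <- 0
  for (i in 1:3) for (j in 1:2) {
    p <- tab[i, j]
    if (p > 0) mi <- mi + p * log(p / (sum(tab[i, ]) * sum(tab[, j])))
  }
  h1 <- -sum(rowSums(tab) * log(rowSums(tab)))
  h2 <- -sum(colSums(tab) * log(colSums(tab)))
  expect_equal(nmi(pred, true), mi / ((h1 + h2) / 2), tolerance = 1e-12)
  set.seed(6)
  a <- sample(1:4, 200, TRUE); b <- sample(1:3, 200, TRUE)
  expect_equal(nmi(a, b),
               igraph::compare(a, b, method = "nmi"), tolerance = 1e-9)
  expect_equal(nmi(a, b), nmi(match(a, c(3, 1, 4, 2)), b),
               tolerance = 1e-12)
  # independent labelings at large n are near zero
  set.seed(7)
  big_a <- sample(1:3, 1e4, TRUE); big_b <- sample(1:3, 1e4, TRUE)
  expect_lt(nmi(big_a, big_b), 0.05)
  expect_warning(nmi(rep(1, 5), rep(2, 5)), "single-cluster")
})

test_that("ARI matches the pair-counting oracle", {
  expect_equal(ari(c(1, 2, 1, 2), c("x", "y", "x", "y")), 1)
  expect_equal(ari(1:6, rep(1, 6)), 0)
  set.seed(8)
  pred <- sample(1:3, 30, TRUE); true <- sample(1:4, 30, TRUE)
  # O(n^2) oracle over all pairs
  agree <- 0; n11 <- 0; n00 <- 0
  for (i in 1:29) for (j in (i + 1):30) {
    sp <- pred[i] == pred[j]; st <- true[i] == true[j]
    if (sp && st) n11 <- n11 + 1
    if (!sp && !st) n00 <- n00 + 1
  }
  npairs <- choose(30, 2)
  ri <- (n11 + n00) / npairs
  # expected index from marginals
  sum_i <- sum(choose(table(pred), 2)); sum_j <- sum(choose(table(true), 2))
  exp_ri <- (sum_i * sum_j / npairs +
               (npairs - sum_i) * (npairs - sum_j) / npairs) / npairs
  oracle <- (ri - exp_ri) / (1 - exp_ri)
  expect_equal(ari(pred, true), oracle, tolerance = 1e-12)
  expect_equal(ari(pred, true), mclust::adjustedRandIndex(pred, true),
               tolerance = 1e-12)
  expect_equal(ari(pred, true), ari(match(pred, c(2, 3, 1)), true),
               tolerance = 1e-12)
  expect_error(ari(1, 1), "at least 2")
})

test_that("evaluation reports carry a consistent confusion matrix", {
  pred <- c("a", "a", "b", "b", "b")
  true <- c("a", "b", "b", "b", "a")
  rep_ <- evaluate_labels(pred, true)
  expect_equal(sum(rep_$confusion), 5)
  expect_equal(rep_$acc, 3 / 5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_report(rep_, path)
  back <- read.csv(path)
  expect_equal(back$value[back$metric == "acc"], 3 / 5)
})

test_that("fused accuracy is not dominated by the weaker branch", {
  # statistical property: fusing can only rarely fall below both branches
  set.seed(9)
  viol <- 0
  for (i in 1:100) {
    n <- 40
    labels <- sample(c("a", "b"), n, TRUE)
    mk <- function(q) {
      m <- matrix(runif(n * 2), n, 2)
      hit <- runif(n) < q
      m[cbind(which(hit), match(labels[hit], c("a", "b")))] <- 2
      class_probabilities(m / rowSums(m), c("a", "b"))
    }
    A <- mk(0.8); B <- mk(0.6)
    accA <- mean(predicted_labels(A) == labels)
    accB <- mean(predicted_labels(B) == labels)
    P <- fuse(A, B, fusion_weights(max(accA, 1e-3), max(accB, 1e-3)))
    if (mean(predicted_labels(P) == labels) < min(accA, accB))
      viol <- viol + 1
  }
  expect_lte(viol, 10)
})
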