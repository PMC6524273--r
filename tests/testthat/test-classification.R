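make_expr2 <- function(mat) {
  dimnames(mat) <- list(sprintf("mir-%03d", seq_len(nrow(mat))),
                        sprintf("S%02d", seq_len(ncol(mat))))
  mat
}

test_that("KNN base cases and its error contract", {
  train <- rbind(c(0, 0), c(5, 5), c(5.1, 5))
  expect_equal(knn_predict(train, c("a", "b", "b"), c(0.1, 0), k = 1), "a")
  # query identical to k duplicated points with one label
  dup <- matrix(rep(c(2, 2), 5), ncol = 2, byrow = TRUE)
  expect_equal(knn_predict(rbind(dup, c(9, 9)),
                           c(rep("x", 5), "y"), c(2, 2), k = 5), "x")
  expect_error(knn_predict(train, c("a", "b", "b"), c(0, 0), k = 0),
               "positive")
  expect_error(knn_predict(train, c("a", "b", "b"), c(0, 0), k = 4),
               "exceeds")
})

test_that("KNN matches exhaustive brute force on random instances", {
  withr::with_seed(23, {
    for (rep in 1:100) {
      n <- sample(15:40, 1)
      p <- sample(2:5, 1)
      train <- matrix(stats::rnorm(n * p), n, p)
      labels <- sample(c("HC", "PC", "BTC"), n, replace = TRUE)
      k <- sample(c(1, 3, 5, 11), 1)
      q <- stats::rnorm(p)
      expect_identical(knn_predict(train, labels, q, k = min(k, n)),
                       bf_knn(train, labels, q, min(k, n)))
    }
  })
})

test_that("LOOCV separates well-separated classes perfectly", {
  m <- withr::with_seed(25, {
    centers <- rep(c(0, 20), each = 15)
    sapply(centers, function(cc) stats::rnorm(5, cc, 1))
  })
  m <- make_expr2(m)
  labels <- rep(c("cancer", "control"), each = 15)
  rep_ <- loocv_report(m, labels, k = 11)
  expect_equal(rep_$accuracy, 1)
  expect_equal(unname(rep_$sensitivity), c(1, 1))
  expect_equal(sum(rep_$contingency), 30)
  expect_equal(unname(colSums(rep_$contingency)), c(15, 15))
})

test_that("permuted labels score inside the binomial null band", {
  withr::with_seed(27, {
    m <- make_expr2(matrix(stats::rnorm(5 * 40), 5, 40))
    labels <- sample(rep(c("cancer", "control"), c(24, 16)))
    rep_ <- loocv_report(m, labels, k = 11)
    # majority-rate 0.6; 3 SD binomial band at n = 40
    band <- 3 * sqrt(0.6 * 0.4 / 40)
    expect_lt(abs(rep_$accuracy - 0.6), band + 0.15)
  })
})

test_that("a constant feature forces one shared prediction via tie-breaks", {
  m <- make_expr2(matrix(1, 1, 22))
  labels <- rep(c("cancer", "control"), each = 11)
  rep_ <- loocv_report(m, labels, k = 11)
  expect_equal(length(unique(rep_$predictions)), 1L)
  pred <- unique(rep_$predictions)
  expect_equal(rep_$accuracy, mean(labels == pred))
})

test_that("LOOCV report is invariant to sample ordering", {
  withr::with_seed(29, {
    m <- make_expr2(matrix(stats::rnorm(4 * 24), 4, 24))
    labels <- rep(c("PC", "BTC", "HC"), each = 8)
    r1 <- loocv_report(m, labels, k = 5)
    perm <- sample(24)
    r2 <- loocv_report(m[, perm], labels[perm], k = 5)
    expect_equal(r1$accuracy, r2$accuracy)
    expect_equal(r1$contingency, r2$contingency)
    expect_equal(r1$predictions, r2$predictions[names(r1$predictions)])
  })
})

test_that("classes with one member are rejected", {
  m <- make_expr2(matrix(stats::rnorm(3 * 5), 3, 5))
  expect_error(loocv_report(m, c("a", "a", "a", "a", "b"), k = 3), "b")
})

test_that("ranking puts an informative feature first and noise later", {
  withr::with_seed(31, {
    n <- 30
    labels <- rep(c("cancer", "control"), each = 15)
    good <- ifelse(labels == "cancer", 10, -10) + stats::rnorm(n, 0, 0.5)
    noise <- stats::rnorm(n)
    m <- make_expr2(rbind(good, noise))
    rk <- rank_and_accumulate(m, labels, c("mir-001", "mir-002"), k = 5)
    expect_equal(rk$individual$mirna_id[1], "mir-001")
    expect_equal(rk$cumulative$cum_accuracy[1], 1)
    # one candidate: cumulative equals individual
    rk1 <- rank_and_accumulate(m, labels, "mir-001", k = 5)
    expect_equal(rk1$cumulative$cum_accuracy, rk1$individual$accuracy[1])
  })
})

test_that("indistinguishable classes drain the minority class's sensitivity", {
  # classes PC and BTC share a feature distribution; HC is distinct
  withr::with_seed(33, {
    labels <- rep(c("PC", "BTC", "HC"), c(24, 10, 21))
    n <- length(labels)
    shared <- ifelse(labels == "HC", 0, 6)
    m <- make_expr2(t(sapply(1:8, function(g)
      shared + stats::rnorm(n, 0, 1))))
    rk <- rank_and_accumulate(m, labels, rownames(m), k = 11)
    final <- rk$reports[[length(rk$reports)]]
    expect_equal(unname(final$sensitivity["BTC"]), 0)
    expect_gt(final$contingency["PC", "BTC"], final$contingency["BTC", "BTC"])
  })
})

test_that("three informative features among noise rise to the top ranks", {
  withr::with_seed(35, {
    labels <- rep(c("cancer", "control"), c(34, 21))
    n <- length(labels)
    m <- rbind(t(sapply(1:3, function(g)
      ifelse(labels == "cancer", 3, 0) + stats::rnorm(n, 0, 1))),
      matrix(stats::rnorm(39 * n), 39, n))
    m <- make_expr2(m)
    rk <- rank_and_accumulate(m, labels, rownames(m), k = 11)
    expect_true(all(c("mir-001", "mir-002", "mir-003") %in%
                      rk$individual$mirna_id[1:6]))
    expect_true(all(diff(rk$cumulative$cum_accuracy[1:3]) >= -1e-12) ||
                  rk$cumulative$cum_accuracy[3] >=
                    rk$cumulative$cum_accuracy[1])
  })
})

test_that("bootstrap k selection is deterministic and honors its rule", {
  withr::with_seed(37, {
    labels <- rep(c("cancer", "control"), each = 15)
    m <- make_expr2(t(matrix(ifelse(labels == "cancer", 10, -10) +
                               stats::rnorm(30, 0, 0.3))))
    s1 <- select_k_bootstrap(m, labels, k_grid = c(1, 3, 5), B = 30, seed = 5)
    s2 <- select_k_bootstrap(m, labels, k_grid = c(1, 3, 5), B = 30, seed = 5)
    expect_identical(s1, s2)
    # perfect separation: every k attains 1, smallest wins
    expect_equal(s1$chosen_k, 1)
    expect_true(all(s1$per_k$mean_accuracy == 1))
  })
})

test_that("bootstrap selection lands near the brute-force optimum band", {
  withr::with_seed(39, {
    labels <- rep(c("cancer", "control"), each = 20)
    # noisy boundary: 1-NN overfits, large k oversmooths
    m <- make_expr2(t(matrix(ifelse(labels == "cancer", 1, -1) +
                               stats::rnorm(40, 0, 1.2))))
    sel <- select_k_bootstrap(m, labels, k_grid = seq(1, 15, 2), B = 80,
                              seed = 9)
    best <- sel$per_k$k[which.max(sel$per_k$mean_accuracy)]
    lim <- sel$per_k$mean_accuracy[which.max(sel$per_k$mean_accuracy)] -
      sel$per_k$se_accuracy[which.max(sel$per_k$mean_accuracy)]
    in_band <- sel$per_k$k[sel$per_k$mean_accuracy >= lim]
    expect_true(sel$chosen_k %in% in_band)
    expect_equal(sel$chosen_k, min(in_band))
    expect_gt(best, 1)   # intermediate k beats 1-NN on a noisy boundary
  })
})

test_that("two-group collapse preserves totals and rejects unknown labels", {
  expect_equal(two_group_collapse(c("PC", "BTC", "HC")),
               c("cancer", "cancer", "control"))
  expect_equal(two_group_collapse(rep("HC", 4)), rep("control", 4))
  x <- c("PC", "PC", "BTC", "HC")
  expect_equal(length(two_group_collapse(x)), length(x))
  expect_error(two_group_collapse(c("PC", "XX")), "XX")
})
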