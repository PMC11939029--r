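unit_rows <- function(m) m / sqrt(rowSums(m * m))

test_that("mutual nearest neighbors of identical points", {
  E <- unit_rows(rbind(c(1, 0), c(1, 0), c(0, 1)))
  nb <- mine_neighbors(E, k = 1)
  expect_equal(nb[1L, ], 2L)
  expect_equal(nb[2L, ], 1L)
})

test_that("neighbor table matches a brute-force pairwise computation", {
  ang <- c(0, 10, 90, 180, 200) * pi / 180
  E <- cbind(cos(ang), sin(ang))
  nb <- mine_neighbors(E, k = 2)
  ## brute force: all 25 cosines, self excluded, ties by lower index
  sims <- E %*% t(E)
  want <- t(vapply(1:5, function(i) {
    s <- sims[i, ]
    s[i] <- -Inf
    order(-s, seq_len(5))[1:2]
  }, integer(2)))
  expect_equal(unclass(nb)[, ], want, ignore_attr = TRUE)
  expect_true(all(nb != row(nb)))
})

test_that("neighbor ties break toward the lower index", {
  ## duplicates at rows 2 and 4 tie as neighbors of row 1
  E <- unit_rows(rbind(c(1, 0.1), c(0.6, 0.8), c(-1, 0), c(0.6, 0.8)))
  nb <- mine_neighbors(E, k = 1)
  expect_equal(nb[1L, ], 2L)
})

test_that("neighbor mining validates inputs", {
  E <- unit_rows(matrix(rnorm(20), 5))
  expect_error(mine_neighbors(E, k = 5), "smaller")
  expect_error(mine_neighbors(E, k = 0), "k")
  E[2L, 1L] <- NA
  expect_error(mine_neighbors(E, k = 1), "non-finite")
})

test_that("scan_loss closed forms", {
  one_hot <- matrix(c(1, 0, 0, 0), 1)
  expect_equal(scan_loss(one_hot, one_hot, lambda = 2), 0)

  ## four one-hot anchors, each its own neighbor: consistency 0, usage
  ## uniform over C = 4, lambda = 1 -> -ln 4
  anchors <- diag(4)
  expect_equal(scan_loss(anchors, anchors, lambda = 1), -log(4))

  ## B = 2, k = 1, everything uniform over C = 2, lambda = 0.5:
  ## -(1/2)(log .5 + log .5) + 0.5 * (2 * .5 * log .5)
  u <- matrix(0.5, 2, 2)
  expect_equal(scan_loss(u, u, lambda = 0.5),
               -log(0.5) + 0.5 * log(0.5))
})

test_that("scan_loss equals the scalar oracle on random batches", {
  set.seed(1)
  for (trial in seq_len(100)) {
    B <- sample(1:6, 1)
    k <- sample(1:4, 1)
    C <- sample(2:6, 1)
    anchor <- random_prob_rows(B, C)
    neigh <- array(0, c(B, k, C))
    for (j in seq_len(k)) neigh[, j, ] <- random_prob_rows(B, C)
    lambda <- stats::runif(1, 0, 3)
    expect_lt(abs(scan_loss(anchor, neigh, lambda) -
                    oracle_scan_loss(anchor, neigh, lambda)), 1e-8)
  }
})

test_that("consistency term is non-negative; lambda = 0 bounds the loss", {
  set.seed(2)
  for (trial in seq_len(20)) {
    B <- sample(1:5, 1)
    C <- sample(2:5, 1)
    anchor <- random_prob_rows(B, C)
    neigh <- random_prob_rows(B, C)
    expect_gte(scan_loss(anchor, neigh, lambda = 0), 0)
  }
})

test_that("scan_loss rejects invalid shapes and weights", {
  a <- random_prob_rows(3, 4)
  expect_error(scan_loss(a, random_prob_rows(2, 4), lambda = 1), "mismatch")
  expect_error(scan_loss(a, a, lambda = -1), "lambda")
})

test_that("an untrained head equals its seeded initialization and outputs
           valid distributions", {
  sim <- simulate_embeddings(c(30, 30, 30, 30), dim = 16, seed = 4)
  nb <- mine_neighbors(sim$values, k = 3)
  h1 <- train_scan(sim$values, nb, epochs = 0, seed = 11)
  h2 <- train_scan(sim$values, nb, epochs = 0, seed = 11)
  expect_identical(h1$params, h2$params)
  expect_length(h1$loss_trajectory, 0L)
  P <- predict(h1, sim$values, type = "prob")
  expect_true(all(P >= 0))
  expect_true(all(abs(rowSums(P) - 1) < 1e-6))
})

test_that("cluster assignment is equivariant and matches a scalar forward
           pass", {
  sim <- simulate_embeddings(c(20, 20, 20, 20), dim = 16, seed = 6)
  nb <- mine_neighbors(sim$values, k = 3)
  fit <- train_scan(sim$values, nb, epochs = 3, seed = 6)
  a <- predict(fit, sim$values)
  perm <- sample(nrow(sim$values))
  expect_equal(predict(fit, sim$values[perm, ]), a[perm])
  for (i in c(1L, 17L, 80L)) {
    p <- oracle_head_forward_row(fit$params, sim$values[i, ])
    expect_equal(predict(fit, sim$values[i, , drop = FALSE], "prob")[1L, ],
                 p, tolerance = 1e-12)
    expect_equal(a[i], which.max(p))
  }
})

test_that("training reduces the SCAN objective and is seed-reproducible", {
  sim <- simulate_embeddings(c(50, 50, 50, 50), dim = 16,
                             within_class_spread = 0.1,
                             class_separation = 2, seed = 3)
  nb <- mine_neighbors(sim$values, k = 3)
  f1 <- train_scan(sim$values, nb, epochs = 8, seed = 3)
  f2 <- train_scan(sim$values, nb, epochs = 8, seed = 3)
  expect_identical(f1$params, f2$params)
  expect_lt(f1$loss_trajectory[8L], f1$loss_trajectory[1L])
})

test_that("k-means baseline behaves at the edges and is deterministic", {
  sim <- simulate_embeddings(c(10, 10, 10, 10), dim = 8, seed = 2)
  expect_equal(kmeans_baseline(sim$values, 1, seed = 1),
               rep(1L, 40L))
  ## two tight, far-apart blobs
  blobs <- unit_rows(rbind(matrix(rnorm(40, 10, 0.01), 20),
                           matrix(rnorm(40, -10, 0.01), 20)))
  truth <- rep(1:2, each = 20)
  km <- kmeans_baseline(blobs, 2, seed = 4)
  expect_equal(evaluate_clustering(truth, km)$report$accuracy, 1)
  expect_identical(kmeans_baseline(sim$values, 4, seed = 9),
                   kmeans_baseline(sim$values, 4, seed = 9))
  expect_error(kmeans_baseline(sim$values, 100, seed = 1), "clusters")
})
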