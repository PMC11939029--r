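test_that("linear perturbation adds the same scalar everywhere", {
  expect_identical(linear_perturb(c(1, 2, 3), 0), c(1, 2, 3))
  expect_equal(linear_perturb(c(0, 0, 0, 0), 0.1), rep(0.1, 4))
  set.seed(3)
  for (trial in seq_len(100)) {
    v <- rnorm(sample(2:20, 1))
    n <- rnorm(1)
    w <- linear_perturb(v, n)
    expect_true(all(abs((w - v) - n) < 1e-15))
  }
  expect_error(linear_perturb(c(1, 2), Inf), "finite")
})

test_that("corruption is exact at sigma 0 and reproducible", {
  v <- rnorm(50)
  z <- corrupt(v, 0, seed = 1)
  expect_identical(z$vn, v)
  expect_identical(z$eps, rep(0, 50))
  a <- corrupt(v, 0.3, seed = 9)
  b <- corrupt(v, 0.3, seed = 9)
  expect_identical(a$eps, b$eps)
  expect_equal(a$vn - v, a$eps)
  expect_error(corrupt(v, -0.1), "sigma")
})

test_that("corruption noise has the requested variance", {
  v <- numeric(1e5)
  eps <- corrupt(v, 0.1, seed = 2)$eps
  s2 <- stats::var(eps)
  ## SE of the sample variance of N(0, sigma^2): sigma^2 * sqrt(2/(n-1))
  se <- 0.01 * sqrt(2 / (1e5 - 1))
  expect_lt(abs(s2 - 0.01), 3 * se)
})

test_that("autoencoder training reduces reconstruction error on duplicate
           pairs", {
  set.seed(4)
  x <- matrix(rnorm(10 * 16), 10, 16)
  ae <- train_autoencoder(x, hidden = 32, epochs = 400, seed = 4)
  mse <- mean((predict(ae, x) - x)^2)
  expect_lt(mse, 1e-3)
  expect_lte(ae$final_loss, ae$initial_loss)
})

test_that("zero-epoch autoencoders return their seeded initialization", {
  x <- matrix(rnorm(5 * 8), 5, 8)
  a1 <- train_autoencoder(x, hidden = 4, epochs = 0, seed = 7)
  a2 <- train_autoencoder(x, hidden = 4, epochs = 0, seed = 7)
  expect_identical(a1$params, a2$params)
  expect_length(a1$loss_trajectory, 0L)
  expect_error(train_autoencoder(x, matrix(0, 5, 9)), "mismatch")
})

test_that("autoencoder loss trajectories are mostly non-increasing", {
  set.seed(5)
  x <- matrix(rnorm(60 * 12), 60, 12)
  for (s in 1:5) {
    ae <- train_autoencoder(x, hidden = 16, epochs = 40, seed = s)
    steps <- diff(ae$loss_trajectory)
    expect_gte(mean(steps <= 1e-12), 0.9)
  }
})

test_that("denoising autoencoder learns to undo corruption", {
  set.seed(6)
  x <- matrix(rnorm(10 * 16), 10, 16)
  da0 <- train_denoising_autoencoder(x, sigma = 0, hidden = 32,
                                     epochs = 1200, seed = 6)
  expect_lt(mean((predict(da0, x) - x)^2), 1e-3)

  base <- matrix(rnorm(200 * 16), 200, 16)
  untrained <- train_denoising_autoencoder(base, sigma = 0.1, hidden = 32,
                                           epochs = 0, seed = 8)
  trained <- train_denoising_autoencoder(base, sigma = 0.1, hidden = 32,
                                         epochs = 150, seed = 8)
  held <- matrix(rnorm(50 * 16), 50, 16)
  noisy <- corrupt(held, 0.1, seed = 99)$vn
  err_untrained <- mean((predict(untrained, noisy) - held)^2)
  err_trained <- mean((predict(trained, noisy) - held)^2)
  expect_lt(err_trained, err_untrained)
  expect_equal(dim(predict(trained, held)), dim(held))
})

test_that("dynamic convolution matches a scalar reimplementation on a toy
           configuration", {
  set.seed(10)
  layer <- rhetclass:::dc_init(8, kernel_sizes = c(2L, 3L),
                               total_filters = 4L, n_candidates = 3L)
  X <- matrix(rnorm(5 * 16), 5, 16)
  out <- dynamic_conv(layer, X)
  for (i in seq_len(5)) {
    expect_equal(out[i, ], oracle_dynamic_conv_row(layer, X[i, ]),
                 tolerance = 1e-10)
  }
})

test_that("a single candidate bank reduces to a standard convolution and
           gates normalize", {
  set.seed(11)
  layer1 <- rhetclass:::dc_init(8, kernel_sizes = 2L, total_filters = 3L,
                                n_candidates = 1L)
  X <- matrix(rnorm(4 * 16), 4, 16)
  o <- dynamic_conv(layer1, X, cache = TRUE)
  g <- attr(o, "cache")$g
  expect_true(all(g == 1))

  layerK <- rhetclass:::dc_init(8, kernel_sizes = c(2L, 3L),
                                total_filters = 4L, n_candidates = 4L)
  oK <- dynamic_conv(layerK, X, cache = TRUE)
  gK <- attr(oK, "cache")$g
  expect_true(all(abs(rowSums(gK) - 1) < 1e-9))
  expect_error(dynamic_conv(layerK, matrix(0, 2, 10)), "2\\*dim")
})

test_that("filters split evenly with the remainder on the largest size", {
  expect_equal(rhetclass:::split_filters(256L, c(2L, 3L, 4L)),
               c(85L, 85L, 86L))
  expect_equal(rhetclass:::split_filters(6L, c(2L, 3L)), c(3L, 3L))
})

test_that("MEC training is reproducible and rejects degenerate labels", {
  sim <- simulate_embeddings(rep(40L, 4L), dim = 16,
                             within_class_spread = 0.2,
                             class_separation = 2, seed = 12)
  m1 <- train_mec(sim$values, sim$labels, epochs = 2, seed = 12,
                  dc_total_filters = 12L, ae_hidden = 16L)
  m2 <- train_mec(sim$values, sim$labels, epochs = 2, seed = 12,
                  dc_total_filters = 12L, ae_hidden = 16L)
  expect_identical(m1$classifier, m2$classifier)
  expect_identical(m1$layers, m2$layers)
  expect_error(train_mec(sim$values, rep(1L, nrow(sim$values)),
                         epochs = 1), "single class")
})

test_that("MEC predictions are distributions, equivariant, and match a
           row-wise forward pass", {
  sim <- simulate_embeddings(rep(50L, 4L), dim = 16,
                             within_class_spread = 0.2,
                             class_separation = 2, seed = 13)
  m <- train_mec(sim$values, sim$labels, epochs = 3, seed = 13,
                 dc_total_filters = 12L, ae_hidden = 16L)
  P <- predict(m, sim$values, type = "prob")
  expect_true(all(P >= 0))
  expect_true(all(abs(rowSums(P) - 1) < 1e-6))
  cls <- predict(m, sim$values)
  perm <- sample(nrow(sim$values))
  expect_equal(predict(m, sim$values[perm, ]), cls[perm])
  for (i in c(3L, 120L)) {
    expect_equal(predict(m, sim$values[i, , drop = FALSE], "prob")[1L, ],
                 P[i, ], tolerance = 1e-10)
  }
})

test_that("the masked no-convolution model reduces to a linear classifier
           on the embedding and still separates easy data", {
  sim <- simulate_embeddings(rep(500L, 4L), dim = 64,
                             within_class_spread = 0.05,
                             class_separation = 4, seed = 2)
  set.seed(42)
  te <- sample.int(nrow(sim$values), 400L)
  tr <- setdiff(seq_len(nrow(sim$values)), te)
  m <- train_mec(sim$values[tr, ], sim$labels[tr], epochs = 30, seed = 2,
                 dc = "none", supervision_weight = 0)
  acc <- mean(predict(m, sim$values[te, ]) == sim$labels[te])
  expect_gte(acc, 0.85)
})

test_that("the full cascade reaches high held-out accuracy on the separable
           benchmark", {
  sim <- simulate_embeddings(rep(500L, 4L), dim = 64,
                             within_class_spread = 0.05,
                             class_separation = 4, seed = 2)
  set.seed(42)
  te <- sample.int(nrow(sim$values), 400L)
  tr <- setdiff(seq_len(nrow(sim$values)), te)
  m <- train_mec(sim$values[tr, ], sim$labels[tr], epochs = 30, seed = 2,
                 dc_total_filters = 96L)
  acc <- mean(predict(m, sim$values[te, ]) == sim$labels[te])
  expect_gte(acc, 0.90)
})

test_that("duplicate pairs encode originals and paraphrases consistently", {
  corp <- generate_abstract_corpus(rep(6L, 4L), seed = 14)
  dp <- duplicate_pairs(corp, encoder_config(dim = 24, seed = 14))
  expect_equal(dim(dp$x), dim(dp$y))
  sims <- rowSums(dp$x * dp$y)
  expect_true(all(sims > 0.5))  # paraphrases stay close to originals
})
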