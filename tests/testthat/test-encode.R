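make_corpus <- function(n_per = 5L, lang = "en", seed = 1L) {
  generate_abstract_corpus(rep(n_per, 4L), language = lang, seed = seed)
}

test_that("encode is deterministic and unit-normalized", {
  corp <- make_corpus()
  cfg <- encoder_config(dim = 32, seed = 2)
  E1 <- encode(corp, cfg)
  E2 <- encode(corp, cfg)
  expect_identical(E1, E2)
  expect_true(all(abs(sqrt(rowSums(E1^2)) - 1) < 1e-6))
  expect_equal(nrow(E1), nrow(corp))
})

test_that("encode is a pure per-sentence function (batch independence)", {
  corp <- make_corpus(6L)
  cfg <- encoder_config(dim = 24, seed = 5)
  full <- encode(corp, cfg)
  sub <- encode(corp[3:7, ], cfg)
  expect_equal(unname(full[3:7, ]), unname(sub), tolerance = 1e-12)
})

test_that("zh text is encoded at character level and round-trips", {
  corp <- make_corpus(4L, lang = "zh")
  E <- encode(corp, encoder_config(dim = 24, seed = 3))
  expect_true(all(is.finite(E)))
  expect_true(all(abs(sqrt(rowSums(E^2)) - 1) < 1e-6))
})

test_that("sentences sharing no character n-grams are less similar than a
           sentence with itself", {
  pairs <- list(c("abcd", "wxyz"),
                c("qqq rrr", "sss ttt"),
                c("lmn opq", "uvw xyz"))
  for (p in pairs) {
    E <- encode(p, encoder_config(dim = 64, seed = 1))
    cross <- sum(E[1L, ] * E[2L, ])
    self <- sum(E[1L, ] * E[1L, ])
    expect_lt(cross, self - 1e-6)
    expect_equal(self, 1, tolerance = 1e-9)
  }
})

test_that("token truncation caps what reaches the n-gram counter", {
  long_tail <- paste(c(rep("alpha", 3L), "zzzz"), collapse = " ")
  cfg_short <- encoder_config(dim = 24, max_tokens = 3, seed = 1)
  cfg_long <- encoder_config(dim = 24, max_tokens = 10, seed = 1)
  trunc3 <- encode(paste(rep("alpha", 3L), collapse = " "), cfg_short)
  with_tail <- encode(long_tail, cfg_short)
  expect_equal(unname(trunc3), unname(with_tail), tolerance = 1e-12)
  expect_gt(max(abs(encode(long_tail, cfg_long) - with_tail)), 1e-6)
})

test_that("encoder config validation", {
  expect_error(encoder_config(dim = 4), "dim")
  expect_error(encoder_config(dim = 512, hash_buckets = 256),
               "hash_buckets")
  expect_error(encode(character(0), encoder_config(dim = 16)), "empty")
  expect_error(encode("   ", encoder_config(dim = 16)), "nonempty")
})

test_that("fine-tuning returns an identity adapter at 0 epochs", {
  corp <- make_corpus()
  E <- encode(corp, encoder_config(dim = 24, seed = 1))
  ad <- finetune_encoder(E, corp$label, epochs = 0)
  expect_identical(ad$W, diag(24))
  expect_identical(ad$b, numeric(24))
  expect_equal(apply_adapter(ad, E), l2_norm_rows_ref(E))
})

test_that("fine-tuning decreases the probe loss and preserves dimension", {
  corp <- make_corpus(40L, seed = 5)
  E <- encode(corp, encoder_config(dim = 48, seed = 5))
  ad <- finetune_encoder(E, corp$label, epochs = 10, seed = 5)
  expect_lte(ad$final_loss, ad$initial_loss)
  A <- apply_adapter(ad, E)
  expect_equal(dim(A), dim(E))
  expect_true(all(abs(sqrt(rowSums(A^2)) - 1) < 1e-6))
})

test_that("adapter application commutes with row permutation", {
  corp <- make_corpus(10L, seed = 8)
  E <- encode(corp, encoder_config(dim = 24, seed = 8))
  ad <- finetune_encoder(E, corp$label, epochs = 3, seed = 8)
  perm <- sample(nrow(E))
  expect_equal(apply_adapter(ad, E)[perm, ],
               apply_adapter(ad, E[perm, ]))
})

test_that("single-class fine-tuning is rejected", {
  corp <- make_corpus(6L)
  E <- encode(corp, encoder_config(dim = 24))
  expect_error(finetune_encoder(E, rep("methods", nrow(E))), "2 classes")
})

test_that("a label probe on a 400-sentence corpus reaches high training
           accuracy", {
  corp <- generate_abstract_corpus(c(100, 100, 100, 100), language = "en",
                                   seed = 5)
  E <- encode(corp, encoder_config(dim = 128, seed = 5))
  ad <- finetune_encoder(E, corp$label, epochs = 30, seed = 5)
  expect_gte(ad$probe_train_accuracy, 0.9)
})
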