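test_that("generated corpora meet per-class counts exactly", {
  for (case in list(list(counts = c(10, 12, 8, 5), lang = "en"),
                    list(counts = c(7, 7, 7, 7), lang = "zh"),
                    list(counts = c(0, 0, 0, 1), lang = "en"))) {
    corp <- generate_abstract_corpus(case$counts, language = case$lang,
                                     seed = 7)
    expect_equal(nrow(corp), sum(case$counts))
    tab <- table(factor(corp$label,
                        levels = c("objective", "methods", "results",
                                   "conclusion")))
    expect_equal(as.integer(tab), as.integer(case$counts))
    expect_true(all(nzchar(trimws(corp$text))))
    expect_false(anyDuplicated(paste(corp$abstract_id,
                                     corp$sentence_index)) > 0)
  }
})

test_that("abstract sections appear in rhetorical order", {
  corp <- generate_abstract_corpus(c(30, 30, 30, 30), seed = 3)
  order_of <- c(objective = 1L, methods = 2L, results = 3L, conclusion = 4L)
  for (aid in unique(corp$abstract_id)) {
    sub <- corp[corp$abstract_id == aid, ]
    sub <- sub[order(sub$sentence_index), ]
    expect_false(is.unsorted(order_of[sub$label]))
    expect_equal(sub$sentence_index, seq_len(nrow(sub)) - 1L)
  }
})

test_that("identical corpus specs give byte-identical serialized output", {
  a <- generate_abstract_corpus(c(9, 9, 9, 9), language = "zh", seed = 42)
  b <- generate_abstract_corpus(c(9, 9, 9, 9), language = "zh", seed = 42)
  fa <- tempfile(fileext = ".jsonl")
  fb <- tempfile(fileext = ".jsonl")
  write_corpus(a, fa)
  write_corpus(b, fb)
  expect_identical(readBin(fa, "raw", file.size(fa)),
                   readBin(fb, "raw", file.size(fb)))
})

test_that("label noise corrupts exactly floor(rate * n) labels", {
  counts <- c(25, 25, 25, 25)
  clean <- generate_abstract_corpus(counts, seed = 5)
  noisy <- generate_abstract_corpus(counts, label_noise_rate = 0.2, seed = 5)
  expect_equal(nrow(noisy), 100L)
  expect_equal(sum(clean$label != noisy$label), 20L)
  expect_true(all(noisy$label %in% c("objective", "methods", "results",
                                     "conclusion")))
})

test_that("template banks are rich and cue-bearing", {
  for (lang in c("en", "zh")) {
    bank <- rhetclass:::template_bank(lang)
    expect_true(all(lengths(bank) >= 20L))
    expect_true(all(!duplicated(unlist(bank))))
  }
  expect_error(rhetclass:::template_bank("fr"), "unknown language")
})

test_that("degenerate corpus specs are rejected", {
  expect_error(generate_abstract_corpus(c(0, 0, 0, 0)), "zero")
  expect_error(generate_abstract_corpus(c(-1, 2, 3, 4)), "non-negative")
  expect_error(generate_abstract_corpus(c(1, 2, 3))) # wrong length
})

test_that("splits are abstract-atomic, disjoint and exhaustive", {
  corp <- generate_abstract_corpus(c(40, 40, 40, 40), seed = 2)
  sp <- split_corpus(corp, 0.8, seed = 3)
  expect_equal(nrow(sp$train) + nrow(sp$test), nrow(corp))
  expect_length(intersect(sp$train$abstract_id, sp$test$abstract_id), 0L)
  got <- rbind(as.data.frame(sp$train), as.data.frame(sp$test))
  got <- got[order(got$abstract_id, got$sentence_index), ]
  want <- as.data.frame(corp)[order(corp$abstract_id, corp$sentence_index), ]
  rownames(got) <- rownames(want) <- NULL
  expect_equal(got, want)

  n_ab <- length(unique(corp$abstract_id))
  n_tr <- length(unique(sp$train$abstract_id))
  expect_equal(n_tr, round(0.8 * n_ab))

  sp2 <- split_corpus(corp, 0.5, seed = 10)
  sp3 <- split_corpus(corp, 0.5, seed = 11)
  expect_false(setequal(unique(sp2$train$abstract_id),
                        unique(sp3$train$abstract_id)))
})

test_that("invalid split fractions are rejected", {
  corp <- generate_abstract_corpus(c(5, 5, 5, 5), seed = 1)
  expect_error(split_corpus(corp, 1, 0), "positive")
  expect_error(split_corpus(corp, 0.6, 0.6), "sum to 1")
  one_ab <- corp[corp$abstract_id == corp$abstract_id[1L], ]
  expect_error(split_corpus(one_ab, 0.5), "at least 2 abstracts")
})

test_that("paraphrases preserve content and are seeded", {
  texts <- c("This study aimed to evaluate acupuncture.",
             "Patients were randomized to two arms.")
  p1 <- paraphrase_sentences(texts, "en", seed = 4)
  p2 <- paraphrase_sentences(texts, "en", seed = 4)
  expect_identical(p1, p2)
  expect_true(all(mapply(grepl, texts, p1, fixed = TRUE)))
  expect_false(any(p1 == texts))
})
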