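test_that("confusion tallies hand-listed pairs", {
  truth <- c(1, 1, 1, 2, 2, 3, 3, 3, 4, 4, 4, 4)
  pred  <- c(1, 2, 1, 2, 2, 3, 4, 3, 4, 4, 1, 4)
  m <- confusion(truth, pred)
  want <- matrix(c(2, 1, 0, 0,
                   0, 2, 0, 0,
                   0, 0, 2, 1,
                   1, 0, 0, 3), 4, 4, byrow = TRUE)
  expect_equal(unclass(m), want, ignore_attr = TRUE)
  expect_equal(sum(m), length(truth))
})

test_that("perfect predictions give a diagonal matrix", {
  labs <- sample(c("objective", "methods", "results", "conclusion"), 50,
                 replace = TRUE)
  m <- confusion(labs, labs)
  expect_equal(sum(diag(m)), 50L)
  expect_equal(sum(m) - sum(diag(m)), 0L)
})

test_that("confusion validates inputs", {
  expect_error(confusion(1:3, 1:4), "equal length")
  expect_error(confusion(c(1, 5), c(1, 2), n_classes = 4), "range")
  expect_error(confusion(c("objective", "bogus"), c("methods", "methods")),
               "labels")
})

test_that("hungarian matching solves canonical cases", {
  d <- diag(c(5L, 7L, 2L, 9L))
  hm <- hungarian_match(d)
  expect_equal(hm$permutation, 1:4)
  expect_equal(hm$matched, 23)

  anti <- matrix(0L, 3, 3)
  anti[cbind(1:3, 3:1)] <- c(4L, 5L, 6L)
  expect_equal(hungarian_match(anti)$permutation, 3:1)

  expect_error(hungarian_match(matrix(1, 2, 3)), "square")
})

test_that("exhaustive and algorithmic assignment agree with the oracle", {
  set.seed(7)
  for (trial in seq_len(30)) {
    C <- sample(2:6, 1)
    m <- matrix(rpois(C * C, 10), C, C)
    hm <- hungarian_match(m)
    or <- oracle_best_assignment(m)
    expect_equal(hm$matched, or$matched)
    ## the matched count is unique; permutations may tie, so compare scores
    expect_equal(sum(m[cbind(hm$permutation, seq_len(C))]), or$matched)
  }
  ## the O(n^3) path (used for C > 8) against the exhaustive oracle
  for (trial in seq_len(10)) {
    m <- matrix(rpois(49, 20), 7, 7)
    perm <- rhetclass:::hungarian_max(m)
    expect_equal(sum(m[cbind(perm, 1:7)]),
                 oracle_best_assignment(m)$matched)
  }
})

test_that("metrics: identity matrix scores 1 everywhere; micro F1 equals
           accuracy", {
  m <- rhetclass:::as_confusion(diag(rep(10L, 4)))
  rep_ <- metrics(m)
  expect_equal(rep_$accuracy, 1)
  expect_equal(unname(rep_$precision), rep(1, 4))
  expect_equal(unname(rep_$recall), rep(1, 4))
  expect_equal(rep_$macro_f1, 1)
  expect_equal(rep_$micro_f1, 1)

  set.seed(11)
  for (trial in seq_len(25)) {
    C <- sample(2:6, 1)
    m <- rhetclass:::as_confusion(matrix(rpois(C * C, 6), C, C))
    if (sum(m) == 0) next
    rep_ <- metrics(m)
    expect_equal(rep_$micro_f1, rep_$accuracy)
    vals <- unlist(rep_)
    expect_true(all(vals >= 0 & vals <= 1))
  }
})

test_that("metrics are invariant to simultaneous row+column permutation", {
  set.seed(12)
  m <- matrix(rpois(16, 8), 4, 4)
  perm <- sample(4)
  a <- metrics(rhetclass:::as_confusion(m))
  b <- metrics(rhetclass:::as_confusion(m[perm, perm]))
  expect_equal(a$accuracy, b$accuracy)
  expect_equal(sort(unname(a$f1)), sort(unname(b$f1)))
  expect_equal(a$macro_f1, b$macro_f1)
})

test_that("0/0 cells define their metrics as 0 and rounding is half away
           from zero", {
  m <- matrix(0L, 4, 4)
  m[1, 1] <- 10L
  m[2, 1] <- 5L  # class 2 never predicted correctly; column 2 empty
  rep_ <- metrics(rhetclass:::as_confusion(m))
  expect_equal(unname(rep_$precision[2L]), 0)
  expect_equal(unname(rep_$f1[2L]), 0)
  expect_equal(rhetclass:::round_half_away(0.8985, 3), 0.899)
  expect_equal(rhetclass:::round_half_away(0.91225, 4), 0.9123)
  expect_equal(rhetclass:::round_half_away(-0.5, 0), -1)
})

test_that("clustering evaluation is invariant to cluster relabeling", {
  truth <- rep(1:4, each = 25)
  relab <- c(3L, 1L, 4L, 2L)
  ev <- evaluate_clustering(truth, relab[truth])
  expect_equal(ev$report$accuracy, 1)
  expect_equal(sum(diag(ev$confusion)), 100L)
})

test_that("random assignments score near chance after matching", {
  set.seed(21)
  truth <- rep(1:4, each = 2500)
  assign <- sample(1:4, 10000, replace = TRUE)
  acc <- evaluate_clustering(truth, assign)$report$accuracy
  ## matching inflates chance slightly above 0.25; stay below 0.30
  expect_gte(acc, 0.25 - 3 * sqrt(0.25 * 0.75 / 10000))
  expect_lte(acc, 0.30)
})

test_that("reference confusion matrices reproduce the published figures", {
  ref <- reference_confusions()
  expect_equal(sum(ref$pseudolabel), 87529)
  expect_equal(sum(ref$paraphrase), 87529)

  rep2 <- metrics(ref$pseudolabel, decimals = 4)
  expect_equal(rep2$accuracy, 0.8983)
  expect_equal(unname(rep2$recall[1:3]), c(0.9183, 0.9341, 0.8247))
  expect_equal(unname(rep2$precision[1L]), 0.9522)

  rep3 <- metrics(ref$paraphrase)
  expect_equal(rhetclass:::round_half_away(rep3$accuracy, 3), 0.913)
  expect_equal(rhetclass:::round_half_away(unname(rep3$precision[3L]), 4),
               0.9152)
})
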