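## Evaluation: confusion matrices, Hungarian matching, metrics ---------------

#' Build a confusion matrix
#'
#' `counts[i, j]` is the number of sentences with true class `i` and
#' prediction (or raw cluster id) `j`. Row order is the canonical rhetorical
#' order: objective, methods, results, conclusion (for 4-class labels).
#'
#' @param truth,predicted Equal-length label vectors; character rhetorical
#'   labels or integers in `1..n_classes`.
#' @param n_classes Number of classes/clusters (default: inferred, at
#'   least 4 for character labels).
#' @return A square integer matrix of class `confusion_matrix`.
#' @export
confusion <- function(truth, predicted, n_classes = NULL) {
  if (length(truth) != length(predicted)) {
    stop("`truth` and `predicted` must have equal length", call. = FALSE)
  }
  if (is.character(truth) || is.factor(truth)) {
    t_int <- as_label_int(truth)
  } else t_int <- as.integer(truth)
  if (is.character(predicted) || is.factor(predicted)) {
    p_int <- as_label_int(predicted)
  } else p_int <- as.integer(predicted)
  if (is.null(n_classes)) n_classes <- max(t_int, p_int, 4L)
  if (any(t_int < 1L | t_int > n_classes) ||
      any(p_int < 1L | p_int > n_classes)) {
    stop("labels out of range 1..", n_classes, call. = FALSE)
  }
  m <- matrix(0L, n_classes, n_classes)
  tab <- table(factor(t_int, levels = seq_len(n_classes)),
               factor(p_int, levels = seq_len(n_classes)))
  m[] <- as.integer(tab)
  if (n_classes == 4L) {
    dimnames(m) <- list(true = RHET_CLASSES, predicted = RHET_CLASSES)
  }
  structure(m, class = c("confusion_matrix", "matrix"))
}

as_confusion <- function(m) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m), all(m >= 0))
  structure(m, class = c("confusion_matrix", "matrix"))
}

## All permutations of 1..n in lexicographic order (n small).
perms_lex <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- perms_lex(n - 1L)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    out[[i]] <- cbind(i, matrix(rest[sub], nrow(sub), n - 1L))
  }
  do.call(rbind, out)
}

## O(n^3) Hungarian algorithm (potentials form) maximizing the assignment
## sum; used when exhaustive search over permutations is no longer cheap.
hungarian_max <- function(M) {
  n <- nrow(M)
  cost <- max(M) - M                     # minimize cost == maximize M
  INF <- sum(cost) + 1
  u <- numeric(n + 1L)
  v <- numeric(n + 1L)
  p <- integer(n + 1L)                   # p[j]: row assigned to column j
  way <- integer(n + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(INF, n + 1L)
    used <- rep(FALSE, n + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      delta <- INF
      j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j + 1L]) {
          cur <- cost[i0, j] - u[i0 + 1L] - v[j + 1L]
          if (cur < minv[j + 1L]) {
            minv[j + 1L] <- cur
            way[j + 1L] <- j0
          }
          if (minv[j + 1L] < delta) {
            delta <- minv[j + 1L]
            j1 <- j
          }
        }
      }
      for (j in 0:n) {
        if (used[j + 1L]) {
          u[p[j + 1L] + 1L] <- u[p[j + 1L] + 1L] + delta
          v[j + 1L] <- v[j + 1L] - delta
        } else {
          minv[j + 1L] <- minv[j + 1L] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  perm <- integer(n)                     # perm[j] = class assigned to col j
  for (j in seq_len(n)) perm[j] <- p[j + 1L]
  ## return column -> row mapping as used by hungarian_match
  perm
}

#' Optimal cluster-to-class matching
#'
#' Finds the bijection between raw cluster columns and true-class rows that
#' maximizes the total matched count. For `C <= 8` the search is exhaustive
#' over all permutations in lexicographic order (so ties resolve to the
#' lexicographically smallest permutation); larger matrices use the
#' Hungarian assignment algorithm.
#'
#' @param m A square `confusion_matrix` (rows = true classes, columns = raw
#'   cluster ids).
#' @return A list with `permutation` (`permutation[j]` is the class matched
#'   to cluster column `j`) and `matched` (the maximized matched count).
#' @export
hungarian_match <- function(m) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    stop("confusion matrix must be square", call. = FALSE)
  }
  C <- nrow(m)
  if (C <= 8L) {
    pp <- perms_lex(C)
    scores <- apply(pp, 1L, function(perm) sum(m[cbind(perm, seq_len(C))]))
    best <- which.max(scores)            # first max => lexicographically
    perm <- pp[best, ]                   # smallest permutation on ties
    matched <- scores[best]
  } else {
    perm <- hungarian_max(m)
    matched <- sum(m[cbind(perm, seq_len(C))])
  }
  list(permutation = as.integer(perm), matched = as.numeric(matched))
}

#' Classification metrics from a confusion matrix
#'
#' One-vs-rest per class: `precision = TP/(TP+FP)`, `recall = TP/(TP+FN)`,
#' F1 the harmonic mean of the two, with `0/0 := 0`. Overall accuracy is
#' `trace/total`; `macro_f1` is the unweighted mean of class F1 values;
#' `micro_f1` is computed from pooled TP/FP/FN and coincides with accuracy
#' for single-label multi-class data. Optional rounding is half away from
#' zero.
#'
#' @param m A `confusion_matrix`.
#' @param decimals Optional number of decimals to round the report to.
#' @return A list of class `metrics_report`: `accuracy`, `precision`,
#'   `recall`, `f1` (per-class vectors), `macro_f1`, `micro_f1`.
#' @export
metrics <- function(m, decimals = NULL) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  total <- sum(m)
  if (total == 0) stop("confusion matrix is empty", call. = FALSE)
  tp <- diag(m)
  fp <- colSums(m) - tp
  fn <- rowSums(m) - tp
  safe_div <- function(a, b) ifelse(b == 0, 0, a / b)
  precision <- safe_div(tp, tp + fp)
  recall <- safe_div(tp, tp + fn)
  f1 <- safe_div(2 * precision * recall, precision + recall)
  accuracy <- sum(tp) / total
  micro_p <- safe_div(sum(tp), sum(tp) + sum(fp))
  micro_r <- safe_div(sum(tp), sum(tp) + sum(fn))
  micro_f1 <- safe_div(2 * micro_p * micro_r, micro_p + micro_r)
  rep_ <- list(accuracy = accuracy, precision = precision, recall = recall,
               f1 = f1, macro_f1 = mean(f1), micro_f1 = micro_f1)
  if (!is.null(decimals)) {
    rep_ <- lapply(rep_, round_half_away, digits = decimals)
  }
  structure(rep_, class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("accuracy  %.4f   macro F1 %.4f   micro F1 %.4f\n",
              x$accuracy, x$macro_f1, x$micro_f1))
  tab <- rbind(precision = x$precision, recall = x$recall, f1 = x$f1)
  colnames(tab) <- names(x$precision) %||% seq_along(x$precision)
  print(round(tab, 4))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate a clustering against true labels
#'
#' Builds the raw true-class x cluster count matrix, relabels the cluster
#' columns by [hungarian_match()], and computes the metric report on the
#' remapped matrix. The reported accuracy equals matched count / total.
#'
#' @param truth True labels (character or integer 1..C).
#' @param assignment Integer cluster assignment in 1..C.
#' @param decimals Optional rounding for the report.
#' @return A list with `confusion` (remapped `confusion_matrix`),
#'   `permutation`, and `report` (a `metrics_report`).
#' @export
evaluate_clustering <- function(truth, assignment, decimals = NULL) {
  raw <- confusion(truth, assignment)
  hm <- hungarian_match(raw)
  ## column j of the raw matrix is class hm$permutation[j]; reorder columns
  ## so column i holds the cluster matched to class i
  inv <- order(hm$permutation)
  remapped <- raw[, inv, drop = FALSE]
  colnames(remapped) <- rownames(raw)
  remapped <- as_confusion(remapped)
  list(confusion = remapped, permutation = hm$permutation,
       report = metrics(remapped, decimals = decimals))
}

#' Reference confusion matrices for SBERT-DocSCAN clustering
#'
#' The two internally consistent published confusion matrices of an
#' SBERT-DocSCAN clustering of an 87,529-sentence labeled Chinese
#' medical-abstract test corpus (models trained on a pseudolabeled and a
#' paraphrased synthetic corpus respectively). They are shipped as fixed
#' inputs for validating the metric implementations: feeding them through
#' [metrics()] and [evaluate_clustering()] must reproduce the published
#' accuracy, precision and recall figures.
#'
#' @return A named list of two `confusion_matrix` objects,
#'   `pseudolabel` and `paraphrase`.
#' @export
reference_confusions <- function() {
  dir <- system.file("extdata", package = "rhetclass")
  load_one <- function(f) {
    m <- as.matrix(utils::read.csv(file.path(dir, f), row.names = 1L))
    colnames(m) <- rownames(m)
    as_confusion(m)
  }
  list(pseudolabel = load_one("confusion_pseudolabel.csv"),
       paraphrase = load_one("confusion_paraphrase.csv"))
}
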