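## Deterministic hashing sentence encoder ------------------------------------
##
## The default encoder maps a sentence to character 1-3-gram term
## frequencies, hashes the grams into a fixed bucket space (FNV-1a), and
## projects the bucket counts through a seed-fixed Gaussian matrix to the
## target dimension, then L2-normalizes. It is a pure function of
## (records, config): each occupied bucket's projection row is derived from
## (seed, bucket) alone, so embeddings do not depend on which other
## sentences are in the batch. A pretrained sentence encoder can stand
## behind the same interface by supplying an embedding matrix directly to
## downstream functions.

#' Encoder configuration
#'
#' @param dim Output dimension (default 768, the usual sentence-transformer
#'   width); at least 8.
#' @param max_tokens Token cap per sentence (default 64). Tokens are
#'   whitespace words, or single characters for CJK text.
#' @param hash_buckets Size of the hashed n-gram space (default 2^18).
#' @param normalize Unit-normalize output rows (default TRUE).
#' @param seed Seed fixing the Gaussian projection.
#' @return A list of class `encoder_config`.
#' @export
encoder_config <- function(dim = 768L, max_tokens = 64L,
                           hash_buckets = 2L^18L, normalize = TRUE,
                           seed = 1L) {
  check_scalar(dim, "dim", lower = 8, integer = TRUE)
  check_scalar(max_tokens, "max_tokens", lower = 1, integer = TRUE)
  check_scalar(hash_buckets, "hash_buckets", lower = 8, integer = TRUE)
  if (dim > hash_buckets) {
    stop("`dim` must not exceed `hash_buckets`", call. = FALSE)
  }
  structure(list(dim = as.integer(dim), max_tokens = as.integer(max_tokens),
                 hash_buckets = as.integer(hash_buckets),
                 normalize = isTRUE(normalize), seed = as.integer(seed)),
            class = "encoder_config")
}

has_cjk <- function(x) {
  grepl("[一-鿿　-〿＀-￯]", x)
}

truncate_tokens <- function(text, max_tokens) {
  if (has_cjk(text)) {
    chars <- strsplit(text, "", fixed = FALSE)[[1L]]
    paste(head(chars, max_tokens), collapse = "")
  } else {
    words <- strsplit(trimws(text), "\\s+")[[1L]]
    paste(head(words, max_tokens), collapse = " ")
  }
}

char_ngrams <- function(text, n_min = 1L, n_max = 3L) {
  chars <- strsplit(text, "", fixed = FALSE)[[1L]]
  L <- length(chars)
  if (L == 0L) return(character(0))
  out <- vector("list", n_max - n_min + 1L)
  for (n in n_min:n_max) {
    if (L < n) break
    starts <- seq_len(L - n + 1L)
    grams <- vapply(starts, function(s) {
      paste(chars[s:(s + n - 1L)], collapse = "")
    }, character(1))
    out[[n - n_min + 1L]] <- grams
  }
  grams <- unlist(out, use.names = FALSE)
  grams[!grepl("^\\s+$", grams)]
}

## Projection row for one hash bucket, a pure function of (seed, bucket).
bucket_row <- function(bucket, dim, seed) {
  set.seed((derive_seed(seed, paste0("bucket", bucket)) %% 2147483647L))
  rnorm(dim)
}

#' Encode sentences into fixed-dimension embeddings
#'
#' Deterministic hashing encoder: character 1-3-gram term frequencies of the
#' token-truncated sentence, hashed into `hash_buckets` buckets, projected by
#' a seed-fixed Gaussian matrix to `dim` dimensions and (optionally)
#' L2-normalized. Identical `(corpus, config)` always give bit-identical
#' matrices.
#'
#' @param corpus A `sentence_corpus` data frame, or a character vector of
#'   sentences.
#' @param config An [encoder_config()].
#' @return An n x dim matrix with unit-norm rows (if `normalize`); rownames
#'   are `abstract_id#sentence_index` ids (or `s...` for bare text).
#' @examples
#' corp <- generate_abstract_corpus(c(3, 3, 3, 3), seed = 1)
#' E <- encode(corp, encoder_config(dim = 32))
#' dim(E)
#' @export
encode <- function(corpus, config = encoder_config()) {
  stopifnot(inherits(config, "encoder_config"))
  if (is.character(corpus)) {
    texts <- corpus
    ids <- sprintf("s%06d", seq_along(texts))
  } else {
    stopifnot(is.data.frame(corpus))
    texts <- corpus$text
    ids <- paste0(corpus$abstract_id, "#", corpus$sentence_index)
  }
  if (length(texts) == 0L) stop("empty record list", call. = FALSE)
  if (any(!nzchar(trimws(texts)))) {
    stop("texts must be nonempty after whitespace stripping", call. = FALSE)
  }

  truncated <- vapply(texts, truncate_tokens, character(1),
                      max_tokens = config$max_tokens, USE.NAMES = FALSE)
  gram_lists <- lapply(truncated, char_ngrams)
  all_grams <- unlist(gram_lists, use.names = FALSE)
  uniq <- unique(all_grams)
  buckets <- (fnv1a32(uniq) %% config$hash_buckets) + 1
  bucket_of <- buckets[match(all_grams, uniq)]

  sent_of <- rep.int(seq_along(gram_lists), lengths(gram_lists))
  occ <- sort(unique(buckets))
  bcol <- match(bucket_of, occ)

  ## sparse tf counts (n x occupied buckets); duplicate triplets are summed
  S <- Matrix::sparseMatrix(i = sent_of, j = bcol, x = 1,
                            dims = c(length(texts), length(occ)))
  S <- Matrix::Diagonal(x = 1 / lengths(gram_lists)) %*% S

  ## with_seed shields the caller's RNG stream from the per-bucket seeding
  proj <- with_seed(config$seed, {
    vapply(occ, bucket_row, numeric(config$dim),
           dim = config$dim, seed = config$seed)         # dim x occupied
  })
  E <- as.matrix(S %*% t(proj))
  if (config$normalize) E <- l2_normalize_rows(E)
  rownames(E) <- ids
  E
}

#' Fine-tune a linear encoder adapter with a label probe
#'
#' Trains a square linear adapter (initialized at the identity) jointly with
#' a softmax 4-class probe by cross-entropy on base embeddings, then
#' discards the probe. Applying the adapter re-orients the embedding space
#' toward the functional (rhetorical) aspects of sentences rather than their
#' literal content, which is what makes downstream clustering work.
#'
#' @param embeddings Base embedding matrix (n x d, unit-norm rows).
#' @param labels Rhetorical labels (character in the 4-class set, or integers
#'   1..4), length n; at least 2 distinct classes.
#' @param epochs Training epochs (default 30); 0 returns the identity
#'   adapter unchanged.
#' @param batch_size Mini-batch size (default 64).
#' @param learning_rate Adam step size (default 1e-3; the adapter is a
#'   shallow linear map, not a transformer, so it takes a larger step than
#'   deep fine-tuning would).
#' @param seed Seed for initialization and batch order.
#' @return An object of class `encoder_adapter`: the d x d map and bias,
#'   training metadata (epochs, seed, loss trajectory, final probe training
#'   accuracy).
#' @export
finetune_encoder <- function(embeddings, labels, epochs = 30L,
                             batch_size = 64L, learning_rate = 1e-3,
                             seed = 1L) {
  stopifnot(is.matrix(embeddings))
  y <- as_label_int(labels)
  if (length(unique(y)) < 2L) {
    stop("need at least 2 classes to fine-tune", call. = FALSE)
  }
  check_scalar(epochs, "epochs", lower = 0, integer = TRUE)
  n <- nrow(embeddings)
  d <- ncol(embeddings)
  C <- 4L
  stopifnot(length(y) == n)

  with_seed(derive_seed(seed, "adapter"), {
    params <- list(
      W = diag(d),
      b = numeric(d),
      P = matrix(rnorm(d * C, sd = 0.01), d, C),
      pb = numeric(C)
    )
    st <- adam_init(params)
    traj <- numeric(0)
    final_acc <- NA_real_
    if (epochs > 0L) {
      for (ep in seq_len(epochs)) {
        ord <- sample.int(n)
        ep_loss <- 0
        nb <- 0L
        for (start in seq(1L, n, by = batch_size)) {
          idx <- ord[start:min(start + batch_size - 1L, n)]
          X <- embeddings[idx, , drop = FALSE]
          B <- length(idx)
          H <- X %*% params$W + rep(params$b, each = B)
          Z <- H %*% params$P + rep(params$pb, each = B)
          Pr <- softmax_rows(Z)
          yb <- y[idx]
          loss <- -mean(log(pmax(Pr[cbind(seq_len(B), yb)], 1e-12)))
          dZ <- Pr
          dZ[cbind(seq_len(B), yb)] <- dZ[cbind(seq_len(B), yb)] - 1
          dZ <- dZ / B
          grads <- list(
            W = crossprod(X, dZ %*% t(params$P)),
            b = colSums(dZ %*% t(params$P)),
            P = crossprod(H, dZ),
            pb = colSums(dZ)
          )
          upd <- adam_step(params, grads, st, learning_rate)
          params <- upd$params
          st <- upd$state
          ep_loss <- ep_loss + loss
          nb <- nb + 1L
        }
        traj <- c(traj, ep_loss / nb)
      }
      H <- embeddings %*% params$W + rep(params$b, each = n)
      Pr <- softmax_rows(H %*% params$P + rep(params$pb, each = n))
      final_acc <- mean(max.col(Pr, ties.method = "first") == y)
    }
    structure(list(
      W = params$W, b = params$b, dim = d,
      epochs = as.integer(epochs), seed = as.integer(seed),
      loss_trajectory = traj,
      initial_loss = if (length(traj)) traj[1L] else NA_real_,
      final_loss = if (length(traj)) traj[length(traj)] else NA_real_,
      probe_train_accuracy = final_acc
    ), class = "encoder_adapter")
  })
}

#' Apply a fine-tuned adapter to embeddings
#'
#' @param adapter An `encoder_adapter`.
#' @param embeddings n x d matrix (d must match the adapter).
#' @param normalize Re-normalize rows after mapping (default TRUE).
#' @return The adapted n x d matrix (rownames preserved).
#' @export
apply_adapter <- function(adapter, embeddings, normalize = TRUE) {
  stopifnot(inherits(adapter, "encoder_adapter"), is.matrix(embeddings))
  if (ncol(embeddings) != adapter$dim) {
    stop("embedding dimension does not match adapter", call. = FALSE)
  }
  out <- embeddings %*% adapter$W + rep(adapter$b, each = nrow(embeddings))
  if (normalize) out <- l2_normalize_rows(out)
  rownames(out) <- rownames(embeddings)
  out
}

#' @export
predict.encoder_adapter <- function(object, newdata, normalize = TRUE, ...) {
  apply_adapter(object, newdata, normalize = normalize)
}

#' @export
print.encoder_adapter <- function(x, ...) {
  cat(sprintf("Encoder adapter: %d x %d linear map, %d epochs (seed %d)\n",
              x$dim, x$dim, x$epochs, x$seed))
  if (x$epochs > 0L) {
    cat(sprintf("  probe cross-entropy %.4f -> %.4f; probe accuracy %.3f\n",
                x$initial_loss, x$final_loss, x$probe_train_accuracy))
  }
  invisible(x)
}
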