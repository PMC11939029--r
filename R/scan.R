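## SCAN-loss clustering ------------------------------------------------------
##
## The clustering route rests on the inductive bias that a point and its
## nearest neighbors in embedding space share a rhetorical class. A small
## softmax head f(.) is trained to minimize
##
##   L = -(1/|D|) sum_x sum_{k in N_x} log( f(x) . f(k) )
##       + lambda * sum_i p_i log p_i
##
## where N_x are the k mined cosine neighbors of x and p is the mean cluster
## usage over the batch. The first (consistency) term pushes neighbors to the
## same cluster; the entropy term blocks the shortcut of collapsing every
## point into one cluster.

#' Mine exact cosine nearest neighbors
#'
#' Row i of the result holds the indices (1-based) of the `k` rows with the
#' highest cosine similarity to row i, self excluded; ties break toward the
#' lower index. Search is exact (full pairwise similarities, computed in row
#' blocks).
#'
#' @param embeddings n x d matrix; rows are normalized internally so the
#'   metric is cosine regardless of input scaling.
#' @param k Number of neighbors (default 5), `1 <= k < n`.
#' @return An n x k integer matrix of class `neighbor_table`.
#' @export
mine_neighbors <- function(embeddings, k = 5L) {
  stopifnot(is.matrix(embeddings))
  if (any(!is.finite(embeddings))) {
    stop("embeddings contain non-finite rows", call. = FALSE)
  }
  n <- nrow(embeddings)
  check_scalar(k, "k", lower = 1, integer = TRUE)
  if (k >= n) stop("`k` must be smaller than the number of rows",
                   call. = FALSE)
  E <- l2_normalize_rows(embeddings)
  idx <- matrix(0L, n, k)
  block <- 1024L
  for (start in seq(1L, n, by = block)) {
    rows <- start:min(start + block - 1L, n)
    sims <- E[rows, , drop = FALSE] %*% t(E)     # |rows| x n
    for (r in seq_along(rows)) {
      s <- sims[r, ]
      s[rows[r]] <- -Inf
      ## order(): ties resolved by the secondary index key (lower first)
      idx[rows[r], ] <- order(-s, seq_len(n))[seq_len(k)]
    }
  }
  structure(idx, class = c("neighbor_table", "matrix"))
}

#' SCAN loss of a batch
#'
#' Evaluates the clustering objective for a batch of anchor probability rows
#' and their neighbors' probability rows: the consistency term
#' `-(1/B) * sum log(anchor . neighbor)` over all anchor-neighbor pairs plus
#' the entropy regulariser `lambda * sum_i p_i log p_i`, where `p` is the
#' column mean of the anchor probabilities. Natural logarithms; dot products
#' are clipped below at 1e-12; `0 * log 0` is 0.
#'
#' @param anchor_probs B x C matrix of probability rows.
#' @param neighbor_probs B x k x C array (or B x C matrix when k = 1).
#' @param lambda Non-negative entropy weight.
#' @return The scalar loss.
#' @export
scan_loss <- function(anchor_probs, neighbor_probs, lambda = 2) {
  check_scalar(lambda, "lambda", lower = 0)
  if (is.matrix(neighbor_probs)) {
    neighbor_probs <- array(neighbor_probs,
                            c(nrow(neighbor_probs), 1L, ncol(neighbor_probs)))
  }
  B <- nrow(anchor_probs)
  C <- ncol(anchor_probs)
  if (dim(neighbor_probs)[1L] != B || dim(neighbor_probs)[3L] != C) {
    stop("anchor/neighbor shape mismatch", call. = FALSE)
  }
  k <- dim(neighbor_probs)[2L]
  cons <- 0
  for (j in seq_len(k)) {
    dots <- rowSums(anchor_probs * neighbor_probs[, j, , drop = TRUE])
    cons <- cons - sum(log(pmax(dots, 1e-12)))
  }
  cons <- cons / B
  p <- colMeans(anchor_probs)
  ent <- sum(ifelse(p > 0, p * log(p), 0))
  cons + lambda * ent
}

## Forward pass of the cluster head MLP. Returns hidden activations and
## probabilities; `mask` is a dropout mask applied to the hidden layer.
head_forward <- function(params, X, mask = NULL) {
  B <- nrow(X)
  H <- relu(X %*% params$W1 + rep(params$b1, each = B))
  if (!is.null(mask)) H <- H * mask
  Z <- H %*% params$W2 + rep(params$b2, each = B)
  list(H = H, P = softmax_rows(Z))
}

head_init <- function(dim, hidden_width, C) {
  list(
    W1 = matrix(rnorm(dim * hidden_width, sd = sqrt(2 / dim)),
                dim, hidden_width),
    b1 = numeric(hidden_width),
    W2 = matrix(rnorm(hidden_width * C, sd = sqrt(2 / hidden_width)),
                hidden_width, C),
    b2 = numeric(C)
  )
}

#' Train a SCAN cluster head
#'
#' Minimizes the SCAN loss by mini-batch Adam over a dim -> hidden -> C
#' softmax MLP on frozen embeddings. Each batch consists of a set of anchors
#' plus all their `k` mined neighbors; cluster usage `p` is computed per
#' batch from the anchor probabilities. Dropout is applied to the hidden
#' layer during training only. With `epochs = 0` the seeded initialization
#' is returned untrained.
#'
#' @param embeddings n x d matrix (unit-norm rows).
#' @param neighbors A `neighbor_table` from [mine_neighbors()] consistent
#'   with `embeddings`.
#' @param num_clusters Number of clusters C (default 4).
#' @param entropy_weight Entropy regulariser weight lambda (default 2).
#' @param epochs Training epochs (default 30).
#' @param batch_size Anchors per batch (default 64).
#' @param learning_rate Adam step size (default 1e-3 for the shallow head;
#'   see the methods vignette for the choice).
#' @param dropout Hidden-layer dropout rate (default 0.5).
#' @param hidden_width Hidden layer width (default 128).
#' @param seed Seed for initialization, batch order and dropout.
#' @return An object of class `docscan` holding the trained head, the
#'   configuration and the per-epoch loss trajectory.
#' @examples
#' sim <- simulate_embeddings(c(40, 40, 40, 40), dim = 16,
#'                            within_class_spread = 0.05,
#'                            class_separation = 4, seed = 1)
#' nb <- mine_neighbors(sim$values, k = 3)
#' fit <- train_scan(sim$values, nb, epochs = 5, seed = 1)
#' table(predict(fit, sim$values), sim$labels)
#' @export
train_scan <- function(embeddings, neighbors, num_clusters = 4L,
                       entropy_weight = 2, epochs = 30L, batch_size = 64L,
                       learning_rate = 1e-3, dropout = 0.5,
                       hidden_width = 128L, seed = 1L) {
  stopifnot(is.matrix(embeddings), inherits(neighbors, "neighbor_table"))
  n <- nrow(embeddings)
  if (n == 0L) stop("empty embedding matrix", call. = FALSE)
  if (nrow(neighbors) != n || max(neighbors) > n) {
    stop("neighbor table inconsistent with embeddings", call. = FALSE)
  }
  check_scalar(num_clusters, "num_clusters", lower = 2, integer = TRUE)
  check_scalar(entropy_weight, "entropy_weight", lower = 0)
  check_scalar(epochs, "epochs", lower = 0, integer = TRUE)
  check_scalar(dropout, "dropout", lower = 0, upper = 1)
  C <- as.integer(num_clusters)
  d <- ncol(embeddings)
  k <- ncol(neighbors)
  lambda <- entropy_weight

  with_seed(derive_seed(seed, "scan"), {
    params <- head_init(d, hidden_width, C)
    st <- adam_init(params)
    traj <- numeric(0)

    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      nb_count <- 0L
      for (start in seq(1L, n, by = batch_size)) {
        anchors <- ord[start:min(start + batch_size - 1L, n)]
        B <- length(anchors)
        nbr <- neighbors[anchors, , drop = FALSE]       # B x k
        Xa <- embeddings[anchors, , drop = FALSE]
        Xn <- embeddings[as.vector(nbr), , drop = FALSE] # (B*k) x d

        mask_a <- if (dropout > 0) {
          matrix(stats::rbinom(B * hidden_width, 1L, 1 - dropout),
                 B, hidden_width) / (1 - dropout)
        } else NULL
        mask_n <- if (dropout > 0) {
          matrix(stats::rbinom(B * k * hidden_width, 1L, 1 - dropout),
                 B * k, hidden_width) / (1 - dropout)
        } else NULL

        fa <- head_forward(params, Xa, mask_a)
        fn <- head_forward(params, Xn, mask_n)
        Pa <- fa$P                                       # B x C
        Pn <- fn$P                                       # (B*k) x C, column j
                                                         # blocks of B rows

        ## consistency: dots s[b,j] = Pa[b,] . Pn[b + (j-1)B, ]
        Pn_arr <- array(Pn, c(B, k, C))
        dots <- matrix(0, B, k)
        for (j in seq_len(k)) {
          dots[, j] <- rowSums(Pa * Pn_arr[, j, , drop = TRUE])
        }
        dots_c <- pmax(dots, 1e-12)
        p_use <- colMeans(Pa)
        ## training objective: consistency as the per-anchor MEAN over the
        ## k neighbors (not the sum), so the consistency/entropy balance is
        ## independent of k; see the methods vignette. scan_loss() itself
        ## keeps the canonical neighbor-sum form.
        loss <- -sum(log(dots_c)) / (B * k) +
          lambda * sum(ifelse(p_use > 0, p_use * log(p_use), 0))

        ## gradients wrt probability rows
        dPa <- matrix(0, B, C)
        dPn <- array(0, c(B, k, C))
        for (j in seq_len(k)) {
          w <- -1 / (B * k * dots_c[, j])
          dPa <- dPa + w * Pn_arr[, j, , drop = TRUE]
          dPn[, j, ] <- w * Pa
        }
        ## entropy term: d/dPa[b,i] of lambda * sum p log p, p = colMeans
        dPa <- dPa + rep((lambda / B) * (log(pmax(p_use, 1e-12)) + 1),
                         each = B)

        ## softmax backward: dZ = P * (dP - rowSums(dP * P))
        dZa <- Pa * (dPa - rowSums(dPa * Pa))
        dPn_mat <- matrix(dPn, B * k, C)
        dZn <- Pn * (dPn_mat - rowSums(dPn_mat * Pn))

        ## accumulate parameter grads over anchor and neighbor passes
        bw <- function(X, f, dZ, mask) {
          dH <- dZ %*% t(params$W2)
          if (!is.null(mask)) dH <- dH * mask
          dH[f$H <= 0] <- 0
          list(W1 = crossprod(X, dH), b1 = colSums(dH),
               W2 = crossprod(f$H, dZ), b2 = colSums(dZ))
        }
        ga <- bw(Xa, fa, dZa, mask_a)
        gn <- bw(Xn, fn, dZn, mask_n)
        grads <- Map(`+`, ga, gn)

        upd <- adam_step(params, grads, st, learning_rate)
        params <- upd$params
        st <- upd$state
        ep_loss <- ep_loss + loss
        nb_count <- nb_count + 1L
        if (!is.finite(loss)) {
          stop("SCAN training diverged to a non-finite loss at epoch ", ep,
               call. = FALSE)
        }
      }
      traj <- c(traj, ep_loss / nb_count)
    }

    structure(list(
      params = params, dim = d, num_clusters = C, k = k,
      entropy_weight = lambda, epochs = as.integer(epochs),
      hidden_width = as.integer(hidden_width), dropout = dropout,
      learning_rate = learning_rate, seed = as.integer(seed),
      loss_trajectory = traj
    ), class = "docscan")
  })
}

#' Cluster probabilities or assignments from a trained head
#'
#' @param object A `docscan` fit.
#' @param newdata n x d embedding matrix.
#' @param type `"cluster"` for hard assignments (argmax, ties to the lowest
#'   cluster id) or `"prob"` for the probability matrix.
#' @param ... Unused.
#' @return Integer vector in 1..C, or an n x C probability matrix.
#' @export
predict.docscan <- function(object, newdata, type = c("cluster", "prob"),
                            ...) {
  type <- match.arg(type)
  stopifnot(is.matrix(newdata))
  if (ncol(newdata) != object$dim) {
    stop("embedding dimension does not match the fitted head", call. = FALSE)
  }
  P <- head_forward(object$params, newdata)$P
  if (type == "prob") return(P)
  max.col(P, ties.method = "first")
}

#' Hard cluster assignment (argmax of the head probabilities)
#'
#' @param head A `docscan` fit.
#' @param embeddings n x d matrix.
#' @return Integer assignment vector in 1..C.
#' @export
assign_clusters <- function(head, embeddings) {
  predict(head, embeddings, type = "cluster")
}

#' @export
print.docscan <- function(x, ...) {
  cat(sprintf(
    "SCAN cluster head: %d -> %d -> %d, lambda = %g, k = %d, %d epochs\n",
    x$dim, x$hidden_width, x$num_clusters, x$entropy_weight, x$k, x$epochs))
  if (length(x$loss_trajectory)) {
    cat(sprintf("  loss %.4f -> %.4f\n", x$loss_trajectory[1L],
                x$loss_trajectory[length(x$loss_trajectory)]))
  }
  invisible(x)
}

#' @export
summary.docscan <- function(object, ...) {
  cat("SCAN-loss clustering fit\n")
  print(object)
  if (length(object$loss_trajectory) > 1L) {
    cat("  per-epoch loss trajectory:\n")
    print(round(object$loss_trajectory, 4))
  }
  invisible(object)
}

#' @export
plot.docscan <- function(x, ...) {
  if (!length(x$loss_trajectory)) {
    stop("no recorded loss trajectory (epochs = 0)", call. = FALSE)
  }
  plot(seq_along(x$loss_trajectory), x$loss_trajectory, type = "b",
       xlab = "epoch", ylab = "SCAN loss", main = "SCAN training", ...)
  invisible(x)
}

#' k-means clustering baseline
#'
#' Standard seeded Lloyd iterations on (unit-normalized) embeddings, the
#' conventional baseline against which SCAN clustering is compared.
#'
#' @param embeddings n x d matrix.
#' @param num_clusters Number of clusters C.
#' @param seed Integer seed.
#' @param nstart Random restarts (default 10).
#' @return Integer assignment vector in 1..C.
#' @export
kmeans_baseline <- function(embeddings, num_clusters = 4L, seed = 1L,
                            nstart = 10L) {
  stopifnot(is.matrix(embeddings))
  check_scalar(num_clusters, "num_clusters", lower = 1, integer = TRUE)
  if (num_clusters > nrow(embeddings)) {
    stop("more clusters than points", call. = FALSE)
  }
  E <- l2_normalize_rows(embeddings)
  with_seed(derive_seed(seed, "kmeans"), {
    km <- suppressWarnings(
      stats::kmeans(E, centers = num_clusters, nstart = nstart,
                    iter.max = 100L, algorithm = "Lloyd")
    )
    as.integer(km$cluster)
  })
}
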