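## Multi-encoder cascade (MEC) classifier ------------------------------------
##
## The supervised route augments each sentence embedding V through three
## parallel encoders -- a constant-shift linear perturbation V + n, an
## autoencoder trained on duplicate pairs, and a denoising autoencoder
## trained to undo Gaussian corruption -- and cross-supervises the branches
## through dynamic-convolution layers: for each branch, the other two
## branches' outputs are concatenated and convolved (with an
## attention-over-kernels mixture of K candidate kernel banks) into a
## dim-vector that is pulled toward that branch's output. The three
## dynamic-convolution outputs are concatenated with the original embedding
## and fed to a softmax classifier.

#' Constant-shift linear perturbation
#'
#' Adds the same scalar `n` to every coordinate of the embedding(s).
#'
#' @param v A numeric vector or an n x d matrix of embeddings.
#' @param n A single finite scalar shift.
#' @return `v + n`, same shape.
#' @export
linear_perturb <- function(v, n) {
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n)) {
    stop("`n` must be a single finite scalar", call. = FALSE)
  }
  if (any(!is.finite(v))) stop("`v` must be finite", call. = FALSE)
  v + n
}

#' Gaussian corruption of an embedding
#'
#' Draws `eps ~ N(0, sigma^2 I)` i.i.d. per coordinate and returns the noisy
#' embedding `vn = v + eps` together with the noise itself, so that
#' `vn - v == eps` exactly.
#'
#' @param v Numeric vector or matrix.
#' @param sigma Non-negative noise standard deviation.
#' @param seed Integer seed; the draw is reproducible.
#' @return A list with `vn` and `eps`.
#' @export
corrupt <- function(v, sigma, seed = 1L) {
  check_scalar(sigma, "sigma", lower = 0)
  eps <- with_seed(derive_seed(seed, "corrupt"), {
    e <- rnorm(length(v), sd = sigma)
    if (is.matrix(v)) matrix(e, nrow(v), ncol(v)) else e
  })
  if (sigma == 0) eps <- eps * 0   # exact zeros, not -0 noise
  list(vn = v + eps, eps = eps)
}

## Dense autoencoder: d -> hidden (ReLU) -> d (linear) -----------------------

ae_init <- function(dim, hidden) {
  list(
    W1 = matrix(rnorm(dim * hidden, sd = sqrt(2 / dim)), dim, hidden),
    b1 = numeric(hidden),
    W2 = matrix(rnorm(hidden * dim, sd = sqrt(2 / hidden)), hidden, dim),
    b2 = numeric(dim)
  )
}

ae_forward <- function(params, X) {
  B <- nrow(X)
  H <- relu(X %*% params$W1 + rep(params$b1, each = B))
  list(H = H, Y = H %*% params$W2 + rep(params$b2, each = B))
}

ae_train_core <- function(X_fun, Y, hidden, epochs, batch_size,
                          learning_rate, seed, tag) {
  n <- nrow(Y)
  d <- ncol(Y)
  with_seed(derive_seed(seed, tag), {
    params <- ae_init(d, hidden)
    st <- adam_init(params)
    traj <- numeric(0)
    for (ep in seq_len(epochs)) {
      X <- X_fun(ep)
      ord <- sample.int(n)
      ep_loss <- 0
      nb <- 0L
      for (start in seq(1L, n, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1L, n)]
        Xb <- X[idx, , drop = FALSE]
        Yb <- Y[idx, , drop = FALSE]
        B <- length(idx)
        f <- ae_forward(params, Xb)
        R <- f$Y - Yb
        loss <- mean(R * R)
        dY <- 2 * R / (B * d)
        dH <- dY %*% t(params$W2)
        dH[f$H <= 0] <- 0
        grads <- list(W1 = crossprod(Xb, dH), b1 = colSums(dH),
                      W2 = crossprod(f$H, dY), b2 = colSums(dY))
        upd <- adam_step(params, grads, st, learning_rate)
        params <- upd$params
        st <- upd$state
        ep_loss <- ep_loss + loss
        nb <- nb + 1L
      }
      traj <- c(traj, ep_loss / nb)
    }
    structure(list(params = params, dim = d, hidden = as.integer(hidden),
                   epochs = as.integer(epochs), seed = as.integer(seed),
                   loss_trajectory = traj,
                   initial_loss = if (length(traj)) traj[1L] else NA_real_,
                   final_loss = if (length(traj)) traj[length(traj)]
                                else NA_real_),
              class = "dense_autoencoder")
  })
}

#' Train a dense autoencoder on duplicate pairs
#'
#' Minimizes the mean squared error between `AE(x)` and `y` over pairs of
#' duplicate embeddings (two embeddings expressing the same content). With
#' `y = x` this is plain reconstruction. `epochs = 0` returns the seeded
#' initialization.
#'
#' @param x n x d matrix of first-pair embeddings.
#' @param y n x d matrix of duplicate embeddings (default `x`).
#' @param hidden Hidden width (default 256).
#' @param epochs,batch_size,learning_rate Training hyperparameters.
#' @param seed Integer seed.
#' @return A `dense_autoencoder` with training metadata.
#' @export
train_autoencoder <- function(x, y = x, hidden = 256L, epochs = 30L,
                              batch_size = 64L, learning_rate = 1e-3,
                              seed = 1L) {
  stopifnot(is.matrix(x), is.matrix(y))
  if (nrow(x) < 1L) stop("need at least one pair", call. = FALSE)
  if (!all(dim(x) == dim(y))) {
    stop("pair dimension mismatch", call. = FALSE)
  }
  check_scalar(epochs, "epochs", lower = 0, integer = TRUE)
  ae_train_core(function(ep) x, y, hidden, epochs, batch_size,
                learning_rate, seed, "ae")
}

#' Train a denoising autoencoder
#'
#' Minimizes the MSE between `DA(v + eps)` and `v`, with fresh Gaussian
#' noise `eps ~ N(0, sigma^2 I)` drawn each epoch.
#'
#' @param x n x d matrix of clean embeddings.
#' @param sigma Non-negative corruption scale (default 0.1).
#' @inheritParams train_autoencoder
#' @return A `dense_autoencoder`.
#' @export
train_denoising_autoencoder <- function(x, sigma = 0.1, hidden = 256L,
                                        epochs = 30L, batch_size = 64L,
                                        learning_rate = 1e-3, seed = 1L) {
  stopifnot(is.matrix(x))
  if (nrow(x) < 1L) stop("empty input", call. = FALSE)
  check_scalar(sigma, "sigma", lower = 0)
  check_scalar(epochs, "epochs", lower = 0, integer = TRUE)
  ae_train_core(
    function(ep) corrupt(x, sigma, seed = derive_seed(seed, paste0("dae-ep", ep)))$vn,
    x, hidden, epochs, batch_size, learning_rate, seed, "dae"
  )
}

#' @export
predict.dense_autoencoder <- function(object, newdata, ...) {
  stopifnot(is.matrix(newdata), ncol(newdata) == object$dim)
  out <- ae_forward(object$params, newdata)$Y
  rownames(out) <- rownames(newdata)
  out
}

#' @export
print.dense_autoencoder <- function(x, ...) {
  cat(sprintf("Dense autoencoder %d -> %d -> %d, %d epochs (seed %d)\n",
              x$dim, x$hidden, x$dim, x$epochs, x$seed))
  if (x$epochs > 0L) {
    cat(sprintf("  MSE %.6f -> %.6f\n", x$initial_loss, x$final_loss))
  }
  invisible(x)
}

## Dynamic convolution -------------------------------------------------------
##
## A dynamic-convolution layer holds, for every kernel size s, K candidate
## kernel banks; a gate (global average pool over the two input channels ->
## linear -> softmax over K) mixes the candidates into one effective bank
## per input. The mixed 1-D convolution over the 2-channel length-dim input,
## ReLU, and max-pooling over positions give `total_filters` features, which
## a linear map returns to a dim-vector.

split_filters <- function(total, sizes) {
  base <- total %/% length(sizes)
  f <- rep(base, length(sizes))
  f[which.max(sizes)] <- f[which.max(sizes)] + (total - base * length(sizes))
  f
}

dc_init <- function(dim, kernel_sizes = c(2L, 3L, 4L), total_filters = 256L,
                    n_candidates = 4L) {
  fs <- split_filters(total_filters, kernel_sizes)
  banks <- list()
  biases <- list()
  for (si in seq_along(kernel_sizes)) {
    s <- kernel_sizes[si]
    banks[[si]] <- lapply(seq_len(n_candidates), function(k) {
      matrix(rnorm(fs[si] * 2L * s, sd = sqrt(2 / (2 * s))), fs[si], 2L * s)
    })
    biases[[si]] <- numeric(fs[si])
  }
  list(
    dim = as.integer(dim), kernel_sizes = as.integer(kernel_sizes),
    filters = as.integer(fs), K = as.integer(n_candidates),
    banks = banks, biases = biases,
    U = matrix(rnorm(n_candidates * 2L, sd = 0.1), n_candidates, 2L),
    cgate = numeric(n_candidates),
    ## near-zero output map: untrained convolution features start silent and
    ## fade in as the mutual supervision shapes them, instead of feeding the
    ## classifier noise in the first epochs
    Wout = matrix(rnorm(dim * total_filters, sd = 0.01), dim, total_filters),
    bout = numeric(dim)
  )
}

dc_patch_index <- function(dim, s) {
  T <- dim - s + 1L
  idx <- matrix(0L, T, 2L * s)
  for (j in seq_len(s)) {
    idx[, j] <- seq_len(T) + j - 1L
    idx[, s + j] <- dim + seq_len(T) + j - 1L
  }
  idx
}

#' Dynamic-convolution forward pass
#'
#' @param layer A layer parameter list from the internal initializer (held
#'   inside a fitted `mec_model`).
#' @param x2 B x (2*dim) matrix: each row is the concatenation of the two
#'   supervising branches' outputs (two channels of length dim).
#' @param cache Keep intermediates for backpropagation.
#' @return A B x dim matrix (attribute `"cache"` when `cache = TRUE`).
#' @export
dynamic_conv <- function(layer, x2, cache = FALSE) {
  stopifnot(is.matrix(x2))
  dim <- layer$dim
  if (ncol(x2) != 2L * dim) {
    stop("input length must be 2*dim", call. = FALSE)
  }
  B <- nrow(x2)
  pool <- cbind(rowMeans(x2[, seq_len(dim), drop = FALSE]),
                rowMeans(x2[, dim + seq_len(dim), drop = FALSE]))
  glog <- pool %*% t(layer$U) + rep(layer$cgate, each = B)
  g <- softmax_rows(glog)                              # B x K

  z_parts <- vector("list", length(layer$kernel_sizes))
  caches <- vector("list", length(layer$kernel_sizes))
  for (si in seq_along(layer$kernel_sizes)) {
    s <- layer$kernel_sizes[si]
    Fs <- layer$filters[si]
    idx <- dc_patch_index(dim, s)
    T <- nrow(idx)
    ## P[(t-1)*B + b, j] = x2[b, idx[t, j]]
    P <- matrix(x2[, as.vector(idx), drop = FALSE], B * T, 2L * s)
    ## gated mixture as one stacked product:
    ## sum_k g_k (P K_k') == [g_1 P | ... | g_K P] [K_1 | ... | K_K]'
    Pg <- do.call(cbind, lapply(seq_len(layer$K), function(k) {
      rep(g[, k], times = T) * P
    }))
    Kcat <- do.call(cbind, layer$banks[[si]])          # Fs x (K*2s)
    Ypre <- Pg %*% t(Kcat) + rep(layer$biases[[si]], each = B * T)
    ## max-pool commutes with ReLU: pool the pre-activations, clip after
    pooled <- .dc_blockmax(Ypre, B, T)
    z_parts[[si]] <- relu(pooled$zpre)
    if (cache) {
      caches[[si]] <- list(P = P, zpre = pooled$zpre, mf = pooled$mf, T = T)
    }
  }
  zcat <- do.call(cbind, z_parts)
  out <- zcat %*% t(layer$Wout) + rep(layer$bout, each = B)
  if (cache) {
    attr(out, "cache") <- list(pool = pool, g = g, zcat = zcat,
                               sizes = caches, B = B)
  }
  out
}

## Backward pass; returns gradients in the layer's own structure. Inputs are
## frozen branch outputs, so no input gradient is produced.
dc_backward <- function(layer, cc, dout) {
  B <- cc$B
  dWout <- crossprod(dout, cc$zcat)                    # dim x F_total
  dbout <- colSums(dout)
  dzcat <- dout %*% layer$Wout                         # B x F_total
  dg <- matrix(0, B, layer$K)
  dbanks <- vector("list", length(layer$kernel_sizes))
  dbiases <- vector("list", length(layer$kernel_sizes))
  off <- 0L
  for (si in seq_along(layer$kernel_sizes)) {
    Fs <- layer$filters[si]
    sc <- cc$sizes[[si]]
    dz <- dzcat[, off + seq_len(Fs), drop = FALSE]
    off <- off + Fs
    ## the max-pool gradient is nonzero at one position per (sample,
    ## filter); work only on those selected patch rows
    rmat <- (sc$mf - 1L) * B + seq_len(B)              # B x Fs row indices
    dz <- dz * (sc$zpre > 0)                           # ReLU mask
    dbiases[[si]] <- colSums(dz)
    Pall <- sc$P[as.vector(rmat), , drop = FALSE]      # (B*Fs) x 2s, the
    fgroup <- rep(seq_len(Fs), each = B)               # pooled patch rows
    dbanks[[si]] <- vector("list", layer$K)
    for (k in seq_len(layer$K)) {
      w <- as.vector(cc$g[, k] * dz)                   # B*Fs weights
      ## f-blocks are contiguous: group sums as a 3-D column sum
      dbanks[[si]][[k]] <- colSums(array(w * Pall,
                                         c(B, Fs, ncol(Pall))), dims = 1L)
      ## raw conv value of bank k at each pooled position
      val <- rowSums(Pall * layer$banks[[si]][[k]][fgroup, , drop = FALSE])
      dg[, k] <- dg[, k] + rowSums(dz * matrix(val, B, Fs))
    }
  }
  dglog <- cc$g * (dg - rowSums(dg * cc$g))
  list(banks = dbanks, biases = dbiases,
       U = crossprod(dglog, cc$pool), cgate = colSums(dglog),
       Wout = dWout, bout = dbout)
}

## Flatten/unflatten DC layer params for the Adam state.
dc_params_flat <- function(layer) {
  out <- list(U = layer$U, cgate = layer$cgate,
              Wout = layer$Wout, bout = layer$bout)
  for (si in seq_along(layer$kernel_sizes)) {
    out[[paste0("bias", si)]] <- layer$biases[[si]]
    for (k in seq_len(layer$K)) {
      out[[paste0("bank", si, "_", k)]] <- layer$banks[[si]][[k]]
    }
  }
  out
}

dc_params_unflat <- function(layer, flat) {
  layer$U <- flat$U
  layer$cgate <- flat$cgate
  layer$Wout <- flat$Wout
  layer$bout <- flat$bout
  for (si in seq_along(layer$kernel_sizes)) {
    layer$biases[[si]] <- flat[[paste0("bias", si)]]
    for (k in seq_len(layer$K)) {
      layer$banks[[si]][[k]] <- flat[[paste0("bank", si, "_", k)]]
    }
  }
  layer
}

dc_grads_flat <- function(layer, gr) {
  out <- list(U = gr$U, cgate = gr$cgate, Wout = gr$Wout, bout = gr$bout)
  for (si in seq_along(layer$kernel_sizes)) {
    out[[paste0("bias", si)]] <- gr$biases[[si]]
    for (k in seq_len(layer$K)) {
      out[[paste0("bank", si, "_", k)]] <- gr$banks[[si]][[k]]
    }
  }
  out
}

## MEC training ---------------------------------------------------------------

#' Train the multi-encoder-cascade classifier
#'
#' Trains the classifier and (optionally) the three dynamic-convolution
#' layers on frozen branch encoders. Per epoch, every sample's
#' constant-shift scalar `n ~ Uniform(-perturb_scale, perturb_scale)` is
#' redrawn; the autoencoder and denoising-autoencoder branches are
#' precomputed and frozen. The objective is the classifier cross-entropy
#' plus `supervision_weight` times the mean squared error between each
#' dynamic-convolution output and its own branch's (stop-gradient) output.
#'
#' @param embeddings n x d training embedding matrix.
#' @param labels 4-class rhetorical labels, length n.
#' @param ae,dae Pretrained `dense_autoencoder` objects for the autoencoder
#'   and denoising branches; if `NULL`, they are pretrained internally (the
#'   autoencoder on identity duplicate pairs, the denoising autoencoder at
#'   `dae_sigma`) and then frozen.
#' @param perturb_scale Half-width of the uniform constant shift
#'   (default 0.01).
#' @param dae_sigma Corruption scale for internal DA pretraining
#'   (default 0.1).
#' @param ae_hidden Hidden width for internal AE/DA pretraining
#'   (default 256).
#' @param dc_kernel_sizes Dynamic-convolution kernel sizes (default 2, 3, 4).
#' @param dc_total_filters Total filters across sizes (default 256; split
#'   evenly, remainder to the largest size).
#' @param dc_candidates Number K of candidate kernel banks per size
#'   (default 4).
#' @param supervision_weight Mutual-supervision weight gamma (default 0.1).
#' @param supervision_target `"own_branch"` (each dynamic-convolution output
#'   is pulled toward its own branch's encoder output; default) or
#'   `"other_mean"` (toward the mean of the two supervising branches) --
#'   the two readings of the mutual-supervision arrow.
#' @param dc `"dynamic"` (full model), `"identity"` (ablation: branch
#'   outputs bypass the convolution layers), or `"none"` (branch features
#'   masked to zero; the model reduces to a linear classifier on the
#'   original embedding).
#' @param dropout Classifier input dropout (default 0.5).
#' @param epochs,batch_size,learning_rate Training hyperparameters
#'   (defaults 30, 64, 1e-3).
#' @param seed Integer seed; training is fully reproducible.
#' @return An object of class `mec_model`.
#' @export
train_mec <- function(embeddings, labels, ae = NULL, dae = NULL,
                      perturb_scale = 0.01, dae_sigma = 0.1,
                      ae_hidden = 256L, dc_kernel_sizes = c(2L, 3L, 4L),
                      dc_total_filters = 256L, dc_candidates = 4L,
                      supervision_weight = 0.1,
                      supervision_target = c("own_branch", "other_mean"),
                      dc = c("dynamic", "identity", "none"),
                      dropout = 0.5, epochs = 30L, batch_size = 64L,
                      learning_rate = 1e-3, seed = 1L) {
  stopifnot(is.matrix(embeddings))
  dc <- match.arg(dc)
  supervision_target <- match.arg(supervision_target)
  y <- as_label_int(labels)
  if (length(unique(y)) < 2L) {
    stop("labels contain a single class", call. = FALSE)
  }
  n <- nrow(embeddings)
  d <- ncol(embeddings)
  C <- 4L
  stopifnot(length(y) == n)
  check_scalar(perturb_scale, "perturb_scale", lower = 1e-12)
  check_scalar(dae_sigma, "dae_sigma", lower = 0)
  check_scalar(supervision_weight, "supervision_weight", lower = 0)
  check_scalar(epochs, "epochs", lower = 0, integer = TRUE)
  if (min(dc_kernel_sizes) < 1L || max(dc_kernel_sizes) >= d) {
    stop("kernel sizes must lie in [1, dim)", call. = FALSE)
  }

  if (is.null(ae)) {
    ae <- train_autoencoder(embeddings, hidden = ae_hidden,
                            epochs = max(epochs, 1L),
                            seed = derive_seed(seed, "mec-ae"))
  }
  if (is.null(dae)) {
    dae <- train_denoising_autoencoder(embeddings, sigma = dae_sigma,
                                       hidden = ae_hidden,
                                       epochs = max(epochs, 1L),
                                       seed = derive_seed(seed, "mec-dae"))
  }
  stopifnot(inherits(ae, "dense_autoencoder"),
            inherits(dae, "dense_autoencoder"))
  if (ae$dim != d || dae$dim != d) {
    stop("autoencoder dimension mismatch", call. = FALSE)
  }

  e2_all <- predict(ae, embeddings)
  e3_all <- predict(dae, embeddings)

  with_seed(derive_seed(seed, "mec"), {
    layers <- NULL
    if (dc == "dynamic") {
      layers <- lapply(1:3, function(i) {
        dc_init(d, dc_kernel_sizes, dc_total_filters, dc_candidates)
      })
    }
    clf <- list(W = matrix(rnorm(4L * d * C, sd = sqrt(1 / (4 * d))),
                           4L * d, C),
                b = numeric(C))
    clf_st <- adam_init(clf)
    dc_st <- if (dc == "dynamic") {
      lapply(layers, function(l) adam_init(dc_params_flat(l)))
    } else NULL
    traj <- numeric(0)

    for (ep in seq_len(epochs)) {
      n_shift <- runif(n, -perturb_scale, perturb_scale)
      e1_all <- embeddings + n_shift            # per-sample scalar, recycled
      ord <- sample.int(n)
      ep_loss <- 0
      nbatch <- 0L
      for (start in seq(1L, n, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1L, n)]
        B <- length(idx)
        V <- embeddings[idx, , drop = FALSE]
        e1 <- e1_all[idx, , drop = FALSE]
        e2 <- e2_all[idx, , drop = FALSE]
        e3 <- e3_all[idx, , drop = FALSE]
        yb <- y[idx]

        if (dc == "dynamic") {
          o1 <- dynamic_conv(layers[[1L]], cbind(e2, e3), cache = TRUE)
          o2 <- dynamic_conv(layers[[2L]], cbind(e1, e3), cache = TRUE)
          o3 <- dynamic_conv(layers[[3L]], cbind(e1, e2), cache = TRUE)
        } else if (dc == "identity") {
          o1 <- e1; o2 <- e2; o3 <- e3
        } else {
          o1 <- o2 <- o3 <- matrix(0, B, d)
        }

        X <- cbind(strip_cache(o1), strip_cache(o2), strip_cache(o3), V)
        mask <- if (dropout > 0) {
          matrix(stats::rbinom(B * 4L * d, 1L, 1 - dropout),
                 B, 4L * d) / (1 - dropout)
        } else NULL
        Xd <- if (is.null(mask)) X else X * mask
        Z <- Xd %*% clf$W + rep(clf$b, each = B)
        Pr <- softmax_rows(Z)
        ce <- -mean(log(pmax(Pr[cbind(seq_len(B), yb)], 1e-12)))

        sup <- 0
        targets <- NULL
        if (dc == "dynamic" && supervision_weight > 0) {
          targets <- if (supervision_target == "own_branch") {
            list(e1, e2, e3)
          } else {
            list((e2 + e3) / 2, (e1 + e3) / 2, (e1 + e2) / 2)
          }
          ## per-sample squared error summed over coordinates (averaged over
          ## the batch), so the supervision anchor is on the cross-entropy
          ## scale rather than vanishing with the embedding dimension
          sup <- sum((strip_cache(o1) - targets[[1L]])^2) / B +
            sum((strip_cache(o2) - targets[[2L]])^2) / B +
            sum((strip_cache(o3) - targets[[3L]])^2) / B
        }
        loss <- ce + supervision_weight * sup
        if (!is.finite(loss)) {
          stop("MEC training diverged to a non-finite loss at epoch ", ep,
               call. = FALSE)
        }

        dZ <- Pr
        dZ[cbind(seq_len(B), yb)] <- dZ[cbind(seq_len(B), yb)] - 1
        dZ <- dZ / B
        gW <- crossprod(Xd, dZ)
        gb <- colSums(dZ)

        upd <- adam_step(clf, list(W = gW, b = gb), clf_st, learning_rate)
        clf <- upd$params
        clf_st <- upd$state

        ## the dynamic-convolution layers are trained by the mutual
        ## supervision objective alone: the classifier consumes their
        ## outputs through a stop-gradient, so the convolution features
        ## cannot co-adapt to the training labels
        if (dc == "dynamic" && supervision_weight > 0) {
          oo <- list(o1, o2, o3)
          for (i in 1:3) {
            doi <- supervision_weight * 2 *
              (strip_cache(oo[[i]]) - targets[[i]]) / B
            gr <- dc_backward(layers[[i]], attr(oo[[i]], "cache"), doi)
            updi <- adam_step(dc_params_flat(layers[[i]]),
                              dc_grads_flat(layers[[i]], gr),
                              dc_st[[i]], learning_rate)
            layers[[i]] <- dc_params_unflat(layers[[i]], updi$params)
            dc_st[[i]] <- updi$state
          }
        }
        ep_loss <- ep_loss + loss
        nbatch <- nbatch + 1L
      }
      traj <- c(traj, ep_loss / nbatch)
    }

    structure(list(
      classifier = clf, layers = layers, ae = ae, dae = dae,
      dim = d, n_classes = C, dc = dc,
      perturb_scale = perturb_scale, dae_sigma = dae_sigma,
      dc_kernel_sizes = as.integer(dc_kernel_sizes),
      dc_total_filters = as.integer(dc_total_filters),
      dc_candidates = as.integer(dc_candidates),
      supervision_weight = supervision_weight,
      supervision_target = supervision_target,
      dropout = dropout, epochs = as.integer(epochs),
      batch_size = as.integer(batch_size), learning_rate = learning_rate,
      seed = as.integer(seed), loss_trajectory = traj
    ), class = "mec_model")
  })
}

strip_cache <- function(x) {
  attr(x, "cache") <- NULL
  x
}

## Deterministic branch features at prediction time: the constant shift is
## zero, the autoencoder branches are applied as trained.
mec_features <- function(model, embeddings) {
  e1 <- embeddings
  e2 <- predict(model$ae, embeddings)
  e3 <- predict(model$dae, embeddings)
  B <- nrow(embeddings)
  d <- model$dim
  if (model$dc == "dynamic") {
    o1 <- dynamic_conv(model$layers[[1L]], cbind(e2, e3))
    o2 <- dynamic_conv(model$layers[[2L]], cbind(e1, e3))
    o3 <- dynamic_conv(model$layers[[3L]], cbind(e1, e2))
  } else if (model$dc == "identity") {
    o1 <- e1; o2 <- e2; o3 <- e3
  } else {
    o1 <- o2 <- o3 <- matrix(0, B, d)
  }
  cbind(o1, o2, o3, embeddings)
}

#' Predict rhetorical classes with a fitted MEC model
#'
#' @param object A `mec_model`.
#' @param newdata n x d embedding matrix.
#' @param type `"class"` for hard labels (ties to the lowest class id) or
#'   `"prob"` for the probability matrix (rows sum to 1).
#' @param ... Unused.
#' @return Integer class vector in 1..4, or an n x 4 probability matrix.
#' @export
predict.mec_model <- function(object, newdata,
                              type = c("class", "prob"), ...) {
  type <- match.arg(type)
  stopifnot(is.matrix(newdata))
  if (ncol(newdata) != object$dim) {
    stop("embedding dimension does not match the fitted model",
         call. = FALSE)
  }
  X <- mec_features(object, newdata)
  Z <- X %*% object$classifier$W +
    rep(object$classifier$b, each = nrow(newdata))
  P <- softmax_rows(Z)
  if (type == "prob") return(P)
  max.col(P, ties.method = "first")
}

#' @export
print.mec_model <- function(x, ...) {
  cat(sprintf(
    "MEC classifier: dim %d, dc = %s, gamma = %g, %d epochs (seed %d)\n",
    x$dim, x$dc, x$supervision_weight, x$epochs, x$seed))
  if (length(x$loss_trajectory)) {
    cat(sprintf("  loss %.4f -> %.4f\n", x$loss_trajectory[1L],
                x$loss_trajectory[length(x$loss_trajectory)]))
  }
  invisible(x)
}

#' @export
summary.mec_model <- function(object, ...) {
  print(object)
  cat(sprintf("  branches: shift +/- %g, AE %d->%d->%d, DA sigma %g\n",
              object$perturb_scale, object$dim, object$ae$hidden,
              object$dim, object$dae_sigma))
  if (object$dc == "dynamic") {
    cat(sprintf("  dynamic conv: sizes (%s), %d filters, K = %d\n",
                paste(object$dc_kernel_sizes, collapse = ", "),
                object$dc_total_filters, object$dc_candidates))
  }
  invisible(object)
}

#' Duplicate embedding pairs from a corpus
#'
#' Encodes each sentence and a light paraphrase of it with the same encoder
#' configuration, yielding the duplicate pairs used to pretrain the
#' autoencoder branch.
#'
#' @param corpus A `sentence_corpus`.
#' @param config An [encoder_config()].
#' @param language Paraphrase language (default inferred per sentence by
#'   script detection: `"zh"` when the text contains CJK characters).
#' @param seed Seed for paraphrase rule selection.
#' @return A list with matrices `x` (original) and `y` (paraphrase).
#' @export
duplicate_pairs <- function(corpus, config = encoder_config(),
                            language = NULL, seed = 1L) {
  stopifnot(is.data.frame(corpus))
  lang <- language %||% if (any(has_cjk(corpus$text))) "zh" else "en"
  para <- paraphrase_sentences(corpus$text, language = lang, seed = seed)
  list(x = encode(corpus, config),
       y = encode(structure(data.frame(
         text = para, label = corpus$label,
         abstract_id = corpus$abstract_id,
         sentence_index = corpus$sentence_index,
         stringsAsFactors = FALSE
       ), class = c("sentence_corpus", "data.frame")), config))
}
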