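# Independent scalar oracles used across tests. These deliberately avoid the
# package's vectorized code paths: plain loops over scalars only.

# SCAN loss evaluated element by element from the printed formula.
oracle_scan_loss <- function(anchor, neighbors, lambda) {
  if (is.matrix(neighbors)) {
    neighbors <- array(neighbors, c(nrow(neighbors), 1L, ncol(neighbors)))
  }
  B <- nrow(anchor)
  C <- ncol(anchor)
  k <- dim(neighbors)[2L]
  cons <- 0
  for (b in seq_len(B)) {
    for (j in seq_len(k)) {
      dot <- 0
      for (c in seq_len(C)) dot <- dot + anchor[b, c] * neighbors[b, j, c]
      cons <- cons - log(max(dot, 1e-12))
    }
  }
  p <- numeric(C)
  for (c in seq_len(C)) p[c] <- mean(anchor[, c])
  ent <- 0
  for (c in seq_len(C)) if (p[c] > 0) ent <- ent + p[c] * log(p[c])
  cons / B + lambda * ent
}

# random probability rows
random_prob_rows <- function(n, C) {
  m <- matrix(stats::rexp(n * C), n, C)
  m / rowSums(m)
}

# scalar forward pass of a SCAN cluster head (no dropout)
oracle_head_forward_row <- function(params, x) {
  hidden <- length(params$b1)
  C <- length(params$b2)
  h <- numeric(hidden)
  for (j in seq_len(hidden)) {
    s <- params$b1[j]
    for (i in seq_along(x)) s <- s + x[i] * params$W1[i, j]
    h[j] <- max(s, 0)
  }
  z <- numeric(C)
  for (c in seq_len(C)) {
    s <- params$b2[c]
    for (j in seq_len(hidden)) s <- s + h[j] * params$W2[j, c]
    z[c] <- s
  }
  e <- exp(z - max(z))
  e / sum(e)
}

# scalar dynamic-convolution forward for one input row
oracle_dynamic_conv_row <- function(layer, x2) {
  d <- layer$dim
  ch1 <- x2[seq_len(d)]
  ch2 <- x2[d + seq_len(d)]
  pool <- c(mean(ch1), mean(ch2))
  glog <- numeric(layer$K)
  for (k in seq_len(layer$K)) {
    glog[k] <- layer$cgate[k] + layer$U[k, 1] * pool[1] +
      layer$U[k, 2] * pool[2]
  }
  g <- exp(glog - max(glog))
  g <- g / sum(g)
  feats <- numeric(0)
  for (si in seq_along(layer$kernel_sizes)) {
    s <- layer$kernel_sizes[si]
    Fs <- layer$filters[si]
    Tn <- d - s + 1L
    z <- numeric(Fs)
    for (f in seq_len(Fs)) {
      best <- -Inf
      for (t in seq_len(Tn)) {
        acc <- layer$biases[[si]][f]
        for (k in seq_len(layer$K)) {
          kk <- layer$banks[[si]][[k]]
          conv <- 0
          for (j in seq_len(s)) {
            conv <- conv + kk[f, j] * ch1[t + j - 1L] +
              kk[f, s + j] * ch2[t + j - 1L]
          }
          acc <- acc + g[k] * conv
        }
        best <- max(best, max(acc, 0))
      }
      z[f] <- best
    }
    feats <- c(feats, z)
  }
  out <- numeric(d)
  for (i in seq_len(d)) {
    s <- layer$bout[i]
    for (f in seq_along(feats)) s <- s + layer$Wout[i, f] * feats[f]
    out[i] <- s
  }
  out
}

# exhaustive assignment oracle: best column -> class bijection
oracle_best_assignment <- function(m) {
  C <- nrow(m)
  best <- -Inf
  best_perm <- NULL
  rec <- function(perm, used) {
    if (length(perm) == C) {
      sc <- sum(m[cbind(perm, seq_len(C))])
      if (sc > best) {
        best <<- sc
        best_perm <<- perm
      }
      return(invisible())
    }
    for (i in seq_len(C)) {
      if (!used[i]) rec(c(perm, i), replace(used, i, TRUE))
    }
  }
  rec(integer(0), rep(FALSE, C))
  list(permutation = best_perm, matched = best)
}

# reference row normalization
l2_norm_rows_ref <- function(m) {
  out <- m / sqrt(rowSums(m * m))
  rownames(out) <- rownames(m)
  out
}

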