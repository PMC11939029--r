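#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm runif kmeans
#' @importFrom utils head modifyList
#' @importFrom Rcpp evalCpp
#' @useDynLib rhetclass, .registration = TRUE
NULL

RHET_CLASSES <- c("objective", "methods", "results", "conclusion")

## Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
## the caller's stream afterwards so library calls never perturb user code.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

## Derive a child seed from a parent seed and a stage tag, kept within the
## 32-bit signed integer range.
derive_seed <- function(seed, tag) {
  h <- fnv1a32(paste0("rhetclass:", tag, ":", as.integer(seed)))
  as.integer(h %% 2147483587) + 1L
}

check_scalar <- function(x, name, lower = -Inf, upper = Inf, integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (x < lower || x > upper) {
    stop(sprintf("`%s` must be in [%s, %s]", name, lower, upper), call. = FALSE)
  }
  if (integer && x != round(x)) {
    stop(sprintf("`%s` must be an integer", name), call. = FALSE)
  }
  invisible(x)
}

## FNV-1a 32-bit hash of a character vector (UTF-8 bytes). Multiplication is
## split into 16-bit halves so the modular arithmetic stays exact in doubles.
fnv1a32 <- function(x) {
  prime <- 16777619
  vapply(enc2utf8(x), function(s) {
    bytes <- as.integer(charToRaw(s))
    h <- 2166136261
    for (b in bytes) {
      h <- bitwXor_dbl(h, b)
      lo <- h %% 65536
      hi <- (h - lo) / 65536
      h <- (lo * prime + ((hi * prime) %% 65536) * 65536) %% 4294967296
    }
    h
  }, numeric(1), USE.NAMES = FALSE)
}

## XOR of a value in [0, 2^32) with a byte, exact in doubles.
bitwXor_dbl <- function(h, b) {
  lo <- h %% 16777216          # low 24 bits always cover the byte
  hi <- h - lo
  hi + bitwXor(as.integer(lo), as.integer(b))
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

## One Adam update; `state` carries first/second moments and the step count.
adam_init <- function(params) {
  list(
    m = lapply(params, function(p) p * 0),
    v = lapply(params, function(p) p * 0),
    t = 0L
  )
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

## Round half away from zero (base round() is half-to-even).
round_half_away <- function(x, digits = 0L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

l2_normalize_rows <- function(m) {
  if (nrow(m) == 0L) return(m)
  nrm <- sqrt(rowSums(m * m))
  nrm[nrm == 0] <- 1
  m / nrm
}

as_label_int <- function(labels, n_classes = 4L, classes = RHET_CLASSES) {
  if (is.character(labels) || is.factor(labels)) {
    idx <- match(as.character(labels), classes)
    if (anyNA(idx)) {
      stop("labels must be one of: ", paste(classes, collapse = ", "),
           call. = FALSE)
    }
    return(idx)
  }
  labels <- as.integer(labels)
  if (any(labels < 1L | labels > n_classes)) {
    stop("integer labels must lie in 1..", n_classes, call. = FALSE)
  }
  labels
}
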