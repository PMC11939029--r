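#' Simulate unit-sphere sentence embeddings with controlled class separation
#'
#' Draws a 4-class mixture on the unit sphere as a stand-in for fine-tuned
#' sentence-transformer embeddings of rhetorical classes. Class mean
#' directions are `normalize(u0 + class_separation * uc)` where `u0, u1..u4`
#' are seeded orthonormal directions, so all means coincide at separation 0
#' and their pairwise angular distance grows monotonically with
#' `class_separation`. Points are the class mean plus isotropic Gaussian
#' noise of scale `within_class_spread`, renormalized to unit length.
#'
#' @param n_per_class Integer vector of length 4 (non-negative counts).
#' @param dim Embedding dimension, at least 2 (default 768).
#' @param within_class_spread Positive noise scale (default 0.1).
#' @param class_separation Non-negative separation parameter (default 1).
#' @param seed Integer seed; output is reproducible.
#' @return A list with `values` (n x dim matrix, unit-norm rows, rownames are
#'   sentence ids) and `labels` (integer vector in 1..4, aligned with rows).
#' @examples
#' sim <- simulate_embeddings(c(50, 50, 50, 50), dim = 16, seed = 1)
#' range(rowSums(sim$values^2))
#' @export
simulate_embeddings <- function(n_per_class, dim = 768L,
                                within_class_spread = 0.1,
                                class_separation = 1,
                                seed = 1L) {
  if (length(n_per_class) != 4L || any(!is.finite(n_per_class)) ||
      any(n_per_class < 0) || any(n_per_class != round(n_per_class))) {
    stop("`n_per_class` must be 4 non-negative integers", call. = FALSE)
  }
  check_scalar(dim, "dim", lower = 2, integer = TRUE)
  if (!is.numeric(within_class_spread) || within_class_spread <= 0) {
    stop("`within_class_spread` must be positive", call. = FALSE)
  }
  check_scalar(class_separation, "class_separation", lower = 0)
  n_per_class <- as.integer(n_per_class)
  n <- sum(n_per_class)
  if (n == 0L) {
    return(list(values = matrix(numeric(0), 0L, dim),
                labels = integer(0)))
  }
  with_seed(seed, {
    ## seeded orthonormal frame: u0 shared, u1..u4 class-specific
    frame <- qr.Q(qr(matrix(rnorm(dim * 5L), dim, 5L)))
    mu <- vapply(1:4, function(ci) {
      v <- frame[, 1L] + class_separation * frame[, ci + 1L]
      v / sqrt(sum(v * v))
    }, numeric(dim))                      # dim x 4
    labels <- rep.int(1:4, n_per_class)
    noise <- matrix(rnorm(n * dim, sd = within_class_spread), n, dim)
    values <- t(mu)[labels, , drop = FALSE] + noise
    values <- l2_normalize_rows(values)
    rownames(values) <- sprintf("s%06d", seq_len(n))
    list(values = values, labels = labels)
  })
}
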