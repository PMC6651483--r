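#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded at `seed`, restoring the previous
#' RNG state afterwards so library callers never perturb user randomness.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  code
}

#' Derive a stream seed from a base seed
#'
#' Deterministic mixing of a base seed and stream indices into a positive
#' 32-bit integer, so every participant/stage gets an independent,
#' reproducible seed.
#'
#' @param base Integer base seed.
#' @param ... Further integer stream components.
#' @return A positive integer below 2^31.
#' @keywords internal
derive_seed <- function(base, ...) {
  parts <- c(base, ...)
  s <- 0
  for (p in parts) {
    # double-precision arithmetic is exact below 2^53, so the modulus keeps
    # every intermediate representable
    s <- (s * 69069 + as.double(p) * 2654435761 + 1013904223) %% 2147483629
  }
  as.integer(s + 1)
}

#' Draw a uniformly random 3x3 rotation matrix
#'
#' @return An orthogonal matrix with determinant +1.
#' @keywords internal
random_rotation <- function() {
  # QR of a Gaussian matrix with sign-fixed R diagonal gives Haar measure
  qr_dec <- qr(matrix(stats::rnorm(9), 3, 3))
  q <- qr.Q(qr_dec)
  d <- sign(diag(qr.R(qr_dec)))
  d[d == 0] <- 1
  q <- q %*% diag(d)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

#' Rotate each row of a matrix by a per-row rotation vector
#'
#' Applies the Rodrigues formula row-wise: row i of `v` is rotated by the
#' axis-angle vector in row i of `theta` (angle = Euclidean norm, axis =
#' direction).
#'
#' @param v Numeric n x 3 matrix of vectors.
#' @param theta Numeric n x 3 matrix of rotation vectors (radians).
#' @return Numeric n x 3 matrix of rotated vectors.
#' @keywords internal
rodrigues_rotate <- function(v, theta) {
  ang <- sqrt(rowSums(theta^2))
  safe <- ifelse(ang > 0, ang, 1)
  k <- theta / safe
  ct <- cos(ang)
  st <- sin(ang)
  kxv <- cbind(k[, 2] * v[, 3] - k[, 3] * v[, 2],
               k[, 3] * v[, 1] - k[, 1] * v[, 3],
               k[, 1] * v[, 2] - k[, 2] * v[, 1])
  kdv <- rowSums(k * v)
  v * ct + kxv * st + k * (kdv * (1 - ct))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
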