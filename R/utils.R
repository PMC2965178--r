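#' @importFrom rlang %||% abort warn inform
#' @importFrom stats sd cor rnorm runif integrate
#' @importFrom utils head read.table write.table
NULL

# unit vector; errors on (near-)zero input
.unit <- function(v, tol = 1e-12) {
  n <- sqrt(sum(v^2))
  if (n < tol) abort("cannot normalise a zero-length vector")
  v / n
}

.cross <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

# vectorised cross product for n x 3 matrices
.cross_m <- function(a, b) {
  cbind(a[, 2L] * b[, 3L] - a[, 3L] * b[, 2L],
        a[, 3L] * b[, 1L] - a[, 1L] * b[, 3L],
        a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L])
}

.row_norm <- function(m) sqrt(rowSums(m^2))

# NeRF-style placement: position d with bond |c-d| = len, angle b-c-d = ang,
# dihedral a-b-c-d = dih (radians)
.place_atom <- function(a, b, c, len, ang, dih) {
  bc <- .unit(c - b)
  n <- .unit(.cross(b - a, bc))
  m <- cbind(bc, .cross(n, bc), n)
  d2 <- len * c(-cos(ang), sin(ang) * cos(dih), sin(ang) * sin(dih))
  c + as.numeric(m %*% d2)
}

# uniform random rotation matrix (one draw from the current RNG stream)
.random_rotation <- function() {
  repeat {
    q <- rnorm(4L)
    n <- sqrt(sum(q^2))
    if (n > 1e-8) break
  }
  q <- q / n
  w <- q[1L]; x <- q[2L]; y <- q[3L]; z <- q[4L]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3L, byrow = TRUE)
}

# deterministic polynomial hash of a character vector (order-sensitive),
# exact in double arithmetic; used to stamp table compatibility
.hash_strings <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\x1f"))
  h <- 0
  p <- 2147483647
  for (b in bytes) h <- (h * 257 + b) %% p
  sprintf("%010d", as.integer(h))
}

.round3 <- function(x) round(x, 3L)

.is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x == floor(x) && x >= 0
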