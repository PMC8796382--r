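# Internal helpers: error conditions, seeded RNG scope, rotation utilities.

mc_error <- function(class, msg, ...) {
  stop(errorCondition(msg, ..., class = c(class, "mc_error", "error")))
}

# Evaluate `code` under a local RNG seed without disturbing the caller's
# global random state (fixtures promise "no global random state").
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

vnorm <- function(v) sqrt(sum(v^2))

unit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) mc_error("mc_value_error", "cannot normalise a zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Rotation about z by `theta` radians.
rot_z <- function(theta) {
  c_ <- cos(theta); s_ <- sin(theta)
  matrix(c(c_, s_, 0, -s_, c_, 0, 0, 0, 1), 3, 3)
}

# Intrinsic z-y-z Euler rotation, angles in degrees.
euler_zyz <- function(alpha, beta, gamma) {
  a <- alpha * pi / 180; b <- beta * pi / 180; g <- gamma * pi / 180
  rot_y <- function(t) matrix(c(cos(t), 0, -sin(t), 0, 1, 0, sin(t), 0, cos(t)), 3, 3)
  rot_z(a) %*% rot_y(b) %*% rot_z(g)
}

# Rotation matrix from a unit quaternion (w, x, y, z).
quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
    2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
    2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)), 3, 3)
}

# n rotation matrices drawn uniformly from SO(3) (normalised Gaussian
# quaternions); caller is responsible for seeding.
random_rotations <- function(n) {
  lapply(seq_len(n), function(i) {
    q <- rnorm(4)
    quat_to_matrix(q / vnorm(q))
  })
}

# Quasi-uniform points on the unit sphere (golden-spiral / Fibonacci layout).
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 1
  z <- 1 - 2 * (i + 0.5) / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- i * pi * (3 - sqrt(5))
  cbind(r * cos(phi), r * sin(phi), z)
}
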