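# Internal geometry helpers shared across modules. All coordinates in Angstrom.

`%||%` <- function(a, b) if (is.null(a)) b else a

vnorm <- function(v) sqrt(sum(v * v))

unit_vec <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalise a zero-length vector")
  v / n
}

#' Rotation matrix about an arbitrary axis
#'
#' @param axis 3-vector (need not be normalised).
#' @param theta angle in radians.
#' @return 3x3 rotation matrix (Rodrigues formula).
#' @keywords internal
#' @noRd
rotation_about_axis <- function(axis, theta) {
  u <- unit_vec(axis)
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

# Uniform random rotation (Shoemake quaternion method); draws from the
# current RNG stream so callers control seeding.
random_rotation <- function() {
  u <- stats::runif(3)
  q <- c(
    sqrt(1 - u[1]) * sin(2 * pi * u[2]),
    sqrt(1 - u[1]) * cos(2 * pi * u[2]),
    sqrt(u[1]) * sin(2 * pi * u[3]),
    sqrt(u[1]) * cos(2 * pi * u[3])
  )
  w <- q[4]; x <- q[1]; y <- q[2]; z <- q[3]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
    2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
    2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3)
}

random_unit_vector <- function() unit_vec(stats::rnorm(3))

# All pairwise Euclidean distances between the rows of two n x 3 matrices.
cross_dist <- function(a, b) {
  a <- rbind(a); b <- rbind(b)
  d2 <- -2 * tcrossprod(a, b)
  d2 <- d2 + rowSums(a^2)              # recycle down columns
  d2 <- sweep(d2, 2, rowSums(b^2), "+")
  d2[d2 < 0] <- 0
  sqrt(d2)
}

min_cross_dist <- function(a, b) min(cross_dist(a, b))

# Deterministic quasi-uniform points on the unit sphere (golden-section
# spiral). Reproducible without any RNG, which keeps SASA bit-stable.
golden_spiral_points <- function(n) {
  stopifnot(n >= 1)
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# Best-fit plane normal through points (rows of m); unit vector.
plane_normal <- function(m) {
  c0 <- sweep(m, 2, colMeans(m))
  s <- svd(c0)
  s$v[, 3]
}

# Angle in degrees between two vectors, folded into [0, 90].
folded_angle <- function(a, b) {
  ca <- abs(sum(unit_vec(a) * unit_vec(b)))
  ca <- min(1, max(-1, ca))
  acos(ca) * 180 / pi
}

aa_three_to_one <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V"
)

aa_one_to_three <- structure(names(aa_three_to_one), names = aa_three_to_one)
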