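# Low-level geometry: minimum-image conventions, pairwise minimum distances,
# and internal-coordinate (bond/angle/torsion) atom placement.

# Minimum-image displacement components for one periodic dimension.
wrapMinImage <- function(d, L) d - L * round(d / L)

# Minimum distance between two coordinate sets (matrices n x 3) under the
# orthorhombic minimum-image convention.  `lateral = TRUE` restricts the
# metric to the x-y projection (z ignored), as used by the annular sorter.
# Vectorised all-pairs evaluation; exact, no cutoffs.
minPairDistance <- function(a, b, box = NULL, periodic = FALSE,
                            lateral = FALSE) {
  if (!is.matrix(a)) a <- matrix(a, ncol = 3L)
  if (!is.matrix(b)) b <- matrix(b, ncol = 3L)
  if (nrow(a) == 0L || nrow(b) == 0L)
    stopf("empty coordinate selection")
  ndim <- if (lateral) 2L else 3L
  d2 <- matrix(0, nrow(a), nrow(b))
  for (k in seq_len(ndim)) {
    dk <- outer(a[, k], b[, k], "-")
    if (periodic) dk <- wrapMinImage(dk, box[k])
    d2 <- d2 + dk * dk
  }
  sqrt(min(d2))
}

# Full pairwise distance matrix (min image); used by the contact-map stage
# where per-pair minima must then be aggregated by residue.
pairDistanceMatrix <- function(a, b, box = NULL, periodic = FALSE) {
  d2 <- matrix(0, nrow(a), nrow(b))
  for (k in 1:3) {
    dk <- outer(a[, k], b[, k], "-")
    if (periodic) dk <- wrapMinImage(dk, box[k])
    d2 <- d2 + dk * dk
  }
  sqrt(d2)
}

vnorm <- function(v) sqrt(sum(v * v))

unitv <- function(v) {
  n <- vnorm(v)
  if (n == 0) stopf("degenerate geometry: zero-length vector")
  v / n
}

cross3 <- function(u, v) {
  c(u[2L] * v[3L] - u[3L] * v[2L],
    u[3L] * v[1L] - u[1L] * v[3L],
    u[1L] * v[2L] - u[2L] * v[1L])
}

# Angle (degrees) between two vectors.
vecAngle <- function(u, v) {
  cosv <- sum(u * v) / (vnorm(u) * vnorm(v))
  acos(max(-1, min(1, cosv))) * 180 / pi
}

# Place atom D given positions A, B, C so that |CD| = bond,
# angle(B,C,D) = theta (degrees) and torsion(A,B,C,D) = tau (degrees).
# Standard natural-extension (NeRF) construction.
placeAtom <- function(a, b, c, bond, theta, tau) {
  thetar <- theta * pi / 180
  taur <- tau * pi / 180
  bc <- unitv(c - b)
  n <- unitv(cross3(b - a, bc))
  m <- cbind(bc, cross3(n, bc), n)
  d2 <- bond * c(-cos(thetar), sin(thetar) * cos(taur),
                 -sin(thetar) * sin(taur))
  c(c + m %*% d2)
}

# Torsion angle (degrees, signed) over four points.
torsionAngle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  m1 <- cross3(n1, unitv(b2))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}
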