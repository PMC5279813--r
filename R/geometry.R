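## Low-level vector geometry shared by all analysis stages.
## Coordinates are rows of length-3 numeric vectors in Angstrom; angles in
## degrees on (-180, 180].

vnorm <- function(v) sqrt(sum(v * v))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize near-zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Wrap angles into (-180, 180]
#'
#' @param x numeric vector of angles in degrees.
#' @return angles mapped into the principal interval (-180, 180].
#' @export
wrap_angle <- function(x) {
  y <- x %% 360
  y[y > 180] <- y[y > 180] - 360
  ## map -180 (from y == 180 after shift) onto +180 to keep the half-open range
  y[y <= -180] <- y[y <= -180] + 360
  y
}

#' Signed torsion angle of four points
#'
#' Computes the dihedral angle defined by points p1-p2-p3-p4 with the IUPAC
#' sign convention: looking from p2 towards p3, a clockwise rotation of the
#' far bond relative to the near bond is positive.
#'
#' @param p1,p2,p3,p4 numeric length-3 coordinate vectors (Angstrom).
#' @return angle in degrees in (-180, 180].
#' @export
torsion <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  if (vnorm(n1) < 1e-9 || vnorm(n2) < 1e-9)
    stop("torsion undefined: collinear points")
  m1 <- cross3(unitv(b2), n1)
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  ang <- atan2(y, x) * 180 / pi
  wrap_angle(ang)
}

## NeRF-style atom placement: given three placed atoms a, b, c, put atom d at
## bond length |cd| = bond, angle b-c-d = theta (deg), torsion a-b-c-d = chi
## (deg).  Standard internal-coordinate chain construction.
place_atom <- function(a, b, c, bond, theta, chi) {
  th <- theta * pi / 180
  ch <- chi * pi / 180
  d2 <- c(bond * cos(pi - th),
          bond * cos(ch) * sin(pi - th),
          bond * sin(ch) * sin(pi - th))
  bc <- unitv(c - b)
  n <- unitv(cross3(b - a, bc))
  m <- cross3(n, bc)
  ## columns: bc, m, n form a right-handed frame at c
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

## Random rotation matrix (uniform over SO(3)) from a given RNG stream.
random_rotation <- function() {
  repeat {
    q <- stats::rnorm(4)
    n <- vnorm(q)
    if (n > 1e-8) break
  }
  q <- q / n
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         nrow = 3, byrow = TRUE)
}

## Near-uniform unit vectors on the sphere (Fibonacci lattice); deterministic.
fibonacci_sphere <- function(n) {
  stopifnot(n >= 1)
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}
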