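## Shared fixtures built in code: canonical geometries and small helpers.

rot_x <- function(th) matrix(c(1, 0, 0,
                               0, cos(th), -sin(th),
                               0, sin(th), cos(th)), 3, 3, byrow = TRUE)
rot_z <- function(th) matrix(c(cos(th), -sin(th), 0,
                               sin(th), cos(th), 0,
                               0, 0, 1), 3, 3, byrow = TRUE)

## Random rotation matrix from the current RNG stream.
random_rot <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

## Ideal 12-residue alpha helix.
ideal_helix <- function(n = 12) build_backbone(rep(-57, n), rep(-47, n))

## Two registered antiparallel 6-residue strands as one (disconnected)
## conformation: strand A residues 10..15, strand B (rotated 180 degrees
## about z and shifted) residues 22..27.  The placement was chosen so the
## Kabsch-Sander assigner sees registered inter-strand H-bonds.
antiparallel_sheet <- function() {
  A <- build_backbone(rep(-139, 6), rep(135, 6))
  B <- transform_conformation(A, rot_z(pi), c(8.75, 6, 0))
  resB <- lapply(B$residues, function(r) {
    r$seq_index <- r$seq_index + 12L
    r
  })
  reconstruct_amide_h(conformation(c(A$residues, resB), check = FALSE))
}

## Single isolated extended strand (no partner, so no bridges possible).
isolated_strand <- function(n = 10) build_backbone(rep(-139, n), rep(135, n))

## A tiny two-residue fixture with explicit coordinates.
toy_residue <- function(seq_index = 1L, name = "ALA", shift = c(0, 0, 0),
                        sidechain = NULL) {
  bb <- rbind(N = c(0, 0, 0), CA = c(1.458, 0, 0), C = c(2.0, 1.4, 0),
              O = c(1.5, 2.5, 0))
  bb <- bb + matrix(shift, 4, 3, byrow = TRUE)
  residue(seq_index, name, bb, sidechain)
}

## Gaussian-model analytic free energy oracle: density of states
## g(E) = exp(a E - E^2 / (2 s^2)) gives p_beta(E) ~ N((a - beta) s^2, s^2)
## and dimensionless free energy f(beta) = -s^2 (a - beta)^2 / 2 + const.
gaussian_df_oracle <- function(beta0, beta1, a, s) {
  -s^2 / 2 * ((a - beta1)^2 - (a - beta0)^2)
}
gaussian_mean_energy_oracle <- function(beta, a, s) (a - beta) * s^2
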