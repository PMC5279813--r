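## Back-calculation of NMR observables: three-bond J(HN-HA) couplings from
## the Karplus relation on backbone phi angles, and residual dipolar
## couplings (RDCs) via a steric-obstruction alignment model (an in-package
## stand-in for external alignment-prediction programs: orientations of the
## molecule between parallel obstructing plates are weighted by the
## accessible fraction, giving a symmetric traceless alignment tensor whose
## overall physical prefactor is absorbed by a least-squares scale fit).

#' Built-in Karplus coefficient sets
#'
#' Three published calibrations of J(phi) = A cos^2(phi - 60) +
#' B cos(phi - 60) + C (Hz): "pardi" (6.4, -1.4, 1.9), "brueschweiler"
#' (9.5, -1.4, 0.3) and "vuister" (6.51, -1.76, 1.60).
#'
#' @param label one of "pardi", "brueschweiler", "vuister".
#' @return named numeric vector c(A, B, C) with attribute "label".
#' @export
karplus_coefficients <- function(label = c("pardi", "brueschweiler",
                                           "vuister")) {
  label <- match.arg(label)
  co <- switch(label,
               pardi = c(A = 6.4, B = -1.4, C = 1.9),
               brueschweiler = c(A = 9.5, B = -1.4, C = 0.3),
               vuister = c(A = 6.51, B = -1.76, C = 1.60))
  attr(co, "label") <- label
  co
}

#' Karplus equation for 3J(HN-HA)
#'
#' J = A cos^2(phi - 60) + B cos(phi - 60) + C with phi in degrees.
#'
#' @param phi backbone phi angle(s), degrees.
#' @param coeffs coefficient vector c(A, B, C), see
#'   [karplus_coefficients()].
#' @return coupling constant(s) in Hz.
#' @export
karplus_j <- function(phi, coeffs = karplus_coefficients("pardi")) {
  th <- (phi - 60) * pi / 180
  coeffs[["A"]] * cos(th)^2 + coeffs[["B"]] * cos(th) + coeffs[["C"]]
}

#' Ensemble-averaged J-couplings per residue
#'
#' Weighted average over frames of the per-frame Karplus coupling.  The
#' N-terminal residue is excluded (its phi angle is undefined and, in capped
#' peptides, distorted by the capping group).
#'
#' @param ensemble a [pep_ensemble()].
#' @param weights optional per-frame weights.
#' @param coeffs Karplus coefficients.
#' @return named numeric vector (Hz) keyed by residue sequence number,
#'   without the first residue.
#' @export
ensemble_jcouplings <- function(ensemble, weights = NULL,
                                coeffs = karplus_coefficients("pardi")) {
  w <- frame_weights(ensemble, weights)
  dih <- extract_dihedrals(ensemble)
  keep <- seq_len(ncol(dih$phi))[-1]
  j <- vapply(keep, function(i) {
    sum(w * karplus_j(dih$phi[, i], coeffs))
  }, numeric(1))
  stats::setNames(j, dih$seq_index[keep])
}

## All heavy-atom (plus pseudo-centroid) coordinates of a conformation.
all_coords <- function(conf) {
  do.call(rbind, lapply(conf$residues, function(r) {
    bb <- r$backbone[setdiff(rownames(r$backbone), "H"), , drop = FALSE]
    rbind(bb, r$sidechain)
  }))
}

#' Steric-obstruction alignment tensor of one conformation
#'
#' The molecule is considered between two parallel obstructing plates at
#' spacing L.  For each plate-normal direction u on a near-uniform
#' (Fibonacci) spherical grid, the accessible fraction is
#' max(0, 1 - h(u)/L), where h(u) is the molecular extent along u.  (The
#' steric weight is invariant under rotation about the plate normal, so the
#' SO(3) orientation average reduces to this spherical grid.)  The alignment
#' tensor is the accessible-fraction-weighted average of
#' (3 u u' - I)/2 over the grid, which is symmetric and traceless by
#' construction.
#'
#' @param conf a [conformation()] (or any n x 3 coordinate matrix).
#' @param grid_size number of grid directions (default 1152).
#' @param plate_spacing plate separation in Angstrom; default 1.2 times the
#'   maximal molecular extent.
#' @return 3 x 3 symmetric traceless matrix of order parameters.
#' @export
steric_alignment_tensor <- function(conf, grid_size = 1152,
                                    plate_spacing = NULL) {
  P <- if (is.matrix(conf)) conf else all_coords(conf)
  if (nrow(P) < 3) stop("need at least 3 points")
  P <- sweep(P, 2, colMeans(P))
  if (all(svd(P, nu = 0, nv = 0)$d[2:3] < 1e-8))
    stop("degenerate (collinear) coordinates: alignment tensor undefined")
  U <- fibonacci_sphere(grid_size)
  proj <- P %*% t(U)                       # natoms x grid
  h <- apply(proj, 2, function(x) max(x) - min(x))
  if (is.null(plate_spacing)) plate_spacing <- 1.2 * max(h)
  f <- pmax(0, 1 - h / plate_spacing)
  if (sum(f) <= 0) stop("plate spacing leaves no accessible orientation")
  f <- f / sum(f)
  A <- 1.5 * t(U * f) %*% U - 0.5 * diag(sum(f), 3)
  A <- (A + t(A)) / 2
  A - diag(sum(diag(A)) / 3, 3)
}

#' Unscaled RDC of a bond vector under an alignment tensor
#'
#' D proportional to e' A e; the physical prefactor is absorbed by the
#' subsequent least-squares scaling against experiment.
#'
#' @param e unit bond vector (length 3) or n x 3 matrix of unit vectors.
#' @param tensor 3 x 3 alignment tensor.
#' @return dimensionless coupling(s).
#' @export
rdc_unscaled <- function(e, tensor) {
  if (is.matrix(e)) return(rowSums((e %*% tensor) * e))
  sum((tensor %*% e) * e)
}

#' Ensemble-averaged unscaled NH RDCs per residue
#'
#' For each frame, computes the frame's steric alignment tensor and the
#' coupling of every backbone N-H unit vector, then averages across frames
#' with the given weights.  Residues lacking an amide H after
#' reconstruction (the N-terminal residue) are omitted.
#'
#' @param ensemble a [pep_ensemble()].
#' @param weights optional per-frame weights.
#' @param grid_size,plate_spacing passed to [steric_alignment_tensor()].
#' @return named numeric vector keyed by residue sequence number.
#' @export
ensemble_rdc <- function(ensemble, weights = NULL, grid_size = 1152,
                         plate_spacing = NULL) {
  w <- frame_weights(ensemble, weights)
  idx <- ensemble$frames[[1]]$seq_index
  n <- length(idx)
  acc <- rep(0, n)
  has <- rep(FALSE, n)
  for (f in seq_along(ensemble$frames)) {
    conf <- reconstruct_amide_h(ensemble$frames[[f]])
    A <- steric_alignment_tensor(conf, grid_size, plate_spacing)
    N <- backbone_matrix(conf, "N")
    H <- backbone_matrix(conf, "H")
    for (i in seq_len(n)) {
      if (any(is.na(H[i, ]))) next
      e <- unitv(H[i, ] - N[i, ])
      acc[i] <- acc[i] + w[f] * rdc_unscaled(e, A)
      has[i] <- TRUE
    }
  }
  stats::setNames(acc[has], idx[has])
}

#' Least-squares scale between computed and experimental couplings
#'
#' s = sum(D_comp * D_exp) / sum(D_comp^2) over the shared residue support,
#' the closed-form minimizer of ||s D_comp - D_exp||^2.
#'
#' @param d_comp,d_exp named numeric vectors keyed by residue number.
#' @return scale factor s.
#' @export
fit_scale <- function(d_comp, d_exp) {
  shared <- intersect(names(d_comp), names(d_exp))
  if (length(shared) < 2) stop("need at least 2 shared residues")
  x <- d_comp[shared]; y <- d_exp[shared]
  den <- sum(x^2)
  if (den <= 0) stop("all computed couplings are zero: scale undefined")
  sum(x * y) / den
}
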