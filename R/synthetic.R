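## Synthetic peptide ensembles, replica-exchange energy records and noisy
## "experimental" observable tables.  These generators stand in for the
## conformational preferences a force field would impose: frames are
## independent draws from per-residue Ramachandran basins, built with ideal
## internal coordinates.  No physical energy function or kinetics.

## Default 31-residue test peptide: residues 10..40 of the 40-residue
## Alzheimer's amyloid-beta peptide (YEVHHQKLVFFAEDVGSNKGAIIGLMVGGVV).
ABETA_SEQ <- c("TYR", "GLU", "VAL", "HIS", "HIS", "GLN", "LYS", "LEU", "VAL",
               "PHE", "PHE", "ALA", "GLU", "ASP", "VAL", "GLY", "SER", "ASN",
               "LYS", "GLY", "ALA", "ILE", "ILE", "GLY", "LEU", "MET", "VAL",
               "GLY", "GLY", "VAL", "VAL")
ABETA_START <- 10L

## Ideal internal-coordinate constants (Engh-Huber-style).
BOND_N_CA <- 1.458
BOND_CA_C <- 1.525
BOND_C_N  <- 1.329
BOND_C_O  <- 1.231
ANGLE_N_CA_C <- 111.2
ANGLE_CA_C_N <- 116.2
ANGLE_C_N_CA <- 121.7
ANGLE_CA_C_O <- 120.5
## Single pseudo side-chain centroid: 2.4 A from CA along the CB direction.
SC_BOND <- 2.4
SC_ANGLE <- 109.5    # C-CA-centroid
SC_TORSION <- 122.686  # N-C-CA-centroid, L-chirality

#' Exponential replica-exchange temperature ladder
#'
#' T_k = T_min * (T_max / T_min)^(k / (n - 1)) for k = 0..n-1, the standard
#' geometric spacing giving roughly uniform exchange acceptance.
#'
#' @param t_min,t_max ladder endpoints in K (0 < t_min < t_max).
#' @param n_replicas number of replicas (>= 2).
#' @return strictly increasing numeric vector of temperatures (K).
#' @export
temperature_ladder <- function(t_min = 300, t_max = 440, n_replicas = 40) {
  if (!(t_min > 0 && t_max > t_min)) stop("need 0 < t_min < t_max")
  if (n_replicas < 2) stop("need at least 2 replicas")
  k <- seq_len(n_replicas) - 1
  t_min * (t_max / t_min)^(k / (n_replicas - 1))
}

#' Define a Ramachandran basin mixture
#'
#' A basin spec is a table of (phi, psi) basin centers with angular spreads
#' and mixture weights, applied to every residue (per-residue tables may be
#' supplied as a list of such tables).
#'
#' @param basin character vector of basin labels.
#' @param phi,psi basin mean angles (degrees).
#' @param sd_phi,sd_psi wrapped-normal spreads (degrees, > 0).
#' @param weight mixture weights (nonnegative, summing to 1).
#' @return a `basin_spec` data.frame.
#' @export
basin_spec <- function(basin, phi, psi, sd_phi, sd_psi, weight) {
  stopifnot(length(basin) == length(phi), length(phi) == length(psi))
  if (any(sd_phi <= 0) || any(sd_psi <= 0)) stop("spreads must be > 0")
  if (any(weight < 0) || abs(sum(weight) - 1) > 1e-9)
    stop("weights must be nonnegative and sum to 1")
  structure(data.frame(basin = basin, phi = phi, psi = psi,
                       sd_phi = sd_phi, sd_psi = sd_psi, weight = weight,
                       stringsAsFactors = FALSE),
            class = c("basin_spec", "data.frame"))
}

#' Preset basin mixtures
#'
#' `basins_helix`: pure alpha-helix basin (-57, -47). `basins_strand`: pure
#' extended basin (-135, 135).  `basins_coil`: a disordered mixture of
#' extended, polyproline-II and left-handed-turn basins with broad spreads,
#' emulating a random-coil ensemble.  `basins_turn`: left-handed turn basin.
#'
#' @param sd angular spread in degrees applied to each basin.
#' @return a [basin_spec()].
#' @export
basins_helix <- function(sd = 8) basin_spec("helix", -57, -47, sd, sd, 1)

#' @rdname basins_helix
#' @export
basins_strand <- function(sd = 15) basin_spec("strand", -135, 135, sd, sd, 1)

#' @rdname basins_helix
#' @export
basins_turn <- function(sd = 15) basin_spec("turnL", 60, 30, sd, sd, 1)

#' @rdname basins_helix
#' @export
basins_coil <- function(sd = 20) {
  ## turn-L weight kept at 0.20 so that runs of consecutive left-handed
  ## draws (which the assigner reads as 3-10 helix) stay rare: the mixture
  ## is meant to emulate a genuine random coil
  basin_spec(c("strand", "ppII", "turnL"),
             phi = c(-135, -75, 60), psi = c(135, 145, 30),
             sd_phi = rep(sd, 3), sd_psi = rep(sd, 3),
             weight = c(0.35, 0.45, 0.20))
}

## Per-residue spec list from a single table or a list of tables.
expand_spec <- function(spec, n_residues) {
  if (inherits(spec, "basin_spec")) return(rep(list(spec), n_residues))
  stopifnot(is.list(spec), length(spec) == n_residues)
  spec
}

#' Sample per-residue backbone dihedrals from a basin mixture
#'
#' For each residue a basin is chosen by its mixture weight and (phi, psi)
#' drawn from independent wrapped normals around the basin center.
#' Deterministic for a fixed seed.
#'
#' @param spec a [basin_spec()] or per-residue list of them.
#' @param n_residues chain length.
#' @param seed optional integer seed.
#' @return data.frame with columns phi, psi (degrees in (-180, 180]).
#' @export
sample_dihedrals <- function(spec, n_residues, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  spec <- expand_spec(spec, n_residues)
  phi <- psi <- numeric(n_residues)
  for (i in seq_len(n_residues)) {
    tb <- spec[[i]]
    b <- sample.int(nrow(tb), 1, prob = tb$weight)
    phi[i] <- wrap_angle(stats::rnorm(1, tb$phi[b], tb$sd_phi[b]))
    psi[i] <- wrap_angle(stats::rnorm(1, tb$psi[b], tb$sd_psi[b]))
  }
  data.frame(phi = phi, psi = psi)
}

#' Build a peptide backbone from internal coordinates
#'
#' Sequential NeRF placement with ideal bond lengths and angles
#' (N-CA 1.458, CA-C 1.525, C-N 1.329, C=O 1.231 Angstrom; angles
#' N-CA-C 111.2, CA-C-N 116.2, C-N-CA 121.7 degrees).  Backbone torsions
#' recomputed from the built coordinates reproduce the inputs to 1e-6
#' degrees.  A single pseudo side-chain centroid atom ("CEN") is placed
#' 2.4 Angstrom from CA along the CB direction (omitted for glycine); amide
#' hydrogens are reconstructed for residues 2..n.
#'
#' @param phi,psi equal-length angle vectors (degrees); phi of residue 1 and
#'   psi of residue n only orient terminal O/H atoms.
#' @param omega peptide-bond torsion, default 180 (all-trans).
#' @param sequence three-letter residue names (default: the bundled
#'   31-residue amyloid-beta 10-40 sequence, truncated/recycled to length).
#' @param start_index sequence number of the first residue.
#' @param frame_id frame identifier.
#' @return a [conformation()].
#' @export
build_backbone <- function(phi, psi, omega = 180, sequence = NULL,
                           start_index = ABETA_START, frame_id = 1L) {
  n <- length(phi)
  if (length(psi) != n) stop("phi and psi must have equal length")
  if (n < 2) stop("need at least 2 residues")
  if (is.null(sequence)) {
    sequence <- if (n <= length(ABETA_SEQ)) ABETA_SEQ[seq_len(n)]
                else rep(ABETA_SEQ, length.out = n)
  }
  stopifnot(length(sequence) == n)
  N <- CA <- C <- O <- matrix(NA_real_, n, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(BOND_N_CA, 0, 0)
  a <- ANGLE_N_CA_C * pi / 180
  C[1, ] <- CA[1, ] + BOND_CA_C * c(cos(pi - a), sin(pi - a), 0)
  for (i in seq_len(n - 1)) {
    N[i + 1, ] <- place_atom(N[i, ], CA[i, ], C[i, ], BOND_C_N,
                             ANGLE_CA_C_N, psi[i])
    CA[i + 1, ] <- place_atom(CA[i, ], C[i, ], N[i + 1, ], BOND_N_CA,
                              ANGLE_C_N_CA, omega)
    C[i + 1, ] <- place_atom(C[i, ], N[i + 1, ], CA[i + 1, ], BOND_CA_C,
                             ANGLE_N_CA_C, phi[i + 1])
  }
  for (i in seq_len(n)) {
    O[i, ] <- place_atom(N[i, ], CA[i, ], C[i, ], BOND_C_O,
                         ANGLE_CA_C_O, wrap_angle(psi[i] - 180))
  }
  residues <- vector("list", n)
  for (i in seq_len(n)) {
    bb <- rbind(N = N[i, ], CA = CA[i, ], C = C[i, ], O = O[i, ])
    sc <- NULL
    if (sequence[i] != "GLY") {
      cen <- place_atom(N[i, ], C[i, ], CA[i, ], SC_BOND, SC_ANGLE, SC_TORSION)
      sc <- matrix(cen, 1, 3, dimnames = list("CEN", NULL))
    }
    residues[[i]] <- residue(start_index + i - 1L, sequence[i], bb, sc)
  }
  reconstruct_amide_h(conformation(residues, frame_id = frame_id))
}

#' Generate a synthetic conformational ensemble
#'
#' Independent frames from [sample_dihedrals()] + [build_backbone()].  An
#' optional contact bias enforces, with probability `prob`, that a named
#' residue pair's side-chain centroids lie within `cutoff` (frames are
#' rejection-sampled until the contact forms), enabling contact-recovery
#' tests.  Deterministic per seed.
#'
#' @param spec a [basin_spec()] or per-residue list.
#' @param n_frames number of frames (>= 1).
#' @param seed integer seed.
#' @param contact_bias optional list(pair = c(i, j), prob, cutoff = 6.5)
#'   using residue sequence numbers.
#' @param n_residues chain length (default 31).
#' @param start_index first residue sequence number (default 10).
#' @param max_attempts rejection-sampling cap per biased frame.
#' @return a [pep_ensemble()].
#' @export
generate_ensemble <- function(spec, n_frames, seed = 1L, contact_bias = NULL,
                              n_residues = 31L, start_index = ABETA_START,
                              max_attempts = 5000L) {
  if (n_frames < 1) stop("n_frames must be >= 1")
  set.seed(seed)
  frames <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    force_contact <- !is.null(contact_bias) &&
      stats::runif(1) < contact_bias$prob
    attempts <- 0L
    repeat {
      attempts <- attempts + 1L
      ang <- sample_dihedrals(spec, n_residues)
      conf <- build_backbone(ang$phi, ang$psi, start_index = start_index,
                             frame_id = f)
      if (!force_contact) break
      cutoff <- if (is.null(contact_bias$cutoff)) 6.5 else contact_bias$cutoff
      ij <- match(contact_bias$pair, conf$seq_index)
      if (any(is.na(ij))) stop("contact_bias pair outside residue range")
      d <- vnorm(side_chain_centroid(conf$residues[[ij[1]]]) -
                 side_chain_centroid(conf$residues[[ij[2]]]))
      if (d < cutoff) break
      if (attempts >= max_attempts)
        stop("contact bias rejection sampling exceeded max_attempts")
    }
    frames[[f]] <- conf
  }
  pep_ensemble(frames)
}

#' Specify a synthetic replica-energy model
#'
#' @param temperatures replica temperatures (K), distinct.
#' @param mean,sd per-replica Gaussian potential-energy mean and spread
#'   (kcal/mol); recycled to the number of replicas.
#' @param n_per_replica samples per replica (>= 1).
#' @param seed integer seed.
#' @return an `energy_model_spec` list.
#' @export
energy_model_spec <- function(temperatures, mean, sd, n_per_replica,
                              seed = 1L) {
  k <- length(temperatures)
  if (anyDuplicated(temperatures) > 0 || any(temperatures <= 0))
    stop("temperatures must be positive and distinct")
  mean <- rep_len(mean, k); sd <- rep_len(sd, k)
  if (any(sd < 0)) stop("sd must be >= 0")
  if (n_per_replica < 1) stop("n_per_replica must be >= 1")
  structure(list(temperatures = temperatures, mean = mean, sd = sd,
                 n = as.integer(n_per_replica), seed = as.integer(seed)),
            class = "energy_model_spec")
}

#' Generate canonical replica-exchange energy records
#'
#' Gaussian potential-energy draws per replica, deterministic per seed, in
#' the plain-text record layout `replica  temperature  step  energy`.
#'
#' @param spec an [energy_model_spec()].
#' @return data.frame(replica, temperature, step, energy).
#' @export
generate_replica_energies <- function(spec) {
  stopifnot(inherits(spec, "energy_model_spec"))
  set.seed(spec$seed)
  out <- vector("list", length(spec$temperatures))
  for (k in seq_along(spec$temperatures)) {
    e <- stats::rnorm(spec$n, spec$mean[k], spec$sd[k])
    out[[k]] <- data.frame(replica = k, temperature = spec$temperatures[k],
                           step = seq_len(spec$n), energy = e)
  }
  do.call(rbind, out)
}

#' Generate a noisy synthetic experimental table from an ensemble
#'
#' Computes the requested observable from the ensemble (J-couplings via the
#' Karplus equation, RDCs via the steric alignment model) and adds i.i.d.
#' Gaussian noise, yielding a ground-truth table for recovery tests.
#'
#' @param ensemble a [pep_ensemble()].
#' @param observable "JHNHA" or "RDC".
#' @param noise_sd Gaussian noise level in Hz (0 reproduces the computed
#'   observable exactly).
#' @param seed integer seed for the noise.
#' @param weights optional frame weights.
#' @param coeffs Karplus coefficient set for JHNHA (see
#'   [karplus_coefficients()]).
#' @param ... further arguments passed to [ensemble_rdc()].
#' @return a `pep_exptable`.
#' @export
generate_synthetic_experiment <- function(ensemble,
                                          observable = c("JHNHA", "RDC"),
                                          noise_sd = 0, seed = 1L,
                                          weights = NULL,
                                          coeffs = karplus_coefficients("pardi"),
                                          ...) {
  observable <- match.arg(observable)
  vals <- if (observable == "JHNHA")
    ensemble_jcouplings(ensemble, weights = weights, coeffs = coeffs)
  else
    ensemble_rdc(ensemble, weights = weights, ...)
  set.seed(seed)
  noisy <- vals + stats::rnorm(length(vals), 0, noise_sd)
  structure(list(observable = observable, entries = noisy,
                 source_label = sprintf("synthetic %s (noise sd %g Hz)",
                                        observable, noise_sd)),
            class = "pep_exptable")
}

#' Write replica energy records as TSV
#'
#' @param records data.frame from [generate_replica_energies()].
#' @param path output path.
#' @param header_comment optional comment lines.
#' @return invisibly, the path.
#' @export
write_replica_tsv <- function(records, path, header_comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  for (h in header_comment) writeLines(paste0("# ", h), con)
  writeLines("replica\ttemperature\tstep\tenergy", con)
  writeLines(sprintf("%d\t%.6f\t%d\t%.6f", records$replica,
                     records$temperature, records$step, records$energy), con)
  invisible(path)
}

#' Read replica energy records
#'
#' @param path TSV path as written by [write_replica_tsv()].
#' @return data.frame(replica, temperature, step, energy).
#' @export
read_replica_tsv <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#")
}
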