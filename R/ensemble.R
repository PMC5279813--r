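## Core containers: Residue, Conformation (one frame), Ensemble (frames plus
## optional energies / temperature / weights), and experimental observable
## tables.  Residue numbering is preserved from the input (the bundled test
## peptide uses the Abeta numbering 10..40); every |j - i| sequence-separation
## computation uses these numbers, never array positions.

BACKBONE_ATOMS <- c("N", "H", "CA", "C", "O")

## Average atomic masses (u) for side-chain heavy atoms.
ATOMIC_MASSES <- c(C = 12.011, N = 14.007, O = 15.999, S = 32.06, H = 1.008)

#' Construct a residue
#'
#' @param seq_index integer residue sequence number.
#' @param name three-letter amino-acid code.
#' @param backbone named 3-column matrix of backbone atom coordinates
#'   (rows named among N, H, CA, C, O); N, CA and C are mandatory.
#' @param sidechain named 3-column matrix of side-chain heavy-atom
#'   coordinates (possibly zero rows, e.g. glycine).
#' @return a `pep_residue` list.
#' @export
residue <- function(seq_index, name, backbone, sidechain = NULL) {
  if (is.null(sidechain)) {
    sidechain <- matrix(numeric(0), ncol = 3)
    rownames(sidechain) <- character(0)
  }
  stopifnot(ncol(backbone) == 3, ncol(sidechain) == 3)
  miss <- setdiff(c("N", "CA", "C"), rownames(backbone))
  if (length(miss) > 0)
    stop(sprintf("residue %d (%s): missing backbone atom(s) %s",
                 seq_index, name, paste(miss, collapse = ", ")))
  if (!all(is.finite(backbone)) || !all(is.finite(sidechain)))
    stop(sprintf("residue %d: non-finite coordinates", seq_index))
  structure(list(seq_index = as.integer(seq_index), name = name,
                 backbone = backbone, sidechain = sidechain),
            class = "pep_residue")
}

#' Construct a single-frame conformation
#'
#' @param residues list of [residue()] objects, ordered along the chain.
#' @param frame_id integer frame identifier.
#' @param check if TRUE, verify increasing numbering and peptide-bond
#'   connectivity (consecutive C-N distance < 2.5 Angstrom).
#' @return a `pep_conformation` object.
#' @export
conformation <- function(residues, frame_id = 1L, check = TRUE) {
  stopifnot(length(residues) >= 2)
  idx <- vapply(residues, function(r) r$seq_index, integer(1))
  if (check) {
    if (any(diff(idx) <= 0)) stop("residue sequence numbers must be strictly increasing")
    for (k in seq_len(length(residues) - 1)) {
      d <- vnorm(residues[[k]]$backbone["C", ] - residues[[k + 1]]$backbone["N", ])
      if (d >= 2.5)
        stop(sprintf("chain break between residues %d and %d (C-N %.2f A)",
                     idx[k], idx[k + 1], d))
    }
  }
  structure(list(residues = residues, frame_id = as.integer(frame_id),
                 seq_index = idx),
            class = "pep_conformation")
}

#' Construct an ensemble of conformations
#'
#' @param frames list of [conformation()] objects sharing one residue range.
#' @param energies optional per-frame potential energies (kcal/mol).
#' @param temperature optional source temperature(s) in K (scalar or per
#'   frame).
#' @param trajectory_id integer trajectory label.
#' @param weights optional nonnegative per-frame weights summing to 1.
#' @return a `pep_ensemble` object.
#' @export
pep_ensemble <- function(frames, energies = NULL, temperature = NULL,
                         trajectory_id = 1L, weights = NULL) {
  stopifnot(length(frames) >= 1)
  if (!is.null(energies) && length(energies) != length(frames))
    stop("energies length must equal number of frames")
  if (!is.null(weights)) {
    if (length(weights) != length(frames)) stop("weights length mismatch")
    if (any(weights < 0)) stop("weights must be nonnegative")
    if (abs(sum(weights) - 1) > 1e-9) stop("weights must sum to 1")
  }
  structure(list(frames = frames, energies = energies,
                 temperature = temperature,
                 trajectory_id = as.integer(trajectory_id),
                 weights = weights),
            class = "pep_ensemble")
}

#' @export
print.pep_ensemble <- function(x, ...) {
  nr <- length(x$frames[[1]]$residues)
  idx <- x$frames[[1]]$seq_index
  cat(sprintf("pep_ensemble: %d frame(s), %d residues (%d..%d)\n",
              length(x$frames), nr, min(idx), max(idx)))
  if (!is.null(x$energies)) cat("  with per-frame energies\n")
  if (!is.null(x$weights)) cat("  with frame weights\n")
  invisible(x)
}

#' @export
length.pep_ensemble <- function(x) length(x$frames)

## Contiguous frame blocks for block-error estimation (handles n < blocks).
frame_blocks <- function(nf, n_blocks) {
  nb <- max(1L, min(n_blocks, nf))
  split(seq_len(nf), ceiling(seq_len(nf) * nb / nf))
}

## Effective frame weights: stored weights or uniform.
frame_weights <- function(ensemble, weights = NULL) {
  n <- length(ensemble$frames)
  w <- if (!is.null(weights)) weights
       else if (!is.null(ensemble$weights)) ensemble$weights
       else rep(1 / n, n)
  if (length(w) != n) stop("weights length does not match frame count")
  w / sum(w)
}

#' Geometric center of side-chain heavy atoms
#'
#' Unweighted mean of side-chain heavy-atom positions; glycine (no side-chain
#' heavy atoms) falls back to the CA position so contact criteria still apply
#' to it.
#'
#' @param res a [residue()] object.
#' @return length-3 coordinate vector (Angstrom).
#' @export
side_chain_centroid <- function(res) {
  if (nrow(res$sidechain) == 0) return(res$backbone["CA", ])
  colMeans(res$sidechain)
}

#' Mass-weighted side-chain center of mass
#'
#' @param res a [residue()] object.
#' @param masses named vector of atomic masses (u) keyed by element symbol.
#' @return length-3 coordinate vector (Angstrom).
#' @export
side_chain_com <- function(res, masses = ATOMIC_MASSES) {
  if (nrow(res$sidechain) == 0) return(res$backbone["CA", ])
  elem <- element_of(rownames(res$sidechain))
  m <- masses[elem]
  if (any(is.na(m))) stop("unknown element in side chain of residue ", res$seq_index)
  colSums(res$sidechain * m) / sum(m)
}

## Element symbol from a PDB atom name (first non-digit character; two-letter
## elements do not occur among standard amino-acid heavy atoms except S which
## is single-letter anyway).
element_of <- function(atom_names) {
  substr(sub("^[0-9]*", "", atom_names), 1, 1)
}

## Matrix (n_residues x 3) of one backbone atom across the chain; NA rows if
## the atom is absent.
backbone_matrix <- function(conf, atom) {
  t(vapply(conf$residues, function(r) {
    if (atom %in% rownames(r$backbone)) r$backbone[atom, ] else rep(NA_real_, 3)
  }, numeric(3)))
}

#' Reconstruct missing amide hydrogens
#'
#' Places each missing backbone amide H at 1.01 Angstrom from N along the
#' direction opposing the bisector of the C(i-1)->N and CA->N bonds, i.e. in
#' the C(i-1)-N(i)-CA(i) plane.  The first residue (no preceding carbonyl) is
#' left untouched.  Needed for hydrogen-bond energies and NH-vector residual
#' dipolar couplings when the input lacks protons.
#'
#' @param conf a [conformation()].
#' @return the conformation with amide H atoms filled in.
#' @export
reconstruct_amide_h <- function(conf) {
  for (k in seq_along(conf$residues)[-1]) {
    r <- conf$residues[[k]]
    if ("H" %in% rownames(r$backbone)) next
    cprev <- conf$residues[[k - 1]]$backbone["C", ]
    n <- r$backbone["N", ]
    ca <- r$backbone["CA", ]
    u <- unitv(unitv(n - cprev) + unitv(n - ca))
    h <- n + 1.01 * u
    bb <- rbind(r$backbone, H = h)
    conf$residues[[k]]$backbone <- bb
  }
  conf
}

#' Read a multi-model PDB file as an ensemble
#'
#' Parses MODEL/ENDMDL records (a file without MODEL records yields one
#' frame).  Hydrogens are retained when present (the amide H is needed for
#' hydrogen-bond detection and NH residual dipolar coupling vectors).
#' Histidine tautomer aliases (HSD/HSE/HSP/HID/HIE/HIP) are normalized to HIS.
#'
#' @param path path to a PDB file.
#' @return a [pep_ensemble()] with one conformation per model.
#' @export
read_multimodel_pdb <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  atom <- pdb$atom
  keep <- atom$type %in% c("ATOM")
  atom <- atom[keep, , drop = FALSE]
  if (nrow(atom) == 0) stop("no ATOM records in ", path)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  n_models <- nrow(xyz)
  if (n_models < 1) stop("zero models in ", path)
  atom$resid <- normalize_his(atom$resid)
  cols <- as.vector(t(cbind((which(keep) - 1) * 3 + 1,
                            (which(keep) - 1) * 3 + 2,
                            (which(keep) - 1) * 3 + 3)))
  resnos <- unique(atom$resno)
  frames <- vector("list", n_models)
  for (m in seq_len(n_models)) {
    co <- matrix(xyz[m, cols], ncol = 3, byrow = TRUE)
    residues <- vector("list", length(resnos))
    for (ri in seq_along(resnos)) {
      sel <- atom$resno == resnos[ri]
      anames <- atom$elety[sel]
      rxyz <- co[sel, , drop = FALSE]
      rownames(rxyz) <- anames
      is_bb <- anames %in% BACKBONE_ATOMS
      is_h_side <- !is_bb & element_of(anames) == "H"
      bb <- rxyz[is_bb, , drop = FALSE]
      sc <- rxyz[!is_bb & !is_h_side, , drop = FALSE]
      residues[[ri]] <- residue(resnos[ri], atom$resid[sel][1], bb, sc)
    }
    frames[[m]] <- conformation(residues, frame_id = m)
  }
  pep_ensemble(frames)
}

normalize_his <- function(x) {
  x[x %in% c("HSD", "HSE", "HSP", "HID", "HIE", "HIP")] <- "HIS"
  x
}

#' Write an ensemble as a multi-model PDB file
#'
#' Emits standard fixed-width ATOM records wrapped in MODEL/ENDMDL pairs;
#' round-trips through [read_multimodel_pdb()] at the format's coordinate
#' precision (1e-3 Angstrom).
#'
#' @param ensemble a [pep_ensemble()].
#' @param path output file path.
#' @return invisibly, the path.
#' @export
write_multimodel_pdb <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "pep_ensemble"))
  if (length(ensemble$frames) == 0) stop("cannot write an empty ensemble")
  con <- file(path, "w")
  on.exit(close(con))
  for (m in seq_along(ensemble$frames)) {
    conf <- ensemble$frames[[m]]
    writeLines(sprintf("MODEL     %4d", m), con)
    serial <- 0L
    for (r in conf$residues) {
      coords <- rbind(r$backbone, r$sidechain)
      anames <- c(rownames(r$backbone), rownames(r$sidechain))
      for (a in seq_along(anames)) {
        serial <- serial + 1L
        nm <- anames[a]
        ## PDB atom-name column alignment: 1-letter elements start in col 14
        nmfmt <- if (nchar(nm) < 4) sprintf(" %-3s", nm) else nm
        writeLines(sprintf(
          "ATOM  %5d %4s %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00           %s",
          serial, nmfmt, r$name, r$seq_index,
          coords[a, 1], coords[a, 2], coords[a, 3], element_of(nm)), con)
      }
    }
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a per-residue experimental observable table
#'
#' Expects a TSV with header `residue<TAB>value` (values in Hz).  Rows whose
#' residue index falls outside `residue_range` are dropped with a warning;
#' duplicate residue indices or non-numeric values are hard errors.
#'
#' @param path TSV file path.
#' @param observable one of "JHNHA" or "RDC".
#' @param residue_range optional length-2 integer vector (inclusive) of the
#'   modeled peptide range used to filter rows.
#' @param source_label free-text provenance label.
#' @return a `pep_exptable` with fields observable, entries (named numeric
#'   vector keyed by residue index) and source_label.
#' @export
read_experimental_table <- function(path, observable = c("JHNHA", "RDC"),
                                    residue_range = NULL,
                                    source_label = basename(path)) {
  observable <- match.arg(observable)
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character",
                           comment.char = "#")
  if (!all(c("residue", "value") %in% names(raw)))
    stop("expected columns 'residue' and 'value' in ", path)
  res <- suppressWarnings(as.integer(raw$residue))
  val <- suppressWarnings(as.numeric(raw$value))
  bad <- which(is.na(res) | is.na(val))
  if (length(bad) > 0)
    stop(sprintf("non-numeric entry at line %d of %s", bad[1] + 1L, path))
  if (anyDuplicated(res) > 0)
    stop("duplicate residue index in ", path)
  if (!is.null(residue_range)) {
    out <- res < residue_range[1] | res > residue_range[2]
    if (any(out)) {
      warning(sprintf("dropping %d row(s) outside residue range %d..%d: %s",
                      sum(out), residue_range[1], residue_range[2],
                      paste(res[out], collapse = ", ")))
      res <- res[!out]; val <- val[!out]
    }
  }
  entries <- stats::setNames(val, res)
  structure(list(observable = observable, entries = entries,
                 source_label = source_label),
            class = "pep_exptable")
}

#' Write a per-residue observable table (TSV)
#'
#' @param values named numeric vector keyed by residue index.
#' @param path output TSV path.
#' @param header_comment optional comment lines (without leading '#').
#' @return invisibly, the path.
#' @export
write_observable_table <- function(values, path, header_comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  for (h in header_comment) writeLines(paste0("# ", h), con)
  writeLines("residue\tvalue", con)
  writeLines(sprintf("%s\t%.6f", names(values), values), con)
  invisible(path)
}

#' Apply a rigid-body transform to a conformation
#'
#' @param conf a [conformation()].
#' @param R 3 x 3 rotation matrix (identity if omitted).
#' @param t length-3 translation vector.
#' @return the transformed conformation.
#' @export
transform_conformation <- function(conf, R = diag(3), t = c(0, 0, 0)) {
  shift <- function(m) if (nrow(m) > 0)
    m %*% t(R) + matrix(t, nrow(m), 3, byrow = TRUE) else m
  for (k in seq_along(conf$residues)) {
    rn_b <- rownames(conf$residues[[k]]$backbone)
    rn_s <- rownames(conf$residues[[k]]$sidechain)
    conf$residues[[k]]$backbone <- shift(conf$residues[[k]]$backbone)
    conf$residues[[k]]$sidechain <- shift(conf$residues[[k]]$sidechain)
    rownames(conf$residues[[k]]$backbone) <- rn_b
    rownames(conf$residues[[k]]$sidechain) <- rn_s
  }
  conf
}
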