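## Secondary-structure assignment from backbone hydrogen-bond patterns.
## This is a documented in-package assigner (Kabsch-Sander electrostatic
## H-bond energy + minimal-repeat pattern rules + a phi/psi turn fallback)
## reproducing the four-state reduction used downstream: helix H (alpha,
## 3-10 or pi), strand S (extended or isolated bridge), turn T, random
## coil RC.

KS_FACTOR <- 0.084 * 332  # kcal/mol * Angstrom, Kabsch-Sander constant
HBOND_CUTOFF <- -0.5      # kcal/mol; bond declared below this energy
SS4_LEVELS <- c("H", "S", "T", "RC")

## phi/psi turn fallback region (see vignette): right-handed turn/helical
## region and the left-handed turn region.  Strand and polyproline-II
## (psi >~ 90) are excluded.
in_turn_region <- function(phi, psi) {
  ifelse(is.na(phi) | is.na(psi), FALSE,
         (phi < 0 & psi > -120 & psi < 60) |
         (phi > 0 & psi > -60 & psi < 90))
}

#' Kabsch-Sander hydrogen-bond energy
#'
#' E = 0.084 * 332 * (1/r_ON + 1/r_CH - 1/r_OH - 1/r_CN) kcal/mol between a
#' donor amide (N-H of residue i) and an acceptor carbonyl (C=O of residue
#' j).  Any interatomic distance below 0.5 Angstrom clamps the energy to
#' -9.9 (DSSP convention).  A hydrogen bond is declared when E < -0.5.
#'
#' @param donor residue providing N-H (must carry an H atom).
#' @param acceptor residue providing C=O.
#' @return energy in kcal/mol.
#' @export
hbond_energy <- function(donor, acceptor) {
  if (!"H" %in% rownames(donor$backbone))
    stop("donor residue lacks an amide H (reconstruct_amide_h first)")
  N <- donor$backbone["N", ]; H <- donor$backbone["H", ]
  C <- acceptor$backbone["C", ]; O <- acceptor$backbone["O", ]
  r <- c(ON = vnorm(O - N), CH = vnorm(C - H),
         OH = vnorm(O - H), CN = vnorm(C - N))
  if (any(r < 0.5)) return(-9.9)
  KS_FACTOR * (1 / r["ON"] + 1 / r["CH"] - 1 / r["OH"] - 1 / r["CN"])[[1]]
}

## n x n logical matrix: hb[d, a] TRUE when NH of residue d donates to CO of
## residue a, for |d - a| >= 2.  Vectorized over all pairs.
hbond_matrix <- function(conf) {
  n <- length(conf$residues)
  N <- backbone_matrix(conf, "N")
  H <- backbone_matrix(conf, "H")
  C <- backbone_matrix(conf, "C")
  O <- backbone_matrix(conf, "O")
  pd <- function(A, B) { # |A_d - B_a| over all (d, a)
    sqrt(outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B))
  }
  rON <- pd(N, O); rCH <- pd(H, C); rOH <- pd(H, O); rCN <- pd(N, C)
  E <- KS_FACTOR * (1 / rON + 1 / rCH - 1 / rOH - 1 / rCN)
  E[rON < 0.5 | rCH < 0.5 | rOH < 0.5 | rCN < 0.5] <- -9.9
  sep <- abs(outer(seq_len(n), seq_len(n), "-"))
  hb <- !is.na(E) & E < HBOND_CUTOFF & sep >= 2
  ## an amide proton donates a single hydrogen bond: each donor keeps only
  ## its lowest-energy acceptor
  for (d in seq_len(n)) {
    acc <- which(hb[d, ])
    if (length(acc) > 1) {
      best <- acc[which.min(E[d, acc])]
      hb[d, ] <- FALSE
      hb[d, best] <- TRUE
    }
  }
  hb
}

#' Assign per-residue secondary-structure states for one frame
#'
#' Minimal-repeat hydrogen-bond patterns: two consecutive i->i+4 turns make
#' an alpha run, i->i+3 a 3-10 run, i->i+5 a pi run; parallel/antiparallel
#' bridge patterns give isolated bridges, two consecutive bridges an
#' extended strand.  Residues covered by an H-bonded 3- or 4-turn, or whose
#' (phi, psi) fall in the turn region, and which are not already helix or
#' strand, are turns; everything else is coil.  Priority H > S > T > RC.
#' The two chain-terminal residues on each side are never helix.
#'
#' @param conf a [conformation()] with >= 5 residues (amide H reconstructed
#'   automatically if missing).
#' @param detail if TRUE return sub-labels (alpha, three10, pi, extended,
#'   bridge, turn, coil) instead of the four-state reduction.
#' @return character vector of per-residue states ("H", "S", "T", "RC"), or
#'   sub-labels when `detail = TRUE`.
#' @export
assign_states <- function(conf, detail = FALSE) {
  n <- length(conf$residues)
  if (n < 5) stop("need at least 5 residues to assign states")
  conf <- reconstruct_amide_h(conf)
  hb <- hbond_matrix(conf)
  turn_at <- function(i, k) { # H-bond i -> i+k (donor i+k, acceptor i)
    i >= 1 && i + k <= n && hb[i + k, i]
  }
  sub <- rep("coil", n)
  ## helix runs (priority alpha > three10 > pi)
  mark_helix <- function(sub, k, label) {
    for (i in seq_len(max(0, n - k - 1))) {
      if (turn_at(i, k) && turn_at(i + 1, k)) {
        span <- (i + 1):(i + k)
        span <- span[span > 2 & span < n - 1]  # terminal-2 mask
        repl <- sub[span] == "coil" |
          (label == "alpha" & sub[span] %in% c("three10", "pi"))
        sub[span[repl]] <- label
      }
    }
    sub
  }
  sub <- mark_helix(sub, 4, "alpha")
  sub <- mark_helix(sub, 3, "three10")
  sub <- mark_helix(sub, 5, "pi")
  ## bridges (DSSP patterns), |i - j| >= 3; Hbond(a, d) == hb[d, a]
  bridges <- list()
  for (i in 2:(n - 1)) {
    for (j in i:(n - 1)) {
      if (j - i < 3) next
      antip <- (hb[j, i] && hb[i, j]) ||
        (i - 1 >= 1 && j + 1 <= n && hb[j + 1, i - 1] && hb[i + 1, j - 1])
      paral <- (hb[j, i - 1] && hb[i + 1, j]) ||
        (hb[i, j - 1] && hb[j + 1, i])
      if (antip || paral) bridges[[length(bridges) + 1]] <- c(i, j)
    }
  }
  is_helix <- sub %in% c("alpha", "three10", "pi")
  if (length(bridges) > 0) {
    bm <- do.call(rbind, bridges)
    for (b in seq_len(nrow(bm))) {
      i <- bm[b, 1]; j <- bm[b, 2]
      ext <- any((bm[, 1] == i + 1 & (bm[, 2] == j - 1 | bm[, 2] == j + 1)) |
                 (bm[, 1] == i - 1 & (bm[, 2] == j + 1 | bm[, 2] == j - 1)))
      lab <- if (ext) "extended" else "bridge"
      for (r in c(i, j)) {
        if (!is_helix[r] && (sub[r] == "coil" || sub[r] == "bridge"))
          sub[r] <- if (sub[r] == "bridge" && lab == "bridge") "bridge" else lab
      }
    }
  }
  ## turns: H-bonded 3-/4-turn cover plus phi/psi fallback
  is_hs <- sub != "coil"
  turn_cover <- rep(FALSE, n)
  for (i in seq_len(n)) {
    if (turn_at(i, 3)) turn_cover[(i + 1):(i + 2)] <- TRUE
    if (turn_at(i, 4)) turn_cover[(i + 1):(i + 3)] <- TRUE
  }
  dih <- extract_dihedrals(pep_ensemble(list(conf)))
  fallback <- in_turn_region(dih$phi[1, ], dih$psi[1, ])
  sub[!is_hs & (turn_cover | fallback)] <- "turn"
  if (detail) return(sub)
  ss_reduce(sub)
}

#' Reduce sub-labels to the four-state alphabet
#'
#' @param sub character vector of sub-labels.
#' @return factor-free character vector over H, S, T, RC.
#' @export
ss_reduce <- function(sub) {
  out <- rep("RC", length(sub))
  out[sub %in% c("alpha", "three10", "pi")] <- "H"
  out[sub %in% c("extended", "bridge")] <- "S"
  out[sub == "turn"] <- "T"
  out
}

#' Assign states for every frame of an ensemble
#'
#' @param ensemble a [pep_ensemble()].
#' @return character matrix (frames x residues) over H, S, T, RC.
#' @export
assign_ensemble_states <- function(ensemble) {
  t(vapply(ensemble$frames, assign_states,
           character(length(ensemble$frames[[1]]$residues))))
}

#' Four-state secondary-structure propensity profile
#'
#' Weighted per-residue frequencies of helix, strand, turn and coil states,
#' plus sequence totals (mean over residues).  The four per-residue values
#' sum to 1.  Sampling errors are block standard errors over `n_blocks`
#' contiguous frame blocks.
#'
#' @param states character matrix (frames x residues) from
#'   [assign_ensemble_states()].
#' @param weights optional per-frame weights (uniform if NULL).
#' @param seq_index residue sequence numbers (defaults to column positions).
#' @param n_blocks number of blocks for error estimation.
#' @return a `propensity_profile`: list with `profile` data.frame (residue,
#'   H, S, T, RC and *_err columns) and `totals` named vector.
#' @export
propensity_profile <- function(states, weights = NULL, seq_index = NULL,
                               n_blocks = 4L) {
  nf <- nrow(states); n <- ncol(states)
  w <- if (is.null(weights)) rep(1 / nf, nf) else weights / sum(weights)
  if (is.null(seq_index)) seq_index <- seq_len(n)
  freq_of <- function(rows, wt) {
    wt <- wt / sum(wt)
    sapply(SS4_LEVELS, function(s)
      colSums((states[rows, , drop = FALSE] == s) * wt))
  }
  p <- freq_of(seq_len(nf), w)
  blocks <- frame_blocks(nf, n_blocks)
  err <- matrix(NA_real_, n, 4, dimnames = list(NULL, SS4_LEVELS))
  if (length(blocks) >= 2) {
    bl <- lapply(blocks, function(b) freq_of(b, w[b]))
    for (s in SS4_LEVELS) {
      bs <- sapply(bl, function(m) m[, s])
      err[, s] <- apply(bs, 1, stats::sd) / sqrt(length(bl))
    }
  }
  profile <- data.frame(residue = seq_index, p, err)
  names(profile) <- c("residue", SS4_LEVELS, paste0(SS4_LEVELS, "_err"))
  totals <- colMeans(p)
  structure(list(profile = profile, totals = totals),
            class = "propensity_profile")
}

#' @export
print.propensity_profile <- function(x, ...) {
  cat("Four-state secondary-structure propensities\n")
  cat(sprintf("  <H> = %.3f  <S> = %.3f  <T> = %.3f  <RC> = %.3f\n",
              x$totals["H"], x$totals["S"], x$totals["T"], x$totals["RC"]))
  cat(sprintf("  %d residues (%d..%d)\n", nrow(x$profile),
              min(x$profile$residue), max(x$profile$residue)))
  invisible(x)
}
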