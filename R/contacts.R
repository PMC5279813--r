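## Side-chain contact maps, contact statistics, and compactness observables.
## A contact forms when the geometric centers of two side chains (heavy
## atoms; CA for glycine) lie strictly within the cutoff (default 6.5 A,
## the onset of side-chain hydration).  Contacts are long-range when
## |j - i| >= 5 in residue sequence numbering.

#' Side-chain centroid matrix of a conformation
#'
#' @param conf a [conformation()].
#' @return n x 3 matrix of per-residue side-chain geometric centers.
#' @export
centroid_matrix <- function(conf) {
  t(vapply(conf$residues, side_chain_centroid, numeric(3)))
}

#' Detect side-chain contacts in one frame
#'
#' @param conf a [conformation()].
#' @param cutoff contact cutoff in Angstrom (strict `<`).
#' @param min_separation minimum |j - i| in sequence numbers (default 2;
#'   bonded neighbors are trivially within cutoff).
#' @return integer matrix with columns i, j (sequence numbers, i < j).
#' @export
frame_contacts <- function(conf, cutoff = 6.5, min_separation = 2) {
  cen <- centroid_matrix(conf)
  idx <- conf$seq_index
  d <- as.matrix(stats::dist(cen))
  sep <- abs(outer(idx, idx, "-"))
  hit <- d < cutoff & sep >= min_separation & upper.tri(d)
  which_hit <- which(hit, arr.ind = TRUE)
  cbind(i = idx[which_hit[, 1]], j = idx[which_hit[, 2]])
}

#' Classify a residue pair as long- or short-range
#'
#' Long-range iff |j - i| >= 5.
#'
#' @param i,j residue sequence numbers (vectorized).
#' @return character vector "long"/"short".
#' @export
classify_range <- function(i, j) {
  if (any(i == j)) stop("i and j must differ")
  ifelse(abs(j - i) >= 5, "long", "short")
}

#' Ensemble side-chain contact map
#'
#' Occupancy <C(i,j)> is the weighted fraction of frames containing each
#' contact; <C> is the weighted mean per-frame contact count (equal to the
#' sum of occupancies over i < j) and <C_LR> its long-range part.  Sampling
#' errors for the counts are block SEs over `n_blocks` frame blocks.
#'
#' @param ensemble a [pep_ensemble()].
#' @param weights optional per-frame weights.
#' @param cutoff,min_separation as in [frame_contacts()].
#' @param n_blocks number of frame blocks for errors.
#' @return a `contact_map` object: occupancy matrix (dimnames = residue
#'   numbers), n_all, n_long (with errors), cutoff, min_separation.
#' @export
contact_map <- function(ensemble, weights = NULL, cutoff = 6.5,
                        min_separation = 2, n_blocks = 4L) {
  frames <- ensemble$frames
  nf <- length(frames)
  w <- frame_weights(ensemble, weights)
  idx <- frames[[1]]$seq_index
  n <- length(idx)
  occ <- matrix(0, n, n, dimnames = list(idx, idx))
  count_all <- count_long <- numeric(nf)
  for (f in seq_len(nf)) {
    cm <- frame_contacts(frames[[f]], cutoff, min_separation)
    count_all[f] <- nrow(cm)
    if (nrow(cm) > 0) {
      rng <- classify_range(cm[, 1], cm[, 2])
      count_long[f] <- sum(rng == "long")
      ii <- match(cm[, 1], idx); jj <- match(cm[, 2], idx)
      for (k in seq_len(nrow(cm))) {
        occ[ii[k], jj[k]] <- occ[ii[k], jj[k]] + w[f]
        occ[jj[k], ii[k]] <- occ[jj[k], ii[k]] + w[f]
      }
    }
  }
  blocks <- frame_blocks(nf, n_blocks)
  block_mean <- function(x) vapply(blocks, function(b)
    sum(w[b] * x[b]) / sum(w[b]), numeric(1))
  sem <- function(x) if (length(blocks) >= 2)
    stats::sd(block_mean(x)) / sqrt(length(blocks)) else NA_real_
  structure(list(occupancy = occ, seq_index = idx,
                 n_all = sum(w * count_all), n_all_err = sem(count_all),
                 n_long = sum(w * count_long), n_long_err = sem(count_long),
                 cutoff = cutoff, min_separation = min_separation),
            class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf("contact_map: %d residues, cutoff %.2f A, min separation %d\n",
              length(x$seq_index), x$cutoff, x$min_separation))
  cat(sprintf("  <C> = %.2f  <C_LR> = %.2f (%.0f%% long-range)\n",
              x$n_all, x$n_long,
              if (x$n_all > 0) 100 * x$n_long / x$n_all else 0))
  invisible(x)
}

## Long-format view of the upper triangle of a contact map.
contact_long_format <- function(cm) {
  idx <- cm$seq_index
  ut <- which(upper.tri(cm$occupancy), arr.ind = TRUE)
  data.frame(i = idx[ut[, 1]], j = idx[ut[, 2]],
             occupancy = cm$occupancy[ut],
             range = classify_range(idx[ut[, 1]], idx[ut[, 2]]))
}

#' Top-ranked side-chain contacts
#'
#' The k highest-occupancy pairs of the requested range class, descending;
#' ties broken by ascending (i, then j).
#'
#' @param cm a [contact_map()].
#' @param k number of pairs to report.
#' @param range_class "long", "short", or "all".
#' @return data.frame(rank, i, j, occupancy, range).
#' @export
top_contacts <- function(cm, k = 5, range_class = c("long", "short", "all")) {
  range_class <- match.arg(range_class)
  lf <- contact_long_format(cm)
  if (range_class != "all") lf <- lf[lf$range == range_class, ]
  ord <- order(-lf$occupancy, lf$i, lf$j)
  out <- lf[ord, ][seq_len(min(k, nrow(lf))), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out[, c("rank", "i", "j", "occupancy", "range")]
}

#' Stable contacts above an occupancy threshold
#'
#' Pairs with occupancy strictly greater than the threshold, partitioned by
#' range class.
#'
#' @param cm a [contact_map()].
#' @param threshold occupancy threshold (strict `>`), default 0.35.
#' @return list with `long` and `short` data.frames (i, j, occupancy).
#' @export
stable_contacts <- function(cm, threshold = 0.35) {
  lf <- contact_long_format(cm)
  st <- lf[lf$occupancy > threshold, ]
  list(long = st[st$range == "long", c("i", "j", "occupancy")],
       short = st[st$range == "short", c("i", "j", "occupancy")])
}

#' Radius of gyration of one conformation
#'
#' Unweighted RMS distance from the mean of the point set made of the
#' per-residue side-chain mass centers together with the CA atoms.
#'
#' @param conf a [conformation()].
#' @return Rg in Angstrom.
#' @export
radius_of_gyration <- function(conf) {
  com <- t(vapply(conf$residues, side_chain_com, numeric(3)))
  ca <- backbone_matrix(conf, "CA")
  pts <- rbind(com, ca)
  ctr <- colMeans(pts)
  sqrt(mean(rowSums((pts - matrix(ctr, nrow(pts), 3, byrow = TRUE))^2)))
}

#' End-to-end distance of one conformation
#'
#' CA(first) to CA(last) distance.
#'
#' @param conf a [conformation()].
#' @return distance in Angstrom.
#' @export
end_to_end <- function(conf) {
  r <- conf$residues
  vnorm(r[[length(r)]]$backbone["CA", ] - r[[1]]$backbone["CA", ])
}

#' Radius-of-gyration distribution and compactness statistics
#'
#' Weighted normalized histogram P(Rg) (densities integrate to 1) with the
#' ensemble averages <Rg> and <R_1N> and block standard errors.
#'
#' @param ensemble a [pep_ensemble()].
#' @param weights optional per-frame weights.
#' @param bin_width histogram bin width in Angstrom.
#' @param n_blocks number of frame blocks for errors.
#' @return list: histogram data.frame(center, density), mean_rg, mean_rg_err,
#'   mean_r1n, mean_r1n_err, rg (per-frame values).
#' @export
rg_distribution <- function(ensemble, weights = NULL, bin_width = 0.5,
                            n_blocks = 4L) {
  w <- frame_weights(ensemble, weights)
  rg <- vapply(ensemble$frames, radius_of_gyration, numeric(1))
  r1n <- vapply(ensemble$frames, end_to_end, numeric(1))
  lo <- floor(min(rg) / bin_width) * bin_width
  hi <- ceiling(max(rg) / bin_width + 1e-9) * bin_width
  breaks <- seq(lo, hi + bin_width / 2, by = bin_width)
  bin <- findInterval(rg, breaks, rightmost.closed = TRUE)
  dens <- vapply(seq_len(length(breaks) - 1),
                 function(b) sum(w[bin == b]), numeric(1)) / bin_width
  nf <- length(rg)
  blocks <- frame_blocks(nf, n_blocks)
  bmean <- function(x) vapply(blocks, function(b)
    sum(w[b] * x[b]) / sum(w[b]), numeric(1))
  sem <- function(x) if (length(blocks) >= 2)
    stats::sd(bmean(x)) / sqrt(length(blocks)) else NA_real_
  list(histogram = data.frame(center = breaks[-length(breaks)] + bin_width / 2,
                              density = dens),
       mean_rg = sum(w * rg), mean_rg_err = sem(rg),
       mean_r1n = sum(w * r1n), mean_r1n_err = sem(r1n),
       rg = rg, bin_width = bin_width)
}
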