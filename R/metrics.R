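## Agreement metrics between computed and experimental per-residue
## observables, and profile/contact-map distances between analyzed runs.
## All pairwise metrics act only on the shared residue support (residues
## present in both vectors).

shared_support <- function(x, y) {
  if (!is.null(names(x)) && !is.null(names(y))) {
    s <- intersect(names(x), names(y))
    if (length(s) == 0) stop("no shared residue support")
    list(x = x[s], y = y[s])
  } else {
    if (length(x) != length(y)) stop("unnamed vectors of different length")
    list(x = x, y = y)
  }
}

#' Root-mean-square deviation over shared support
#'
#' @param x,y numeric vectors (named by residue, or equal length).
#' @return sqrt(mean((x - y)^2)), same units as inputs.
#' @export
metric_rmsd <- function(x, y) {
  s <- shared_support(x, y)
  sqrt(mean((s$x - s$y)^2))
}

#' Pearson correlation over shared support
#'
#' @param x,y numeric vectors (>= 3 shared entries).
#' @return sample correlation, or NA with a warning if either variance is 0.
#' @export
metric_pcc <- function(x, y) {
  s <- shared_support(x, y)
  if (length(s$x) < 3) stop("need at least 3 shared entries")
  if (stats::sd(s$x) == 0 || stats::sd(s$y) == 0) {
    warning("zero variance: correlation undefined")
    return(NA_real_)
  }
  stats::cor(s$x, s$y)
}

#' Quality factor Q over shared support
#'
#' Q = sqrt( sum((D_comp - D_exp)^2) / sum(D_exp^2) ).
#'
#' @param d_comp,d_exp computed and experimental values.
#' @return dimensionless Q >= 0.
#' @export
metric_q <- function(d_comp, d_exp) {
  s <- shared_support(d_comp, d_exp)
  den <- sum(s$y^2)
  if (den <= 0) stop("experimental values are all zero: Q undefined")
  sqrt(sum((s$x - s$y)^2) / den)
}

#' Agreement summary over experimental-table x Karplus-set combinations
#'
#' Evaluates RMSD, PCC and Q of the ensemble J-couplings against each of
#' the supplied experimental tables for each Karplus coefficient set (by
#' default all nine combinations of three tables and three sets) and reports
#' the per-combination values with their mean and standard deviation.
#'
#' @param exp_tables list of `pep_exptable` objects (JHNHA).
#' @param ensemble a [pep_ensemble()].
#' @param weights optional per-frame weights.
#' @param karplus_sets character vector of coefficient-set labels.
#' @return list: `rows` data.frame(table, karplus, rmsd, pcc, q) and
#'   `summary` data.frame(metric, mean, sd).
#' @export
nine_combination_summary <- function(exp_tables, ensemble, weights = NULL,
                                     karplus_sets = c("pardi",
                                                      "brueschweiler",
                                                      "vuister")) {
  rows <- list()
  for (ks in karplus_sets) {
    jc <- ensemble_jcouplings(ensemble, weights,
                              karplus_coefficients(ks))
    for (ti in seq_along(exp_tables)) {
      ex <- exp_tables[[ti]]$entries
      rows[[length(rows) + 1]] <- data.frame(
        table = exp_tables[[ti]]$source_label, karplus = ks,
        rmsd = metric_rmsd(jc, ex), pcc = metric_pcc(jc, ex),
        q = metric_q(jc, ex))
    }
  }
  rows <- do.call(rbind, rows)
  summary <- data.frame(
    metric = c("rmsd", "pcc", "q"),
    mean = c(mean(rows$rmsd), mean(rows$pcc), mean(rows$q)),
    sd = c(stats::sd(rows$rmsd), stats::sd(rows$pcc), stats::sd(rows$q)))
  list(rows = rows, summary = summary)
}

#' RMSD between two per-residue profiles or contact maps
#'
#' Propensity profiles and RMSF profiles are compared entrywise on their
#' common residue support; contact maps are flattened over the upper
#' triangle (i < j) before comparison.
#'
#' @param a,b two `propensity_profile` objects, two [rmsf_profile()]
#'   data.frames, two [contact_map()] objects, or two named vectors.
#' @param field which column to compare for propensity ("H", "S", "T",
#'   "RC") or RMSF ("dphi", "dpsi") profiles.
#' @return RMSD (dimensionless for propensities/maps, degrees for RMSF).
#' @export
profile_rmsd <- function(a, b, field = NULL) {
  grab <- function(x) {
    if (inherits(x, "propensity_profile"))
      return(stats::setNames(x$profile[[field]], x$profile$residue))
    if (inherits(x, "contact_map"))
      return(x$occupancy[upper.tri(x$occupancy)])
    if (is.data.frame(x))
      return(stats::setNames(x[[field]], x$residue))
    x
  }
  va <- grab(a); vb <- grab(b)
  keep <- !is.na(va) & !is.na(vb)
  metric_rmsd(va[keep], vb[keep])
}

#' Rank analyzed runs by similarity to a reference run
#'
#' Computes, for every run, the profile RMSDs to the reference for helix
#' and turn propensities, dihedral RMSFs (phi and psi) and the contact map,
#' then aggregates them into a similarity score: each RMSD column is
#' min-max normalized across runs and the score is the mean of the
#' normalized columns (0 = closest to the reference).  Runs are reported in
#' descending similarity (ascending score).
#'
#' @param runs named list of analyzed runs, each a list with elements
#'   `propensity` ([propensity_profile()]), `rmsf` ([rmsf_profile()]) and
#'   `contacts` ([contact_map()]).
#' @param reference name of the reference run in `runs`.
#' @return data.frame, one row per non-reference run plus the reference
#'   itself, with the individual RMSDs, aggregate score and rank.
#' @export
forcefield_report <- function(runs, reference = names(runs)[1]) {
  stopifnot(length(runs) >= 2, reference %in% names(runs))
  ref <- runs[[reference]]
  nm <- names(runs)
  rows <- lapply(nm, function(r) {
    x <- runs[[r]]
    data.frame(run = r,
               helix_rmsd = profile_rmsd(x$propensity, ref$propensity, "H"),
               turn_rmsd = profile_rmsd(x$propensity, ref$propensity, "T"),
               dphi_rmsd = profile_rmsd(x$rmsf, ref$rmsf, "dphi"),
               dpsi_rmsd = profile_rmsd(x$rmsf, ref$rmsf, "dpsi"),
               contact_rmsd = profile_rmsd(x$contacts, ref$contacts))
  })
  rep <- do.call(rbind, rows)
  cols <- c("helix_rmsd", "turn_rmsd", "dphi_rmsd", "dpsi_rmsd",
            "contact_rmsd")
  norm <- sapply(cols, function(cn) {
    v <- rep[[cn]]
    rng <- max(v) - min(v)
    if (rng < 1e-12) rep(0, length(v)) else (v - min(v)) / rng
  })
  rep$score <- rowMeans(norm)
  ord <- order(rep$score, rep$run)
  rep <- rep[ord, ]
  rep$rank <- seq_len(nrow(rep))
  rownames(rep) <- NULL
  rep
}
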