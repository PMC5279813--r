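## Orchestration: generate -> reweight -> analyze -> compare as reproducible
## steps driven by a single JSON config.  Every emitted table carries a
## provenance header (config hash, seed, package version) and all numeric
## output uses fixed formats so identical inputs give byte-identical
## bundles.

#' Default pipeline configuration
#'
#' Analysis temperatures default to 330 K for structural observables and
#' 300 K for J-couplings and RDCs (the closest simulation temperature to
#' typical experimental conditions); the contact cutoff is 6.5 Angstrom
#' with minimum sequence separation 2 and stability threshold 0.35.
#'
#' @param seed integer seed for all generator randomness.
#' @param out_dir output directory.
#' @param ... overrides for any default key.
#' @return a named list of configuration values.
#' @export
default_config <- function(seed = 1L, out_dir = tempfile("peprun"), ...) {
  cfg <- list(
    seed = as.integer(seed),
    out_dir = out_dir,
    n_frames = 100L,
    n_residues = 31L,
    start_index = 10L,
    basins = "coil",
    contact_bias = NULL,
    temperatures = temperature_ladder(300, 440, 4),
    n_energy_samples = 500L,
    energy_mean = -100,
    ## slope and spread chosen so adjacent replica energy distributions
    ## overlap (separation ~ 1.3 sd), emulating the 27-29% exchange
    ## acceptance of a production replica-exchange ladder
    energy_slope = 0.5,    # kcal/mol per K, d<E>/dT
    energy_sd = 16,
    analysis_temperature = 330,
    jrdc_temperature = 300,
    cutoff = 6.5,
    min_separation = 2L,
    stability_threshold = 0.35,
    karplus = "pardi",
    rdc_grid = 1152L,
    experimental_tables = NULL
  )
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

#' Read a pipeline configuration from JSON
#'
#' Keys present in the file override the defaults of [default_config()].
#'
#' @param path JSON file path.
#' @return configuration list.
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(default_config, c(list(seed = if (is.null(raw$seed)) 1L
                                 else raw$seed),
                            raw[setdiff(names(raw), "seed")]))
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  keep <- config[setdiff(names(config), "out_dir")]
  jsonlite::write_json(keep[order(names(keep))], tmp, auto_unbox = TRUE,
                       digits = 10)
  unname(tools::md5sum(tmp))
}

provenance <- function(config) {
  c(sprintf("config_hash=%s", config_hash(config)),
    sprintf("seed=%d", config$seed),
    sprintf("package=pepensemble %s",
            as.character(utils::packageVersion("pepensemble"))))
}

basins_from_config <- function(config) {
  b <- config$basins
  if (is.character(b)) {
    return(switch(b,
                  helix = basins_helix(),
                  strand = basins_strand(),
                  coil = basins_coil(),
                  turn = basins_turn(),
                  stop("unknown basin preset: ", b)))
  }
  basin_spec(b$basin, b$phi, b$psi, b$sd_phi, b$sd_psi, b$weight)
}

write_tsv <- function(df, path, config, formats) {
  con <- file(path, "w")
  on.exit(close(con))
  for (h in provenance(config)) writeLines(paste0("# ", h), con)
  writeLines(paste(names(df), collapse = "\t"), con)
  if (nrow(df) > 0) {
    cols <- lapply(seq_along(df), function(k) {
      v <- df[[k]]
      fm <- formats[[names(df)[k]]]
      if (is.null(fm)) as.character(v) else sprintf(fm, v)
    })
    writeLines(do.call(paste, c(cols, sep = "\t")), con)
  }
  invisible(path)
}

#' Generate the synthetic inputs of a run
#'
#' Writes one multi-model PDB ensemble per ladder temperature (same basin
#' spec at every temperature; only the energy records differ), a replica
#' energy TSV whose per-replica mean rises linearly with temperature, and a
#' manifest JSON recording the seed and file list.
#'
#' @param config configuration list from [default_config()] /
#'   [read_config()].
#' @return invisibly, the manifest list.
#' @export
run_generate <- function(config = default_config()) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  spec <- basins_from_config(config)
  temps <- config$temperatures
  pdbs <- character(length(temps))
  for (k in seq_along(temps)) {
    ens <- generate_ensemble(spec, config$n_frames,
                             seed = config$seed + 1000L * k,
                             contact_bias = config$contact_bias,
                             n_residues = config$n_residues,
                             start_index = config$start_index)
    pdbs[k] <- file.path(config$out_dir,
                         sprintf("ensemble_T%07.2f.pdb", temps[k]))
    write_multimodel_pdb(ens, pdbs[k])
  }
  espec <- energy_model_spec(
    temps,
    mean = config$energy_mean + config$energy_slope * (temps - temps[1]),
    sd = config$energy_sd,
    n_per_replica = config$n_frames,
    seed = config$seed + 777L)
  rec <- generate_replica_energies(espec)
  rpath <- file.path(config$out_dir, "replicas.tsv")
  write_replica_tsv(rec, rpath, header_comment = provenance(config))
  manifest <- list(seed = config$seed, config_hash = config_hash(config),
                   ensembles = basename(pdbs), replicas = basename(rpath),
                   temperatures = temps,
                   package = as.character(utils::packageVersion("pepensemble")))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(manifest)
}

## Load the pooled ensemble + replica records of a generated run.
load_run <- function(config) {
  manifest <- jsonlite::read_json(file.path(config$out_dir, "manifest.json"),
                                  simplifyVector = TRUE)
  frames <- list(); temp_of_frame <- numeric(0)
  for (k in seq_along(manifest$ensembles)) {
    ens <- read_multimodel_pdb(file.path(config$out_dir,
                                         manifest$ensembles[k]))
    frames <- c(frames, ens$frames)
    temp_of_frame <- c(temp_of_frame,
                       rep(manifest$temperatures[k], length(ens$frames)))
  }
  rec <- read_replica_tsv(file.path(config$out_dir, manifest$replicas))
  list(ensemble = pep_ensemble(frames), temperatures = temp_of_frame,
       records = rec, manifest = manifest)
}

#' Analyze a generated run
#'
#' Solves WHAM over the replica energy records and computes every
#' observable from the pooled frames: four-state secondary-structure
#' propensities (at the analysis temperature, default 330 K), dihedral
#' RMSF profile, contact map with top-5 and stable-contact tables, the
#' radius-of-gyration distribution and end-to-end distance, and per-residue
#' J-coupling and RDC tables (at the J/RDC temperature, default 300 K).
#' Emits each as a provenance-stamped TSV in `out_dir` and returns the
#' results as a `pep_analysis` object.
#'
#' @param config configuration list whose `out_dir` holds a generated run.
#' @return a `pep_analysis` object (invisibly contains all tables).
#' @export
run_analyze <- function(config) {
  run <- load_run(config)
  ens <- run$ensemble
  sol <- wham_solve(run$records)
  ## WHAM weights are per energy sample; energy samples map 1:1 onto frames
  ## (same replica order and count)
  w_struct <- weights_at(sol, config$analysis_temperature)
  w_jrdc <- weights_at(sol, config$jrdc_temperature)
  if (length(w_struct) != length(ens$frames))
    stop("replica records and pooled frames are inconsistent")
  states <- assign_ensemble_states(ens)
  prop <- propensity_profile(states, w_struct,
                             seq_index = ens$frames[[1]]$seq_index)
  dih <- extract_dihedrals(ens)
  rmsf <- rmsf_profile(dih, w_struct)
  cm <- contact_map(ens, w_struct, cutoff = config$cutoff,
                    min_separation = config$min_separation)
  top_long <- top_contacts(cm, 5, "long")
  top_short <- top_contacts(cm, 5, "short")
  stable <- stable_contacts(cm, config$stability_threshold)
  rgd <- rg_distribution(ens, w_struct)
  jc <- ensemble_jcouplings(ens, w_jrdc,
                            karplus_coefficients(config$karplus))
  rdc <- ensemble_rdc(ens, w_jrdc, grid_size = config$rdc_grid)
  out <- config$out_dir
  f3 <- "%.6f"
  write_tsv(data.frame(state = SS4_LEVELS,
                       fraction = unname(prop$totals[SS4_LEVELS])),
            file.path(out, "ss_fractions.tsv"), config,
            list(fraction = f3))
  write_tsv(prop$profile, file.path(out, "propensity.tsv"), config,
            stats::setNames(as.list(rep(f3, 8)),
                            c(SS4_LEVELS, paste0(SS4_LEVELS, "_err"))))
  write_tsv(rmsf, file.path(out, "rmsf.tsv"), config,
            list(dphi = f3, dphi_err = f3, dpsi = f3, dpsi_err = f3))
  write_tsv(contact_long_format(cm), file.path(out, "contact_map.tsv"),
            config, list(occupancy = f3))
  tt <- rbind(cbind(top_long, class = "long"),
              cbind(top_short, class = "short"))
  write_tsv(tt, file.path(out, "top_contacts.tsv"), config,
            list(occupancy = f3))
  sc <- rbind(if (nrow(stable$long)) cbind(stable$long, range = "long"),
              if (nrow(stable$short)) cbind(stable$short, range = "short"))
  if (is.null(sc)) sc <- data.frame(i = integer(0), j = integer(0),
                                    occupancy = numeric(0),
                                    range = character(0))
  write_tsv(sc, file.path(out, "stable_contacts.tsv"), config,
            list(occupancy = f3))
  write_tsv(rgd$histogram, file.path(out, "rg_distribution.tsv"), config,
            list(center = "%.3f", density = f3))
  write_tsv(data.frame(quantity = c("mean_rg", "mean_rg_err",
                                    "mean_r1n", "mean_r1n_err",
                                    "n_contacts", "n_contacts_long"),
                       value = c(rgd$mean_rg, rgd$mean_rg_err,
                                 rgd$mean_r1n, rgd$mean_r1n_err,
                                 cm$n_all, cm$n_long)),
            file.path(out, "compactness.tsv"), config, list(value = f3))
  write_observable_table(jc, file.path(out, "jcoupling.tsv"),
                         provenance(config))
  write_observable_table(rdc, file.path(out, "rdc.tsv"),
                         provenance(config))
  structure(list(config = config, wham = sol, propensity = prop,
                 rmsf = rmsf, contacts = cm, top_long = top_long,
                 top_short = top_short, stable = stable,
                 compactness = rgd, jcoupling = jc, rdc = rdc,
                 weights = list(structural = w_struct, jrdc = w_jrdc)),
            class = "pep_analysis")
}

#' @export
print.pep_analysis <- function(x, ...) {
  cat("pep_analysis run:", x$config$out_dir, "\n")
  t <- x$propensity$totals
  cat(sprintf("  <H>=%.3f <S>=%.3f <T>=%.3f <RC>=%.3f | <C>=%.1f (LR %.1f) | <Rg>=%.1f A\n",
              t["H"], t["S"], t["T"], t["RC"], x$contacts$n_all,
              x$contacts$n_long, x$compactness$mean_rg))
  invisible(x)
}

#' Compare analyzed runs with experiment and each other
#'
#' For each analyzed run, evaluates the J-coupling agreement metrics over
#' every combination of experimental table and Karplus coefficient set, and
#' the RDC agreement after least-squares scaling; also ranks the runs by
#' similarity to a reference run ([forcefield_report()]).  Writes
#' `agreement.tsv` and `similarity.tsv` into `out_dir`.
#'
#' @param runs named list of `pep_analysis` objects.
#' @param j_tables list of experimental JHNHA `pep_exptable`s (may be
#'   empty).
#' @param rdc_table optional experimental RDC `pep_exptable`.
#' @param reference name of the reference run.
#' @param out_dir where to write the comparison tables (default: the
#'   reference run's directory).
#' @return list with `agreement` and `similarity` data.frames.
#' @export
run_compare <- function(runs, j_tables = list(), rdc_table = NULL,
                        reference = names(runs)[1], out_dir = NULL) {
  stopifnot(length(runs) >= 1)
  if (is.null(out_dir)) out_dir <- runs[[reference]]$config$out_dir
  agreement <- NULL
  for (nm in names(runs)) {
    x <- runs[[nm]]
    row <- data.frame(run = nm)
    if (length(j_tables) > 0) {
      ens_w <- x$weights$jrdc
      nine <- nine_combination_summary(
        j_tables,
        load_run(x$config)$ensemble,
        weights = ens_w)
      s <- nine$summary
      row$j_rmsd <- s$mean[s$metric == "rmsd"]
      row$j_rmsd_sd <- s$sd[s$metric == "rmsd"]
      row$j_pcc <- s$mean[s$metric == "pcc"]
      row$j_pcc_sd <- s$sd[s$metric == "pcc"]
      row$j_q <- s$mean[s$metric == "q"]
      row$j_q_sd <- s$sd[s$metric == "q"]
    }
    if (!is.null(rdc_table)) {
      sc <- fit_scale(x$rdc, rdc_table$entries)
      scaled <- sc * x$rdc
      row$rdc_rmsd <- metric_rmsd(scaled, rdc_table$entries)
      row$rdc_pcc <- metric_pcc(scaled, rdc_table$entries)
      row$rdc_q <- metric_q(scaled, rdc_table$entries)
      row$rdc_scale <- sc
    }
    agreement <- if (is.null(agreement)) row else rbind(agreement, row)
  }
  similarity <- if (length(runs) >= 2)
    forcefield_report(runs, reference) else NULL
  cfg <- runs[[reference]]$config
  numcols <- setdiff(names(agreement), "run")
  write_tsv(agreement, file.path(out_dir, "agreement.tsv"), cfg,
            stats::setNames(as.list(rep("%.6f", length(numcols))), numcols))
  if (!is.null(similarity)) {
    simcols <- setdiff(names(similarity), c("run", "rank"))
    write_tsv(similarity, file.path(out_dir, "similarity.tsv"), cfg,
              stats::setNames(as.list(rep("%.6f", length(simcols))),
                              simcols))
  }
  list(agreement = agreement, similarity = similarity)
}
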