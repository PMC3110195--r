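#' Pipeline run configuration
#'
#' Collects every tunable constant of the modelling pipeline with the
#' reference defaults: building block and fold (12-fold monomer /
#' 6-fold dimer annulus), 10 Angstrom core radius, 5 degree
#' self-rotation step (72 candidates), 4.7 Angstrom dimer stacking,
#' 6.0 Angstrom sidechain contacts, 3.5 Angstrom / 120 degree hydrogen
#' bonds, 4.0 Angstrom salt bridges, 1.4 Angstrom probe, 330 K, and the
#' 3000-draw / 75 percent dimer rule. Validation happens here, before
#' any stage runs.
#'
#' @param block_type `"monomer"` or `"dimer"`.
#' @param fold n-fold symmetry; default 12 for monomer, 6 for dimer
#'   blocks (12 peptides either way).
#' @param core_radius,scan_step,stacking Angstrom / degrees.
#' @param contact_cutoff,hbond_dist,hbond_angle,salt_bridge_cutoff,probe
#'   analysis thresholds.
#' @param temperature Kelvin.
#' @param n_draws,threshold dimer-rule parameters.
#' @param n_frames,sigma,drift_rate synthetic-trajectory settings.
#' @param ref_frames isolated-dimer ensemble size for the reference set.
#' @param n_top candidates carried into the analysis/population stages.
#' @param energy_points surface sample points per atom used inside the
#'   screening score.
#' @param seed master seed.
#' @return A validated list of class `ab_run_config`.
#' @export
run_config <- function(block_type = c("monomer", "dimer"), fold = NULL,
                       core_radius = 10, scan_step = 5, stacking = 4.7,
                       contact_cutoff = 6.0, hbond_dist = 3.5,
                       hbond_angle = 120, salt_bridge_cutoff = 4.0,
                       probe = 1.4, temperature = 330, n_draws = 3000L,
                       threshold = 0.75, n_frames = 20L, sigma = 0.5,
                       drift_rate = 0, ref_frames = 200L, n_top = 3L,
                       energy_points = 240L, seed = 1L) {
  block_type <- match.arg(block_type)
  fold <- fold %||% if (block_type == "monomer") 12L else 6L
  cfg <- list(block_type = block_type, fold = as.integer(fold),
              core_radius = core_radius, scan_step = scan_step,
              stacking = stacking, contact_cutoff = contact_cutoff,
              hbond_dist = hbond_dist, hbond_angle = hbond_angle,
              salt_bridge_cutoff = salt_bridge_cutoff, probe = probe,
              temperature = temperature, n_draws = as.integer(n_draws),
              threshold = threshold, n_frames = as.integer(n_frames),
              sigma = sigma, drift_rate = drift_rate,
              ref_frames = as.integer(ref_frames), n_top = as.integer(n_top),
              energy_points = as.integer(energy_points), seed = as.integer(seed))
  positive <- c("core_radius", "scan_step", "stacking", "contact_cutoff",
                "hbond_dist", "hbond_angle", "salt_bridge_cutoff", "probe",
                "temperature", "n_draws", "threshold", "n_frames",
                "ref_frames", "n_top", "energy_points")
  for (nm in positive) {
    if (!is.finite(cfg[[nm]]) || cfg[[nm]] <= 0) {
      abort(sprintf("config field '%s' must be positive", nm))
    }
  }
  if (abs(360 / cfg$scan_step - round(360 / cfg$scan_step)) > 1e-9) {
    abort(sprintf("scan_step of %s degrees does not divide 360",
                  format(cfg$scan_step)))
  }
  if (cfg$sigma < 0) abort("sigma must be non-negative")
  if (cfg$fold < 1) abort("fold must be at least 1")
  structure(cfg, class = "ab_run_config")
}

#' @rdname run_config
#' @param path plain-text `key = value` configuration file; `#` starts a
#'   comment. Unknown keys raise an error.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- lengths(kv) != 2
  if (any(bad)) abort(sprintf("cannot parse config line: '%s'", lines[bad][1]))
  keys <- vapply(kv, `[[`, character(1), 1)
  vals <- vapply(kv, `[[`, character(1), 2)
  known <- names(formals(run_config))
  unknown <- setdiff(keys, known)
  if (length(unknown) > 0) {
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  args <- lapply(seq_along(keys), function(i) {
    if (keys[i] == "block_type") vals[i] else as.numeric(vals[i])
  })
  names(args) <- keys
  do.call(run_config, args)
}

#' Run the full modelling pipeline into a directory
#'
#' Stages, in order: template generation, assembly building and
#' self-rotation scan (one PDB per candidate plus a manifest), candidate
#' screening (ranking table), trajectory analysis of the top-ranked
#' candidate (per-frame RMSD/Rg/sphericity, RMSF, region SASA, salt
#' bridges, contact/hydrogen-bond map, free-energy landscape), dimer
#' counting against an isolated-dimer reference set, and population
#' estimation over the top candidates. Every output is listed in
#' `manifest.tsv` with its MD5 hash; identical configurations and seeds
#' give byte-identical tables. A stage failure aborts with the stage
#' named; outputs of completed stages are retained.
#'
#' @param config an [run_config()].
#' @param out_dir run directory (created; must be empty or absent).
#' @return Invisibly, a list with the manifest tibble and the key result
#'   objects.
#' @export
run_pipeline <- function(config = run_config(), out_dir) {
  stopifnot(inherits(config, "ab_run_config"))
  if (dir.exists(out_dir) && length(list.files(out_dir)) > 0) {
    abort(sprintf("output directory '%s' is not empty", out_dir))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "candidates"), showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(...) cat(sprintf(...), "\n", sep = "", file = log_path,
                            append = TRUE)
  stage <- "simulate-data"
  result <- list()
  tryCatch({
    logf("globulomeR %s pipeline run", as.character(utils::packageVersion("globulomeR")))
    logf("config: %s", paste(names(unclass(config)),
                             vapply(unclass(config), format, character(1)),
                             sep = "=", collapse = " "))

    template <- make_hairpin_template(hairpin_spec(seed = config$seed))
    write_multimodel_pdb(template, file.path(out_dir, "template.pdb"))
    logf("[simulate-data] wrote template.pdb")

    stage <- "build"
    block <- if (config$block_type == "dimer") {
      stack_dimer(template, config$stacking)
    } else template
    base <- replicate_annular(block, config$fold, config$core_radius)
    scan <- self_rotation_scan(base, config$scan_step)
    files <- character(nrow(scan))
    for (i in seq_len(nrow(scan))) {
      files[i] <- file.path("candidates", paste0(scan$model_label[i], ".pdb"))
      write_multimodel_pdb(scan$assembly[[i]], file.path(out_dir, files[i]))
    }
    readr::write_tsv(tibble(angle = scan$angle, model_label = scan$model_label,
                            file = files),
                     file.path(out_dir, "candidates.tsv"))
    logf("[build] %d candidates", nrow(scan))

    stage <- "screen"
    ranking <- screen_candidates(scan, n_points = config$energy_points)
    readr::write_tsv(ranking, file.path(out_dir, "ranking.tsv"))
    logf("[screen] best candidate %s (total %.1f)",
         ranking$model_label[1], ranking$total[1])

    stage <- "analyze"
    best <- scan$assembly[[match(ranking$model_label[1], scan$model_label)]]
    traj <- make_synthetic_trajectory(
      best, noise_spec(sigma = config$sigma, drift_rate = config$drift_rate,
                       n_frames = config$n_frames, seed = config$seed))
    write_multimodel_pdb(traj, file.path(out_dir, "trajectory.pdb"))
    per_frame <- rmsd_to_ref(traj, best) |>
      left_join(radius_of_gyration(traj), by = "frame") |>
      left_join(sphericity(traj)[, c("frame", "phi")], by = "frame")
    readr::write_tsv(per_frame, file.path(out_dir, "per_frame.tsv"))
    rp <- rmsf_and_average(traj)
    readr::write_tsv(rp$profile, file.path(out_dir, "rmsf.tsv"))
    sasa_chain <- sasa_by_region(trajectory_frame(traj, n_frames(traj)),
                                 probe = config$probe)
    readr::write_tsv(sasa_chain, file.path(out_dir, "sasa_by_chain.tsv"))
    sasa_tot <- sasa_chain |> group_by(.data$region) |>
      summarise(sasa = sum(.data$sasa), .groups = "drop")
    readr::write_tsv(sasa_tot, file.path(out_dir, "sasa_totals.tsv"))
    readr::write_tsv(salt_bridge_summary(traj, config$salt_bridge_cutoff),
                     file.path(out_dir, "salt_bridges.tsv"))
    cmap <- contact_hbond_map(traj, config$contact_cutoff, config$hbond_dist,
                              config$hbond_angle)
    readr::write_tsv(tidy(cmap), file.path(out_dir, "contact_hbond_map.tsv"))
    ls <- landscape(traj, best, temperature = config$temperature)
    readr::write_tsv(as_tibble(ls), file.path(out_dir, "landscape.tsv"))
    logf("[analyze] %d frames analysed", n_frames(traj))

    stage <- "dimers"
    dimer_block <- stack_dimer(template, config$stacking)
    ens <- make_isolated_dimer_ensemble(dimer_block, config$ref_frames,
                                        noise_spec(sigma = config$sigma,
                                                   seed = config$seed + 1L))
    refset <- build_reference_dataset(ens, n_samples = config$ref_frames,
                                      contact_cutoff = config$contact_cutoff,
                                      seed = config$seed)
    readr::write_tsv(as_tibble(refset), file.path(out_dir, "reference_set.tsv"))
    dimers <- count_dimers(traj, refset, n_draws = config$n_draws,
                           threshold = config$threshold, seed = config$seed)
    readr::write_tsv(dimers$counts, file.path(out_dir, "dimers.tsv"))
    logf("[dimers] mean %.2f dimers/frame", mean(dimers$counts$n_dimers))

    stage <- "populations"
    top <- ranking$model_label[seq_len(min(config$n_top, nrow(ranking)))]
    pool_rows <- purrr::map(top, function(lbl) {
      asm <- scan$assembly[[match(lbl, scan$model_label)]]
      tr <- make_synthetic_trajectory(
        asm, noise_spec(sigma = config$sigma, n_frames = 5L,
                        seed = config$seed + match(lbl, top)))
      en <- vapply(seq_len(n_frames(tr)), function(i)
        assembly_energy(trajectory_frame(tr, i),
                        n_points = config$energy_points)$total, numeric(1))
      tibble(model = lbl, energy = en)
    })
    pool <- conformer_pool(bind_rows(pool_rows), temperature = config$temperature)
    pops <- estimate_populations(pool)
    readr::write_tsv(population_report(pops), file.path(out_dir, "populations.tsv"))
    logf("[populations] done")
  }, error = function(e) {
    logf("[%s] FAILED: %s", stage, conditionMessage(e))
    abort(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)))
  })

  files <- setdiff(list.files(out_dir, recursive = TRUE), "manifest.tsv")
  manifest <- tibble(file = files,
                     md5 = unname(tools::md5sum(file.path(out_dir, files))))
  readr::write_tsv(manifest, file.path(out_dir, "manifest.tsv"))
  invisible(list(manifest = manifest, out_dir = out_dir))
}
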