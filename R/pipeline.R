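#' Default end-to-end pipeline configuration
#'
#' A nested list with one section per stage (build, simulate, analyze, pb)
#' plus a global seed. The defaults are the packaged demo: the default
#' synthetic channel with an open 2.5-A constriction, a +3 three-bead
#' ligand driven by a 0.2 V/A field toward the cytoplasmic exit, ions
#' mobile, and the standard analysis settings. All fields can be
#' overridden via a YAML file ([read_pipeline_config()]) or by editing the
#' list.
#'
#' @param seed Global seed; stage seeds derive from it.
#' @return A `pk_pipeline_config` list.
#' @export
default_pipeline_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    build = list(
      constriction_radius = 2.5,
      constriction_z = -5,
      n_cations = 95L, n_anions = 95L, n_lipids = 230L,
      ligand_position = c(0, 0, 5)
    ),
    simulate = list(
      field = 0.2,                # V/A, applied along -Z to the ligand
      n_steps = 6000L,
      timestep = 0.01,
      temperature = 300,
      friction = 5,
      save_interval = 4,
      mobile = "resname LIG or resname K"
    ),
    analyze = list(
      ligand_sel = "resname LIG",
      ring_sel = "resnum 106 and name CA",
      z_upper = 10, z_lower = -5,
      bands = c(20, 10, 0, -10),
      min_dwell = 0,
      contact_resnum = 103L,
      contact_threshold = 6.5,
      pore_z = c(-55, 30), pore_step = 2, pore_r_max = 10,
      pore_seed_step = 3
    ),
    pb = list(
      spacing = 1.0, buffer = 8,
      n_frames = 6,
      subsystem = "monomer 0:100 or resname LIG"
    )
  ), class = "pk_pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Fields present in the file override the defaults; everything else keeps
#' its default value.
#'
#' @param path YAML file path.
#' @return A `pk_pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_pipeline_config()
  for (sec in names(user)) {
    if (is.list(user[[sec]]) && sec %in% names(cfg)) {
      for (k in names(user[[sec]])) cfg[[sec]][[k]] <- user[[sec]][[k]]
    } else {
      cfg[[sec]] <- user[[sec]]
    }
  }
  cfg
}

#' Validate a pipeline configuration
#'
#' Schema checks run before any computation; an invalid configuration
#' never starts a run.
#'
#' @param config A `pk_pipeline_config`.
#' @return The config, invisibly, or an error.
#' @export
validate_pipeline_config <- function(config) {
  a <- config$analyze
  if (a$z_upper <= a$z_lower) abort("config error: z_upper must be > z_lower")
  if (config$build$constriction_radius <= 0) {
    abort("config error: constriction_radius must be > 0")
  }
  if (config$simulate$n_steps <= 0) abort("config error: n_steps must be > 0")
  if (config$simulate$field < 0) abort("config error: field must be >= 0")
  if (length(a$bands) > 0 && any(diff(a$bands) >= 0)) {
    abort("config error: bands must be strictly decreasing")
  }
  if (config$pb$spacing <= 0) abort("config error: pb spacing must be > 0")
  invisible(config)
}

#' Run the full build - simulate - analyze pipeline
#'
#' Executes every stage and writes the artifact set to `output_dir`:
#' `system.pdb` + `charges.csv` (the built system), `traj.xyz` (the
#' trajectory), `deltaz.csv` (the permeation coordinate), `report.json`
#' (crossings, stages, first passage, ion displacement, contact averages),
#' `energies.csv` (per-frame MM-PB energies), `profile.csv` (final-frame
#' pore profile), `rotations.csv` (final-frame per-helix rotations vs the
#' built closed reference) and `manifest.json` (config hash, seed, package
#' version, artifact list). Identical config + seed give byte-identical
#' CSV/XYZ artifacts. On a stage failure the manifest is still written,
#' with status FAILED, and the error is re-raised.
#'
#' @param config A `pk_pipeline_config`.
#' @param output_dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory results (`system`,
#'   `trajectory`, `report`, `energies`, `profile`, `rotations`,
#'   `manifest`).
#' @export
run_pipeline <- function(config = default_pipeline_config(), output_dir) {
  validate_pipeline_config(config)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config_hash = rlang::hash(unclass(config)),
                   seed = config$seed,
                   package_version = as.character(utils::packageVersion("permeakit")),
                   status = "RUNNING", artifacts = character(0))
  write_manifest <- function() {
    jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = 10)
  }
  fail <- function(e) {
    manifest$status <<- "FAILED"
    manifest$error <<- conditionMessage(e)
    write_manifest()
    abort(conditionMessage(e))
  }
  result <- tryCatch({
    b <- config$build
    chan <- channel_spec(pore_constriction_radius = b$constriction_radius,
                         constriction_z = b$constriction_z,
                         rng_seed = config$seed)
    system <- build_pentamer(chan)
    closed_ref <- system
    system <- place_ligand(system, ligand_spec(), b$ligand_position)
    system <- place_ions_and_slab(
      system, bath_spec(n_cations = b$n_cations, n_anions = b$n_anions,
                        n_lipids = b$n_lipids, rng_seed = config$seed))
    write_pdb(system, file.path(output_dir, "system.pdb"))
    write_charge_csv(system, file.path(output_dir, "charges.csv"))

    s <- config$simulate
    ff <- forcefield(eef_field = c(0, 0, -s$field),
                     eef_mask = config$analyze$ligand_sel)
    cfg <- dynamics_config(n_steps = s$n_steps, timestep = s$timestep,
                           temperature = s$temperature, friction = s$friction,
                           save_interval = s$save_interval, mobile = s$mobile,
                           rng_seed = config$seed)
    traj <- run_dynamics(system, ff, cfg)
    write_xyz(traj, file.path(output_dir, "traj.xyz"))

    a <- config$analyze
    series <- delta_z(traj, a$ligand_sel, a$ring_sel)
    write_series_csv(series, file.path(output_dir, "deltaz.csv"))
    report <- permeation_report(traj, a$ligand_sel, a$ring_sel,
                                z_upper = a$z_upper, z_lower = a$z_lower,
                                bands = a$bands, min_dwell = a$min_dwell)
    ion <- ion_displacement(traj, "resname K")
    contacts <- contact_number(traj, a$contact_resnum, a$contact_threshold)

    pbc <- config$pb
    eframes <- unique(round(seq(1, n_frames(traj),
                                length.out = min(pbc$n_frames, n_frames(traj)))))
    energies <- mm_pb_series(traj, pbc$subsystem, frames = eframes,
                             spacing = pbc$spacing, buffer = pbc$buffer)
    write_numeric_csv(energies, file.path(output_dir, "energies.csv"))

    final <- frame_structure(traj, n_frames(traj))
    prot <- pk_structure(as_tibble(final)[final$monomer_index >= 0L, ],
                         monomer_offset = monomer_offset(final))
    profile <- pore_profile(prot, z_range = a$pore_z, step = a$pore_step,
                            r_max = a$pore_r_max,
                            seed_step = a$pore_seed_step)
    write_profile_csv(profile, file.path(output_dir, "profile.csv"))

    helix_map <- pipeline_helix_selections(chan)
    rotations <- helix_rotation(prot, closed_ref, helix_map)
    write_numeric_csv(rotations, file.path(output_dir, "rotations.csv"))

    report_json <- list(
      first_passage_ps = if (is.finite(report$first_passage_ps))
        report$first_passage_ps else NULL,
      n_down = sum(report$events$direction == "down"),
      n_up = sum(report$events$direction == "up"),
      events = report$events,
      stages = report$stages,
      ion_mean_dz_A = attr(ion, "mean_dz"),
      contact_means = glance(contacts),
      net_charge = sum(system$charge)
    )
    jsonlite::write_json(report_json, file.path(output_dir, "report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = 10,
                         dataframe = "rows")
    list(system = system, trajectory = traj, report = report, ion = ion,
         contacts = contacts, energies = energies, profile = profile,
         rotations = rotations)
  }, error = fail)
  manifest$status <- "OK"
  manifest$artifacts <- c("system.pdb", "charges.csv", "traj.xyz",
                          "deltaz.csv", "report.json", "energies.csv",
                          "profile.csv", "rotations.csv")
  write_manifest()
  result$manifest <- manifest
  invisible(result)
}

# per-helix alpha-carbon selections of monomer 0, as used by the pipeline's
# rotation analysis
pipeline_helix_selections <- function(chan) {
  sel_of <- function(res) {
    sprintf("monomer 0 and resnum %d:%d and name CA", min(res), max(res))
  }
  setNames(lapply(chan$helices, sel_of), names(chan$helices))
}
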