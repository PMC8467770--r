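#' Run the full contact-to-kinetics pipeline
#'
#' Orchestrates every analysis stage over one system and writes a report
#' bundle: per-cutoff loop-center contact profiles, the loop-vs-site
#' residue contact maps, the per-frame state sequence, the dwell table,
#' the kinetics report (rate constants with CIs, effective volume,
#' effective concentration), the state-conditioned per-residue contact
#' ratios at site B, and a run manifest. All numerical outputs are plain
#' TSV/JSON and are a pure function of (inputs, config, seed). Any stage
#' failure aborts with the stage name and cause.
#'
#' @param topology_path,trajectory_paths input structure files (PDB + DCD),
#'   or leave both `NULL` and pass an `ensemble` directly.
#' @param ens an [ensemble], alternative to file input.
#' @param regions list with `loop`, `siteA`, `siteB` residue ids (e.g. the
#'   `regions` element of [read_analysis_config()]).
#' @param config an [analysis_config].
#' @param frame_interval frame spacing, ps (file input only).
#' @param out_dir output directory (created if needed).
#' @param box_volume box volume, Angstrom^3, for the effective-volume
#'   stage; `veff_liters` overrides the whole volume model.
#' @param veff_liters direct effective-volume override, litres.
#' @param plots write advisory PNG figures.
#' @return invisibly, a list with the in-memory stage results and the
#'   written file paths.
#' @export
run_full_pipeline <- function(topology_path = NULL, trajectory_paths = NULL,
                              ens = NULL, regions, config = analysis_config(),
                              frame_interval = NULL, out_dir = "loopkin_out",
                              box_volume = NULL, veff_liters = NULL,
                              plots = FALSE) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  files <- character(0)

  ens <- stage("load", {
    if (is.null(ens)) {
      if (is.null(topology_path) || is.null(trajectory_paths))
        stop("need either an ensemble or topology + trajectories")
      load_ensemble(topology_path, trajectory_paths, frame_interval,
                    box_volume = box_volume)
    } else ens
  })
  message("loopkin: loaded ", n_frames(ens), " frames (",
          length(unique(ens$replica)), " replicas)")

  reg <- stage("regions", resolve_regions(
    ens, regions$loop, regions$siteA, regions$siteB,
    numbering = regions$numbering %||% "topology numbering"))

  profile <- stage("contact_profile", loop_center_contact_profile(
    ens, reg, cutoffs = config$center_cutoffs))
  files["contact_profile"] <- tsv(as.data.frame(profile),
                                  "contact_profile.tsv")

  maps <- stage("contact_map", {
    lapply(c(siteA = "siteA", siteB = "siteB"), function(s)
      residue_contact_map(ens, reg$loop, reg[[s]],
                          cutoff = config$atom_contact_cutoff,
                          include_hydrogens = config$include_hydrogens))
  })
  for (s in names(maps))
    files[paste0("map_", s)] <- tsv(
      data.frame(loop_resno = maps[[s]]$loop_res,
                 round(maps[[s]]$ratio, 6), check.names = FALSE),
      paste0("contact_map_", s, ".tsv"))

  states <- stage("states", classify_frames(ens, reg, config))
  message("loopkin: state occupancy ",
          paste(sprintf("%s=%.3f", levels(states$labels),
                        table(states$labels) / length(states$labels)),
                collapse = " "))
  files["states"] <- tsv(
    data.frame(time_ps = seq_along(states$labels) * states$frame_interval,
               replica = states$replica,
               label = as.character(states$labels)), "states.tsv")

  dwells <- stage("dwells", extract_dwells(states))
  files["dwells"] <- tsv(as.data.frame(dwells), "dwells.tsv")

  volume <- stage("volume", {
    if (!is.null(veff_liters)) veff_liters
    else if (!is.null(ens$box_volume)) compute_effective_volume(ens)
    else NULL
  })

  fit <- stage("kinetics", {
    tryCatch(loop_kinetics(dwells, config = config, volume = volume),
             error = function(e) {
               message("loopkin: kinetics unavailable: ",
                       conditionMessage(e))
               NULL
             })
  })
  if (!is.null(fit) && is.null(fit$rates))
    message("loopkin: kinetics unavailable: no binding events observed")
  if (!is.null(fit) && !is.null(fit$rates)) {
    report <- fit$rates
    if (inherits(volume, "volume_model")) {
      report$v_eff_L <- volume$v_eff_L
      report$c_eff_M <- 1 / (N_AVOGADRO * volume$v_eff_L)
    } else if (is.numeric(volume)) {
      report$v_eff_L <- volume
      report$c_eff_M <- 1 / (N_AVOGADRO * volume)
    }
    files["kinetics"] <- tsv(report, "kinetics.tsv")
    jsonlite::write_json(report, file.path(out_dir, "kinetics.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    files["kinetics_json"] <- file.path(out_dir, "kinetics.json")
  }

  cond <- stage("conditional_ratios", {
    mask <- states$labels == "SITE_B"
    if (any(mask)) {
      m <- residue_contact_map(ens, reg$loop, reg$siteB,
                               cutoff = config$atom_contact_cutoff,
                               frame_mask = mask,
                               include_hydrogens = config$include_hydrogens)
      per_site_residue_ratio(m)
    } else NULL
  })
  if (!is.null(cond))
    files["siteB_conditional"] <- tsv(
      data.frame(resno = as.integer(names(cond)), contact_ratio = cond),
      "siteB_residue_ratio_conditional.tsv")

  if (plots) {
    grDevices::png(file.path(out_dir, "contact_profile.png"), 900, 500)
    plot(profile); grDevices::dev.off()
    if (!is.null(fit) && !is.null(fit$rates) &&
        any(fit$rates$kind == "k_off")) {
      grDevices::png(file.path(out_dir, "rates.png"), 700, 500)
      plot(fit, which = intersect(c("k_off", "k_on"), fit$rates$kind))
      grDevices::dev.off()
    }
  }

  manifest <- list(
    tool = paste0("loopkin ",
                  as.character(utils::packageVersion("loopkin"))),
    timestamp = format(Sys.time(), tz = "UTC"),
    seed = config$seed,
    config = unclass(config),
    regions = regions[c("loop", "siteA", "siteB")],
    n_frames = n_frames(ens),
    n_replicas = length(unique(ens$replica)),
    frame_interval_ps = ens$frame_interval,
    input_md5 = if (!is.null(topology_path))
      as.list(tools::md5sum(c(topology_path, trajectory_paths))) else NULL,
    outputs = as.list(files))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(ensemble = ens, regions = reg, profile = profile,
                 maps = maps, states = states, dwells = dwells,
                 volume = volume, fit = fit, conditional_siteB = cond,
                 files = files, manifest = manifest))
}

#' Study-design accounting
#'
#' Frame and aggregate-time bookkeeping for a multi-system, multi-replica
#' sampling design: frames per system = replicas x floor(duration /
#' interval); aggregate time = systems x replicas x duration.
#'
#' @param n_systems number of independently simulated systems.
#' @param n_replicas independent trajectories per system.
#' @param traj_ns length of one trajectory, ns.
#' @param frame_interval_ps frame spacing, ps.
#' @return list with `frames_per_replica`, `frames_per_system`,
#'   `total_time_us`.
#' @export
study_design <- function(n_systems = 7L, n_replicas = 5L, traj_ns = 500,
                         frame_interval_ps = 200) {
  stopifnot(n_systems >= 1, n_replicas >= 1, traj_ns > 0,
            frame_interval_ps > 0)
  fpr <- floor(traj_ns * 1000 / frame_interval_ps)
  list(frames_per_replica = fpr,
       frames_per_system = n_replicas * fpr,
       total_time_us = n_systems * n_replicas * traj_ns / 1000)
}
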