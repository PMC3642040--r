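#' Default pipeline configuration
#'
#' Nested list of every tunable of the end-to-end toy workflows; any
#' subset can be overridden via `run_*(config = list(...))` or a YAML
#' file with the same structure.  Defaults are desk-scale: minutes, not
#' microseconds.
#'
#' @return nested named list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    toy = list(beads_per_helix = 6L, k_spring = 800, double_well_bias = NULL,
               mixing_eps = 4, temperature = 310, friction = 1),
    ed = list(n_steps = 3000L, replicas = 3L, dt = 5e-4,
              save_every = 10L, success_rmsd = 0.2,
              closing_success_rmsd = 0.23),
    rotamer = list(p_up_to_down = 0.004, p_down_to_up = 0.0005,
                   noise_sd = 8, n_residues = 4L),
    umbrella = list(n_windows = 39L, default_k = 30, boosted_k = 100,
                    n_samples = 20000L, discard_first_fraction = 0.5,
                    n_bins = 150L, n_boot = 20L, temperature = 310,
                    tol = 1e-7),
    pore = list(z_step = 0.05, mc_steps = 150L),
    cooperativity = list(k_subunits = 1:4, n_steps = 3000L,
                         success_rmsd = 0.25, gate_residue = 112L)
  )
}

merge_config <- function(user, base = default_config(), path = "config") {
  if (is.null(user)) return(base)
  if (!is.list(user)) stop("config section ", path, " must be a list")
  bad <- setdiff(names(user), names(base))
  if (length(bad))
    stop("unknown config key(s): ",
         paste(paste0(path, "$", bad), collapse = ", "))
  for (nm in names(user)) {
    base[[nm]] <- if (is.list(base[[nm]]))
      merge_config(user[[nm]], base[[nm]], paste0(path, "$", nm))
    else user[[nm]]
  }
  base
}

load_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  merge_config(config)
}

write_manifest <- function(out_dir, stage, config, seed, files, timings) {
  digests <- vapply(files, function(f)
    unname(tools::md5sum(file.path(out_dir, f))), character(1))
  manifest <- list(stage = stage,
                   package_version =
                     as.character(utils::packageVersion("gatedyn")),
                   seed = seed, config = config,
                   timings_sec = timings,
                   outputs = as.list(stats::setNames(digests, files)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

toy_from_config <- function(cfg) {
  make_toy_channel(toy_channel_spec(
    beads_per_helix = cfg$toy$beads_per_helix,
    k_spring = cfg$toy$k_spring,
    double_well_bias = cfg$toy$double_well_bias,
    mixing_eps = cfg$toy$mixing_eps,
    temperature = cfg$toy$temperature,
    friction = cfg$toy$friction,
    seed = cfg$seed))
}

#' Run the replica opening workflow on the toy channel
#'
#' End-to-end opening analysis: build the toy end states and the
#' difference eigenvector, run `replicas` constrained opening drives,
#' and report replica-averaged RMSD traces, gate-distance traces,
#' synthetic rotamer state fractions and pore profiles of both
#' endpoints.  All tables are written as CSV with a JSON run manifest.
#'
#' @param config nested list or YAML path; see [default_config()].
#' @param out_dir output directory (created if needed).
#' @return list with `runs`, `rmsd_avg`, `gate`, `rotamer_fractions`,
#'   `profiles`, `verdicts` and the manifest, invisibly written to
#'   `out_dir`.
#' @export
run_opening <- function(config = NULL, out_dir = tempfile("opening")) {
  cfg <- load_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- proc.time()[["elapsed"]]
  toy <- toy_from_config(cfg)
  cv <- build_difference_ev(toy$closed, toy$open, toy$selection)
  idx <- cv$fit_indices
  runs <- lapply(seq_len(cfg$ed$replicas), function(r) {
    prot <- ed_protocol(cv, n_steps = cfg$ed$n_steps,
                        success_rmsd = cfg$ed$success_rmsd)
    run_ed(toy$energy, toy$closed, prot, reference = toy$open,
           dt = cfg$ed$dt, temperature = cfg$toy$temperature,
           friction = cfg$toy$friction, seed = cfg$seed + r,
           save_every = cfg$ed$save_every)
  })
  rmsd_series <- lapply(runs, function(r) r$rmsd_to_reference * ANG_PER_NM)
  rmsd_avg <- rmsd_replica_average(rmsd_series)
  rmsd_avg$time_ps <- runs[[1]]$traj$times
  gate <- lapply(runs, function(r)
    vapply(seq_len(n_frames(r$traj)), function(i)
      opposite_distance(traj_frame(r$traj, i), toy$closed$atoms,
                        residue_seq = 112L)$mean_ang, numeric(1)))
  gate_df <- data.frame(time_ps = runs[[1]]$traj$times,
                        do.call(cbind, stats::setNames(
                          gate, paste0("replica_", seq_along(gate)))))
  rot <- lapply(seq_len(cfg$rotamer$n_residues * cfg$ed$replicas),
                function(i)
    gen_dihedral_trace(cfg$rotamer$p_up_to_down,
                       cfg$rotamer$p_down_to_up,
                       noise_sd = cfg$rotamer$noise_sd,
                       n_steps = nrow(rmsd_avg),
                       seed = cfg$seed * 1000L + i)$angles)
  fr <- state_fractions(rot, mode = "strict")
  profiles <- lapply(list(closed = toy$closed, open = toy$open),
                     function(m)
    pore_profile(m, selection = toy$selection,
                 z_step = cfg$pore$z_step,
                 mc_steps = cfg$pore$mc_steps, seed = cfg$seed))
  prof_df <- data.frame(z = profiles$closed$z,
                        radius_closed = profiles$closed$radius,
                        radius_open = profiles$open$radius)
  verdicts <- data.frame(replica = seq_along(runs),
                         final_rmsd_ang =
                           vapply(runs, `[[`, numeric(1),
                                  "final_rmsd") * ANG_PER_NM,
                         success = vapply(runs, `[[`, logical(1),
                                          "success"))
  files <- c("rmsd_avg.csv", "gate_distance.csv",
             "rotamer_fractions.csv", "pore_profiles.csv",
             "verdicts.csv")
  utils::write.csv(rmsd_avg, file.path(out_dir, files[1]),
                   row.names = FALSE)
  utils::write.csv(gate_df, file.path(out_dir, files[2]),
                   row.names = FALSE)
  utils::write.csv(fr, file.path(out_dir, files[3]), row.names = FALSE)
  utils::write.csv(prof_df, file.path(out_dir, files[4]),
                   row.names = FALSE)
  utils::write.csv(verdicts, file.path(out_dir, files[5]),
                   row.names = FALSE)
  man <- write_manifest(out_dir, "opening", cfg, cfg$seed, files,
                        c(total = proc.time()[["elapsed"]] - t0))
  invisible(list(runs = runs, rmsd_avg = rmsd_avg, gate = gate_df,
                 rotamer_fractions = fr, profiles = profiles,
                 verdicts = verdicts, manifest = man,
                 out_dir = out_dir))
}

#' Run the umbrella/WHAM landscape workflow
#'
#' Samples umbrella windows across the bundled triple-well landscape
#' (or a supplied [analytic_landscape()]), solves WHAM, attaches
#' bootstrap errors, and shades the wells with biased state samples
#' drawn at the well centers.  Emits PMF and overlap CSVs plus a
#' manifest.
#'
#' @param config nested list or YAML path.
#' @param out_dir output directory.
#' @param landscape an [analytic_landscape()]; default
#'   [triple_well_landscape()].
#' @return list with `windows`, `pmf`, `shades`, `rmse_vs_truth`
#'   (doubly-covered bins), invisibly written to `out_dir`.
#' @export
run_landscape <- function(config = NULL, out_dir = tempfile("landscape"),
                          landscape = triple_well_landscape()) {
  cfg <- load_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- proc.time()[["elapsed"]]
  u <- cfg$umbrella
  centers <- seq(landscape$domain[1] + 0.3, landscape$domain[2] - 0.3,
                 length.out = u$n_windows)
  barriers <- barrier_positions(landscape)
  boosted <- unique(unlist(lapply(barriers, function(b)
    which(abs(centers - b) < 0.5))))
  windows <- lapply(seq_along(centers), function(i)
    sample_window(landscape, centers[i],
                  k = if (i %in% boosted) u$boosted_k else u$default_k,
                  n_samples = u$n_samples,
                  discard_first_fraction = u$discard_first_fraction,
                  temperature = u$temperature, seed = cfg$seed * 100L + i))
  if (u$n_windows == 1L)
    warning("single window: the profile is local to that window")
  boot <- bootstrap_pmf(windows, n_boot = u$n_boot,
                        seed = cfg$seed + 7L, n_bins = u$n_bins,
                        temperature = u$temperature, tol = u$tol)
  pmf <- boot$pmf
  truth <- landscape$U(pmf$bin_centers)
  covered2 <- bins_covered(windows, pmf, min_windows = 2L)
  resid <- (pmf$free_energy - min(pmf$free_energy[covered2],
                                  na.rm = TRUE)) -
           (truth - min(truth[covered2]))
  rmse <- sqrt(mean(resid[covered2]^2, na.rm = TRUE))
  wells <- landscape$centers[landscape$depths > 0]
  shades <- shade_states(pmf, stats::setNames(lapply(
    wells, function(c0)
      sample_biased_1d(landscape, c0, 8, 2000,
                       temperature = u$temperature,
                       seed = cfg$seed + round(100 * c0))),
    paste0("well_", seq_along(wells))), cv = NULL)
  files <- c("pmf.csv", "overlap.csv", "shades.csv")
  utils::write.csv(data.frame(bin_center = pmf$bin_centers,
                              free_energy = pmf$free_energy,
                              bootstrap_se = pmf$bootstrap_se,
                              truth = truth - min(truth)),
                   file.path(out_dir, files[1]), row.names = FALSE)
  utils::write.csv(pmf$overlap, file.path(out_dir, files[2]),
                   row.names = FALSE)
  utils::write.csv(shades, file.path(out_dir, files[3]),
                   row.names = FALSE)
  man <- write_manifest(out_dir, "landscape", cfg, cfg$seed, files,
                        c(total = proc.time()[["elapsed"]] - t0))
  invisible(list(windows = windows, pmf = pmf, shades = shades,
                 rmse_vs_truth = rmse, manifest = man,
                 out_dir = out_dir))
}

#' Locate barrier positions of an analytic landscape
#'
#' Local maxima of U between consecutive well centers, found on a fine
#' grid.
#'
#' @param landscape an [analytic_landscape()].
#' @return numeric vector of barrier positions (nm).
#' @export
barrier_positions <- function(landscape) {
  cc <- sort(landscape$centers[landscape$depths > 0])
  if (length(cc) < 2) return(numeric(0))
  vapply(seq_len(length(cc) - 1), function(i) {
    s <- seq(cc[i], cc[i + 1], length.out = 2000)
    s[which.max(landscape$U(s))]
  }, numeric(1))
}

bins_covered <- function(windows, pmf, min_windows = 2L) {
  cov <- sapply(windows, function(w)
    pmf$bin_centers >= min(w$samples) & pmf$bin_centers <= max(w$samples))
  rowSums(cov) >= min_windows & is.finite(pmf$free_energy)
}

#' Run the subunit-cooperativity workflow on the toy channel
#'
#' @param config nested list or YAML path.
#' @param out_dir output directory.
#' @return the per-k outcome table (written as CSV with a manifest).
#' @export
run_cooperativity <- function(config = NULL,
                              out_dir = tempfile("cooperativity")) {
  cfg <- load_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- proc.time()[["elapsed"]]
  toy <- toy_from_config(cfg)
  tab <- cooperativity_scan(toy$energy, toy$closed, toy$open,
                            spec = toy$selection,
                            k_subunits = cfg$cooperativity$k_subunits,
                            n_steps = cfg$cooperativity$n_steps,
                            gate_residue = cfg$cooperativity$gate_residue,
                            success_rmsd = cfg$cooperativity$success_rmsd,
                            dt = cfg$ed$dt,
                            temperature = cfg$toy$temperature,
                            friction = cfg$toy$friction,
                            seed = cfg$seed,
                            save_every = cfg$ed$save_every)
  utils::write.csv(tab, file.path(out_dir, "cooperativity.csv"),
                   row.names = FALSE)
  man <- write_manifest(out_dir, "cooperativity", cfg, cfg$seed,
                        "cooperativity.csv",
                        c(total = proc.time()[["elapsed"]] - t0))
  invisible(list(table = tab, manifest = man, out_dir = out_dir))
}
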