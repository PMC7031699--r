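# Configuration-driven pipeline: synthetic simulation -> equilibration ->
# contacts -> durations -> k_off -> sites -> spatial statistics -> interplay
# -> PMF, with all intermediates persisted under a run directory.

#' Build a pipeline configuration
#'
#' @param seed Global seed; per-stage/per-repeat seeds are derived from it
#'   deterministically.
#' @param simulate List of synthetic-generator settings: `n_sites`,
#'   `n_repeats`, `n_upper`, `n_lower`, `box_nm`, `stride_ns`,
#'   `total_time_us`, plus optional overrides passed to
#'   [synthetic_binding_system()].
#' @param stages Named logical toggles: `contacts`, `kinetics`, `sites`,
#'   `spatial`, `interplay`, `pmf`.
#' @param params Analysis parameters: `lower`, `upper` (dual cutoffs, nm),
#'   `shell_radius`, `adjacency_radius`, `rdf_bin`, `grid_spacing`, and the
#'   PMF block (`pmf_depth_kJ`, `pmf_windows`, `pmf_spacing`, `pmf_k`,
#'   `pmf_n`, `n_boot`).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L,
                            simulate = list(),
                            stages = list(),
                            params = list()) {
  sim <- utils::modifyList(list(n_sites = 4L, n_repeats = 3L, n_upper = 25L,
                                n_lower = 25L, box_nm = c(12, 12, 10),
                                stride_ns = 1, total_time_us = 1), simulate)
  stg <- utils::modifyList(list(contacts = TRUE, kinetics = TRUE,
                                sites = TRUE, spatial = TRUE,
                                interplay = TRUE, pmf = TRUE), stages)
  par <- utils::modifyList(list(lower = 0.55, upper = 1.4, shell_radius = 1.0,
                                adjacency_radius = 1.0, rdf_bin = 0.1,
                                grid_spacing = 0.5, pmf_depth_kJ = 20,
                                pmf_windows = 30L, pmf_spacing = 0.05,
                                pmf_k = 1000, pmf_n = 500, n_boot = 10L),
                           params)
  structure(list(seed = as.integer(seed), simulate = sim, stages = stg,
                 params = par), class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Stages run in dependency order; contact analyses are restricted to the
#' post-equilibration window. All intermediates are written under `out_dir`
#' and the run is deterministic for a fixed configuration (reports carry no
#' timestamps).
#'
#' @param config A [pipeline_config()] (or a YAML path containing one).
#' @param out_dir Output directory (created if needed).
#' @return Object of class `run_report`.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) {
    doc <- yaml::read_yaml(config)
    config <- pipeline_config(seed = doc$seed,
                              simulate = doc$simulate %||% list(),
                              stages = doc$stages %||% list(),
                              params = doc$params %||% list())
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- config$params
  report <- list(seed = config$seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # --- simulate -------------------------------------------------------------
  sim <- config$simulate
  sys <- stage("simulate", do.call(synthetic_binding_system, c(
    list(n_sites = sim$n_sites),
    sim[intersect(names(sim), c("species", "k_off", "k_on", "capture_radius",
                                "ring_radius", "n_helices"))])))
  comp <- default_composition()
  write_membrane_config(comp, file.path(out_dir, "composition.yaml"))
  events <- list(); ledgers <- list(); trajs <- list()
  for (r in seq_len(sim$n_repeats)) {
    cfg <- system_config(box_nm = sim$box_nm, stride_ns = sim$stride_ns,
                         total_time_us = sim$total_time_us,
                         seed = config$seed + 1000L * r)
    res <- stage("simulate", simulate_membrane_trajectory(
      comp, sys$receptor, sys$sites, cfg,
      n_upper = sim$n_upper, n_lower = sim$n_lower))
    trajs[[r]] <- res$trajectory
    ledgers[[r]] <- res$ledger
  }
  ledger <- do.call(rbind, Map(function(l, r) {
    if (nrow(l) > 0) l$run <- r else l$run <- integer(0); l
  }, ledgers, seq_along(ledgers)))
  write_ledger(ledger, file.path(out_dir, "ledger.csv"))
  report$simulate <- list(n_repeats = sim$n_repeats,
                          n_lipids = nrow(trajs[[1]]$lipids),
                          n_frames = n_frames(trajs[[1]]),
                          n_ledger_events = nrow(ledger))

  # --- equilibration window -------------------------------------------------
  occ <- stage("occupancy", first_shell_series(trajs[[1]],
                                               shell_radius = p$shell_radius))
  write_events_csv(occ, file.path(out_dir, "occupancy.csv"))
  eq_ns <- tryCatch(estimate_equilibration(occ),
                    lipidkinetics_no_plateau = function(e) NA_real_)
  span <- max(trajs[[1]]$times_ns)
  begin_ns <- if (is.na(eq_ns)) 3 / 8 * span else eq_ns
  report$equilibration <- list(equilibration_ns = eq_ns,
                               window_ns = c(begin_ns, span))

  # --- contacts & durations -------------------------------------------------
  profile <- NULL
  if (isTRUE(config$stages$contacts)) {
    events <- do.call(rbind, lapply(seq_along(trajs), function(r)
      stage("contacts", contact_events(trajs[[r]], lower = p$lower,
                                       upper = p$upper, begin_ns = begin_ns,
                                       run = r))))
    write_events_csv(events, file.path(out_dir, "events.csv"))
    profile <- stage("durations", residue_duration_profile(events))
    write_events_csv(as.data.frame(profile), file.path(out_dir, "profile.csv"))
    report$contacts <- list(n_events = sum(!events$censored),
                            n_censored = sum(events$censored))
  }

  # --- sites + k_off --------------------------------------------------------
  if (isTRUE(config$stages$sites) && !is.null(profile)) {
    found <- stage("sites", identify_sites(profile, sys$receptor,
                                           adjacency_radius = p$adjacency_radius))
    site_rows <- lapply(found, function(s) {
      kf <- if (isTRUE(config$stages$kinetics))
        tryCatch(site_koff(profile, s, events, n_boot = 25),
                 error = function(e) NULL) else NULL
      list(site_id = s$site_id, species = s$species,
           residues = as.integer(s$residues), mean_ns = s$mean_ns,
           max_ns = s$max_ns, n_events = s$n_events,
           k_off_us = if (is.null(kf)) NA else kf$k_off_us)
    })
    yaml::write_yaml(site_rows, file.path(out_dir, "sites.yaml"),
                     precision = 6L)
    report$sites <- list(n_sites = length(found),
                         k_off_us = vapply(site_rows, function(s)
                           as.numeric(s$k_off_us), 0))
  }

  # --- spatial statistics ---------------------------------------------------
  if (isTRUE(config$stages$spatial)) {
    sp_all <- unique(trajs[[1]]$lipids$species)
    rdfs <- stage("spatial", lapply(sp_all, function(s)
      surface_rdf(trajs[[1]], s, bin_width = p$rdf_bin,
                  mc_seed = config$seed + 17L)))
    names(rdfs) <- sp_all
    rdf_df <- do.call(rbind, lapply(rdfs, function(r)
      data.frame(species = r$species, r_nm = r$r_mid, g = r$g)))
    write_events_csv(rdf_df, file.path(out_dir, "rdf.csv"))
    groups <- classify_species_by_rdf(rdfs)
    apl <- stage("spatial", voronoi_apl(trajs[[1]],
                                        frame = n_frames(trajs[[1]])))
    write_events_csv(apl$lipids, file.path(out_dir, "apl.csv"))
    for (s in intersect(c("GM3", "CHOL", "PIP2"), sp_all)) {
      m <- density_map_2d(trajs[[1]], s, grid_spacing = p$grid_spacing)
      write_density_map(m, file.path(out_dir, paste0("density_", s, ".txt")),
                        file.path(out_dir, paste0("density_", s, ".json")))
    }
    report$spatial <- list(group1 = groups$group1, group2 = groups$group2,
                           apl_mean_nm2 = stats::setNames(
                             apl$summary$mean_nm2,
                             paste(apl$summary$species, apl$summary$leaflet)))
  }

  # --- interplay ------------------------------------------------------------
  if (isTRUE(config$stages$interplay) && !is.null(profile) &&
      sim$n_repeats >= 3) {
    pr <- attr(profile, "per_repeat")
    means <- tapply(pr$mean_ns, list(pr$run, pr$species), mean)
    keep <- colSums(!is.na(means)) == nrow(means)
    if (sum(keep) >= 2) {
      im <- stage("interplay", interplay_matrix(means[, keep, drop = FALSE]))
      write_events_csv(as.data.frame(unclass(im)),
                       file.path(out_dir, "interplay.csv"))
      report$interplay <- attr(im, "interplay")
    }
  }

  # --- PMF ------------------------------------------------------------------
  if (isTRUE(config$stages$pmf)) {
    D <- p$pmf_depth_kJ
    true_pmf <- function(xi) D * ((1 - exp(-3 * (xi - 0.8)))^2 - 1)
    centers <- 0.5 + p$pmf_spacing * (seq_len(p$pmf_windows) - 1)
    win <- stage("pmf", sample_biased_synthetic(
      true_pmf, centers, k = p$pmf_k, n = max(100L, p$pmf_n),
      seed = config$seed + 31L))
    prof <- stage("pmf", bayesian_bootstrap_pmf(win, n_boot = p$n_boot,
                                                seed = config$seed + 37L))
    write_pmf_csv(prof, file.path(out_dir, "pmf.csv"))
    kd <- tryCatch(estimate_kd(prof), error = function(e) NULL)
    report$pmf <- list(depth_kJ_mol = max(prof$W, na.rm = TRUE),
                       kd_M = if (is.null(kd)) NA_real_ else kd$kd_M)
  }

  report <- structure(report, class = "run_report")
  writeLines(yaml::as.yaml(.report_body(report), precision = 6L),
             file.path(out_dir, "report.yaml"))
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.report_body <- function(report) {
  lapply(unclass(report), function(x) {
    if (is.data.frame(x)) as.list(x) else x
  })
}

#' @export
print.run_report <- function(x, ...) {
  cat("Pipeline run report (seed ", x$seed, ")\n", sep = "")
  if (!is.null(x$simulate))
    cat(sprintf("  simulate: %d repeats x %d frames, %d lipids, %d ledger events\n",
                x$simulate$n_repeats, x$simulate$n_frames,
                x$simulate$n_lipids, x$simulate$n_ledger_events))
  if (!is.null(x$equilibration))
    cat(sprintf("  analysis window: %.0f-%.0f ns\n",
                x$equilibration$window_ns[1], x$equilibration$window_ns[2]))
  if (!is.null(x$contacts))
    cat(sprintf("  contacts: %d events (%d censored)\n",
                x$contacts$n_events, x$contacts$n_censored))
  if (!is.null(x$sites))
    cat(sprintf("  sites: %d identified; k_off = %s /us\n", x$sites$n_sites,
                paste(signif(x$sites$k_off_us, 3), collapse = ", ")))
  if (!is.null(x$spatial))
    cat("  RDF group 1: ", paste(x$spatial$group1, collapse = ", "), "\n",
        sep = "")
  if (!is.null(x$pmf))
    cat(sprintf("  PMF: depth %.1f kJ/mol; Kd %.3g M\n",
                x$pmf$depth_kJ_mol, x$pmf$kd_M))
  invisible(x)
}

#' Group lipid species by their proximity to the receptor
#'
#' Species whose RDF first-peak value within the first shell exceeds the
#' threshold form Group 1 (close-interacting); the remainder are the bulk
#' Group 2.
#'
#' @param rdfs Named list of `surface_rdf` objects on a common grid.
#' @param contact_threshold g(r) threshold (default 2).
#' @param shell_radius First-shell boundary, nm (default 1.0).
#' @return List with `group1`, `group2`, and the named `peaks` vector.
#' @export
classify_species_by_rdf <- function(rdfs, contact_threshold = 2,
                                    shell_radius = 1.0) {
  if (length(rdfs) == 0L) stop("empty RDF set")
  peaks <- vapply(rdfs, function(r) {
    sel <- r$r_mid <= shell_radius
    if (!any(sel) || all(is.na(r$g[sel]))) return(0)
    max(r$g[sel], na.rm = TRUE)
  }, 0)
  if (is.null(names(peaks)))
    names(peaks) <- vapply(rdfs, `[[`, "", "species")
  list(group1 = names(peaks)[peaks >= contact_threshold],
       group2 = names(peaks)[peaks < contact_threshold],
       peaks = peaks)
}
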