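# Synthetic coarse-grained membrane trajectories: laterally diffusing lipids
# around a static receptor, with Markovian binding at designed sites and a
# ground-truth event ledger. Not a physical simulator -- no forces, no
# thermostat; the point is exact, known residence-time statistics.

.wrap <- function(x, L) x - L * round(x / L)

#' Simulate a membrane trajectory with known binding kinetics
#'
#' Unbound lipids perform 2D Brownian steps (per-species diffusion
#' coefficient) in the periodic xy box with a hard-core exclusion around the
#' receptor. An unbound lipid of the right species and leaflet within a site's
#' capture radius binds with hazard `k_on` per microsecond (while the site is
#' free); binding tethers the lipid at the site anchor with Gaussian jitter so
#' its COM stays within the contact lower cutoff of every anchor residue. The
#' residence time is drawn exactly from Exponential(`k_off_true`); on
#' unbinding the lipid is displaced 1.6 nm from the anchor (beyond the 1.4 nm
#' upper cutoff) within one frame. Cholesterol additionally flips leaflet with
#' a small hazard. All transitions are recorded in a ground-truth ledger.
#'
#' @param comp A `membrane_composition` (must validate).
#' @param receptor A `receptor_model`.
#' @param sites List of [binding_site_spec()] (may be empty).
#' @param config A [system_config()]; `seed` drives all randomness.
#' @param n_upper,n_lower Lipids per leaflet (realized from the composition by
#'   largest-remainder rounding).
#' @param diffusion_nm2_us Named per-species diffusion coefficients
#'   (nm^2/us); unnamed scalar applies to all. Default 30 nm^2/us.
#' @param chol_flip_rate Leaflet flip hazard for cholesterol, per microsecond.
#' @param tether_sd,tether_max Gaussian jitter SD and norm clamp (nm) of the
#'   bound-lipid tether.
#' @param release_distance Displacement (nm) from the anchor on unbinding.
#' @param leaflet_z |z| of the leaflet midplanes (nm).
#' @param exclusion_radius Hard-core radius (nm) around the receptor axis;
#'   default slightly beyond the outermost receptor bead.
#' @return List with `trajectory` (class `cg_trajectory`) and `ledger`
#'   (data.frame `lipid_id`, `site_id`, `t_on_us`, `t_off_us`, `censored`).
#' @export
simulate_membrane_trajectory <- function(comp, receptor, sites, config,
                                         n_upper, n_lower,
                                         diffusion_nm2_us = 30,
                                         chol_flip_rate = 0.05,
                                         tether_sd = 0.12, tether_max = 0.30,
                                         release_distance = 1.6,
                                         leaflet_z = 2.0,
                                         exclusion_radius = NULL) {
  viol <- validate_composition(comp)
  if (nrow(viol) > 0)
    stop("invalid composition: ", paste(viol$rule, collapse = ", "))
  for (s in sites)
    if (!all(s$anchor_residues %in% receptor$beads$residue_id))
      stop("site ", s$site_id, " references residues outside the receptor")
  Lx <- config$box_nm[1]; Ly <- config$box_nm[2]
  rb <- receptor$beads
  if (is.null(exclusion_radius))
    exclusion_radius <- max(sqrt(rb$x^2 + rb$y^2)) + 0.05
  if (exclusion_radius > min(Lx, Ly) / 2 - 1)
    stop("box too small for the receptor exclusion zone")

  set.seed(config$seed)
  dt_us <- config$stride_ns / 1000
  n_frames <- as.integer(round(config$total_time_us * 1000 / config$stride_ns)) + 1L
  times_ns <- (seq_len(n_frames) - 1) * config$stride_ns

  species <- character(0); leaf <- integer(0)
  if (n_upper > 0) {
    cu <- realize_counts(comp, n_upper, max(n_lower, 1L))$upper
    species <- c(species, rep(names(cu), cu)); leaf <- c(leaf, rep(1L, sum(cu)))
  }
  if (n_lower > 0) {
    cl <- realize_counts(comp, max(n_upper, 1L), n_lower)$lower
    species <- c(species, rep(names(cl), cl)); leaf <- c(leaf, rep(-1L, sum(cl)))
  }
  n_lip <- length(species)
  n_sites <- length(sites)
  if (n_sites > 0 && n_lip > 0) {
    for (s in sites) {
      elig0 <- sum(species == s$species &
                   leaf == (if (s$leaflet == "upper") 1L else -1L))
      if (elig0 == 0L)
        stop("no lipids of species ", s$species, " in the ", s$leaflet,
             " leaflet to populate site ", s$site_id)
    }
  }

  sig_of <- function(sp) {
    d <- if (!is.null(names(diffusion_nm2_us)) && sp %in% names(diffusion_nm2_us))
      diffusion_nm2_us[[sp]] else unname(diffusion_nm2_us[1])
    sqrt(2 * d * dt_us)
  }
  sigma <- vapply(species, sig_of, 0)

  # initial placement outside the exclusion zone
  x <- y <- numeric(n_lip)
  if (n_lip > 0) {
    todo <- seq_len(n_lip)
    while (length(todo) > 0) {
      x[todo] <- runif(length(todo), -Lx / 2, Lx / 2)
      y[todo] <- runif(length(todo), -Ly / 2, Ly / 2)
      todo <- todo[x[todo]^2 + y[todo]^2 < exclusion_radius^2]
    }
  }
  z <- leaf * leaflet_z

  bound <- integer(n_lip)              # 0 = free, else site index
  t_unbind <- rep(Inf, n_lip)          # exact scheduled unbinding time (us)
  occupant <- integer(n_sites)         # 0 = free site
  ev_lip <- ev_site <- integer(0); ev_on <- ev_off <- numeric(0)
  open_on <- rep(NA_real_, n_lip)

  site_x <- vapply(sites, function(s) s$anchor_point[1], 0)
  site_y <- vapply(sites, function(s) s$anchor_point[2], 0)
  site_leaf <- vapply(sites, function(s) if (s$leaflet == "upper") 1L else -1L, 0L)
  site_cap2 <- vapply(sites, function(s) s$capture_radius^2, 0)
  site_pbind <- vapply(sites, function(s) 1 - exp(-s$k_on * dt_us), 0)
  site_koff <- vapply(sites, function(s) s$k_off_true, 0)
  site_sp <- vapply(sites, function(s) s$species, "")
  site_angle <- atan2(site_y, site_x)

  x_arr <- matrix(NA_real_, n_frames, n_lip)
  y_arr <- matrix(NA_real_, n_frames, n_lip)
  z_arr <- matrix(NA_real_, n_frames, n_lip)

  jitter2 <- function(n) {
    j <- matrix(rnorm(2 * n, 0, tether_sd), n, 2)
    r <- sqrt(rowSums(j^2))
    too <- r > tether_max
    if (any(too)) j[too, ] <- j[too, , drop = FALSE] * (tether_max / r[too])
    j
  }

  is_chol <- species == "CHOL"
  p_flip <- 1 - exp(-chol_flip_rate * dt_us)

  record <- function(k) {
    x_arr[k, ] <<- x; y_arr[k, ] <<- y; z_arr[k, ] <<- z
  }
  if (n_lip > 0) record(1L)

  for (k in seq_len(n_frames)[-1]) {
    if (n_lip == 0L) break
    t_us <- times_ns[k] / 1000
    released <- logical(n_lip)

    ub <- which(bound == 0L)
    if (length(ub) > 0) {
      nx <- .wrap(x[ub] + rnorm(length(ub), 0, sigma[ub]), Lx)
      ny <- .wrap(y[ub] + rnorm(length(ub), 0, sigma[ub]), Ly)
      ok <- nx^2 + ny^2 >= exclusion_radius^2
      x[ub[ok]] <- nx[ok]; y[ub[ok]] <- ny[ok]
      fl <- ub[is_chol[ub]]
      if (length(fl) > 0) {
        flip <- fl[runif(length(fl)) < p_flip]
        z[flip] <- -z[flip]
      }
    }

    due <- which(bound > 0L & t_unbind <= t_us)
    for (i in due) {
      s <- bound[i]
      ev_lip <- c(ev_lip, i); ev_site <- c(ev_site, s)
      ev_on <- c(ev_on, open_on[i]); ev_off <- c(ev_off, t_unbind[i])
      phi <- site_angle[s] + runif(1, -pi / 3, pi / 3)
      x[i] <- .wrap(site_x[s] + release_distance * cos(phi), Lx)
      y[i] <- .wrap(site_y[s] + release_distance * sin(phi), Ly)
      occupant[s] <- 0L; bound[i] <- 0L; t_unbind[i] <- Inf
      open_on[i] <- NA_real_; released[i] <- TRUE
    }

    for (s in seq_len(n_sites)) {
      if (occupant[s] > 0L) next
      elig <- which(bound == 0L & !released & species == site_sp[s] &
                    z * site_leaf[s] > 0)
      if (length(elig) == 0L) next
      d2 <- (x[elig] - site_x[s])^2 + (y[elig] - site_y[s])^2
      inr <- elig[d2 <= site_cap2[s]]
      if (length(inr) == 0L) next
      hit <- inr[runif(length(inr)) < site_pbind[s]]
      if (length(hit) == 0L) next
      win <- hit[which.min((x[hit] - site_x[s])^2 + (y[hit] - site_y[s])^2)]
      bound[win] <- s; occupant[s] <- win
      open_on[win] <- t_us
      t_unbind[win] <- t_us + rexp(1, rate = site_koff[s])
      z[win] <- site_leaf[s] * leaflet_z
    }

    bd <- which(bound > 0L)
    if (length(bd) > 0) {
      j <- jitter2(length(bd))
      x[bd] <- site_x[bound[bd]] + j[, 1]
      y[bd] <- site_y[bound[bd]] + j[, 2]
    }
    record(k)
  }

  still <- which(bound > 0L)
  cens <- logical(length(ev_lip))
  if (length(still) > 0) {
    ev_lip <- c(ev_lip, still); ev_site <- c(ev_site, bound[still])
    ev_on <- c(ev_on, open_on[still])
    ev_off <- c(ev_off, rep(config$total_time_us, length(still)))
    cens <- c(cens, rep(TRUE, length(still)))
  }
  ord <- order(ev_on, ev_lip)
  ledger <- data.frame(lipid_id = ev_lip[ord], site_id = ev_site[ord],
                       t_on_us = ev_on[ord], t_off_us = ev_off[ord],
                       censored = cens[ord])

  lipids <- data.frame(lipid_id = seq_len(n_lip), species = species,
                       leaflet0 = ifelse(leaf > 0, "upper", "lower"),
                       stringsAsFactors = FALSE)
  traj <- structure(list(times_ns = times_ns, stride_ns = config$stride_ns,
                         box_nm = config$box_nm, lipids = lipids,
                         x = x_arr, y = y_arr, z = z_arr,
                         receptor = receptor, species = comp$species,
                         leaflet_z = leaflet_z),
                    class = "cg_trajectory")
  list(trajectory = traj, ledger = ledger)
}

#' Ground-truth residence times per site
#'
#' @param ledger Ledger returned by [simulate_membrane_trajectory()].
#' @param drop_censored Exclude trajectory-end censored events (default TRUE).
#' @return Named list of duration samples (microseconds) per site.
#' @export
ledger_to_reference_durations <- function(ledger, drop_censored = TRUE) {
  if (nrow(ledger) == 0L) return(list())
  if (drop_censored) ledger <- ledger[!ledger$censored, , drop = FALSE]
  split(ledger$t_off_us - ledger$t_on_us, ledger$site_id)
}

#' Write a ground-truth ledger as CSV
#' @param ledger Ledger data.frame.
#' @param path Output file.
#' @export
write_ledger <- function(ledger, path) {
  utils::write.csv(ledger, path, row.names = FALSE)
  invisible(path)
}

#' Number of frames in a trajectory
#' @param traj A `cg_trajectory`.
#' @export
n_frames <- function(traj) length(traj$times_ns)

#' @export
print.cg_trajectory <- function(x, ...) {
  cat("Coarse-grained trajectory: ", n_frames(x), " frames (",
      x$stride_ns, " ns stride, ", max(x$times_ns) / 1000, " us), ",
      nrow(x$lipids), " lipids, ",
      nrow(x$receptor$beads), " receptor beads\n", sep = "")
  invisible(x)
}
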