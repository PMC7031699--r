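# Dual-cutoff contact detection and occupancy/equilibration monitoring.
#
# A contact with a residue starts when the lipid COM comes closer than the
# lower cutoff (default 0.55 nm) and ends only when it moves beyond the upper
# cutoff (default 1.4 nm); the hysteresis suppresses boundary rattling.

#' Minimum-image displacement in a periodic box
#' @param dx Displacement(s).
#' @param L Box length.
#' @return Wrapped displacement in `[-L/2, L/2)`.
#' @export
min_image <- function(dx, L) dx - L * round(dx / L)

#' Lipid-COM to residue-COM distance time series
#'
#' Distances use the minimum-image convention in the periodic xy plane; z is
#' taken as-is (the membrane normal is not periodic for these analyses).
#' Lipid coordinates in a `cg_trajectory` are molecule COMs; residue COMs are
#' equal-weight bead means.
#'
#' @param traj A `cg_trajectory`.
#' @param lipid_ids Lipid ids (default all).
#' @param residue_ids Receptor residue ids (default all).
#' @return Object of class `distance_series`: list with `times_ns`,
#'   `stride_ns`, `pairs` (data.frame `lipid_id`, `species`, `residue_id`) and
#'   `dist` (matrix frames x pairs, nm).
#' @export
com_distance_series <- function(traj, lipid_ids = NULL, residue_ids = NULL) {
  if (is.null(lipid_ids)) lipid_ids <- traj$lipids$lipid_id
  rc <- residue_coms(traj$receptor)
  if (!is.null(residue_ids)) rc <- rc[rc$residue_id %in% residue_ids, ]
  if (length(lipid_ids) == 0L || nrow(rc) == 0L)
    stop("selection resolves to zero particles")
  Lx <- traj$box_nm[1]; Ly <- traj$box_nm[2]
  nf <- n_frames(traj)
  pairs <- expand.grid(residue_id = rc$residue_id, lipid_id = lipid_ids,
                       KEEP.OUT.ATTRS = FALSE)
  pairs <- pairs[c("lipid_id", "residue_id")]
  pairs$species <- traj$lipids$species[match(pairs$lipid_id,
                                             traj$lipids$lipid_id)]
  dist <- matrix(NA_real_, nf, nrow(pairs))
  col <- 0L
  for (l in lipid_ids) {
    li <- match(l, traj$lipids$lipid_id)
    for (r in seq_len(nrow(rc))) {
      col <- col + 1L
      dx <- min_image(traj$x[, li] - rc$x[r], Lx)
      dy <- min_image(traj$y[, li] - rc$y[r], Ly)
      dz <- traj$z[, li] - rc$z[r]
      dist[, col] <- sqrt(dx * dx + dy * dy + dz * dz)
    }
  }
  structure(list(times_ns = traj$times_ns, stride_ns = traj$stride_ns,
                 pairs = pairs, dist = dist),
            class = "distance_series")
}

# two-threshold hysteresis automaton, vectorized over frames
.dual_cutoff_events <- function(d, times, lower, upper) {
  n <- length(d)
  zone <- integer(n)
  zone[d < lower] <- 1L
  zone[d > upper] <- -1L
  idx <- cummax(seq_len(n) * (zone != 0L))
  state <- rep(-1L, n)
  pos <- idx > 0L
  state[pos] <- zone[idx[pos]]
  r <- rle(state == 1L)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ki <- which(r$values)
  if (length(ki) == 0L)
    return(data.frame(t_start_ns = numeric(), t_end_ns = numeric(),
                      duration_ns = numeric(), censored = logical()))
  s <- starts[ki]; e <- ends[ki]
  censored <- e >= n
  t_end <- ifelse(censored, times[n], times[pmin(e + 1L, n)])
  data.frame(t_start_ns = times[s], t_end_ns = t_end,
             duration_ns = t_end - times[s], censored = censored)
}

#' Detect contact events with the dual-cutoff scheme
#'
#' An event opens at the first frame with distance below `lower`, stays open
#' while the distance is at most `upper`, and closes at the first frame beyond
#' `upper`; its duration is the time between those two frames. An event still
#' open at the trajectory end closes at the final frame time and is flagged
#' censored.
#'
#' @param d A numeric distance vector (nm) or a `distance_series` from
#'   [com_distance_series()].
#' @param times_ns Frame times for a vector input (default unit stride).
#' @param lower,upper Cutoffs in nm (defaults 0.55 and 1.4).
#' @return data.frame of events (`t_start_ns`, `t_end_ns`, `duration_ns`,
#'   `censored`, plus `lipid_id`/`residue_id`/`species` for series input).
#' @export
detect_contact_events <- function(d, times_ns = NULL, lower = 0.55,
                                  upper = 1.4) {
  stopifnot(lower < upper)
  if (inherits(d, "distance_series")) {
    out <- vector("list", ncol(d$dist))
    for (j in seq_len(ncol(d$dist))) {
      ev <- .dual_cutoff_events(d$dist[, j], d$times_ns, lower, upper)
      if (nrow(ev) > 0) {
        ev$lipid_id <- d$pairs$lipid_id[j]
        ev$residue_id <- d$pairs$residue_id[j]
        ev$species <- d$pairs$species[j]
      }
      out[[j]] <- ev
    }
    out <- do.call(rbind, out[vapply(out, nrow, 0L) > 0])
    if (is.null(out))
      out <- data.frame(t_start_ns = numeric(), t_end_ns = numeric(),
                        duration_ns = numeric(), censored = logical(),
                        lipid_id = integer(), residue_id = integer(),
                        species = character())
    rownames(out) <- NULL
    return(out)
  }
  if (is.null(times_ns)) times_ns <- seq_along(d) - 1
  if (length(times_ns) >= 3) {
    st <- diff(times_ns)
    if (max(st) - min(st) > 1e-9 * max(st))
      stop("non-uniform stride: resample the series first")
  }
  .dual_cutoff_events(d, times_ns, lower, upper)
}

#' Detect contact events across a whole trajectory
#'
#' Streams lipid-by-lipid so large trajectories never materialize a full
#' pair-distance matrix. Residues whose z offset from every z level the lipid
#' visits exceeds the lower cutoff can never open an event and are skipped.
#'
#' @param traj A `cg_trajectory`.
#' @param species Restrict to these lipid species (default all).
#' @param residue_ids Restrict to these residues (default all).
#' @param lower,upper Dual cutoffs, nm.
#' @param begin_ns,end_ns Analysis window (default full span).
#' @param run Integer repeat label attached to the events (default 1).
#' @return data.frame of events with `lipid_id`, `residue_id`, `species`,
#'   `run`, `t_start_ns`, `t_end_ns`, `duration_ns`, `censored`.
#' @export
contact_events <- function(traj, species = NULL, residue_ids = NULL,
                           lower = 0.55, upper = 1.4,
                           begin_ns = NULL, end_ns = NULL, run = 1L) {
  stopifnot(lower < upper)
  rc <- residue_coms(traj$receptor)
  if (!is.null(residue_ids)) rc <- rc[rc$residue_id %in% residue_ids, ]
  lip <- traj$lipids
  if (!is.null(species)) lip <- lip[lip$species %in% species, ]
  fr <- rep(TRUE, n_frames(traj))
  if (!is.null(begin_ns)) fr <- fr & traj$times_ns >= begin_ns
  if (!is.null(end_ns)) fr <- fr & traj$times_ns <= end_ns
  times <- traj$times_ns[fr]
  Lx <- traj$box_nm[1]; Ly <- traj$box_nm[2]
  out <- list()
  for (li in seq_len(nrow(lip))) {
    i <- match(lip$lipid_id[li], traj$lipids$lipid_id)
    xl <- traj$x[fr, i]; yl <- traj$y[fr, i]; zl <- traj$z[fr, i]
    zlev <- unique(zl)
    keep <- vapply(seq_len(nrow(rc)), function(r)
      min(abs(rc$z[r] - zlev)) < lower, TRUE)
    for (r in which(keep)) {
      dx <- min_image(xl - rc$x[r], Lx)
      dy <- min_image(yl - rc$y[r], Ly)
      dz <- zl - rc$z[r]
      ev <- .dual_cutoff_events(sqrt(dx * dx + dy * dy + dz * dz),
                                times, lower, upper)
      if (nrow(ev) > 0) {
        ev$lipid_id <- lip$lipid_id[li]
        ev$residue_id <- rc$residue_id[r]
        ev$species <- lip$species[li]
        out[[length(out) + 1L]] <- ev
      }
    }
  }
  if (length(out) == 0L)
    return(data.frame(t_start_ns = numeric(), t_end_ns = numeric(),
                      duration_ns = numeric(), censored = logical(),
                      lipid_id = integer(), residue_id = integer(),
                      species = character(), run = integer()))
  out <- do.call(rbind, out)
  out$run <- run
  rownames(out) <- NULL
  out
}

#' Per-residue interaction-duration profile
#'
#' Mean continuous-contact duration per residue and species, pooling events
#' across repeats; censored (trajectory-end) events are counted separately and
#' excluded from the means. Per-repeat means are kept as an attribute for the
#' interplay correlation analysis.
#'
#' @param events Event data.frame from [contact_events()] /
#'   [detect_contact_events()] (needs `residue_id`, `species`, `duration_ns`,
#'   `censored`; optional `run`).
#' @return data.frame of class `duration_profile`: `residue_id`, `species`,
#'   `n_events`, `n_censored`, `mean_ns`; attribute `per_repeat` holds
#'   per-run means.
#' @export
residue_duration_profile <- function(events) {
  if (is.null(events$run)) events$run <- 1L
  if (nrow(events) == 0L) {
    out <- data.frame(residue_id = integer(), species = character(),
                      n_events = integer(), n_censored = integer(),
                      mean_ns = numeric())
    class(out) <- c("duration_profile", "data.frame")
    return(out)
  }
  key <- interaction(events$residue_id, events$species, drop = TRUE)
  unc <- !events$censored
  n_events <- tapply(unc, key, sum)
  n_cens <- tapply(events$censored, key, sum)
  mean_ns <- tapply(ifelse(unc, events$duration_ns, NA_real_), key,
                    mean, na.rm = TRUE)
  lab <- do.call(rbind, strsplit(names(n_events), ".", fixed = TRUE))
  out <- data.frame(residue_id = as.integer(lab[, 1]), species = lab[, 2],
                    n_events = as.integer(n_events),
                    n_censored = as.integer(n_cens),
                    mean_ns = ifelse(n_events > 0, as.numeric(mean_ns),
                                     NA_real_),
                    stringsAsFactors = FALSE)
  out <- out[order(out$species, out$residue_id), ]
  rownames(out) <- NULL
  ev_u <- events[unc, ]
  pr <- aggregate(duration_ns ~ residue_id + species + run, data = ev_u, mean)
  names(pr)[names(pr) == "duration_ns"] <- "mean_ns"
  attr(out, "per_repeat") <- pr
  class(out) <- c("duration_profile", "data.frame")
  out
}

#' First-shell occupancy time series
#'
#' Per-frame count of lipids of each species whose COM lies within
#' `shell_radius` of the receptor surface (minimum distance to any receptor
#' bead).
#'
#' @param traj A `cg_trajectory`.
#' @param species Species to monitor (default: all present).
#' @param shell_radius First-shell radius, nm (default 1.0, the RDF-derived
#'   first shell).
#' @return Object of class `occupancy_series`: data.frame `time_ns` plus one
#'   count column per species.
#' @export
first_shell_series <- function(traj, species = NULL, shell_radius = 1.0) {
  if (is.null(species)) species <- unique(traj$lipids$species)
  missing_sp <- setdiff(species, traj$lipids$species)
  if (length(missing_sp) > 0)
    stop("species absent from topology: ", paste(missing_sp, collapse = ", "))
  rb <- traj$receptor$beads
  Lx <- traj$box_nm[1]; Ly <- traj$box_nm[2]
  nf <- n_frames(traj)
  counts <- matrix(0L, nf, length(species),
                   dimnames = list(NULL, species))
  for (i in seq_len(nrow(traj$lipids))) {
    sp <- traj$lipids$species[i]
    if (!sp %in% species) next
    dmin <- rep(Inf, nf)
    for (b in seq_len(nrow(rb))) {
      dx <- min_image(traj$x[, i] - rb$x[b], Lx)
      dy <- min_image(traj$y[, i] - rb$y[b], Ly)
      dz <- traj$z[, i] - rb$z[b]
      dmin <- pmin(dmin, dx * dx + dy * dy + dz * dz)
    }
    counts[, sp] <- counts[, sp] + (dmin <= shell_radius^2)
  }
  out <- data.frame(time_ns = traj$times_ns, counts, check.names = FALSE)
  class(out) <- c("occupancy_series", "data.frame")
  attr(out, "shell_radius") <- shell_radius
  out
}

#' Estimate the equilibration time of an occupancy series
#'
#' Block-averages the series and returns the start time of the earliest block
#' from which all later block means stay within `tolerance` standard errors
#' of the final-half mean (the standard error a block mean would have if the
#' final half were stationary and uncorrelated at the frame level; for
#' strongly autocorrelated data raise `tolerance`). If no such block exists
#' in the first half of the series, no plateau is declared and an error of
#' class `lipidkinetics_no_plateau` is raised.
#'
#' @param series An `occupancy_series` (counts are summed over species) or a
#'   numeric vector.
#' @param tolerance Tolerance in block-mean standard errors (default 3).
#' @param n_blocks Number of averaging blocks (default 20; the series must be
#'   at least 10 blocks long).
#' @param times_ns Frame times for vector input.
#' @return Equilibration time in ns.
#' @export
estimate_equilibration <- function(series, tolerance = 3, n_blocks = 20,
                                   times_ns = NULL) {
  if (inherits(series, "occupancy_series")) {
    times_ns <- series$time_ns
    series <- rowSums(series[setdiff(names(series), "time_ns")])
  }
  n <- length(series)
  if (is.null(times_ns)) times_ns <- seq_len(n) - 1
  if (n < 10 * max(1, floor(n / n_blocks)) || n < 10)
    stop("series too short: need at least 10 blocks")
  bl <- floor(n / n_blocks)
  idx <- pmin(((seq_len(n) - 1L) %/% bl) + 1L, n_blocks)
  bm <- tapply(series, idx, mean)
  half_start <- floor(n_blocks / 2) + 1L
  tail_frames <- series[idx >= half_start]
  ref <- mean(tail_frames)
  se <- stats::sd(tail_frames) / sqrt(bl)
  ok <- abs(bm - ref) <= tolerance * max(se, 1e-12)
  # earliest block from which every later block stays inside the band
  good_from <- rev(cumprod(rev(ok))) > 0
  k <- which(good_from)[1]
  if (is.na(k) || k > half_start)
    stop(structure(list(message = "no occupancy plateau found; extend the trajectory or set the window manually",
                        call = sys.call()),
                   class = c("lipidkinetics_no_plateau", "error", "condition")))
  times_ns[(k - 1L) * bl + 1L]
}

#' @export
print.duration_profile <- function(x, ...) {
  cat("Duration profile: ", nrow(x), " residue/species entries, ",
      sum(x$n_events), " events\n", sep = "")
  if (nrow(x) > 0) {
    top <- x[order(-x$mean_ns), ][seq_len(min(5L, nrow(x))), ]
    cat("  strongest interactions:\n")
    for (i in seq_len(nrow(top)))
      cat(sprintf("    residue %d / %s: %.1f ns (n=%d)\n", top$residue_id[i],
                  top$species[i], top$mean_ns[i], top$n_events[i]))
  }
  invisible(x)
}

#' @export
plot.duration_profile <- function(x, species = NULL, ...) {
  if (!is.null(species)) x <- x[x$species %in% species, ]
  sp <- unique(x$species)
  cols <- grDevices::hcl.colors(max(3L, length(sp)), "Dark 3")[seq_along(sp)]
  graphics::plot(NA, xlim = range(x$residue_id), ylim = c(0, max(x$mean_ns,
                 na.rm = TRUE)), xlab = "residue", ylab = "mean duration (ns)",
                 ...)
  for (i in seq_along(sp)) {
    xi <- x[x$species == sp[i], ]
    graphics::segments(xi$residue_id, 0, xi$residue_id, xi$mean_ns,
                       col = cols[i])
  }
  graphics::legend("topright", legend = sp, col = cols, lty = 1, bty = "n")
  invisible(x)
}
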