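# Trajectory and table I/O. Topologies and frames use the GRO fixed-width
# text format (0.001 nm precision); multi-frame trajectories are concatenated
# GRO frames, the plain-text trajectory GROMACS tools also accept.

.gro_atom_lines <- function(resid, resname, atom, x, y, z) {
  sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
          resid %% 100000L, substr(resname, 1, 5), substr(atom, 1, 5),
          seq_along(x) %% 100000L, x, y, z)
}

#' Write one frame in GRO format
#'
#' @param atoms data.frame with `resid`, `resname`, `atom`, `x`, `y`, `z`
#'   (nm, in box coordinates `[0, L]`).
#' @param box Box lengths `c(Lx, Ly, Lz)` in nm.
#' @param path Output file or connection.
#' @param title Title line.
#' @param append Append to an existing file (for multi-frame output).
#' @export
write_gro <- function(atoms, box, path, title = "membrane frame",
                      append = FALSE) {
  lines <- c(title, sprintf("%5d", nrow(atoms)),
             .gro_atom_lines(atoms$resid, atoms$resname, atoms$atom,
                             atoms$x, atoms$y, atoms$z),
             sprintf("%10.5f%10.5f%10.5f", box[1], box[2], box[3]))
  if (append) cat(lines, file = path, sep = "\n", append = TRUE)
  else writeLines(lines, path)
  invisible(path)
}

#' Read GRO frames
#'
#' @param path GRO file (single- or multi-frame).
#' @param multi Read all frames (default) or just the first.
#' @return List with `frames` (list of atom data.frames), `box`, `titles`.
#' @export
read_gro <- function(path, multi = TRUE) {
  lines <- readLines(path)
  frames <- list(); titles <- character(); box <- NULL
  i <- 1L
  while (i <= length(lines)) {
    title <- lines[i]
    nat <- as.integer(trimws(lines[i + 1L]))
    at <- lines[i + 1L + seq_len(nat)]
    frames[[length(frames) + 1L]] <- data.frame(
      resid = as.integer(substr(at, 1, 5)),
      resname = trimws(substr(at, 6, 10)),
      atom = trimws(substr(at, 11, 15)),
      x = as.numeric(substr(at, 21, 28)),
      y = as.numeric(substr(at, 29, 36)),
      z = as.numeric(substr(at, 37, 44)),
      stringsAsFactors = FALSE)
    titles <- c(titles, title)
    box <- as.numeric(strsplit(trimws(lines[i + nat + 2L]), "\\s+")[[1]])[1:3]
    i <- i + nat + 3L
    if (!multi) break
  }
  list(frames = frames, box = box, titles = titles)
}

# expand a trajectory frame to an atom table in box coordinates
.frame_atoms <- function(traj, frame) {
  lb <- lipid_bead_coords(traj, frame)
  rb <- traj$receptor$beads
  n_lip <- nrow(traj$lipids)
  atoms <- rbind(
    data.frame(resid = match(lb$lipid_id, traj$lipids$lipid_id),
               resname = lb$species, atom = lb$bead,
               x = lb$x, y = lb$y, z = lb$z, stringsAsFactors = FALSE),
    data.frame(resid = n_lip + rb$residue_id, resname = "REC",
               atom = rb$bead, x = rb$x, y = rb$y, z = rb$z,
               stringsAsFactors = FALSE))
  atoms$x <- atoms$x + traj$box_nm[1] / 2
  atoms$y <- atoms$y + traj$box_nm[2] / 2
  atoms$z <- atoms$z + traj$box_nm[3] / 2
  atoms
}

#' Write a trajectory as GRO topology + multi-frame GRO
#'
#' The topology is the first frame; the frames file concatenates all frames
#' with their times in the title lines. Coordinates survive a round trip to
#' within the format precision of 0.001 nm.
#'
#' @param traj A `cg_trajectory` (non-empty).
#' @param topology_path Output GRO topology path.
#' @param frames_path Output multi-frame GRO path.
#' @param frames Frame indices to write (default all).
#' @export
write_trajectory <- function(traj, topology_path, frames_path, frames = NULL) {
  if (n_frames(traj) == 0L || (nrow(traj$lipids) + nrow(traj$receptor$beads)) == 0L)
    stop("empty trajectory")
  if (is.null(frames)) frames <- seq_len(n_frames(traj))
  write_gro(.frame_atoms(traj, frames[1]), traj$box_nm, topology_path,
            title = sprintf("topology t= %.3f ns", traj$times_ns[frames[1]]))
  con <- file(frames_path, open = "wt")
  on.exit(close(con))
  for (f in frames)
    write_gro(.frame_atoms(traj, f), traj$box_nm, con,
              title = sprintf("frame t= %.3f ns", traj$times_ns[f]),
              append = TRUE)
  invisible(frames_path)
}

#' Read a trajectory written by [write_trajectory()]
#'
#' Lipid molecules (residues whose name matches a known species) are reduced
#' to their bead COMs; everything else is treated as the static receptor
#' (taken from the first frame).
#'
#' @param topology_path GRO topology.
#' @param frames_path Multi-frame GRO trajectory.
#' @return A `cg_trajectory`.
#' @export
read_trajectory <- function(topology_path, frames_path) {
  top <- read_gro(topology_path, multi = FALSE)
  gro <- read_gro(frames_path, multi = TRUE)
  box <- gro$box
  at1 <- top$frames[[1]]
  known <- names(.bead_templates())
  is_lip <- at1$resname %in% known
  lip_resids <- unique(at1$resid[is_lip])
  lipids <- data.frame(
    lipid_id = seq_along(lip_resids),
    species = at1$resname[match(lip_resids, at1$resid)],
    stringsAsFactors = FALSE)
  rec <- at1[!is_lip, ]
  rec_ids <- rec$resid - min(rec$resid) + 1L
  receptor <- receptor_model(data.frame(
    residue_id = rec_ids, bead = rec$atom, helix = NA_integer_,
    x = rec$x - box[1] / 2, y = rec$y - box[2] / 2, z = rec$z - box[3] / 2,
    stringsAsFactors = FALSE))
  nf <- length(gro$frames)
  x <- y <- z <- matrix(NA_real_, nf, length(lip_resids))
  for (f in seq_len(nf)) {
    at <- gro$frames[[f]]
    li <- at$resname %in% known
    cx <- tapply(at$x[li], at$resid[li], mean) - box[1] / 2
    cy <- tapply(at$y[li], at$resid[li], mean) - box[2] / 2
    cz <- tapply(at$z[li], at$resid[li], mean) - box[3] / 2
    ord <- match(as.character(lip_resids), names(cx))
    x[f, ] <- cx[ord]; y[f, ] <- cy[ord]; z[f, ] <- cz[ord]
  }
  tt <- suppressWarnings(as.numeric(sub(".*t=\\s*([-0-9.eE+]+).*", "\\1",
                                        gro$titles)))
  if (any(is.na(tt))) tt <- seq_len(nf) - 1
  stride <- if (nf > 1) tt[2] - tt[1] else 1
  lipids$leaflet0 <- ifelse(z[1, ] >= 0, "upper", "lower")
  structure(list(times_ns = tt, stride_ns = stride, box_nm = box,
                 lipids = lipids, x = x, y = y, z = z, receptor = receptor,
                 species = default_species(), leaflet_z = 2.0),
            class = "cg_trajectory")
}

#' Write contact events / duration profiles / occupancy series as CSV
#' @param x The object to write.
#' @param path Output CSV path.
#' @export
write_events_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' Write a PMF profile as CSV (`xi_nm`, `W_kJ_mol`, `sd_kJ_mol`)
#' @param profile A `pmf_profile`.
#' @param path Output CSV path.
#' @export
write_pmf_csv <- function(profile, path) {
  utils::write.csv(data.frame(
    xi_nm = profile$xi, W_kJ_mol = profile$W,
    sd_kJ_mol = if (is.null(profile$sd)) NA_real_ else profile$sd),
    path, row.names = FALSE)
  invisible(path)
}
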