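# Membrane composition: lipid species definitions, per-leaflet mole fractions,
# validation, discretization into molecule counts, and YAML (de)serialization.

#' Boltzmann constant in kJ/mol/K
#' @keywords internal
.kB <- 0.0083144621

#' Define a lipid species
#'
#' A lipid species couples a short name to its chemical class, the rule used to
#' pick its representative bead for in-plane analyses (Voronoi area-per-lipid,
#' leaflet assignment), and its head-group charge.
#'
#' @param name Short identifier, e.g. `"POPC"`. Must be unique within a
#'   composition.
#' @param class One of `"glycerophospholipid"`, `"sphingolipid"`,
#'   `"glycolipid"`, `"sterol"`, `"phosphoinositide"`.
#' @param bead_rule Representative-bead rule: `"glycerol-midpoint"` (midpoint
#'   of the GL1/GL2 glycerol beads), `"sphingosine-midpoint"` (midpoint of the
#'   AM1/AM2 beads), `"hydroxyl-bead"` (the sterol ROH bead), or
#'   `"named-bead:<NAME>"` for an explicit bead.
#' @param charge Integer head-group charge in elementary charges.
#' @return An object of class `lipid_species`.
#' @export
lipid_species <- function(name, class, bead_rule, charge = 0L) {
  classes <- c("glycerophospholipid", "sphingolipid", "glycolipid",
               "sterol", "phosphoinositide")
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!class %in% classes)
    stop("unknown lipid class: ", class)
  known_rules <- c("glycerol-midpoint", "sphingosine-midpoint", "hydroxyl-bead")
  if (!(bead_rule %in% known_rules || startsWith(bead_rule, "named-bead:")))
    stop("unknown representative-bead rule: ", bead_rule)
  structure(list(name = name, class = class, bead_rule = bead_rule,
                 charge = as.integer(charge)),
            class = "lipid_species")
}

# Coarse-grained bead templates, one row per bead, offsets in nm relative to
# the molecule's centre of mass (offsets sum to zero so the stored COM is the
# exact bead COM).  Offsets are for an upper-leaflet molecule (head up);
# lower-leaflet molecules are mirrored in z.
.bead_templates <- function() {
  gpl <- function(head) data.frame(
    bead = c(head, "PO4", "GL1", "GL2", "C1A", "C1B"),
    dx = c(0, 0, 0.10, -0.10, 0.08, -0.08),
    dy = 0,
    dz = c(0.55, 0.35, 0.05, 0.05, -0.50, -0.50),
    stringsAsFactors = FALSE)
  sph <- function(head) data.frame(
    bead = c(head, "AM1", "AM2", "T1A", "T1B"),
    dx = c(0, 0.10, -0.10, 0.08, -0.08),
    dy = 0,
    dz = c(0.52, 0.06, 0.06, -0.32, -0.32),
    stringsAsFactors = FALSE)
  list(
    POPC = gpl("NC3"), DOPC = gpl("NC3"), POPE = gpl("NH3"), DOPE = gpl("NH3"),
    POPS = gpl("CNO"), DOPS = gpl("CNO"),
    PIP2 = data.frame(
      bead = c("C1", "P1", "P2", "GL1", "GL2", "C1A", "C1B"),
      dx = c(0, 0.12, -0.12, 0.10, -0.10, 0.08, -0.08),
      dy = 0,
      dz = c(0.62, 0.50, 0.50, 0.06, 0.06, -0.87, -0.87),
      stringsAsFactors = FALSE),
    PSM = sph("PO4"),
    GM3 = data.frame(
      bead = c("GM13", "GM4", "AM1", "AM2", "T1A", "T1B"),
      dx = c(0.1, -0.1, 0.10, -0.10, 0.08, -0.08),
      dy = 0,
      dz = c(0.72, 0.72, 0.06, 0.06, -0.80, -0.76),
      stringsAsFactors = FALSE),
    CHOL = data.frame(
      bead = c("ROH", "R1", "R2"),
      dx = 0, dy = 0,
      dz = c(0.30, -0.10, -0.20),
      stringsAsFactors = FALSE))
}

#' Default lipid species registry
#'
#' The ten species of the in vivo-mimetic bilayer. `PSM` is the sphingomyelin
#' species (often abbreviated Sph).
#'
#' @return Named list of [lipid_species()] objects.
#' @export
default_species <- function() {
  sp <- list(
    lipid_species("POPC", "glycerophospholipid", "glycerol-midpoint", 0L),
    lipid_species("DOPC", "glycerophospholipid", "glycerol-midpoint", 0L),
    lipid_species("POPE", "glycerophospholipid", "glycerol-midpoint", 0L),
    lipid_species("DOPE", "glycerophospholipid", "glycerol-midpoint", 0L),
    lipid_species("POPS", "glycerophospholipid", "glycerol-midpoint", -1L),
    lipid_species("DOPS", "glycerophospholipid", "glycerol-midpoint", -1L),
    lipid_species("PIP2", "phosphoinositide", "glycerol-midpoint", -5L),
    lipid_species("PSM",  "sphingolipid", "sphingosine-midpoint", 0L),
    lipid_species("GM3",  "glycolipid", "sphingosine-midpoint", -1L),
    lipid_species("CHOL", "sterol", "hydroxyl-bead", 0L))
  names(sp) <- vapply(sp, `[[`, "", "name")
  sp
}

#' Construct a two-leaflet membrane composition
#'
#' @param upper,lower Named numeric vectors of mole fractions (must sum to 1
#'   per leaflet).
#' @param species Named list of [lipid_species()] covering every name used in
#'   `upper`/`lower`. Defaults to [default_species()].
#' @return An object of class `membrane_composition` with elements `upper`,
#'   `lower`, `species`.
#' @export
membrane_composition <- function(upper, lower, species = default_species()) {
  comp <- structure(list(upper = upper, lower = lower, species = species),
                    class = "membrane_composition")
  comp
}

#' The default in vivo-mimetic asymmetric composition
#'
#' Upper leaflet POPC 20%, DOPC 20%, POPE 5%, DOPE 5%, PSM 15%, GM3 10%,
#' CHOL 25%; lower leaflet POPC 5%, DOPC 5%, POPE 20%, DOPE 20%, POPS 8%,
#' DOPS 7%, PIP2 10%, CHOL 25%. Ten distinct species pooled over both
#' leaflets; cholesterol appears in both (the only species expected to
#' flip-flop).
#'
#' @return A `membrane_composition`.
#' @export
default_composition <- function() {
  upper <- c(POPC = 0.20, DOPC = 0.20, POPE = 0.05, DOPE = 0.05,
             PSM = 0.15, GM3 = 0.10, CHOL = 0.25)
  lower <- c(POPC = 0.05, DOPC = 0.05, POPE = 0.20, DOPE = 0.20,
             POPS = 0.08, DOPS = 0.07, PIP2 = 0.10, CHOL = 0.25)
  membrane_composition(upper, lower)
}

#' Validate a membrane composition
#'
#' Violations are returned as data, not raised as errors, so a configuration
#' file can be checked and reported on in full.
#'
#' @param comp A `membrane_composition`.
#' @return A data.frame with columns `leaflet`, `species`, `rule`, `detail`;
#'   zero rows iff the composition is valid.
#' @export
validate_composition <- function(comp) {
  v <- list()
  add <- function(leaflet, species, rule, detail)
    v[[length(v) + 1L]] <<- data.frame(leaflet = leaflet, species = species,
                                       rule = rule, detail = detail,
                                       stringsAsFactors = FALSE)
  templates <- .bead_templates()
  for (leaflet in c("upper", "lower")) {
    fr <- comp[[leaflet]]
    if (is.null(names(fr)) || any(!nzchar(names(fr)))) {
      add(leaflet, NA_character_, "unnamed_fraction", "fractions must be named")
      next
    }
    if (anyDuplicated(names(fr)))
      add(leaflet, names(fr)[duplicated(names(fr))][1L], "duplicate_species",
          "species listed more than once in a leaflet")
    for (s in names(fr)) {
      if (fr[[s]] < 0)
        add(leaflet, s, "negative_fraction", sprintf("fraction %g < 0", fr[[s]]))
      if (!s %in% names(comp$species))
        add(leaflet, s, "undefined_species", "no lipid_species definition")
    }
    if (abs(sum(fr) - 1) > 1e-9)
      add(leaflet, NA_character_, "sum_not_one",
          sprintf("leaflet fractions sum to %.12g", sum(fr)))
  }
  for (s in names(comp$species)) {
    sp <- comp$species[[s]]
    tpl <- templates[[s]]
    need <- switch(sp$bead_rule,
                   "glycerol-midpoint" = c("GL1", "GL2"),
                   "sphingosine-midpoint" = c("AM1", "AM2"),
                   "hydroxyl-bead" = "ROH",
                   sub("^named-bead:", "", sp$bead_rule))
    if (is.null(tpl) || !all(need %in% tpl$bead))
      add(NA_character_, s, "unresolvable_bead_rule",
          sprintf("rule '%s' cannot be resolved against the topology template",
                  sp$bead_rule))
  }
  if (length(v) == 0L)
    return(data.frame(leaflet = character(), species = character(),
                      rule = character(), detail = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, v)
}

#' Discretize leaflet fractions into molecule counts
#'
#' Largest-remainder rounding with alphabetical tie-break, so per-leaflet
#' counts sum exactly to the requested total and the result is deterministic.
#'
#' @param comp A `membrane_composition`.
#' @param n_upper,n_lower Number of lipids per leaflet (> 0).
#' @return List with named integer vectors `upper` and `lower`.
#' @export
realize_counts <- function(comp, n_upper, n_lower) {
  one <- function(fr, n) {
    if (length(fr) == 0L) stop("species set is empty")
    stopifnot(n > 0)
    exact <- fr * n
    base <- floor(exact)
    rem <- exact - base
    short <- as.integer(round(n - sum(base)))
    if (short > 0L) {
      ord <- order(-rem, names(fr))
      base[ord[seq_len(short)]] <- base[ord[seq_len(short)]] + 1
    }
    stats::setNames(as.integer(base), names(fr))
  }
  list(upper = one(comp$upper, n_upper), lower = one(comp$lower, n_lower))
}

#' Global system configuration
#'
#' @param box_nm Box lengths (x, y, z) in nm.
#' @param temperature_K Temperature in kelvin (CG default 323 K).
#' @param salt_M Salt molarity in mol/L (physiological 0.15 M).
#' @param stride_ns Frame output stride in ns.
#' @param total_time_us Simulated span in microseconds.
#' @param seed Integer RNG seed.
#' @return An object of class `system_config`.
#' @export
system_config <- function(box_nm = c(17, 17, 18), temperature_K = 323,
                          salt_M = 0.15, stride_ns = 1, total_time_us = 8,
                          seed = 1L) {
  stopifnot(length(box_nm) == 3L, all(box_nm > 0),
            stride_ns > 0, total_time_us * 1000 >= stride_ns)
  structure(list(box_nm = as.numeric(box_nm),
                 temperature_K = temperature_K, salt_M = salt_M,
                 stride_ns = stride_ns, total_time_us = total_time_us,
                 seed = as.integer(seed)),
            class = "system_config")
}

#' Write composition + system configuration as YAML
#'
#' Keys: `units` (`fraction` or `percent`), `leaflets`, `species`, `box_nm`,
#' `temperature_K`, `salt_M`, `stride_ns`, `total_time_us`, `seed`.
#'
#' @param comp A `membrane_composition`.
#' @param path Output file.
#' @param config Optional `system_config` to embed.
#' @param units Write fractions as-is (`"fraction"`) or as percentages.
#' @return `path`, invisibly.
#' @export
write_membrane_config <- function(comp, path, config = NULL,
                                  units = c("fraction", "percent")) {
  units <- match.arg(units)
  scale <- if (units == "percent") 100 else 1
  doc <- list(
    units = units,
    leaflets = list(upper = as.list(comp$upper * scale),
                    lower = as.list(comp$lower * scale)),
    species = lapply(comp$species, function(sp)
      list(class = sp$class, bead_rule = sp$bead_rule, charge = sp$charge)))
  if (!is.null(config))
    doc <- c(doc, list(box_nm = config$box_nm,
                       temperature_K = config$temperature_K,
                       salt_M = config$salt_M,
                       stride_ns = config$stride_ns,
                       total_time_us = config$total_time_us,
                       seed = config$seed))
  yaml::write_yaml(doc, path, precision = 12L)
  invisible(path)
}

#' Read a composition (+ optional system configuration) from YAML
#'
#' @param path YAML file written by [write_membrane_config()] (or hand-written
#'   with the same keys).
#' @return List with elements `composition` and (if present in the file)
#'   `config`.
#' @export
read_membrane_config <- function(path) {
  doc <- yaml::read_yaml(path)
  scale <- if (identical(doc$units, "percent")) 1 / 100 else 1
  species <- lapply(names(doc$species), function(nm) {
    d <- doc$species[[nm]]
    lipid_species(nm, d$class, d$bead_rule, d$charge)
  })
  names(species) <- names(doc$species)
  comp <- membrane_composition(
    upper = unlist(doc$leaflets$upper) * scale,
    lower = unlist(doc$leaflets$lower) * scale,
    species = species)
  out <- list(composition = comp)
  if (!is.null(doc$box_nm))
    out$config <- system_config(box_nm = unlist(doc$box_nm),
                                temperature_K = doc$temperature_K,
                                salt_M = doc$salt_M,
                                stride_ns = doc$stride_ns,
                                total_time_us = doc$total_time_us,
                                seed = doc$seed)
  out
}

#' @export
print.membrane_composition <- function(x, ...) {
  cat("Membrane composition (", length(unique(c(names(x$upper), names(x$lower)))),
      " species pooled over leaflets)\n", sep = "")
  for (l in c("upper", "lower")) {
    cat(sprintf("  %s: %s\n", l,
                paste(sprintf("%s %.0f%%", names(x[[l]]), 100 * x[[l]]),
                      collapse = ", ")))
  }
  nv <- nrow(validate_composition(x))
  if (nv > 0) cat("  ", nv, " validation violation(s)\n", sep = "")
  invisible(x)
}
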