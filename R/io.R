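#' Trajectory container
#'
#' Time-ordered coordinate snapshots with constant particle count, species
#' tags and box metadata. Coordinates are unwrapped.
#'
#' @param frames list of `n x 3` matrices
#' @param times numeric snapshot times (\eqn{\tau_B})
#' @param species per-particle tags
#' @param box cubic box side (sigma)
#' @return object of class `Trajectory`
#' @export
trajectory <- function(frames, times, species, box) {
  if (length(frames) != length(times))
    stop("frames and times must have equal length")
  n <- vapply(frames, nrow, integer(1))
  if (length(frames) > 0 && any(n != n[1]))
    stop("frame sizes must be constant")
  if (length(frames) > 0 && n[1] != length(species))
    stop("species length must match frame size")
  tr <- list(frames = frames, times = times, species = species, box = box)
  class(tr) <- "Trajectory"
  tr
}

#' @export
print.Trajectory <- function(x, ...) {
  cat("Trajectory:", length(x$frames), "frames x",
      if (length(x$frames)) nrow(x$frames[[1]]) else 0, "particles | t =",
      if (length(x$times)) paste(signif(range(x$times), 5), collapse = " .. ")
      else "-", "tau_B\n")
  invisible(x)
}

#' Write / read trajectories (extended XYZ and LAMMPS dump text)
#'
#' Extended XYZ frames carry `Properties=species:S:1:pos:R:3`, the box in a
#' `Lattice` record and the time in a `Time` record. LAMMPS dump frames use
#' the text format `ITEM: ATOMS id type x y z` with types 1 = chromatin,
#' 2 = anchor, 3 = bridge. Coordinates are written unwrapped at full
#' precision; reading a malformed file raises an error naming the offending
#' line.
#'
#' @param traj a [trajectory()]
#' @param path file path
#' @param format `"xyz_extended"` or `"lammps_dump"`
#' @return `writeTrajectory` returns `path` invisibly; `readTrajectory`
#'   returns a `Trajectory` (format auto-detected).
#' @export
writeTrajectory <- function(traj, path,
                            format = c("xyz_extended", "lammps_dump")) {
  stopifnot(inherits(traj, "Trajectory"))
  format <- match.arg(format)
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "xyz_extended") {
    for (k in seq_along(traj$frames)) {
      fr <- traj$frames[[k]]
      writeLines(as.character(nrow(fr)), con)
      writeLines(sprintf(
        'Lattice="%.17g 0 0 0 %.17g 0 0 0 %.17g" Properties=species:S:1:pos:R:3 Time=%.17g',
        traj$box, traj$box, traj$box, traj$times[k]), con)
      writeLines(sprintf("%s %.17g %.17g %.17g", traj$species,
                         fr[, 1], fr[, 2], fr[, 3]), con)
    }
  } else {
    type <- speciesCode(traj$species)
    for (k in seq_along(traj$frames)) {
      fr <- traj$frames[[k]]
      writeLines(c("ITEM: TIMESTEP", sprintf("%.17g", traj$times[k]),
                   "ITEM: NUMBER OF ATOMS", as.character(nrow(fr)),
                   "ITEM: BOX BOUNDS pp pp pp",
                   rep(sprintf("0 %.17g", traj$box), 3),
                   "ITEM: ATOMS id type x y z"), con)
      writeLines(sprintf("%d %d %.17g %.17g %.17g", seq_len(nrow(fr)),
                         type, fr[, 1], fr[, 2], fr[, 3]), con)
    }
  }
  invisible(path)
}

#' @rdname writeTrajectory
#' @export
readTrajectory <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0) stop("empty trajectory file: ", path)
  if (grepl("^ITEM: TIMESTEP", lines[1])) readLammpsDump(lines, path)
  else readXyzExtended(lines, path)
}

readXyzExtended <- function(lines, path) {
  frames <- list(); times <- numeric(0); species <- NULL; box <- 0
  i <- 1L
  while (i <= length(lines)) {
    if (!grepl("^\\s*\\d+\\s*$", lines[i]))
      stop("line ", i, ": expected an atom count, got '", lines[i], "'")
    n <- as.integer(lines[i])
    if (i + 1L + n > length(lines))
      stop("line ", i, ": frame declares ", n,
           " atoms but the file ends early")
    header <- lines[i + 1L]
    tm <- regmatches(header, regexec("Time=([-0-9.eE+]+)", header))[[1]]
    times <- c(times, if (length(tm) == 2) as.numeric(tm[2]) else
      length(times))
    lat <- regmatches(header, regexec('Lattice="([^"]+)"', header))[[1]]
    if (length(lat) == 2)
      box <- as.numeric(strsplit(trimws(lat[2]), "\\s+")[[1]][1])
    block <- lines[(i + 2L):(i + 1L + n)]
    parts <- strsplit(trimws(block), "\\s+")
    bad <- which(vapply(parts, length, integer(1)) < 4)
    if (length(bad))
      stop("line ", i + 1L + bad[1], ": malformed atom record")
    sp <- vapply(parts, `[[`, character(1), 1)
    xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    if (is.null(species)) species <- sp
    frames[[length(frames) + 1L]] <- xyz
    i <- i + 2L + n
  }
  trajectory(frames, times, species, box)
}

readLammpsDump <- function(lines, path) {
  frames <- list(); times <- numeric(0); types <- NULL; box <- 0
  i <- 1L
  while (i <= length(lines)) {
    if (!grepl("^ITEM: TIMESTEP", lines[i]))
      stop("line ", i, ": expected 'ITEM: TIMESTEP'")
    tstep <- as.numeric(lines[i + 1L])
    if (!grepl("^ITEM: NUMBER OF ATOMS", lines[i + 2L]))
      stop("line ", i + 2L, ": expected 'ITEM: NUMBER OF ATOMS'")
    n <- as.integer(lines[i + 3L])
    if (!grepl("^ITEM: BOX BOUNDS", lines[i + 4L]))
      stop("line ", i + 4L, ": expected 'ITEM: BOX BOUNDS'")
    bb <- as.numeric(strsplit(trimws(lines[i + 5L]), "\\s+")[[1]])
    box <- bb[2] - bb[1]
    if (!grepl("^ITEM: ATOMS", lines[i + 8L]))
      stop("line ", i + 8L, ": expected 'ITEM: ATOMS'")
    if (i + 8L + n > length(lines))
      stop("line ", i + 8L, ": frame declares ", n,
           " atoms but the file ends early (missing frame terminator)")
    block <- lines[(i + 9L):(i + 8L + n)]
    parts <- strsplit(trimws(block), "\\s+")
    bad <- which(vapply(parts, length, integer(1)) < 5)
    if (length(bad))
      stop("line ", i + 8L + bad[1], ": malformed atom record")
    rec <- t(vapply(parts, function(p) as.numeric(p[1:5]), numeric(5)))
    o <- order(rec[, 1])
    rec <- rec[o, , drop = FALSE]
    if (is.null(types)) types <- as.integer(rec[, 2])
    frames[[length(frames) + 1L]] <- rec[, 3:5, drop = FALSE]
    times <- c(times, tstep)
    i <- i + 9L + n
  }
  species <- c("chromatin", "anchor", "bridge")[types]
  trajectory(frames, times, species, box)
}

#' Export a topology + coordinates as a LAMMPS data file
#'
#' Molecular-style data file (atom ids 1-based as the format requires) with
#' atom types 1 = chromatin, 2 = anchor, 3 = bridge; bond types 1 = chain,
#' 2 = loop spring, 3 = centromere; angle type 1 = Kratky-Porod triplet.
#' Intended for cross-validating runs in an external engine.
#'
#' @param topology a `ChromosomeTopology`
#' @param positions coordinates of all particles (polymer first, then any
#'   bridges)
#' @param box cubic box side
#' @param path output file
#' @return `path`, invisibly
#' @export
writeLammpsData <- function(topology, positions, box, path) {
  positions <- as.matrix(positions)
  n <- nrow(positions)
  nbr <- n - topology$n_beads
  species <- c(speciesCode(topology$species), rep(3L, nbr))
  cent <- topology$centromere_springs
  bonds <- rbind(
    cbind(1L, topology$chain_bonds),
    cbind(2L, topology$loop_springs),
    if (!is.null(cent) && nrow(cent) > 0) cbind(3L, cent))
  ang <- topology$angle_triplets
  lines <- c("LAMMPS data file: looped-chromosome model", "",
             paste(n, "atoms"), paste(nrow(bonds), "bonds"),
             paste(nrow(ang), "angles"), "",
             "3 atom types", "3 bond types", "1 angle types", "",
             sprintf("0 %.10g xlo xhi", box),
             sprintf("0 %.10g ylo yhi", box),
             sprintf("0 %.10g zlo zhi", box), "",
             "Masses", "", "1 1", "2 1", "3 1", "",
             "Atoms # molecular", "",
             sprintf("%d 1 %d %.10g %.10g %.10g", seq_len(n), species,
                     positions[, 1], positions[, 2], positions[, 3]),
             "", "Bonds", "",
             sprintf("%d %d %d %d", seq_len(nrow(bonds)), bonds[, 1],
                     bonds[, 2], bonds[, 3]))
  if (nrow(ang) > 0)
    lines <- c(lines, "", "Angles", "",
               sprintf("%d 1 %d %d %d", seq_len(nrow(ang)), ang[, 1],
                       ang[, 2], ang[, 3]))
  writeLines(lines, path)
  invisible(path)
}

#' Deterministic small structures for tests and examples
#'
#' @param name one of `"tiny_bbp"` (10 loops x 10 beads bottlebrush),
#'   `"tiny_sac"` (the same topology with beads packed into a compact
#'   cylinder plus 20 bridge particles — a synthetic stand-in for a
#'   compacted state), `"helix"` (analytic helix, radius 2, pitch 6),
#'   `"rod"` (50 collinear beads) or `"blob"` (60 beads on a sphere
#'   surface)
#' @return list with `topology` (may be `NULL` for purely geometric
#'   fixtures), `positions`, `species` and `box`
#' @export
makeFixture <- function(name = c("tiny_bbp", "tiny_sac", "helix", "rod",
                                 "blob")) {
  name <- match.arg(name)
  if (name == "tiny_bbp") {
    topo <- buildUniformBottlebrush(10, 10)
    pos <- initBottlebrushCoords(topo, seed = 42L)
    return(list(topology = topo, positions = pos, species = topo$species,
                box = defaultBoxSide(topo)))
  }
  if (name == "tiny_sac") {
    topo <- buildUniformBottlebrush(10, 10)
    # beads wound tightly around a short axis; bridges seeded on the axis
    t <- seq(0, 20 * pi, length.out = topo$n_beads)
    z <- seq(0, 12, length.out = topo$n_beads)
    pos <- cbind(2.0 * cos(t), 2.0 * sin(t), z)
    br <- cbind(0.3 * cos(1:20), 0.3 * sin(1:20),
                seq(0, 12, length.out = 20))
    return(list(topology = topo, positions = rbind(pos, br),
                species = c(topo$species, rep("bridge", 20)), box = 60))
  }
  if (name == "helix") {
    k <- seq(0, 8 * pi, length.out = 200)
    pos <- cbind(2 * cos(k), 2 * sin(k), 6 * k / (2 * pi))
    return(list(topology = NULL, positions = pos,
                species = rep("chromatin", 200), box = 0))
  }
  if (name == "rod") {
    pos <- cbind(0, 0, seq(0, 49) * 1.1)
    return(list(topology = NULL, positions = pos,
                species = rep("chromatin", 50), box = 0))
  }
  # blob: Fibonacci sphere surface
  i <- seq_len(60)
  phi <- acos(1 - 2 * (i - 0.5) / 60)
  theta <- pi * (1 + sqrt(5)) * i
  pos <- 5 * cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
  list(topology = NULL, positions = pos, species = rep("chromatin", 60),
       box = 0)
}
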