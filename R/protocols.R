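#' Scenario specification
#'
#' Describes a perturbation experiment relative to the wild-type run:
#' global knockouts rescale loop length and bridge number, fragile-site
#' (CFS) scenarios perturb the loop table locally, `sisters` duplicates the
#' chromatid.
#'
#' @param name scenario name
#' @param loop_length_factor multiplier on the mean loop length (knockouts)
#' @param bridge_factor multiplier on the bridge count (knockouts)
#' @param perturbed_locus loop index of the first perturbed loop (CFS
#'   scenarios); `NA` = centre of the loop table
#' @param probe_flank number of loops on each side of the perturbed locus
#'   used as simulated FISH probe regions
#' @return object of class `ScenarioSpec`
#' @export
scenarioSpec <- function(name = c("control", "condI_KO", "condII_KO",
                                  "cfs_removal", "cfs_merge", "sisters"),
                         loop_length_factor = NULL, bridge_factor = NULL,
                         perturbed_locus = NA_integer_, probe_flank = 2L) {
  name <- match.arg(name)
  defaults <- list(control = c(1, 1), condI_KO = c(2, 0.5),
                   condII_KO = c(0.5, 2), cfs_removal = c(1, 1),
                   cfs_merge = c(1, 1), sisters = c(1, 2))
  d <- defaults[[name]]
  sp <- list(name = name,
             loop_length_factor = if (is.null(loop_length_factor)) d[1]
               else loop_length_factor,
             bridge_factor = if (is.null(bridge_factor)) d[2]
               else bridge_factor,
             perturbed_locus = as.integer(perturbed_locus),
             probe_flank = as.integer(probe_flank))
  if (sp$loop_length_factor <= 0 || sp$bridge_factor <= 0)
    stop("scenario factors must be positive")
  class(sp) <- "ScenarioSpec"
  sp
}

buildTopologyFromConfig <- function(config) {
  if (config$loop_mode == "uniform")
    buildUniformBottlebrush(config$n_loops, config$L_loop_beads,
                            config$min_loop_beads)
  else
    buildPoissonBottlebrush(config$n_loops, config$L_loop_beads,
                            config$min_loop_beads, seed = config$seed)
}

# uniform placement in [lo, hi] with a hard-core clearance to existing
# particles (prevents diverging initial forces); the clearance uses the
# periodic metric of the simulation box, since a bead protruding past the
# box edge wraps onto the opposite side
sampleBridgeSites <- function(pos, n, lo, hi, seed, clearance = 1.0,
                              box = 0) {
  if (n == 0L) return(matrix(numeric(0), 0, 3))
  withLocalSeed(seed, {
    out <- matrix(numeric(0), 0, 3)
    tries <- 0L
    while (nrow(out) < n && tries < 200L) {
      m <- 2L * (n - nrow(out)) + 10L
      cand <- cbind(stats::runif(m, lo[1], hi[1]),
                    stats::runif(m, lo[2], hi[2]),
                    stats::runif(m, lo[3], hi[3]))
      all <- rbind(pos, out, cand)
      base_n <- nrow(pos) + nrow(out)
      prs <- neighborPairs(all, box = box, cutoff = clearance, skin = 0)
      d <- abs(all[prs[, 1], , drop = FALSE] - all[prs[, 2], , drop = FALSE])
      if (box > 0) d <- pmin(d, box - d)
      prs <- prs[rowSums(d^2) < clearance^2, , drop = FALSE]
      bad <- unique(c(prs[, 1], prs[, 2]))
      bad <- bad[bad > base_n] - base_n
      keep <- setdiff(seq_len(m), bad)
      out <- rbind(out, cand[keep, , drop = FALSE])
      tries <- tries + 1L
    }
    if (nrow(out) < n)
      stop("could not place ", n, " bridges with clearance ", clearance)
    out[seq_len(n), , drop = FALSE]
  })
}

protocolResult <- function(trajectory, phase_marks, series,
                           state = NULL, topology = NULL, summary = list()) {
  pr <- list(trajectory = trajectory, phase_marks = phase_marks,
             series = series, state = state, topology = topology,
             summary = summary)
  class(pr) <- "ProtocolResult"
  pr
}

#' @export
print.ProtocolResult <- function(x, ...) {
  cat("ProtocolResult:", length(x$trajectory$frames), "frames | phases at",
      paste(signif(x$phase_marks, 5), collapse = ", "), "tau_B\n")
  if (length(x$summary))
    for (nm in names(x$summary))
      cat(" ", nm, "=", signif(unlist(x$summary[[nm]])[1], 5), "\n")
  invisible(x)
}

# shape/cluster time series from a trajectory
observableSeries <- function(traj, topology) {
  np <- topology$n_beads
  rows <- lapply(seq_along(traj$frames), function(k) {
    fr <- traj$frames[[k]]
    sh <- gyrationTensorShape(fr[seq_len(np), , drop = FALSE])
    nb <- nrow(fr) - np
    cl <- if (nb > 0)
      clusterBridges(fr[(np + 1):nrow(fr), , drop = FALSE])
    else list(N_c = 0L, S_c = NA_real_)
    data.frame(time = traj$times[k], Rg = sh$Rg, Ac = sh$Ac,
               N_c = cl$N_c, S_c = cl$S_c)
  })
  do.call(rbind, rows)
}

# relative change of windowed mean Rg < tol over two consecutive windows
plateauReached <- function(series, tol = 0.01, windows = 3L) {
  if (nrow(series) < 2L * windows) return(FALSE)
  n <- nrow(series)
  w2 <- mean(series$Rg[(n - windows + 1):n])
  w1 <- mean(series$Rg[(n - 2 * windows + 1):(n - windows)])
  abs(w2 - w1) / w1 < tol
}

#' Run the compaction protocol: bottlebrush to self-assembled cylinder
#'
#' Phase 1 equilibrates the bottlebrush with bridges interacting purely
#' sterically; at the switch-on time (t = 0 of the biological clock) the
#' attractive bridge-chromatin and bridge-anchor interactions are enabled
#' and the run continues until the configured compaction duration. Gyration
#' radius, acylindricity and bridge cluster statistics are recorded along
#' the way; a warning is emitted if the windowed mean Rg has not plateaued
#' (relative change above 1 percent between consecutive windows) within
#' the budget.
#'
#' @param config a [runConfig()]
#' @param topology optional pre-built `ChromosomeTopology` (e.g. a
#'   fragile-site perturbed one); defaults to building from the config
#' @param n_frames number of trajectory snapshots per phase
#' @param bridging enable the attractive phase (set `FALSE` for a control
#'   in which bridges stay sterile, where Rg should remain stationary)
#' @return a `ProtocolResult`: trajectory over both phases, `phase_marks`
#'   (time of switch-on), the observable `series`, the final `state`,
#'   `topology`, and a `summary` with final shape, extension and width
#' @export
runCompaction <- function(config, topology = NULL, n_frames = 25L,
                          bridging = TRUE) {
  stopifnot(inherits(config, "RunConfig"))
  if (is.null(topology)) topology <- buildTopologyFromConfig(config)
  box <- config$box_side_sigma
  if (is.na(box)) box <- defaultBoxSide(topology)
  pos <- initBottlebrushCoords(topology, seed = config$seed) + box / 2
  # bridges start dispersed around the fiber (condensin I loads onto
  # chromatin): uniform in the polymer bounding box inflated by 8 sigma,
  # rejecting placements that overlap a bead or another bridge
  lo <- pmax(apply(pos, 2, min) - 8, 0)
  hi <- pmin(apply(pos, 2, max) + 8, box)
  bridges <- sampleBridgeSites(pos, config$n_bridges, lo, hi,
                               seed = config$seed + 1L, box = box)
  state <- simulationState(rbind(pos, bridges),
                           c(topology$species,
                             rep("bridge", config$n_bridges)), box)
  ff_steric <- forceField(A = config$A_kBT,
                          eps_bridge_bridge = config$eps_bridge_bridge_kBT,
                          bridging = FALSE)
  ff_on <- forceField(A = config$A_kBT, eps_weak = config$eps_weak_kBT,
                      eps_strong = config$eps_strong_kBT,
                      eps_bridge_bridge = config$eps_bridge_bridge_kBT,
                      bridging = bridging)
  dt <- config$dt_tau
  runPhase <- function(state, ff, dur, seed) {
    steps <- max(1L, as.integer(round(dur / dt)))
    stride <- max(1L, steps %/% n_frames)
    langevinRun(state, topology, ff, steps, dt = dt,
                gamma = config$gamma, seed = seed, stride = stride)
  }
  p1 <- runPhase(state, ff_steric, config$phase_durations[["equilibration"]],
                 config$seed)
  t_on <- p1$state$time
  p2 <- runPhase(p1$state, ff_on, config$phase_durations[["compaction"]],
                 config$seed)
  traj <- trajectory(c(p1$trajectory$frames, p2$trajectory$frames),
                     c(p1$trajectory$times, p2$trajectory$times) - t_on,
                     state$species, box)
  series <- observableSeries(traj, topology)
  if (bridging && !plateauReached(series))
    warning("Rg has not plateaued within the configured compaction budget; ",
            "returning the partial result")
  np <- topology$n_beads
  last <- traj$frames[[length(traj$frames)]][seq_len(np), , drop = FALSE]
  anchors <- which(topology$species == "anchor")
  ends <- c(anchors[1], anchors[length(anchors)])
  ew <- extensionAndWidth(last, ends)
  protocolResult(traj, c(switch_on = 0), series, p2$state, topology,
                 summary = list(shape = gyrationTensorShape(last),
                                extension = ew$extension,
                                width = ew$width, ends = ends))
}

#' Run a constant-force extension-retraction cycle
#'
#' Applies equal and opposite constant forces to the two terminal backbone
#' anchors of a compacted chromosome, then releases and lets the structure
#' relax. Extension (end-to-end distance of the pulled beads) and bridge
#' cluster statistics are tracked through both phases. The box is enlarged
#' if needed so the fully stretched chain cannot reach its periodic image.
#'
#' @param sac a `ProtocolResult` from [runCompaction()] (or a
#'   `SimulationState` plus `topology`)
#' @param pulling a [pullingConfig()]; `bead_a`/`bead_b` of 0 select the
#'   terminal anchors automatically
#' @param topology required if `sac` is a bare state
#' @param config the [runConfig()] of the originating run (integrator
#'   settings and seed)
#' @param n_frames snapshots per phase
#' @return a `ProtocolResult`; `series` has columns `time`, `extension`,
#'   `N_c`, `S_c`; `phase_marks` gives force-on and force-off times;
#'   `summary` reports initial/max/final extension
#' @export
runExtensionRetraction <- function(sac, pulling, topology = NULL,
                                   config = runConfig(), n_frames = 25L) {
  if (inherits(sac, "ProtocolResult")) {
    state <- sac$state
    topology <- sac$topology
  } else state <- sac
  if (is.null(topology)) stop("topology required")
  anchors <- which(topology$species == "anchor")
  if (pulling$bead_a == 0L) pulling$bead_a <- anchors[1]
  if (pulling$bead_b == 0L) pulling$bead_b <- anchors[length(anchors)]
  # room for the fully stretched chain
  contour <- 1.3 * sum(nrow(topology$loop_springs) * 2.0 +
                         nrow(topology$loop_table) * 1.2) + 20
  if (state$box > 0 && state$box < contour) state$box <- contour
  ff <- forceField(A = config$A_kBT, eps_weak = config$eps_weak_kBT,
                   eps_strong = config$eps_strong_kBT,
                   eps_bridge_bridge = config$eps_bridge_bridge_kBT)
  dt <- config$dt_tau
  t0 <- state$time
  runPhase <- function(state, dur, pull) {
    steps <- max(1L, as.integer(round(dur / dt)))
    stride <- max(1L, steps %/% n_frames)
    langevinRun(state, topology, ff, steps, dt = dt, gamma = config$gamma,
                seed = config$seed, stride = stride, pulling = pull)
  }
  ext0 <- sqrt(sum((state$positions[pulling$bead_a, ] -
                      state$positions[pulling$bead_b, ])^2))
  p1 <- runPhase(state, pulling$extension_phase, pulling)
  p2 <- runPhase(p1$state, pulling$relaxation_phase, NULL)
  traj <- trajectory(c(p1$trajectory$frames, p2$trajectory$frames),
                     c(p1$trajectory$times, p2$trajectory$times) - t0,
                     state$species, state$box)
  np <- topology$n_beads
  ext <- vapply(traj$frames, function(fr)
    sqrt(sum((fr[pulling$bead_a, ] - fr[pulling$bead_b, ])^2)), numeric(1))
  cl <- lapply(traj$frames, function(fr)
    if (nrow(fr) > np) clusterBridges(fr[(np + 1):nrow(fr), , drop = FALSE])
    else list(N_c = 0L, S_c = NA_real_))
  series <- data.frame(time = traj$times, extension = ext,
                       N_c = vapply(cl, `[[`, integer(1), "N_c"),
                       S_c = vapply(cl, `[[`, numeric(1), "S_c"))
  protocolResult(traj,
                 c(force_on = 0, force_off = pulling$extension_phase),
                 series, p2$state, topology,
                 summary = list(initial_extension = ext0,
                                max_extension = max(ext),
                                final_extension = ext[length(ext)]))
}

#' Run a named perturbation scenario
#'
#' Dispatches on the scenario: knockouts rescale the configuration through
#' [applyKnockout()]; CFS scenarios perturb the topology through
#' [applyCfsPerturbation()] and report the simulated FISH probe distance
#' across the perturbed locus; `sisters` builds centromere-linked sister
#' chromatids with a doubled bridge pool. The control scenario reproduces
#' [runCompaction()] exactly at equal seed.
#'
#' @param config a [runConfig()]
#' @param scenario a [scenarioSpec()] (or a scenario name)
#' @param n_frames snapshots per phase
#' @return a `ProtocolResult`; `summary` gains scenario observables
#'   (`width`, `local_stiffness`, and `probe_distance` for CFS scenarios)
#' @export
runScenario <- function(config, scenario = scenarioSpec("control"),
                        n_frames = 25L) {
  if (is.character(scenario)) scenario <- scenarioSpec(scenario)
  stopifnot(inherits(scenario, "ScenarioSpec"))
  name <- scenario$name
  probe <- NULL
  if (name %in% c("condI_KO", "condII_KO")) {
    config$L_loop_beads <- as.integer(round(config$L_loop_beads *
                                              scenario$loop_length_factor))
    config$n_bridges <- as.integer(round(config$n_bridges *
                                           scenario$bridge_factor))
    config$scenario <- name
    validateRunConfig(config)
    res <- runCompaction(config, n_frames = n_frames)
  } else if (name %in% c("cfs_removal", "cfs_merge")) {
    topo <- buildTopologyFromConfig(config)
    locus <- scenario$perturbed_locus
    if (is.na(locus)) locus <- nrow(topo$loop_table) %/% 2L
    span <- if (name == "cfs_removal") 2L else 3L
    lt <- topo$loop_table
    fl <- scenario$probe_flank
    # probe a sits inside the perturbed region (expelled from the cylinder
    # under the merge), probe b on the first intact loops downstream
    la <- locus:(locus + span - 1L)
    lb <- (locus + span):min(nrow(lt), locus + span + fl - 1L)
    beadsOf <- function(loops) unlist(lapply(loops, function(k)
      seq(lt$anchor[k], length.out = lt$length[k])))
    probe <- list(a = beadsOf(la), b = beadsOf(lb))
    ptopo <- applyCfsPerturbation(topo, sub("cfs_", "", name), locus)
    res <- runCompaction(config, topology = ptopo, n_frames = n_frames)
  } else if (name == "sisters") {
    base <- buildTopologyFromConfig(config)
    nl <- nrow(base$loop_table)
    cent <- max(1L, nl %/% 2L - 2L):min(nl, nl %/% 2L + 2L)
    topo <- buildSisterChromatids(base, cent, n_springs = 10L)
    config$n_bridges <- as.integer(round(config$n_bridges *
                                           scenario$bridge_factor))
    config$scenario <- name
    res <- runCompaction(config, topology = topo, n_frames = n_frames)
  } else {
    res <- runCompaction(config, n_frames = n_frames)
  }
  # scenario observables from the final third of the bridged phase
  topo <- res$topology
  np <- topo$n_beads
  tail_frames <- res$trajectory$frames[res$trajectory$times > 0]
  tail_frames <- tail_frames[seq(max(1, length(tail_frames) - 7),
                                 length(tail_frames))]
  last <- tail_frames[[length(tail_frames)]]
  anchors <- which(topo$species == "anchor")
  width <- mean(vapply(tail_frames, function(fr)
    extensionAndWidth(fr[seq_len(np), , drop = FALSE],
                      res$summary$ends)$width, numeric(1)))
  stiff <- tryCatch(
    localStiffness(last[anchors, , drop = FALSE], stride = 5L),
    error = function(e) NA_real_)
  res$summary$width <- width
  res$summary$local_stiffness <- stiff
  if (!is.null(probe)) {
    ttraj <- trajectory(tail_frames, seq_along(tail_frames),
                        res$trajectory$species, res$trajectory$box)
    res$summary$probe_distance <- probeDistance(ttraj, probe$a, probe$b)
    res$summary$probe_regions <- probe
  }
  res$summary$scenario <- name
  res
}
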