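#' Simulation state
#'
#' Bundles unwrapped bead coordinates, velocities, the periodic cubic box
#' and the elapsed simulation time. Coordinates are kept unwrapped (real
#' space); the engine wraps internally for the minimum-image convention and
#' unwraps on return, so shape observables never need image reconstruction.
#'
#' @param positions `n x 3` matrix (sigma)
#' @param velocities `n x 3` matrix, defaults to zero
#' @param box cubic box side (sigma); `0` disables periodicity
#' @param time elapsed time in \eqn{\tau_B}
#' @param species per-bead tags (chromatin / anchor / bridge)
#' @return object of class `SimulationState`
#' @export
simulationState <- function(positions, species, box, velocities = NULL,
                            time = 0) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3) stop("positions must be n x 3")
  if (length(species) != nrow(positions))
    stop("species length must match bead count")
  if (any(!is.finite(positions))) stop("non-finite coordinates")
  if (is.null(velocities)) velocities <- matrix(0, nrow(positions), 3)
  st <- list(positions = positions, velocities = as.matrix(velocities),
             box = box, time = time, species = species)
  class(st) <- "SimulationState"
  st
}

#' @export
print.SimulationState <- function(x, ...) {
  cat("SimulationState:", nrow(x$positions), "particles | box",
      signif(x$box, 4), "sigma | t =", signif(x$time, 5), "tau_B\n")
  invisible(x)
}

engineArgs <- function(state, topology, ff) {
  n_extra <- nrow(state$positions) - topology$n_beads
  if (n_extra < 0) stop("state has fewer particles than the topology")
  species <- speciesCode(state$species)
  bonds <- topology$chain_bonds
  bK <- rep(ff$K, nrow(bonds)); bR <- rep(ff$r0, nrow(bonds))
  if (nrow(topology$loop_springs) > 0) {
    bonds <- rbind(bonds, topology$loop_springs)
    bK <- c(bK, rep(ff$K_backbone, nrow(topology$loop_springs)))
    bR <- c(bR, rep(ff$r1, nrow(topology$loop_springs)))
  }
  if (!is.null(topology$centromere_springs) &&
      nrow(topology$centromere_springs) > 0) {
    bonds <- rbind(bonds, topology$centromere_springs)
    bK <- c(bK, rep(ff$K, nrow(topology$centromere_springs)))
    bR <- c(bR, rep(ff$r0, nrow(topology$centromere_springs)))
  }
  pm <- pairMatrices(ff)
  list(species = species, bonds = bonds, bondK = bK, bondR0 = bR,
       angles = topology$angle_triplets,
       angleK = rep(ff$K_bend, nrow(topology$angle_triplets)), pm = pm)
}

#' Advance the system with underdamped Langevin dynamics
#'
#' Integrates \eqn{m\,\ddot r = -\nabla U - \gamma \dot r +
#' \sqrt{2k_BT\gamma}\,\eta} with a velocity-Verlet scheme in which the
#' friction and delta-correlated Gaussian noise enter the force evaluation
#' (engine-equivalent splitting). Units: \eqn{m = k_BT = \sigma = 1};
#' with \eqn{\gamma = 1} all microscopic time scales coincide
#' (\eqn{\tau_{LJ} = \tau_{dec} = \tau_B = 1}). Setting `gamma = 0` yields
#' plain (noise-free) velocity-Verlet NVE dynamics. The noise stream is
#' keyed by `(seed, step, particle)`, so trajectories are bit-reproducible
#' for a given call sequence and a restarted run reuses exactly the noise
#' of the continuous one; because the friction force uses the
#' instantaneous velocity, splitting a run into chunks reproduces the
#' continuous trajectory to \eqn{O(\gamma\,dt)} rather than bit-wise.
#'
#' @param state a [simulationState()]
#' @param topology a `ChromosomeTopology`
#' @param ff a [forceField()]
#' @param n_steps number of time steps
#' @param dt time step (default 0.01 \eqn{\tau})
#' @param gamma friction coefficient
#' @param kT thermal energy (default 1)
#' @param seed integer noise seed
#' @param stride snapshot interval in steps (0 = no snapshots)
#' @param pulling optional [pullingConfig()]: constant opposite forces on
#'   two beads
#' @param skin neighbour-list skin (sigma)
#' @return list: updated `state`, a `Trajectory` (`frames`, `times`,
#'   `species`, `box`) if `stride > 0`, final `energy` decomposition and
#'   the advanced `step_offset`
#' @export
langevinRun <- function(state, topology, ff, n_steps, dt = 0.01, gamma = 1,
                        kT = 1, seed = 1L, stride = 0L, pulling = NULL,
                        skin = 0.4) {
  stopifnot(inherits(state, "SimulationState"))
  ea <- engineArgs(state, topology, ff)
  pa <- 0L; pb <- 0L; pf <- 0
  if (!is.null(pulling)) {
    pa <- pulling$bead_a; pb <- pulling$bead_b
    pf <- pulling$force_magnitude
  }
  step0 <- round(state$time / dt)
  res <- .engine_run(state$positions, state$velocities, ea$species,
                     state$box, ea$bonds, ea$bondK, ea$bondR0, ea$angles,
                     ea$angleK, ea$pm$kind, ea$pm$eps, ea$pm$cut,
                     ea$pm$shift, as.integer(n_steps), dt, gamma, kT,
                     as.integer(seed), step0, as.integer(stride),
                     as.integer(pa), as.integer(pb), pf, skin)
  newstate <- simulationState(res$positions, state$species, state$box,
                              res$velocities, state$time + n_steps * dt)
  traj <- NULL
  if (stride > 0 && res$n_frames > 0) {
    n <- nrow(state$positions)
    frames <- lapply(seq_len(res$n_frames), function(k)
      res$frames[((k - 1) * n + 1):(k * n), , drop = FALSE])
    traj <- trajectory(frames, res$frame_times[seq_len(res$n_frames)],
                       state$species, state$box)
  }
  list(state = newstate, trajectory = traj, energy = res$energy)
}

#' Evaluate energies and forces with the compiled engine
#'
#' Runs the engine's neighbour-listed force loop once, without integrating.
#' Useful for validating the neighbour-list evaluation against the
#' brute-force [totalEnergy()] oracle and for finite-difference force
#' checks.
#'
#' @inheritParams langevinRun
#' @return list with `energy` (`pair`, `bond`, `angle`) and an `n x 3`
#'   `forces` matrix
#' @export
engineEval <- function(state, topology, ff, skin = 0.4) {
  ea <- engineArgs(state, topology, ff)
  .engine_eval(state$positions, ea$species, state$box, ea$bonds, ea$bondK,
               ea$bondR0, ea$angles, ea$angleK, ea$pm$kind, ea$pm$eps,
               ea$pm$cut, ea$pm$shift, skin)
}

#' Candidate interaction pairs within a cutoff (+ skin)
#'
#' Returns a superset of all particle pairs within `cutoff`, built with the
#' same cell-binned Verlet construction the integrator uses (minimum-image
#' convention if `box > 0`).
#'
#' @param positions `n x 3` matrix
#' @param box cubic box side (0 = open boundary)
#' @param cutoff interaction cutoff (sigma)
#' @param skin list skin (sigma)
#' @return two-column integer matrix of 1-based pairs `i < j`
#' @export
neighborPairs <- function(positions, box, cutoff, skin = 0.4) {
  if (box > 0 && cutoff + skin > box / 2)
    stop("cutoff + skin exceeds half the box side (minimum-image violation)")
  .neighbor_pairs(as.matrix(positions), box, cutoff, skin)
}

#' Constant-force pulling configuration
#'
#' Describes the in-silico micromanipulation protocol: two equal and
#' opposite constant forces \eqn{\pm F} applied to two beads (the chromosome
#' extremities) along the line joining them, re-evaluated every step, so the
#' net external force is always zero. Forces map to pN through
#' [mapForceUnit()]; the experimentally motivated range is 2-9 pN.
#'
#' @param force_magnitude force in simulation units (kBT/sigma)
#' @param bead_a,bead_b indices of the pulled beads; `0` lets
#'   [runExtensionRetraction()] pick the terminal backbone anchors
#' @param extension_phase,relaxation_phase durations in \eqn{\tau_B}
#' @return object of class `PullingConfig`
#' @export
pullingConfig <- function(force_magnitude, bead_a = 0L, bead_b = 0L,
                          extension_phase = 100, relaxation_phase = 100) {
  if (bead_a == bead_b && bead_a != 0L)
    stop("bead_a and bead_b must differ")
  if (extension_phase < 0 || relaxation_phase < 0)
    stop("phase durations must be >= 0")
  pc <- list(force_magnitude = force_magnitude, bead_a = as.integer(bead_a),
             bead_b = as.integer(bead_b),
             extension_phase = extension_phase,
             relaxation_phase = relaxation_phase)
  class(pc) <- "PullingConfig"
  pc
}

#' Per-bead external force field of a pulling setup
#'
#' @param state a [simulationState()]
#' @param pulling a [pullingConfig()]
#' @return `n x 3` matrix: `+F` on `bead_a`, `-F` on `bead_b` along the
#'   line joining them, zero elsewhere
#' @export
applyEndForces <- function(state, pulling) {
  n <- nrow(state$positions)
  if (pulling$bead_a > n || pulling$bead_b > n) stop("invalid bead index")
  f <- matrix(0, n, 3)
  d <- state$positions[pulling$bead_a, ] - state$positions[pulling$bead_b, ]
  r <- sqrt(sum(d^2))
  if (r > 1e-12) {
    u <- d / r
    f[pulling$bead_a, ] <- pulling$force_magnitude * u
    f[pulling$bead_b, ] <- -pulling$force_magnitude * u
  }
  f
}

#' Initial bottlebrush coordinates
#'
#' Builds a relaxed starting geometry: loop anchors follow a smooth
#' worm-like backbone curve (persistence length `backbone_lp`, rise
#' `spacing` per loop — a straight rod would misrepresent the coiled state
#' of an equilibrated bottlebrush), and each loop is laid out as a planar
#' ring of radius \eqn{L b/2\pi} perpendicular to the local backbone
#' tangent, with golden-angle azimuths so bristles fan out evenly. Sister
#' chromatids are offset laterally. Residual overlaps are bounded by the
#' soft potential and relax within a few \eqn{\tau_B}.
#'
#' @param topology a `ChromosomeTopology`
#' @param spacing backbone rise per loop (sigma)
#' @param bond target bead spacing along a loop (sigma)
#' @param backbone_lp persistence length of the initial backbone curve
#'   (sigma); `Inf` gives a straight rod
#' @param jitter amplitude of deterministic symmetry-breaking displacement
#' @param seed integer seed for the backbone curve and jitter
#' @return `n_beads x 3` coordinate matrix centred at the origin
#' @export
initBottlebrushCoords <- function(topology, spacing = 1.4, bond = 1.05,
                                  backbone_lp = 100, jitter = 0.05,
                                  seed = 1L) {
  lt <- topology$loop_table
  nl <- nrow(lt)
  perChromatid <- tabulate(topology$chromatid[lt$anchor],
                           nbins = topology$n_chromatids)
  rand <- withLocalSeed(seed, list(
    steps = matrix(stats::rnorm(3 * nl), ncol = 3),
    jit = matrix(stats::runif(3 * topology$n_beads, -jitter, jitter),
                 ncol = 3)))
  # worm-like backbone: tangent decorrelates over backbone_lp
  memory <- if (is.finite(backbone_lp))
    exp(-spacing / backbone_lp) else 1
  pos <- matrix(0, topology$n_beads, 3)
  golden <- pi * (3 - sqrt(5))
  xoff_step <- 2 * (max(lt$length) * bond / (2 * pi) + 2)
  kk <- 0L
  for (cid in seq_len(topology$n_chromatids)) {
    tangent <- c(0, 0, 1)
    bpoint <- c((cid - 1) * xoff_step, 0, 0)
    loops <- which(topology$chromatid[lt$anchor] == cid)
    for (idx in seq_along(loops)) {
      k <- loops[idx]
      kk <- kk + 1L
      L <- lt$length[k]
      a <- lt$anchor[k]
      R <- max(L * bond / (2 * pi), 0.6)
      # orthonormal frame at this backbone point
      ref <- if (abs(tangent[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
      e1 <- ref - sum(ref * tangent) * tangent
      e1 <- e1 / sqrt(sum(e1^2))
      e2 <- c(tangent[2] * e1[3] - tangent[3] * e1[2],
              tangent[3] * e1[1] - tangent[1] * e1[3],
              tangent[1] * e1[2] - tangent[2] * e1[1])
      phi <- (kk - 1L) * golden
      u <- cos(phi) * e1 + sin(phi) * e2      # ring offset direction
      v <- -sin(phi) * e1 + cos(phi) * e2
      theta <- 2 * pi * (seq_len(L) - 1) / L
      centre <- bpoint + R * u
      pos[a:(a + L - 1L), ] <-
        matrix(centre, L, 3, byrow = TRUE) -
        outer(cos(theta), R * u) + outer(sin(theta), R * v)
      # advance the backbone
      tangent <- memory * tangent + sqrt(max(0, 1 - memory^2)) *
        rand$steps[k, ]
      tangent <- tangent / sqrt(sum(tangent^2))
      bpoint <- bpoint + spacing * tangent
    }
  }
  pos <- pos + rand$jit
  sweep(pos, 2, colMeans(pos))
}

#' Initial coordinates for an unlooped chain
#'
#' Smooth random-walk geometry (persistent directions, fixed bond length)
#' for linear-chain topologies, centred at the origin.
#'
#' @param n_beads chain length
#' @param bond bond length (sigma)
#' @param lp target persistence length of the walk (sigma); the default
#'   matches the equilibrium stiffness of the Kratky-Porod term, so burn-in
#'   carries no long-wavelength stiffness bias
#' @param seed integer seed
#' @return `n_beads x 3` coordinate matrix
#' @export
initChainCoords <- function(n_beads, bond = 1.1, lp = 2.8, seed = 1L) {
  dirs <- withLocalSeed(seed,
                        matrix(stats::rnorm(3 * (n_beads - 1)), ncol = 3))
  # correlate successive directions: memory exp(-bond/lp)
  m <- exp(-bond / lp)
  for (k in 2:nrow(dirs)) {
    dirs[k - 1, ] <- dirs[k - 1, ] / sqrt(sum(dirs[k - 1, ]^2))
    dirs[k, ] <- m * dirs[k - 1, ] + sqrt(1 - m^2) * dirs[k, ] /
      sqrt(sum(dirs[k, ]^2))
  }
  dirs <- dirs / sqrt(rowSums(dirs^2))
  pos <- rbind(0, apply(dirs * bond, 2, cumsum))
  sweep(pos, 2, colMeans(pos))
}

#' Measure the emergent persistence length of the bare fiber
#'
#' Simulates an ensemble of free semiflexible chains (harmonic bonds +
#' Kratky-Porod bending only, no excluded volume), averages the
#' bond-tangent correlation over chains and frames, and fits its
#' exponential decay. Averaging over independent chains matters: a single
#' chain's large-scale conformation decorrelates slowly, which biases the
#' correlation tail upward. With the default bending modulus of 3 kBT the
#' result is about 3 sigma = 60 nm at the 20-nm mapping.
#'
#' @param n_beads chain length (default 200)
#' @param n_chains independent replicate chains
#' @param K_bend bending modulus (kBT)
#' @param seed integer seed (chain k uses `seed + k`)
#' @param burnin,production phase durations in \eqn{\tau_B}
#' @param n_frames frames sampled per chain
#' @param max_sep largest bond separation used in the fit
#' @param units optional [unitSystem()] for the nm conversion
#' @return list: `lp_sigma`, `lp_nm` (if `units`), and the averaged
#'   `correlation` data frame
#' @export
persistenceLengthRun <- function(n_beads = 200L, n_chains = 6L, K_bend = 3,
                                 seed = 1L, burnin = 300, production = 600,
                                 n_frames = 10L, max_sep = 5L,
                                 units = unitSystem()) {
  topo <- buildLinearChain(n_beads)
  ff <- forceField(A = 0, K_bend = K_bend)
  dt <- 0.01
  cs <- NULL
  avg <- NULL
  for (k in seq_len(n_chains)) {
    st <- simulationState(initChainCoords(n_beads, seed = seed + k) + 150,
                          topo$species, box = 300)
    st <- langevinRun(st, topo, ff, as.integer(burnin / dt),
                      seed = seed + k)$state
    out <- langevinRun(st, topo, ff, as.integer(production / dt),
                       seed = seed + k,
                       stride = as.integer(production / dt / n_frames))
    for (fr in out$trajectory$frames) {
      tc <- tangentCorrelation(fr, stride = 1L)
      if (is.null(avg)) avg <- tc
      cs <- cbind(cs, tc$correlation)
    }
  }
  avg$correlation <- rowMeans(cs)
  fit <- fitPersistenceLength(avg, max_sep = max_sep, units = units)
  c(fit, list(correlation = avg))
}

#' Default box side for a topology
#'
#' 1.5 times the initial backbone extent plus the bristle diameter (so the
#' polymer cannot interact with its own periodic image), with a floor that
#' keeps the box several interaction ranges wide. Bridges placed uniformly
#' in such a box start dilute.
#'
#' @param topology a `ChromosomeTopology`
#' @param spacing backbone rise per loop used by [initBottlebrushCoords()]
#' @return box side in sigma
#' @export
defaultBoxSide <- function(topology, spacing = 1.4) {
  loops_per_chromatid <- nrow(topology$loop_table) / topology$n_chromatids
  bristle <- if (nrow(topology$loop_table) > 0)
    max(topology$loop_table$length) * 1.05 / pi else 0
  max(1.5 * loops_per_chromatid * spacing + bristle, 20)
}
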