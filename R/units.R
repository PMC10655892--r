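#' Physical unit system for the chromosome model
#'
#' Maps the simulation units (bead diameter \eqn{\sigma}, thermal energy
#' \eqn{k_BT}, Brownian time \eqn{\tau_B}) to physical units. The defaults
#' follow the standard mapping of one bead to a 20-nm chromatin segment
#' holding 2 kbp, at T = 300 K in a nucleoplasm-like solvent of 150 cP.
#' Derived quantities: the Brownian time
#' \eqn{\tau_B = 3\pi\sigma^3\eta_{sol}/k_BT} (time for a bead to diffuse its
#' own diameter, from the Stokes-Einstein friction \eqn{\gamma =
#' 3\pi\sigma\eta_{sol}}) and the simulation force unit \eqn{k_BT/\sigma}.
#'
#' @param sigma_nm bead diameter in nm (default 20)
#' @param bp_per_bead genomic content of one bead in bp (default 2000)
#' @param temperature_K absolute temperature (default 300)
#' @param viscosity_cP solvent viscosity in centipoise (default 150)
#' @return object of class `UnitSystem` with fields `kBT_J`, `tau_B_s`
#'   (seconds) and `force_pN` (pN per simulation force unit) alongside the
#'   inputs.
#' @examples
#' us <- unitSystem()
#' mapBrownianTime(us)   # ~2.73 ms per tau_B
#' mapForceUnit(us)      # ~0.207 pN per kBT/sigma
#' @export
unitSystem <- function(sigma_nm = 20, bp_per_bead = 2000,
                       temperature_K = 300, viscosity_cP = 150) {
  vals <- c(sigma_nm = sigma_nm, bp_per_bead = bp_per_bead,
            temperature_K = temperature_K, viscosity_cP = viscosity_cP)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all unit-system parameters must be finite and strictly positive")
  kB <- 1.380649e-23                     # J/K
  kBT <- kB * temperature_K
  sigma_m <- sigma_nm * 1e-9
  eta <- viscosity_cP * 1e-3             # Pa s
  us <- list(sigma_nm = sigma_nm, bp_per_bead = bp_per_bead,
             temperature_K = temperature_K, viscosity_cP = viscosity_cP,
             kBT_J = kBT,
             tau_B_s = 3 * pi * sigma_m^3 * eta / kBT,
             force_pN = kBT / sigma_m * 1e12)
  class(us) <- "UnitSystem"
  us
}

#' @export
print.UnitSystem <- function(x, ...) {
  cat("UnitSystem: sigma =", x$sigma_nm, "nm =", x$bp_per_bead / 1000,
      "kbp | T =", x$temperature_K, "K | eta =", x$viscosity_cP, "cP\n")
  cat(sprintf("  tau_B = %.4g ms   force unit = %.4g pN\n",
              x$tau_B_s * 1e3, x$force_pN))
  invisible(x)
}

#' Physical time per Brownian time unit
#'
#' Returns \eqn{\tau_B = 3\pi\sigma^3\eta/k_BT} in milliseconds. At the
#' default mapping this evaluates to about 2.73 ms; the commonly quoted
#' round figure is ~3 ms per simulation time unit. The unrounded value is
#' returned so that step-count conversions do not compound rounding.
#'
#' @param units a [unitSystem()]
#' @return milliseconds per \eqn{\tau_B}
#' @export
mapBrownianTime <- function(units = unitSystem()) {
  stopifnot(inherits(units, "UnitSystem"))
  units$tau_B_s * 1e3
}

#' Piconewtons per simulation force unit
#'
#' The simulation force unit is \eqn{k_BT/\sigma}; at the default mapping it
#' corresponds to about 0.207 pN (quoted as ~0.2 pN). Divide a physical
#' force in pN by this value to obtain simulation force units.
#'
#' @param units a [unitSystem()]
#' @return pN per \eqn{k_BT/\sigma}
#' @export
mapForceUnit <- function(units = unitSystem()) {
  stopifnot(inherits(units, "UnitSystem"))
  units$force_pN
}

#' Convert genomic length to beads and back
#'
#' One bead holds `units$bp_per_bead` base pairs (2 kbp by default), so e.g.
#' loop sizes of 80/100/120 kbp map to 40/50/60 beads.
#'
#' @param kbp genomic length in kilobase pairs (non-negative)
#' @param beads bead count
#' @param units a [unitSystem()]
#' @return `bpToBeads`: bead count rounded to the nearest integer;
#'   `beadsToBp`: genomic length in kbp.
#' @export
bpToBeads <- function(kbp, units = unitSystem()) {
  stopifnot(inherits(units, "UnitSystem"))
  if (any(kbp < 0)) stop("genomic length must be non-negative")
  as.integer(round(kbp * 1000 / units$bp_per_bead))
}

#' @rdname bpToBeads
#' @export
beadsToBp <- function(beads, units = unitSystem()) {
  stopifnot(inherits(units, "UnitSystem"))
  beads * units$bp_per_bead / 1000
}

#' Simulation run configuration
#'
#' Bundles every tunable of a simulation run: loop statistics, the bounded
#' ("soft") chromatin-chromatin repulsion amplitude `A_kBT` standing in for
#' topoisomerase-II strand passage (small A = high topo II activity), bridge
#' numbers and affinities, integrator settings and protocol phase durations.
#' Default parameter values reproduce the wild-type study conditions: mean
#' loop 40 beads (80 kbp), A = 10 kBT, 500 bridges per 350 loops (scaled
#' proportionally when `n_loops` differs), bridge-chromatin attraction
#' 3 kBT, bridge-anchor 8 kBT, bridge-bridge purely repulsive.
#'
#' @param loop_mode "uniform" or "poisson" loop-length statistics
#' @param L_loop_beads mean loop length in beads (40/50/60 = 80/100/120 kbp)
#' @param n_loops number of loops (full-scale runs use 300-400)
#' @param A_kBT soft-repulsion amplitude in kBT (1, 10 or 100)
#' @param n_bridges number of bridging condensins; `NA` scales the reference
#'   count of 500 bridges per 350 loops to `n_loops`
#' @param eps_weak_kBT bridge-chromatin attraction (kBT)
#' @param eps_strong_kBT bridge-anchor attraction (kBT)
#' @param eps_bridge_bridge_kBT bridge-bridge steric amplitude (kBT)
#' @param dt_tau integrator time step in \eqn{\tau} (default 0.01)
#' @param gamma friction coefficient (default 1, so
#'   \eqn{\tau_{LJ}=\tau_{dec}=\tau_B=1})
#' @param seed integer RNG seed for the whole run
#' @param box_side_sigma cubic box side; `NA` = auto-size from the topology
#' @param scenario one of "control", "condI_KO", "condII_KO", "cfs_removal",
#'   "cfs_merge", "sisters"
#' @param phase_durations named numeric, durations in \eqn{\tau_B} of the
#'   steric equilibration and the bridging (compaction) phase
#' @param min_loop_beads smallest admissible loop (Poisson truncation)
#' @return object of class `RunConfig`
#' @export
runConfig <- function(loop_mode = c("uniform", "poisson"),
                      L_loop_beads = 40L, n_loops = 350L, A_kBT = 10,
                      n_bridges = NA_integer_, eps_weak_kBT = 3,
                      eps_strong_kBT = 8, eps_bridge_bridge_kBT = 1,
                      dt_tau = 0.01, gamma = 1, seed = 1L,
                      box_side_sigma = NA_real_,
                      scenario = c("control", "condI_KO", "condII_KO",
                                   "cfs_removal", "cfs_merge", "sisters"),
                      phase_durations = c(equilibration = 100,
                                          compaction = 1000),
                      min_loop_beads = 5L) {
  loop_mode <- match.arg(loop_mode)
  scenario <- match.arg(scenario)
  if (is.na(n_bridges)) n_bridges <- as.integer(round(500 * n_loops / 350))
  cfg <- list(schema_version = 1L, loop_mode = loop_mode,
              L_loop_beads = as.integer(L_loop_beads),
              n_loops = as.integer(n_loops), A_kBT = A_kBT,
              n_bridges = as.integer(n_bridges),
              eps_weak_kBT = eps_weak_kBT, eps_strong_kBT = eps_strong_kBT,
              eps_bridge_bridge_kBT = eps_bridge_bridge_kBT,
              dt_tau = dt_tau, gamma = gamma, seed = as.integer(seed),
              box_side_sigma = box_side_sigma, scenario = scenario,
              phase_durations = phase_durations,
              min_loop_beads = as.integer(min_loop_beads))
  validateRunConfig(cfg)
  class(cfg) <- "RunConfig"
  cfg
}

validateRunConfig <- function(cfg) {
  if (cfg$L_loop_beads < cfg$min_loop_beads)
    stop("L_loop_beads must be at least the minimum loop size (",
         cfg$min_loop_beads, " beads)")
  if (cfg$n_loops < 1L) stop("n_loops must be >= 1")
  eps <- c(cfg$A_kBT, cfg$eps_weak_kBT, cfg$eps_strong_kBT,
           cfg$eps_bridge_bridge_kBT)
  if (any(eps < 0)) stop("interaction amplitudes must be non-negative")
  if (cfg$dt_tau <= 0) stop("dt_tau must be positive")
  if (cfg$gamma < 0) stop("gamma must be non-negative")
  if (cfg$n_bridges < 0) stop("n_bridges must be non-negative")
  if (any(cfg$phase_durations < 0)) stop("phase durations must be >= 0")
  invisible(cfg)
}

#' @export
print.RunConfig <- function(x, ...) {
  cat("RunConfig:", x$loop_mode, "loops |", x$n_loops, "loops x mean",
      x$L_loop_beads, "beads | A =", x$A_kBT, "kBT |", x$n_bridges,
      "bridges | scenario:", x$scenario, "| seed", x$seed, "\n")
  invisible(x)
}

#' Read / write a run configuration
#'
#' Run configurations are stored as a flat declarative key-value document
#' (YAML) carrying an embedded schema version, so that every
#' figure-generating run can be frozen and replayed exactly.
#'
#' @param path file path
#' @param cfg a [runConfig()]
#' @return `readRunConfig` returns a `RunConfig`; `writeRunConfig` returns
#'   `path` invisibly.
#' @export
writeRunConfig <- function(cfg, path) {
  stopifnot(inherits(cfg, "RunConfig"))
  x <- unclass(cfg)
  x$phase_durations <- as.list(x$phase_durations)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname writeRunConfig
#' @export
readRunConfig <- function(path) {
  x <- yaml::read_yaml(path)
  if (is.null(x$schema_version))
    stop("not a run configuration file (no schema_version key): ", path)
  pd <- unlist(x$phase_durations)
  cfg <- runConfig(loop_mode = x$loop_mode, L_loop_beads = x$L_loop_beads,
                   n_loops = x$n_loops, A_kBT = x$A_kBT,
                   n_bridges = x$n_bridges, eps_weak_kBT = x$eps_weak_kBT,
                   eps_strong_kBT = x$eps_strong_kBT,
                   eps_bridge_bridge_kBT = x$eps_bridge_bridge_kBT,
                   dt_tau = x$dt_tau, gamma = x$gamma, seed = x$seed,
                   box_side_sigma = if (is.null(x$box_side_sigma))
                     NA_real_ else x$box_side_sigma,
                   scenario = x$scenario, phase_durations = pd,
                   min_loop_beads = x$min_loop_beads)
  cfg
}
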