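#' Force field for the looped-chromosome model
#'
#' Assembles all bonded parameters and the species-pair interaction table.
#' Non-bonded chromatin-chromatin (and anchor) pairs repel through the
#' bounded soft potential \eqn{U = A[1 + \cos(\pi r/r_c)]} with
#' \eqn{r_c = 2^{1/6}\sigma}: because the barrier is finite (\eqn{2A} at
#' full overlap), strands can pass through each other, emulating
#' topoisomerase II action. Bridges attract chromatin via a truncated,
#' energy-shifted Lennard-Jones potential (weak, \eqn{\epsilon = 3 k_BT})
#' and loop anchors strongly (\eqn{\epsilon = 8 k_BT}); bridge-bridge
#' contacts are purely repulsive (WCA, \eqn{\epsilon = 1 k_BT}).
#'
#' A Lennard-Jones potential truncated exactly at its minimum
#' \eqn{2^{1/6}\sigma} exerts no attractive force, so the attractive
#' bridge pairs use a cutoff of `attr_cutoff` (1.8 \eqn{\sigma} by default)
#' with the energy shifted to zero there — the standard convention in
#' bridging-induced-attraction models; only the bridge-bridge term keeps the
#' WCA cutoff. See the methods vignette for the discussion of this choice.
#'
#' Bonded terms: harmonic chain bonds \eqn{U = K(r-r_0)^2} with
#' \eqn{K = 100 k_BT/\sigma^2}, \eqn{r_0 = 1.1\sigma}; loop-closure springs
#' with the same stiffness and rest length \eqn{r_1 = 1.8\sigma};
#' Kratky-Porod bending \eqn{U = K_{BEND}(1+\cos\phi)} with
#' \eqn{K_{BEND} = 3 k_BT} (persistence length ~3\eqn{\sigma} = 60 nm).
#'
#' @param A soft-repulsion amplitude in kBT (1/10/100)
#' @param eps_weak bridge-chromatin attraction (kBT)
#' @param eps_strong bridge-anchor attraction (kBT)
#' @param eps_bridge_bridge bridge-bridge repulsion amplitude (kBT)
#' @param attr_cutoff cutoff of the attractive bridge LJ terms (sigma)
#' @param bridging if `FALSE`, bridges interact with the polymer purely
#'   sterically (WCA) — the pre-compaction phase
#' @param K,r0 chain-bond stiffness (kBT/sigma^2) and rest length (sigma)
#' @param K_backbone,r1 loop-spring stiffness and rest length
#' @param K_bend bending modulus (kBT)
#' @return object of class `ForceField` holding the bonded constants and a
#'   symmetric `pair_table` data frame keyed by species pair
#' @export
forceField <- function(A = 10, eps_weak = 3, eps_strong = 8,
                       eps_bridge_bridge = 1, attr_cutoff = 1.8,
                       bridging = TRUE, K = 100, r0 = 1.1,
                       K_backbone = 100, r1 = 1.8, K_bend = 3) {
  rc_soft <- 2^(1/6)
  wca <- 2^(1/6)
  pt <- rbind(
    data.frame(s1 = "chromatin", s2 = "chromatin", kind = "soft",
               epsilon = A, cutoff = rc_soft, shifted = FALSE),
    data.frame(s1 = "chromatin", s2 = "anchor", kind = "soft",
               epsilon = A, cutoff = rc_soft, shifted = FALSE),
    data.frame(s1 = "anchor", s2 = "anchor", kind = "soft",
               epsilon = A, cutoff = rc_soft, shifted = FALSE),
    if (bridging) rbind(
      data.frame(s1 = "bridge", s2 = "chromatin", kind = "lj",
                 epsilon = eps_weak, cutoff = attr_cutoff, shifted = TRUE),
      data.frame(s1 = "bridge", s2 = "anchor", kind = "lj",
                 epsilon = eps_strong, cutoff = attr_cutoff, shifted = TRUE))
    else rbind(
      data.frame(s1 = "bridge", s2 = "chromatin", kind = "lj",
                 epsilon = eps_bridge_bridge, cutoff = wca, shifted = TRUE),
      data.frame(s1 = "bridge", s2 = "anchor", kind = "lj",
                 epsilon = eps_bridge_bridge, cutoff = wca, shifted = TRUE)),
    data.frame(s1 = "bridge", s2 = "bridge", kind = "lj",
               epsilon = eps_bridge_bridge, cutoff = wca, shifted = TRUE))
  ff <- list(A = A, rc_soft = rc_soft, K = K, r0 = r0, K_bend = K_bend,
             K_backbone = K_backbone, r1 = r1, attr_cutoff = attr_cutoff,
             bridging = bridging, pair_table = pt)
  class(ff) <- "ForceField"
  ff
}

#' @export
print.ForceField <- function(x, ...) {
  cat("ForceField: A =", x$A, "kBT | bridging",
      if (x$bridging) "ON" else "off (steric)", "\n")
  print(x$pair_table, row.names = FALSE)
  invisible(x)
}

speciesCode <- function(species) {
  code <- match(species, c("chromatin", "anchor", "bridge"))
  if (anyNA(code)) stop("unknown species tag")
  as.integer(code)
}

# 3x3 matrices (chromatin, anchor, bridge) consumed by the C++ engine
pairMatrices <- function(ff) {
  kind <- matrix(0L, 3, 3); eps <- matrix(0, 3, 3)
  cut <- matrix(0, 3, 3); shift <- matrix(0L, 3, 3)
  for (r in seq_len(nrow(ff$pair_table))) {
    row <- ff$pair_table[r, ]
    i <- speciesCode(row$s1); j <- speciesCode(row$s2)
    k <- if (row$kind == "soft") 1L else 2L
    kind[i, j] <- kind[j, i] <- k
    eps[i, j] <- eps[j, i] <- row$epsilon
    cut[i, j] <- cut[j, i] <- row$cutoff
    shift[i, j] <- shift[j, i] <- as.integer(row$shifted)
  }
  list(kind = kind, eps = eps, cut = cut, shift = shift)
}

lookupPair <- function(ff, s1, s2) {
  pt <- ff$pair_table
  hit <- (pt$s1 == s1 & pt$s2 == s2) | (pt$s1 == s2 & pt$s2 == s1)
  if (!any(hit)) return(NULL)
  pt[which(hit)[1], ]
}

#' Pairwise soft (bounded) repulsion
#'
#' \eqn{U(r) = A[1 + \cos(\pi r/r_c)]} for \eqn{r \le r_c}, zero beyond;
#' the energy is bounded by \eqn{2A} at full overlap, so chains can cross.
#'
#' @param r distance(s), sigma
#' @param A amplitude, kBT
#' @param rc cutoff (default \eqn{2^{1/6}})
#' @return list with vectors `energy` and `force` (\eqn{-dU/dr}, positive =
#'   repulsive)
#' @export
softPair <- function(r, A, rc = 2^(1/6)) {
  stopifnot(all(r >= 0))
  inside <- r <= rc
  e <- ifelse(inside, A * (1 + cos(pi * r / rc)), 0)
  f <- ifelse(inside, A * pi / rc * sin(pi * r / rc), 0)
  list(energy = e, force = f)
}

#' Harmonic bond
#'
#' \eqn{U(r) = K (r - r_{rest})^2}; note the stiffness convention carries no
#' factor 1/2.
#'
#' @param r distance(s)
#' @param K stiffness, kBT/sigma^2
#' @param rest rest length, sigma
#' @return list with `energy` and `force` (\eqn{-dU/dr})
#' @export
harmonicBond <- function(r, K = 100, rest = 1.1) {
  stopifnot(all(r >= 0))
  list(energy = K * (r - rest)^2, force = -2 * K * (r - rest))
}

#' Kratky-Porod bending term
#'
#' \eqn{U(\phi) = K_{BEND}(1 + \cos\phi)} where \eqn{\phi} is the angle at
#' bead `i` formed by beads `(i-1, i, i+1)`; a straight chain
#' (\eqn{\phi = \pi}) has zero energy, a hairpin (\eqn{\phi = 0}) costs
#' \eqn{2 K_{BEND}}.
#'
#' @param phi angle(s) in radians, in `[0, pi]`
#' @param K_bend bending modulus, kBT
#' @return list with `energy` and `torque` (\eqn{-dU/d\phi})
#' @export
kratkyPorod <- function(phi, K_bend = 3) {
  stopifnot(all(phi >= 0 & phi <= pi + 1e-12))
  list(energy = K_bend * (1 + cos(phi)), torque = K_bend * sin(phi))
}

#' Truncated (and optionally shifted) Lennard-Jones potential
#'
#' \eqn{U(r) = 4\epsilon[(\sigma/r)^{12} - (\sigma/r)^6]} for
#' \eqn{r \le r_c}, zero beyond; if `shifted`, the potential is raised so
#' \eqn{U(r_c) = 0}. With `cutoff = 2^{1/6}` and `shifted = TRUE` this is
#' the purely repulsive WCA potential.
#'
#' @param r distance(s), must be positive
#' @param epsilon well depth, kBT
#' @param cutoff cutoff distance, sigma
#' @param shifted shift energy to zero at the cutoff?
#' @param sigma LJ length parameter (default 1)
#' @return list with `energy` and `force` (\eqn{-dU/dr})
#' @export
ljCut <- function(r, epsilon, cutoff = 1.8, shifted = TRUE, sigma = 1) {
  if (any(r <= 0)) stop("overlap: Lennard-Jones force diverges at r = 0")
  sr6 <- (sigma / r)^6
  shift <- if (shifted) {
    s6 <- (sigma / cutoff)^6
    4 * epsilon * (s6^2 - s6)
  } else 0
  inside <- r <= cutoff
  e <- ifelse(inside, 4 * epsilon * (sr6^2 - sr6) - shift, 0)
  f <- ifelse(inside, 24 * epsilon * (2 * sr6^2 - sr6) / r, 0)
  list(energy = e, force = f)
}

#' Total potential energy, decomposed by term
#'
#' Reference implementation: a direct double loop over all bead pairs (no
#' neighbour list, no periodic images — intended for open-boundary
#' configurations and as an oracle for the compiled engine). Pairs joined
#' by a chain bond, loop spring or centromere spring are excluded from the
#' non-bonded terms.
#'
#' @param positions `n x 3` coordinate matrix (sigma)
#' @param topology a `ChromosomeTopology` (bridges may be appended: rows
#'   beyond `topology$n_beads` are taken as bridge particles)
#' @param ff a [forceField()]
#' @return named list: `soft`, `bonds`, `angles`, `loop_springs`,
#'   `centromere`, `pair_lj`, `total`
#' @export
totalEnergy <- function(positions, topology, ff) {
  n <- nrow(positions)
  if (n < topology$n_beads)
    stop("positions (", n, ") inconsistent with topology (",
         topology$n_beads, " beads)")
  species <- c(topology$species, rep("bridge", n - topology$n_beads))
  bondE <- function(pairs, K, rest) {
    if (is.null(pairs) || nrow(pairs) == 0) return(0)
    d <- positions[pairs[, 1], , drop = FALSE] -
      positions[pairs[, 2], , drop = FALSE]
    sum(harmonicBond(sqrt(rowSums(d^2)), K, rest)$energy)
  }
  e_bond <- bondE(topology$chain_bonds, ff$K, ff$r0)
  e_loop <- bondE(topology$loop_springs, ff$K_backbone, ff$r1)
  e_cent <- bondE(topology$centromere_springs, ff$K, ff$r0)
  e_ang <- 0
  if (nrow(topology$angle_triplets) > 0) {
    a <- positions[topology$angle_triplets[, 1], , drop = FALSE] -
      positions[topology$angle_triplets[, 2], , drop = FALSE]
    b <- positions[topology$angle_triplets[, 3], , drop = FALSE] -
      positions[topology$angle_triplets[, 2], , drop = FALSE]
    cphi <- rowSums(a * b) / (sqrt(rowSums(a^2)) * sqrt(rowSums(b^2)))
    cphi <- pmin(1, pmax(-1, cphi))
    e_ang <- sum(ff$K_bend * (1 + cphi))
  }
  excl <- rbind(topology$chain_bonds, topology$loop_springs,
                topology$centromere_springs)
  exclKey <- if (!is.null(excl) && nrow(excl) > 0)
    paste(pmin(excl[, 1], excl[, 2]), pmax(excl[, 1], excl[, 2])) else
      character(0)
  e_soft <- 0; e_lj <- 0
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (paste(i, j) %in% exclKey) next
        p <- lookupPair(ff, species[i], species[j])
        if (is.null(p)) next
        r <- sqrt(sum((positions[i, ] - positions[j, ])^2))
        if (p$kind == "soft") {
          e_soft <- e_soft + softPair(r, p$epsilon, p$cutoff)$energy
        } else {
          e_lj <- e_lj + ljCut(r, p$epsilon, p$cutoff, p$shifted)$energy
        }
      }
    }
  }
  out <- list(soft = e_soft, bonds = e_bond, angles = e_ang,
              loop_springs = e_loop, centromere = e_cent, pair_lj = e_lj)
  out$total <- sum(unlist(out))
  out
}

#' Export force-field coefficients in LAMMPS syntax
#'
#' Writes `pair_coeff` / `bond_coeff` / `angle_coeff` lines so that a run
#' can be reproduced in an external molecular-dynamics engine for
#' cross-validation. Types: 1 chromatin, 2 anchor, 3 bridge; bonds: 1 chain,
#' 2 loop spring, 3 centromere.
#'
#' @param ff a [forceField()]
#' @param path output file
#' @return `path`, invisibly
#' @export
writeForceFieldLammps <- function(ff, path) {
  lines <- c("# pair_style hybrid soft/cosine lj/cut; energies in kBT",
             sprintf("bond_coeff 1 %g %g", ff$K, ff$r0),
             sprintf("bond_coeff 2 %g %g", ff$K_backbone, ff$r1),
             sprintf("bond_coeff 3 %g %g", ff$K, ff$r0),
             sprintf("angle_coeff 1 %g", ff$K_bend))
  for (r in seq_len(nrow(ff$pair_table))) {
    p <- ff$pair_table[r, ]
    i <- speciesCode(p$s1); j <- speciesCode(p$s2)
    lines <- c(lines, sprintf("pair_coeff %d %d %s %g %g%s",
                              min(i, j), max(i, j),
                              if (p$kind == "soft") "soft/cosine" else
                                "lj/cut",
                              p$epsilon, p$cutoff,
                              if (p$kind != "soft" && p$shifted)
                                "  # energy-shifted" else ""))
  }
  writeLines(lines, path)
  invisible(path)
}
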