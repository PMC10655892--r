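#' Radius of gyration
#'
#' Root-mean-square distance of the beads from their centre of mass.
#' Coordinates must be unwrapped; if any chain bond of the supplied
#' topology spans more than half a box side the input looks wrapped and an
#' error is raised.
#'
#' @param positions `n x 3` matrix, unwrapped
#' @param box optional box side used only for the wrapped-coordinate check
#' @param topology optional topology whose chain bonds are checked
#' @return Rg in sigma
#' @export
radiusOfGyration <- function(positions, box = NULL, topology = NULL) {
  positions <- as.matrix(positions)
  if (nrow(positions) < 1) stop("need at least one bead")
  if (!is.null(box) && !is.null(topology) && box > 0 &&
      nrow(topology$chain_bonds) > 0) {
    d <- positions[topology$chain_bonds[, 1], , drop = FALSE] -
      positions[topology$chain_bonds[, 2], , drop = FALSE]
    if (any(sqrt(rowSums(d^2)) > box / 2))
      stop("bond longer than half the box: coordinates look wrapped")
  }
  centred <- sweep(positions, 2, colMeans(positions))
  sqrt(mean(rowSums(centred^2)))
}

#' Gyration-tensor shape descriptors
#'
#' Diagonalises the gyration tensor \eqn{S = N^{-1}\sum (r-\bar r)(r-\bar
#' r)^T}. The principal axis lengths are the square roots of its
#' eigenvalues, ordered \eqn{\lambda_1 \le \lambda_2 \le \lambda_3}, so
#' that \eqn{R_g^2 = \lambda_1^2+\lambda_2^2+\lambda_3^2}. The
#' acylindricity \eqn{Ac = \lambda_2 - \lambda_1} vanishes for an ideal
#' cylinder (or line) and for a sphere; equality of all three axes means a
#' spherical shape, \eqn{\lambda_1 = \lambda_2 < \lambda_3} an ideal
#' cylinder. Set `eigenvalue_axes = TRUE` to define the axes as the raw
#' eigenvalues instead (monotone-equivalent alternative).
#'
#' @param positions `n x 3` matrix, unwrapped
#' @param eigenvalue_axes use eigenvalues rather than their square roots
#' @return object of class `ShapeDescriptors`: `Rg`, `axes` (ascending),
#'   `Ac`, plus the principal axis unit vector `axis3`
#' @export
gyrationTensorShape <- function(positions, eigenvalue_axes = FALSE) {
  positions <- as.matrix(positions)
  centred <- sweep(positions, 2, colMeans(positions))
  S <- crossprod(centred) / nrow(positions)
  eig <- eigen(S, symmetric = TRUE)           # decreasing eigenvalues
  ev <- pmax(rev(eig$values), 0)
  axes <- if (eigenvalue_axes) ev else sqrt(ev)
  out <- list(Rg = sqrt(sum(ev)), axes = axes, Ac = axes[2] - axes[1],
              axis3 = eig$vectors[, 1])
  class(out) <- "ShapeDescriptors"
  out
}

#' @export
print.ShapeDescriptors <- function(x, ...) {
  cat(sprintf("Shape: Rg = %.3f | axes = (%.3f, %.3f, %.3f) | Ac = %.3f\n",
              x$Rg, x$axes[1], x$axes[2], x$axes[3], x$Ac))
  invisible(x)
}

#' Tangent-tangent correlation of a coarse-grained backbone
#'
#' Coarse-grains the ordered backbone (typically the loop-anchor beads in
#' chain order) by `stride` points, forms the tangent vectors joining
#' successive coarse-grained points, and returns the mean normalised dot
#' product as a function of separation along the backbone. Coarse-graining
#' by 5 or 10 smooths the local crumpling that bridging induces. A straight
#' backbone gives correlation 1 everywhere; a negative dip at intermediate
#' separations signals weak helicity.
#'
#' @param backbone `m x 3` matrix of backbone bead positions in chain order
#' @param stride coarse-graining stride (e.g. 5 or 10)
#' @param units optional [unitSystem()]; when given, separations are also
#'   reported in micrometres of backbone contour
#' @return data frame with `sep` (index separation), `distance_sigma`
#'   (mean contour distance), `correlation`, and `distance_um` if `units`
#' @export
tangentCorrelation <- function(backbone, stride = 5L, units = NULL) {
  backbone <- as.matrix(backbone)
  m <- nrow(backbone)
  if (m < 2L * stride) stop("stride too large for this backbone")
  cg <- backbone[seq(1L, m, by = stride), , drop = FALSE]
  tv <- diff(cg)
  len <- sqrt(rowSums(tv^2))
  keep <- len > 1e-12
  tv <- tv[keep, , drop = FALSE] / len[keep]
  nt <- nrow(tv)
  meanseg <- mean(len[keep])
  sep <- seq_len(nt - 1L)
  corr <- vapply(sep, function(d) {
    i <- seq_len(nt - d)
    mean(rowSums(tv[i, , drop = FALSE] * tv[i + d, , drop = FALSE]))
  }, numeric(1))
  out <- data.frame(sep = sep, distance_sigma = sep * meanseg,
                    correlation = corr)
  if (!is.null(units))
    out$distance_um <- out$distance_sigma * units$sigma_nm * 1e-3
  out
}

#' Fit an exponential decay length to a tangent correlation
#'
#' Least-squares fit of `log(correlation)` against contour distance over
#' the initial positive-correlation range; returns the persistence length
#' in sigma (and nm if a unit system is given).
#'
#' @param corr data frame from [tangentCorrelation()]
#' @param max_sep largest separation (in segments) used in the fit
#' @param units optional [unitSystem()]
#' @return list with `lp_sigma` and (optionally) `lp_nm`
#' @export
fitPersistenceLength <- function(corr, max_sep = 10L, units = NULL) {
  use <- corr$sep <= max_sep & corr$correlation > 0
  if (sum(use) < 2) stop("not enough positive correlation points to fit")
  fit <- stats::lm(log(correlation) ~ 0 + distance_sigma, data = corr[use, ])
  lp <- -1 / stats::coef(fit)[[1]]
  out <- list(lp_sigma = lp)
  if (!is.null(units)) out$lp_nm <- lp * units$sigma_nm
  out
}

#' Contact probability versus genomic separation
#'
#' For each trajectory frame, counts polymer bead pairs within
#' `contact_cutoff` and tabulates them by chain separation `s`; P(s) is the
#' number of contacts at separation s divided by the number of pairs at
#' that separation (times frames), binned log-uniformly. A power law is
#' fitted on the log-log curve over `fit_range`. Mitotic chromosomes show
#' \eqn{P(s) \sim s^{-1/2}} at intermediate s.
#'
#' @param trajectory a `Trajectory` (or a single `n x 3` matrix)
#' @param n_polymer number of polymer beads (in chain order at the start of
#'   each frame); defaults to all beads
#' @param contact_cutoff contact distance (sigma), default 3.5
#' @param bins_per_decade log-binning density
#' @param fit_range numeric length-2, kbp range for the exponent fit;
#'   `NULL` picks the intermediate decade from 100 kbp to one tenth of the
#'   polymer length
#' @param units a [unitSystem()] for the bead-to-kbp conversion
#' @return object of class `ContactCurve`: data frame `curve` (`s_kbp`,
#'   `P`), `fit_exponent`, `fit_range`
#' @export
contactProbability <- function(trajectory, n_polymer = NULL,
                               contact_cutoff = 3.5, bins_per_decade = 8,
                               fit_range = NULL, units = unitSystem()) {
  frames <- if (inherits(trajectory, "Trajectory")) trajectory$frames
            else list(as.matrix(trajectory))
  if (length(frames) < 1) stop("need at least one frame")
  n <- nrow(frames[[1]])
  if (is.null(n_polymer)) n_polymer <- n
  counts <- numeric(n_polymer)
  for (fr in frames)
    counts <- counts + .contact_hist(fr, as.integer(n_polymer),
                                     contact_cutoff)
  s <- seq_len(n_polymer - 1L)
  contacts <- counts[-1]                        # counts[1] is s = 0 (unused)
  pairs <- (n_polymer - s) * length(frames)
  kbp_per_bead <- units$bp_per_bead / 1000
  s_kbp <- s * kbp_per_bead
  # log-uniform bins
  edges <- 10^seq(log10(kbp_per_bead * 0.999),
                  log10(max(s_kbp) * 1.001),
                  by = 1 / bins_per_decade)
  bin <- findInterval(s_kbp, edges)
  agg_c <- tapply(contacts, bin, sum)
  agg_p <- tapply(pairs, bin, sum)
  mid <- tapply(s_kbp, bin, function(z) exp(mean(log(z))))
  curve <- data.frame(s_kbp = as.numeric(mid),
                      P = as.numeric(agg_c / agg_p))
  curve <- curve[order(curve$s_kbp), ]
  if (is.null(fit_range))
    fit_range <- c(100, max(400, n_polymer * kbp_per_bead / 10))
  use <- curve$s_kbp >= fit_range[1] & curve$s_kbp <= fit_range[2] &
    curve$P > 0
  fit_exponent <- NA_real_
  if (sum(use) >= 3)
    fit_exponent <- stats::coef(stats::lm(log10(P) ~ log10(s_kbp),
                                          data = curve[use, ]))[[2]]
  out <- list(curve = curve, fit_exponent = fit_exponent,
              fit_range = fit_range, contact_cutoff = contact_cutoff)
  class(out) <- "ContactCurve"
  out
}

#' @export
print.ContactCurve <- function(x, ...) {
  cat(sprintf("ContactCurve: %d bins | fitted exponent %.3f over %g-%g kbp\n",
              nrow(x$curve), x$fit_exponent, x$fit_range[1], x$fit_range[2]))
  invisible(x)
}

#' Single-linkage clustering of bridge particles
#'
#' Connected components of the graph joining bridges closer than
#' `linkage_cutoff` (1.3 sigma by default, slightly beyond the WCA contact
#' distance \eqn{2^{1/6}\sigma}); implemented with union-find.
#'
#' @param bridge_positions `n x 3` matrix
#' @param linkage_cutoff linkage distance (sigma)
#' @return object of class `ClusterStats`: `cluster_sizes`, `N_c`
#'   (cluster count), `S_c` (mean size), `membership`
#' @export
clusterBridges <- function(bridge_positions, linkage_cutoff = 1.3) {
  bridge_positions <- as.matrix(bridge_positions)
  n <- nrow(bridge_positions)
  if (n == 0)
    return(structure(list(cluster_sizes = integer(0), N_c = 0L,
                          S_c = NA_real_, membership = integer(0)),
                     class = "ClusterStats"))
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  if (n > 1) {
    prs <- neighborPairs(bridge_positions, box = 0,
                         cutoff = linkage_cutoff, skin = 0)
    if (nrow(prs) > 0) {
      d <- bridge_positions[prs[, 1], , drop = FALSE] -
        bridge_positions[prs[, 2], , drop = FALSE]
      ok <- rowSums(d^2) < linkage_cutoff^2
      for (q in which(ok)) {
        a <- find(prs[q, 1]); b <- find(prs[q, 2])
        if (a != b) parent[a] <- b
      }
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  membership <- match(root, unique(root))
  sizes <- as.integer(table(membership))
  structure(list(cluster_sizes = sizes, N_c = length(sizes),
                 S_c = mean(sizes), membership = membership),
            class = "ClusterStats")
}

#' @export
print.ClusterStats <- function(x, ...) {
  cat("ClusterStats:", x$N_c, "clusters | mean size",
      signif(x$S_c, 4), "\n")
  invisible(x)
}

#' Mean bridge valence
#'
#' Average number of polymer (chromatin + anchor) beads within `range` of a
#' bridge centre; multivalent binding shows up as a valence around 3 in the
#' compacted state (range 1.1 sigma = 22 nm at the default mapping).
#'
#' @param bridge_positions `nb x 3` matrix
#' @param polymer_positions `np x 3` matrix
#' @param range capture radius (sigma)
#' @return mean valence (0 if there are no bridges)
#' @export
bridgeValence <- function(bridge_positions, polymer_positions, range = 1.1) {
  bridge_positions <- as.matrix(bridge_positions)
  polymer_positions <- as.matrix(polymer_positions)
  nb <- nrow(bridge_positions)
  if (nb == 0) return(NA_real_)
  all <- rbind(polymer_positions, bridge_positions)
  np <- nrow(polymer_positions)
  prs <- neighborPairs(all, box = 0, cutoff = range, skin = 0)
  cnt <- numeric(nb)
  if (nrow(prs) > 0) {
    d <- all[prs[, 1], , drop = FALSE] - all[prs[, 2], , drop = FALSE]
    ok <- rowSums(d^2) <= range^2
    prs <- prs[ok, , drop = FALSE]
    cross <- xor(prs[, 1] > np, prs[, 2] > np)
    prs <- prs[cross, , drop = FALSE]
    if (nrow(prs) > 0) {
      b <- pmax(prs[, 1], prs[, 2]) - np
      tb <- table(b)
      cnt[as.integer(names(tb))] <- as.integer(tb)
    }
  }
  mean(cnt)
}

#' Chromosome extension and width
#'
#' Extension is the distance between two designated end beads; width is
#' twice the RMS radial distance of the beads from the principal
#' (\eqn{\lambda_3}) gyration axis through the centre of mass, so a
#' cylindrical shell of radius R has width ~2R.
#'
#' @param positions `n x 3` polymer coordinates, unwrapped
#' @param ends length-2 integer vector of end bead indices
#' @return list with `extension` and `width` (sigma)
#' @export
extensionAndWidth <- function(positions, ends) {
  positions <- as.matrix(positions)
  if (any(ends < 1) || any(ends > nrow(positions)))
    stop("invalid end bead indices")
  extension <- sqrt(sum((positions[ends[1], ] - positions[ends[2], ])^2))
  sh <- gyrationTensorShape(positions)
  centred <- sweep(positions, 2, colMeans(positions))
  axial <- centred %*% sh$axis3
  perp2 <- rowSums(centred^2) - axial^2
  list(extension = extension, width = 2 * sqrt(mean(pmax(perp2, 0))))
}

#' Local backbone stiffness
#'
#' Mean cosine of the turning angle between successive segments of the
#' coarse-grained backbone: 1 for a straight backbone, ~0 for a random
#' walk or right-angle turns.
#'
#' @param backbone `m x 3` backbone positions in chain order
#' @param stride coarse-graining stride
#' @return mean cos(theta)
#' @export
localStiffness <- function(backbone, stride = 5L) {
  backbone <- as.matrix(backbone)
  cg <- backbone[seq(1L, nrow(backbone), by = stride), , drop = FALSE]
  if (nrow(cg) < 3L) stop("need at least 3 coarse-grained points")
  tv <- diff(cg)
  len <- sqrt(rowSums(tv^2))
  keep <- len > 1e-12
  tv <- tv[keep, , drop = FALSE] / len[keep]
  if (nrow(tv) < 2L) stop("degenerate backbone")
  mean(rowSums(tv[-nrow(tv), , drop = FALSE] * tv[-1, , drop = FALSE]))
}

#' Simulated FISH probe distance
#'
#' Time-averaged 3D distance between the centres of mass of two bead-index
#' intervals (the simulated probe regions).
#'
#' @param trajectory a `Trajectory` or a single coordinate matrix
#' @param region_a,region_b integer vectors of bead indices
#' @return mean centre-of-mass distance (sigma)
#' @export
probeDistance <- function(trajectory, region_a, region_b) {
  if (length(region_a) == 0 || length(region_b) == 0)
    stop("probe regions must be non-empty")
  frames <- if (inherits(trajectory, "Trajectory")) trajectory$frames
            else list(as.matrix(trajectory))
  d <- vapply(frames, function(fr) {
    ca <- colMeans(fr[region_a, , drop = FALSE])
    cb <- colMeans(fr[region_b, , drop = FALSE])
    sqrt(sum((ca - cb)^2))
  }, numeric(1))
  mean(d)
}

#' Bottlebrush bristle repulsion estimate
#'
#' Scaling estimate of the repulsive force per unit axial length between
#' neighbouring bristles of a bottlebrush:
#' \eqn{F \propto (T/\lambda)\sqrt{N a/(\pi\lambda)}}, with axial bristle
#' spacing \eqn{\lambda}, monomer size `a` and `N` monomers per bristle.
#' The proportionality constant is set to one, so the value is meaningful
#' only in ratios. Because \eqn{\sqrt{N}} is concave, Poisson-distributed
#' bristle lengths give a smaller mean repulsion than uniform bristles at
#' the same mean — which is why variable loops compact further.
#'
#' @param T_ temperature (energy units)
#' @param lambda axial spacing between bristles
#' @param a monomer size
#' @param N monomers per bristle (vectorised)
#' @return relative force per unit axial length
#' @export
bristleRepulsion <- function(T_ = 1, lambda = 1, a = 1, N) {
  stopifnot(T_ > 0, lambda > 0, a > 0, all(N >= 0))
  (T_ / lambda) * sqrt(N * a / (pi * lambda))
}
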