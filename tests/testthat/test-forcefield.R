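test_that("soft potential matches its closed form and stays bounded", {
  rc <- 2^(1/6)
  for (A in c(1, 10, 100)) {
    expect_equal(softPair(rc, A)$energy, 0, tolerance = 1e-12)
    expect_equal(softPair(0, A)$energy, 2 * A)
    expect_equal(softPair(rc / 2, A)$energy, A, tolerance = 1e-12)
    r <- seq(0, 2, by = 0.01)
    e <- softPair(r, A)$energy
    expect_true(all(e <= 2 * A + 1e-12))   # crossable barrier
    expect_true(all(e[r > rc] == 0))
    expect_true(all(softPair(r, A)$force >= 0))  # purely repulsive
  }
})

test_that("harmonic bond is a symmetric well with the stated stiffness", {
  expect_equal(harmonicBond(1.1)$energy, 0)
  expect_equal(harmonicBond(2.1, K = 100, rest = 1.1)$energy, 100)
  d <- 0.37
  expect_equal(harmonicBond(1.1 + d)$energy, harmonicBond(1.1 - d)$energy)
})

test_that("Kratky-Porod term vanishes for straight chains", {
  expect_equal(kratkyPorod(pi)$energy, 0, tolerance = 1e-12)
  expect_equal(kratkyPorod(0, K_bend = 3)$energy, 6)
  expect_equal(kratkyPorod(pi / 2, K_bend = 3)$energy, 3)
})

test_that("truncated LJ honours cutoff, shift and the WCA limit", {
  rmin <- 2^(1/6)
  expect_equal(ljCut(rmin, 3, cutoff = 1.8, shifted = FALSE)$energy, -3,
               tolerance = 1e-12)
  expect_equal(ljCut(2.0, 3, cutoff = 1.8)$energy, 0)
  # WCA: zero at the cutoff, repulsive below
  r <- seq(0.9, rmin, by = 0.001)
  wca <- ljCut(r, 1, cutoff = rmin, shifted = TRUE)
  expect_equal(ljCut(rmin, 1, cutoff = rmin, shifted = TRUE)$energy, 0,
               tolerance = 1e-12)
  expect_true(all(wca$force >= -1e-9))
  expect_true(all(wca$energy >= -1e-12))
  expect_error(ljCut(0, 1), "overlap")
})

test_that("analytic forces equal minus the numerical energy gradient", {
  h <- 1e-7
  num <- function(f, r) -(f(r + h)$energy - f(r - h)$energy) / (2 * h)
  r <- c(0.7, 0.95, 1.05, 1.3, 1.7)
  expect_equal(softPair(r, 10)$force,
               num(function(z) softPair(z, 10), r), tolerance = 1e-6)
  expect_equal(harmonicBond(r)$force,
               num(function(z) harmonicBond(z), r), tolerance = 1e-6)
  expect_equal(ljCut(r, 3)$force,
               num(function(z) ljCut(z, 3), r), tolerance = 1e-5)
  phi <- c(0.3, 1.2, 2.5)
  expect_equal(kratkyPorod(phi)$torque,
               -(kratkyPorod(phi + h)$energy -
                   kratkyPorod(phi - h)$energy) / (2 * h),
               tolerance = 1e-6)
})

test_that("the pair table is symmetric and carries the default affinities", {
  ff <- forceField(A = 10)
  pick <- function(s1, s2) {
    pt <- ff$pair_table
    pt[(pt$s1 == s1 & pt$s2 == s2) | (pt$s1 == s2 & pt$s2 == s1), ]
  }
  expect_equal(pick("bridge", "chromatin")$epsilon, 3)
  expect_equal(pick("chromatin", "bridge")$epsilon, 3)   # swap-symmetric
  expect_equal(pick("bridge", "anchor")$epsilon, 8)
  expect_equal(pick("bridge", "bridge")$epsilon, 1)
  expect_equal(pick("bridge", "bridge")$cutoff, 2^(1/6)) # purely repulsive
  expect_equal(pick("anchor", "anchor")$epsilon, 10)     # soft amplitude A
  expect_gt(pick("bridge", "anchor")$cutoff, 2^(1/6))    # attraction acts
  # steric phase: no bridge-polymer attraction
  st <- forceField(A = 10, bridging = FALSE)
  bp <- st$pair_table[st$pair_table$s1 == "bridge" &
                        st$pair_table$s2 == "chromatin", ]
  expect_equal(bp$cutoff, 2^(1/6))
})

test_that("total energy is invariant under rigid motions and matches terms", {
  topo <- buildUniformBottlebrush(2, 8)
  set.seed(42)
  pos <- initBottlebrushCoords(topo, seed = 2) +
    matrix(rnorm(3 * topo$n_beads, sd = 0.05), ncol = 3)
  ff <- forceField(A = 10)
  e0 <- totalEnergy(pos, topo, ff)
  # translation
  e1 <- totalEnergy(pos + 5, topo, ff)
  expect_equal(e1$total, e0$total, tolerance = 1e-10)
  # rotation about z
  th <- 0.71
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  e2 <- totalEnergy(pos %*% R, topo, ff)
  expect_equal(e2$total, e0$total, tolerance = 1e-9)
  expect_equal(e0$total, e0$soft + e0$bonds + e0$angles + e0$loop_springs +
                 e0$centromere + e0$pair_lj)
})

test_that("degenerate configurations have the expected energies", {
  # single bead: nothing interacts
  one <- buildLinearChain(2)
  expect_equal(totalEnergy(rbind(c(0, 0, 0), c(1.1, 0, 0)), one,
                           forceField())$total, 0, tolerance = 1e-12)
  # straight chain at rest spacing: all terms vanish (non-bonded neighbours
  # sit beyond the soft cutoff)
  ch <- buildLinearChain(10)
  pos <- cbind(0, 0, (0:9) * 1.1)
  e <- totalEnergy(pos, ch, forceField(A = 100))
  expect_equal(e$total, 0, tolerance = 1e-12)
  expect_error(totalEnergy(pos[1:5, ], ch, forceField()), "inconsistent")
})

test_that("force-field export writes LAMMPS coefficient lines", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeForceFieldLammps(forceField(A = 10), path)
  lines <- readLines(path)
  expect_true(any(grepl("^bond_coeff 1 100 1.1", lines)))
  expect_true(any(grepl("^angle_coeff 1 3", lines)))
  expect_true(any(grepl("pair_coeff 2 3 lj/cut 8 1.8", lines)))
})
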