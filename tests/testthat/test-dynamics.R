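# small helper: ideal-gas state (interactions off via A = 0 and no bonds)
freeGasState <- function(n, box = 30, seed = 1) {
  topo <- list(n_beads = n, species = rep("chromatin", n),
               chain_bonds = matrix(integer(0), 0, 2),
               loop_springs = matrix(integer(0), 0, 2),
               angle_triplets = matrix(integer(0), 0, 3),
               loop_table = data.frame(anchor = integer(0),
                                       length = integer(0)),
               centromere_springs = NULL, n_chromatids = 1L,
               chromatid = rep(1L, n))
  class(topo) <- "ChromosomeTopology"
  pos <- withr::with_seed(seed, matrix(runif(3 * n, 0, box), ncol = 3))
  list(topo = topo, state = simulationState(pos, topo$species, box))
}

test_that("identical seeds give bit-identical trajectories", {
  fx <- makeFixture("tiny_bbp")
  st <- simulationState(fx$positions + fx$box / 2, fx$species, fx$box)
  ff <- forceField(A = 10)
  r1 <- langevinRun(st, fx$topology, ff, 200, seed = 5L, stride = 50L)
  r2 <- langevinRun(st, fx$topology, ff, 200, seed = 5L, stride = 50L)
  expect_identical(r1$state$positions, r2$state$positions)
  expect_identical(r1$trajectory$frames, r2$trajectory$frames)
  r3 <- langevinRun(st, fx$topology, ff, 200, seed = 6L, stride = 50L)
  expect_false(identical(r1$state$positions, r3$state$positions))
  # a restart reuses the continuous noise stream; the friction splitting
  # makes chunked and continuous runs agree to O(gamma dt), not bit-wise
  h <- langevinRun(st, fx$topology, ff, 100, seed = 5L)
  h2 <- langevinRun(h$state, fx$topology, ff, 100, seed = 5L)
  expect_equal(h2$state$positions, r1$state$positions, tolerance = 1e-2)
})

test_that("the thermostat reproduces equipartition on a 500-bead system", {
  fg <- freeGasState(500)
  st <- fg$state
  ff <- forceField(A = 0)
  kT <- numeric(0)
  for (k in 1:20) {
    out <- langevinRun(st, fg$topo, ff, 200, seed = 100L + k)
    st <- out$state
    if (k > 5) kT <- c(kT, mean(st$velocities^2))
  }
  expect_equal(mean(kT), 1, tolerance = 0.02)
})

test_that("free diffusion follows the Einstein relation", {
  fg <- freeGasState(300, box = 200)
  ff <- forceField(A = 0)
  warm <- langevinRun(fg$state, fg$topo, ff, 500, seed = 2L)
  out <- langevinRun(warm$state, fg$topo, ff, 4000, seed = 2L, stride = 400L)
  x0 <- warm$state$positions
  msd <- vapply(seq_along(out$trajectory$frames), function(k)
    mean(rowSums((out$trajectory$frames[[k]] - x0)^2)), numeric(1))
  t <- seq_along(msd) * 4
  # slope of MSD vs t -> 6 D = 6 kT / gamma = 6
  slope <- coef(lm(msd ~ t))[["t"]]
  expect_equal(slope, 6, tolerance = 0.15)
})

test_that("gamma = 0 recovers energy-conserving velocity-Verlet dynamics", {
  fx <- makeFixture("tiny_bbp")
  ff <- forceField(A = 10)
  st <- simulationState(fx$positions + fx$box / 2, fx$species, fx$box)
  # thermalise, then switch the bath off
  st <- langevinRun(st, fx$topology, ff, 2000, seed = 3L)$state
  e0 <- engineEval(st, fx$topology, ff)$energy
  tot0 <- sum(e0) + 0.5 * sum(st$velocities^2)
  out <- langevinRun(st, fx$topology, ff, 10000, dt = 0.002, gamma = 0,
                     seed = 3L)
  tot1 <- sum(out$energy)
  expect_lt(abs(tot1 - tot0) / abs(tot0), 1e-4)
})

test_that("neighbour-listed energies equal the brute-force double loop", {
  topo <- buildUniformBottlebrush(2, 10)
  ff <- forceField(A = 10)
  for (seed in 1:3) {
    pos <- withr::with_seed(seed,
      initBottlebrushCoords(topo, seed = seed) +
        matrix(rnorm(60, sd = 0.3), ncol = 3))
    nb <- withr::with_seed(seed + 10, matrix(runif(24, -4, 4), ncol = 3))
    allpos <- rbind(pos, nb) + 50
    st <- simulationState(allpos, c(topo$species, rep("bridge", 8)),
                          box = 100)
    ee <- engineEval(st, topo, ff)
    bf <- totalEnergy(st$positions, topo, ff)
    expect_equal(ee$energy[["pair"]], bf$soft + bf$pair_lj,
                 tolerance = 1e-10)
    expect_equal(ee$energy[["bond"]], bf$bonds + bf$loop_springs,
                 tolerance = 1e-10)
    expect_equal(ee$energy[["angle"]], bf$angles, tolerance = 1e-10)
  }
})

test_that("engine forces are exact gradients of the engine energy", {
  topo <- buildUniformBottlebrush(3, 8)
  pos <- initBottlebrushCoords(topo, seed = 5) + 20
  nb <- withr::with_seed(4, matrix(runif(9, 15, 25), ncol = 3))
  st <- simulationState(rbind(pos, nb),
                        c(topo$species, rep("bridge", 3)), box = 40)
  ff <- forceField(A = 10)
  an <- engineEval(st, topo, ff)
  h <- 1e-6
  for (i in c(1L, 8L, 17L, 24L, 26L)) for (k in 1:3) {
    pp <- st$positions; pp[i, k] <- pp[i, k] + h
    pm <- st$positions; pm[i, k] <- pm[i, k] - h
    num <- -(sum(engineEval(simulationState(pp, st$species, st$box),
                            topo, ff)$energy) -
               sum(engineEval(simulationState(pm, st$species, st$box),
                              topo, ff)$energy)) / (2 * h)
    expect_equal(an$forces[i, k], num, tolerance = 1e-5)
  }
})

test_that("neighbour pair lists are supersets within cutoff + skin", {
  # two beads straddling the cutoff
  close <- rbind(c(1, 1, 1), c(1 + 1.99, 1, 1))
  prs <- neighborPairs(close, box = 20, cutoff = 2, skin = 0.3)
  expect_equal(nrow(prs), 1L)
  far <- rbind(c(1, 1, 1), c(1 + 2.4, 1, 1))
  expect_equal(nrow(neighborPairs(far, box = 20, cutoff = 2, skin = 0.3)),
               0L)
  # periodic image pair
  per <- rbind(c(0.5, 5, 5), c(19.5, 5, 5))
  expect_equal(nrow(neighborPairs(per, box = 20, cutoff = 2, skin = 0.3)),
               1L)
  expect_error(neighborPairs(close, box = 3, cutoff = 2, skin = 0.3),
               "minimum-image")
  # superset property against a direct distance scan
  pos <- withr::with_seed(9, matrix(runif(300, 0, 15), ncol = 3))
  prs <- neighborPairs(pos, box = 15, cutoff = 2.5, skin = 0.4)
  key <- paste(prs[, 1], prs[, 2])
  d <- as.matrix(dist(pos))        # box 15, max distance ~13 > box/2 wraps
  for (i in 1:99) for (j in (i + 1):100) {
    dv <- abs(pos[i, ] - pos[j, ])
    dv <- pmin(dv, 15 - dv)
    if (sqrt(sum(dv^2)) < 2.5)
      expect_true(paste(i, j) %in% key || paste(j, i) %in% key)
  }
})

test_that("constant end forces are equal, opposite and along the axis", {
  st <- simulationState(rbind(c(0, 0, 0), c(3, 4, 0)),
                        rep("chromatin", 2), box = 0)
  pc <- pullingConfig(5, 1, 2)
  f <- applyEndForces(st, pc)
  expect_equal(colSums(f), c(0, 0, 0))
  expect_equal(f[1, ], 5 * c(-3 / 5, -4 / 5, 0))
  expect_error(pullingConfig(5, 2, 2), "differ")
})

test_that("a pulled dumbbell stretches to the force-balance extension", {
  topo <- buildLinearChain(2)
  st <- simulationState(rbind(c(10, 10, 10), c(11.1, 10, 10)),
                        topo$species, box = 30)
  ff <- forceField(A = 0)
  pull <- pullingConfig(10, 1, 2)
  st <- langevinRun(st, topo, ff, 2000, seed = 1L, pulling = pull)$state
  ext <- numeric(0)
  for (k in 1:60) {
    out <- langevinRun(st, topo, ff, 100, seed = 1L, pulling = pull)
    st <- out$state
    ext <- c(ext, sqrt(sum((st$positions[1, ] - st$positions[2, ])^2)))
  }
  # U = K(r - r0)^2 balanced against F: r* = r0 + F / (2K) = 1.15, plus a
  # small thermal broadening of order kT/(K r*)
  expect_equal(mean(ext), 1.15 + 1 / (100 * 1.15), tolerance = 0.02)
  # F = 0 reduces to the unpulled trajectory at equal seed
  a <- langevinRun(st, topo, ff, 50, seed = 2L,
                   pulling = pullingConfig(0, 1, 2))
  b <- langevinRun(st, topo, ff, 50, seed = 2L)
  expect_identical(a$state$positions, b$state$positions)
})

test_that("a free semiflexible chain develops the expected stiffness", {
  # bonds + Kratky-Porod only (no excluded volume): persistence length of
  # roughly 3 sigma = 60 nm at the default mapping; the ensemble-averaged
  # tangent correlation also matches the transfer-matrix law point-wise
  lp <- persistenceLengthRun(n_chains = 4L, production = 400, seed = 20L)
  expect_equal(lp$lp_nm, 60, tolerance = 0.15)
  theory <- (1 / tanh(3) - 1 / 3)^(1:4)
  expect_equal(lp$correlation$correlation[1:4], theory, tolerance = 0.06)
})
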