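test_that("radius of gyration matches direct evaluation", {
  expect_equal(radiusOfGyration(matrix(c(1, 2, 3), 1)), 0)
  two <- rbind(c(0, 0, 0), c(0, 0, 4))
  expect_equal(radiusOfGyration(two), 2)
  pos <- withr::with_seed(3, matrix(rnorm(150), ncol = 3))
  direct <- sqrt(mean(rowSums(sweep(pos, 2, colMeans(pos))^2)))
  expect_equal(radiusOfGyration(pos), direct, tolerance = 1e-12)
  # wrapped-coordinate detection through over-long bonds
  topo <- buildLinearChain(3)
  wrapped <- rbind(c(0.5, 0, 0), c(9.5, 0, 0), c(9, 0, 0))
  expect_error(radiusOfGyration(wrapped, box = 10, topology = topo),
               "wrapped")
})

test_that("gyration-tensor shapes classify line, sphere and cylinder", {
  rod <- makeFixture("rod")
  s <- gyrationTensorShape(rod$positions)
  expect_equal(s$axes[1], 0, tolerance = 1e-9)
  expect_equal(s$axes[2], 0, tolerance = 1e-9)
  expect_equal(s$Ac, 0, tolerance = 1e-9)
  blob <- makeFixture("blob")           # uniform sphere surface
  s <- gyrationTensorShape(blob$positions)
  expect_equal(s$axes[1] / s$axes[3], 1, tolerance = 0.05)
  expect_lt(s$Ac / s$Rg, 0.05)
  # long cylinder shell: lambda1 = lambda2 << lambda3, Ac ~ 0
  t <- seq(0, 60 * pi, length.out = 3000)
  cyl <- cbind(2 * cos(t), 2 * sin(t), seq(0, 80, length.out = 3000))
  s <- gyrationTensorShape(cyl)
  expect_equal(s$axes[1], s$axes[2], tolerance = 0.02)
  expect_gt(s$axes[3], 5 * s$axes[2])
  expect_lt(s$Ac / s$Rg, 0.01)
  # Rg^2 equals the sum of squared axis lengths on arbitrary clouds
  pos <- withr::with_seed(8, matrix(rnorm(90), ncol = 3))
  s <- gyrationTensorShape(pos)
  expect_equal(s$Rg^2, sum(s$axes^2), tolerance = 1e-12)
  expect_equal(s$Rg, radiusOfGyration(pos), tolerance = 1e-12)
})

test_that("shape observables are invariant under rigid motions", {
  pos <- withr::with_seed(5, matrix(rnorm(120), ncol = 3))
  th <- 1.1
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  a <- gyrationTensorShape(pos)
  b <- gyrationTensorShape(pos %*% R + 7)
  expect_equal(a$axes, b$axes, tolerance = 1e-10)
  expect_equal(a$Ac, b$Ac, tolerance = 1e-10)
})

test_that("tangent correlations recover straight-line and helical forms", {
  line <- cbind(0, 0, seq_len(40) * 1.8)
  tc <- tangentCorrelation(line, stride = 2L)
  expect_true(all(abs(tc$correlation - 1) < 1e-12))
  # analytic helix: chord correlation (Rc^2 cos(k d) + (c d)^2) /
  # (Rc^2 + (c d)^2) with Rc = 2 R sin(d/2)
  hx <- makeFixture("helix")
  n <- nrow(hx$positions)
  dstep <- 8 * pi / (n - 1)
  for (stride in c(5L, 10L)) {
    tc <- tangentCorrelation(hx$positions, stride = stride)
    d <- stride * dstep
    Rc <- 2 * 2 * sin(d / 2)
    cc <- 6 / (2 * pi)
    expected <- (Rc^2 * cos(tc$sep * d) + (cc * d)^2) /
      (Rc^2 + (cc * d)^2)
    expect_equal(tc$correlation, expected, tolerance = 1e-8)
  }
  expect_error(tangentCorrelation(line, stride = 30L), "stride")
  # micrometre conversion
  tc <- tangentCorrelation(line, stride = 2L, units = unitSystem())
  expect_equal(tc$distance_um, tc$distance_sigma * 0.02)
})

test_that("contact probability is normalised and finds ideal-chain scaling", {
  # bonded neighbours always in contact
  chain <- cbind(0, 0, seq_len(200) * 1.1)
  cc <- contactProbability(chain, contact_cutoff = 1.2,
                           fit_range = c(2, 20))
  expect_true(all(cc$curve$P >= 0 & cc$curve$P <= 1))
  expect_equal(cc$curve$P[1], 1)
  # freely-jointed-chain ensemble decays as s^(-3/2)
  frames <- withr::with_seed(11, lapply(1:150, function(k) {
    steps <- matrix(rnorm(3 * 400), ncol = 3)
    steps <- steps / sqrt(rowSums(steps^2))
    apply(rbind(0, steps), 2, cumsum)
  }))
  traj <- trajectory(frames, seq_along(frames),
                     rep("chromatin", 401), box = 0)
  cc <- contactProbability(traj, contact_cutoff = 1.5,
                           fit_range = c(40, 400))
  expect_equal(cc$fit_exponent, -1.5, tolerance = 0.15)
})

test_that("bridge clustering equals graph connected components", {
  # all isolated
  iso <- withr::with_seed(2, matrix(runif(60, 0, 100), ncol = 3))
  cs <- clusterBridges(iso, linkage_cutoff = 1.3)
  expect_equal(cs$N_c, 20L)
  expect_true(all(cs$cluster_sizes == 1L))
  # one blob
  blob <- withr::with_seed(3, matrix(rnorm(60, sd = 0.3), ncol = 3))
  cs <- clusterBridges(blob, linkage_cutoff = 1.3)
  expect_equal(cs$N_c, 1L)
  expect_equal(cs$cluster_sizes, 20L)
  # arbitrary configuration vs an adjacency-matrix oracle
  skip_if_not_installed("igraph")
  pos <- withr::with_seed(7, matrix(runif(90, 0, 8), ncol = 3))
  cs <- clusterBridges(pos, linkage_cutoff = 1.3)
  adj <- as.matrix(dist(pos)) < 1.3
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)
  expect_equal(cs$N_c, comp$no)
  expect_equal(sort(cs$cluster_sizes), sort(unname(comp$csize)))
  expect_equal(sum(cs$cluster_sizes), 30L)
  # adding one linking particle between two clusters merges them
  pair <- rbind(c(0, 0, 0), c(2, 0, 0))
  expect_equal(clusterBridges(pair, 1.3)$N_c, 2L)
  expect_equal(clusterBridges(rbind(pair, c(1, 0, 0)), 1.3)$N_c, 1L)
})

test_that("bridge valence counts polymer beads in range", {
  lone <- matrix(c(0, 0, 0), 1)
  far <- matrix(c(50, 50, 50), 1)
  expect_equal(bridgeValence(lone, far), 0)
  # k beads placed at exactly distance 1.0
  for (k in c(1, 3, 5)) {
    ang <- 2 * pi * seq_len(k) / k
    beads <- cbind(cos(ang), sin(ang), 0)
    expect_equal(bridgeValence(matrix(0, 1, 3), beads, range = 1.1), k)
  }
})

test_that("extension and width describe rods and cylinder shells", {
  rod <- makeFixture("rod")$positions
  ew <- extensionAndWidth(rod, ends = c(1L, 50L))
  expect_equal(ew$extension, 49 * 1.1)
  expect_lt(ew$width, 1e-9)
  t <- seq(0, 40 * pi, length.out = 2000)
  R <- 3
  cyl <- cbind(R * cos(t), R * sin(t), seq(0, 60, length.out = 2000))
  ew <- extensionAndWidth(cyl, ends = c(1L, 2000L))
  expect_equal(ew$width, 2 * R, tolerance = 0.02)
  expect_error(extensionAndWidth(rod, ends = c(0L, 9L)), "invalid")
})

test_that("local stiffness distinguishes straight, kinked and random paths", {
  line <- cbind(0, 0, seq_len(30))
  expect_equal(localStiffness(line, stride = 1L), 1, tolerance = 1e-12)
  # staircase path turning 90 degrees at every bead
  steps <- matrix(0, 20, 3)
  steps[seq(1, 20, 2), 1] <- 1
  steps[seq(2, 20, 2), 2] <- 1
  sq <- apply(steps, 2, cumsum)
  expect_equal(localStiffness(sq, stride = 1L), 0, tolerance = 1e-12)
  rw <- withr::with_seed(21, {
    s <- matrix(rnorm(3 * 4000), ncol = 3)
    apply(s / sqrt(rowSums(s^2)), 2, cumsum)
  })
  expect_lt(abs(localStiffness(rw, stride = 1L)), 0.05)
  expect_error(localStiffness(line[1:2, ], 1L), "3 coarse-grained")
})

test_that("probe distances average centre-of-mass separations", {
  pos <- rbind(c(0, 0, 0), c(0, 0, 7))
  expect_equal(probeDistance(pos, 1L, 2L), 7)
  expect_equal(probeDistance(pos, 1L, 1L), 0)
  expect_error(probeDistance(pos, integer(0), 1L), "non-empty")
  frames <- list(pos, pos + 3)          # rigid shift leaves distance alone
  traj <- trajectory(frames, 1:2, rep("chromatin", 2), 0)
  expect_equal(probeDistance(traj, 1L, 2L), 7)
})

test_that("bristle repulsion scales as sqrt(N) / lambda^(3/2)", {
  f <- bristleRepulsion(N = 40)
  expect_equal(bristleRepulsion(N = 160), 2 * f)
  expect_equal(bristleRepulsion(lambda = 4, N = 40), f / 8)
  expect_equal(bristleRepulsion(T_ = 2, N = 40), 2 * f)
  # Jensen: concavity of sqrt makes the Poisson average smaller than the
  # uniform-loop value at equal mean bristle length
  Ns <- withr::with_seed(13, rpois(20000, lambda = 40))
  expect_lt(mean(bristleRepulsion(N = Ns)), bristleRepulsion(N = 40))
})
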