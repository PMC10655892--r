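test_that("uniform bottlebrush wiring follows the consecutive-loop rule", {
  topo <- buildUniformBottlebrush(2, 5)
  expect_equal(topo$n_beads, 10L)
  expect_equal(which(topo$species == "anchor"), c(1L, 6L))
  # loop spring joins anchor i to the bead immediately preceding the next
  # anchor: j = i + L - 1
  expect_equal(unname(topo$loop_springs), cbind(c(1L, 6L), c(5L, 10L)))
  one <- buildUniformBottlebrush(1, 7)
  expect_equal(unname(one$loop_springs), cbind(1L, 7L))
  # chain bonds form one simple path; angles run along the chain only
  expect_equal(nrow(topo$chain_bonds), topo$n_beads - 1L)
  expect_equal(nrow(topo$angle_triplets), topo$n_beads - 2L)
  expect_error(buildUniformBottlebrush(3, 3), "minimum loop size")
})

test_that("bead counts and loop tables are consistent for built topologies", {
  for (spec in list(c(2, 5), c(10, 10), c(7, 13))) {
    topo <- buildUniformBottlebrush(spec[1], spec[2])
    expect_equal(topo$n_beads, spec[1] * spec[2])
    expect_equal(sum(topo$loop_table$length), topo$n_beads)
    expect_equal(nrow(topo$loop_springs), nrow(topo$loop_table))
    # every spring spans exactly its loop: j - i + 1 = L
    expect_equal(topo$loop_springs[, 2] - topo$loop_springs[, 1] + 1L,
                 topo$loop_table$length)
  }
})

test_that("Poisson loops are truncated, unbiased and reproducible", {
  t1 <- buildPoissonBottlebrush(300, 40, min_loop = 5L, seed = 7L)
  t2 <- buildPoissonBottlebrush(300, 40, min_loop = 5L, seed = 7L)
  expect_identical(t1, t2)
  t3 <- buildPoissonBottlebrush(300, 40, min_loop = 5L, seed = 8L)
  expect_false(identical(t1$loop_table$length, t3$loop_table$length))
  expect_true(all(t1$loop_table$length >= 5L))
  # sample mean within 3 standard errors of the Poisson mean
  se <- sqrt(40 / 300)
  expect_lt(abs(mean(t1$loop_table$length) - 40), 3 * se)
  expect_equal(sum(t1$loop_table$length), t1$n_beads)
  expect_error(buildPoissonBottlebrush(10, 3, min_loop = 5L), "min_loop")
})

test_that("sister chromatids double the system and pair homologous beads", {
  base <- buildUniformBottlebrush(6, 8)
  sis <- buildSisterChromatids(base, centromere_loops = 3:4, n_springs = 4L)
  expect_equal(sis$n_beads, 2L * base$n_beads)
  expect_equal(sis$n_chromatids, 2L)
  expect_equal(nrow(sis$loop_springs), 12L)
  # centromere springs join (i, i + n)
  expect_true(all(sis$centromere_springs[, 2] -
                    sis$centromere_springs[, 1] == base$n_beads))
  # loop springs never cross the chromatid boundary
  cid <- sis$chromatid
  expect_true(all(cid[sis$loop_springs[, 1]] == cid[sis$loop_springs[, 2]]))
  none <- buildSisterChromatids(base, 3:4, n_springs = 0L)
  expect_null(none$centromere_springs)
  expect_error(buildSisterChromatids(base, 7:8, 2L), "loop range")
  expect_error(buildSisterChromatids(sis, 1:2, 2L), "single chromatid")
})

test_that("global knockouts rescale loops and bridges in opposite ways", {
  cfg <- runConfig(L_loop_beads = 40L, n_bridges = 500L)
  ko1 <- applyKnockout(cfg, "condI_KO")
  expect_equal(ko1$n_bridges, 250L)
  expect_equal(ko1$L_loop_beads, 80L)
  ko2 <- applyKnockout(cfg, "condII_KO")
  expect_equal(ko2$n_bridges, 1000L)
  expect_equal(ko2$L_loop_beads, 20L)
  expect_identical(applyKnockout(cfg, "control"), cfg)
  expect_error(applyKnockout(cfg, "nonsense"))
})

test_that("fragile-site perturbations edit the loop table locally", {
  topo <- buildUniformBottlebrush(8, 10)
  rem <- applyCfsPerturbation(topo, "removal", locus = 4L)
  expect_equal(nrow(rem$loop_springs), nrow(topo$loop_springs) - 2L)
  # the two orphaned anchors become plain chromatin
  expect_equal(sum(rem$species == "anchor"), 6L)
  expect_equal(rem$n_beads, topo$n_beads)
  mrg <- applyCfsPerturbation(topo, "merge", locus = 4L)
  expect_equal(nrow(mrg$loop_table), nrow(topo$loop_table) - 2L)
  expect_equal(mrg$loop_table$length[4], 30L)
  # the merged spring spans all three loops
  big <- mrg$loop_springs[mrg$loop_springs[, 1] == topo$loop_table$anchor[4], ]
  expect_equal(unname(big[2] - big[1] + 1L), 30L)
  expect_error(applyCfsPerturbation(topo, "merge", locus = 7L), "neighbour")
  expect_error(applyCfsPerturbation(topo, "removal", locus = 8L), "neighbour")
})

test_that("bridge placement is uniform in the box and seed-stable", {
  b <- placeBridges(500, box = 50, seed = 3L)
  expect_equal(dim(b), c(500L, 3L))
  expect_true(all(b >= 0 & b <= 50))
  expect_identical(b, placeBridges(500, 50, seed = 3L))
  expect_equal(nrow(placeBridges(0, 50)), 0L)
})

test_that("linear chains have no loops and optional anchor sites", {
  ch <- buildLinearChain(100)
  expect_equal(nrow(ch$loop_springs), 0L)
  expect_equal(nrow(ch$chain_bonds), 99L)
  expect_true(all(ch$species == "chromatin"))
  ch2 <- buildLinearChain(100, anchor_every = 10L)
  expect_equal(sum(ch2$species == "anchor"), 10L)
})
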