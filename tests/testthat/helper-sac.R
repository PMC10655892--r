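# Shared reduced-scale compacted chromosome (self-assembled cylinder).
# Built once per test session and reused by the contact-scaling, valence
# and elasticity checks. Conditions: 100 Poisson loops of mean 80 kbp
# (40 beads), strong topoisomerase activity (A = 1 kBT), bridges scaled
# proportionally from 500 per 350 loops.
.acc_cache <- new.env(parent = emptyenv())

acceptanceSacConfig <- function(seed = 101L,
                                compaction = 3000) {
  runConfig(loop_mode = "poisson", n_loops = 100L, L_loop_beads = 40L,
            A_kBT = 1, seed = seed,
            phase_durations = c(equilibration = 50,
                                compaction = compaction))
}

acceptanceSac <- function() {
  if (!is.null(.acc_cache$sac)) return(.acc_cache$sac)
  cfg <- acceptanceSacConfig()
  res <- suppressWarnings(runCompaction(cfg, n_frames = 48L))
  .acc_cache$sac <- list(res = res, cfg = cfg)
  .acc_cache$sac
}

# smaller chromosome whose full extension-retraction cycle fits the test
# budget (the 100-loop cycle relaxes over much longer times)
acceptanceSac40 <- function() {
  if (!is.null(.acc_cache$sac40)) return(.acc_cache$sac40)
  cfg <- runConfig(loop_mode = "poisson", n_loops = 40L,
                   L_loop_beads = 40L, A_kBT = 1, seed = 7L,
                   phase_durations = c(equilibration = 50,
                                       compaction = 1200))
  res <- suppressWarnings(runCompaction(cfg, n_frames = 24L))
  .acc_cache$sac40 <- list(res = res, cfg = cfg)
  .acc_cache$sac40
}

# frames from the late (quasi-steady) part of the compaction phase
lateFrames <- function(res, from = 2000) {
  keep <- res$trajectory$times > from
  trajectory(res$trajectory$frames[keep], res$trajectory$times[keep],
             res$trajectory$species, res$trajectory$box)
}

# tiny replicate runs for the monotone-trend comparisons
trendRun <- function(seed, loop_mode = "uniform", L = 15L, n_loops = 10L,
                     A = 10, scenario = NULL, compaction = 150) {
  cfg <- runConfig(loop_mode = loop_mode, L_loop_beads = L,
                   n_loops = n_loops, A_kBT = A, seed = seed,
                   phase_durations = c(equilibration = 30,
                                       compaction = compaction))
  if (is.null(scenario)) suppressWarnings(runCompaction(cfg))
  else suppressWarnings(runScenario(cfg, scenario))
}

# steady-state Rg: mean over the last third of the bridged phase
lateRg <- function(res) {
  s <- res$series[res$series$time > 0, ]
  mean(s$Rg[s$time > max(s$time) * 2 / 3])
}
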