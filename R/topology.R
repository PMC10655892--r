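#' @title Bottlebrush chromosome topologies
#' @description Builders for the looped bead-spring chromosome: a linear
#' chain of chromatin beads organised into consecutive, non-overlapping
#' loops. Each loop starts at an anchor bead `i` and is closed by a spring
#' from `i` to the bead immediately preceding the next anchor, `j = i + L - 1`
#' where `L` is the loop length; the set of anchors forms the chromosome
#' backbone. Species tags: `"chromatin"`, `"anchor"`, `"bridge"`.
#'
#' Internally all bead indices are 1-based and contiguous per chromatid.
#' @name topology
NULL

newTopology <- function(n_beads, species, chain_bonds, loop_springs,
                        angle_triplets, loop_table,
                        centromere_springs = NULL, n_chromatids = 1L,
                        chromatid = NULL) {
  topo <- list(n_beads = as.integer(n_beads), species = species,
               chain_bonds = chain_bonds, loop_springs = loop_springs,
               angle_triplets = angle_triplets, loop_table = loop_table,
               centromere_springs = centromere_springs,
               n_chromatids = as.integer(n_chromatids),
               chromatid = if (is.null(chromatid))
                 rep(1L, n_beads) else chromatid)
  class(topo) <- "ChromosomeTopology"
  topo
}

#' @export
print.ChromosomeTopology <- function(x, ...) {
  cat("ChromosomeTopology:", x$n_beads, "beads,", nrow(x$loop_table),
      "loops,", nrow(x$loop_springs), "loop springs,",
      x$n_chromatids, "chromatid(s)")
  if (!is.null(x$centromere_springs))
    cat(",", nrow(x$centromere_springs), "centromere springs")
  cat("\n")
  invisible(x)
}

# chain bonds and angle triplets for one chromatid occupying beads off+1..off+n
chainWiring <- function(n, off = 0L) {
  if (n < 2L) return(list(bonds = matrix(integer(0), 0, 2),
                          angles = matrix(integer(0), 0, 3)))
  bonds <- cbind(off + seq_len(n - 1L), off + seq_len(n - 1L) + 1L)
  angles <- if (n >= 3L)
    cbind(off + seq_len(n - 2L), off + seq_len(n - 2L) + 1L,
          off + seq_len(n - 2L) + 2L)
  else matrix(integer(0), 0, 3)
  list(bonds = bonds, angles = angles)
}

buildFromLoopLengths <- function(lengths) {
  lengths <- as.integer(lengths)
  n <- sum(lengths)
  anchors <- cumsum(c(1L, lengths[-length(lengths)]))
  closers <- anchors + lengths - 1L
  species <- rep("chromatin", n)
  species[anchors] <- "anchor"
  w <- chainWiring(n)
  newTopology(n, species, w$bonds, cbind(anchors, closers), w$angles,
              data.frame(anchor = anchors, length = lengths))
}

#' Build a uniform-loop bottlebrush chromosome
#'
#' All loops share the same length. Anchors sit at beads
#' `1, L+1, 2L+1, ...`; each loop-closure spring joins anchor `i` to bead
#' `i + L - 1` (the bead immediately preceding the next anchor), so loops are
#' back-to-back with no linker beads.
#'
#' @param n_loops number of loops (>= 1)
#' @param loop_beads loop length in beads (>= `min_loop`)
#' @param min_loop smallest admissible loop, default 5 beads (10 kbp)
#' @return a `ChromosomeTopology` with `n_loops * loop_beads` beads
#' @examples
#' topo <- buildUniformBottlebrush(10, 10)   # 100 beads, 10 loop springs
#' @export
buildUniformBottlebrush <- function(n_loops, loop_beads, min_loop = 5L) {
  if (n_loops < 1L) stop("n_loops must be >= 1")
  if (loop_beads < min_loop)
    stop("loop_beads (", loop_beads, ") is below the minimum loop size (",
         min_loop, " beads)")
  buildFromLoopLengths(rep(as.integer(loop_beads), n_loops))
}

#' Build a bottlebrush with Poisson-distributed loop lengths
#'
#' Loop lengths are i.i.d. Poisson with the requested mean, conditioned on
#' being at least `min_loop` beads (truncation prevents degenerate springs
#' between bonded neighbours). The wiring rule is the same as for
#' [buildUniformBottlebrush()]. The topology is a deterministic function of
#' `seed`.
#'
#' @param n_loops number of loops
#' @param mean_loop_beads target mean loop length in beads
#' @param min_loop truncation threshold (default 5 beads)
#' @param seed integer seed
#' @return a `ChromosomeTopology`
#' @export
buildPoissonBottlebrush <- function(n_loops, mean_loop_beads, min_loop = 5L,
                                    seed = 1L) {
  if (n_loops < 1L) stop("n_loops must be >= 1")
  if (mean_loop_beads < min_loop)
    stop("mean_loop_beads must be >= min_loop (", min_loop, ")")
  lengths <- withLocalSeed(seed, {
    out <- integer(0)
    while (length(out) < n_loops) {
      draw <- stats::rpois(2L * n_loops, lambda = mean_loop_beads)
      out <- c(out, draw[draw >= min_loop])
    }
    out[seq_len(n_loops)]
  })
  buildFromLoopLengths(lengths)
}

withLocalSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(expr)
}

#' Build a plain linear chain (no loops)
#'
#' A bare semiflexible fiber: chain bonds and bending triplets only, no
#' loop-closure springs and no anchors. Used for persistence-length
#' calibration runs and for loop-free control simulations.
#'
#' @param n_beads chain length
#' @param anchor_every optionally tag every k-th bead as an `anchor`
#'   (specific bridge-binding sites on an unlooped fiber); `0` = none
#' @return a `ChromosomeTopology` with an empty loop table
#' @export
buildLinearChain <- function(n_beads, anchor_every = 0L) {
  if (n_beads < 2L) stop("n_beads must be >= 2")
  w <- chainWiring(n_beads)
  species <- rep("chromatin", n_beads)
  if (anchor_every > 0L)
    species[seq(1L, n_beads, by = anchor_every)] <- "anchor"
  newTopology(n_beads, species, w$bonds,
              matrix(integer(0), 0, 2), w$angles,
              data.frame(anchor = integer(0), length = integer(0)))
}

#' Duplicate a chromatid into centromere-linked sister chromatids
#'
#' Makes two copies of a single-chromatid topology and joins them by
#' `n_springs` harmonic springs between homologous beads (`i`, `i + n`)
#' evenly spaced within the centromere region given as a range of loop
#' indices.
#'
#' @param base single-chromatid `ChromosomeTopology`
#' @param centromere_loops integer range of loop indices forming the
#'   centromere
#' @param n_springs number of sister-joining springs (0 allowed)
#' @return a two-chromatid `ChromosomeTopology` with doubled bead count
#' @export
buildSisterChromatids <- function(base, centromere_loops, n_springs = 10L) {
  stopifnot(inherits(base, "ChromosomeTopology"))
  if (base$n_chromatids != 1L) stop("base must be a single chromatid")
  nl <- nrow(base$loop_table)
  if (any(centromere_loops < 1L) || any(centromere_loops > nl))
    stop("centromere loop range outside the loop table (1..", nl, ")")
  n <- base$n_beads
  w2 <- chainWiring(n, off = n)
  lt2 <- base$loop_table
  lt2$anchor <- lt2$anchor + n
  cent <- NULL
  if (n_springs > 0L) {
    loops <- seq(min(centromere_loops), max(centromere_loops))
    first <- base$loop_table$anchor[min(loops)]
    last <- base$loop_table$anchor[max(loops)] +
      base$loop_table$length[max(loops)] - 1L
    idx <- unique(as.integer(round(seq(first, last,
                                       length.out = n_springs))))
    cent <- cbind(idx, idx + n)
  }
  newTopology(2L * n, rep(base$species, 2L),
              rbind(base$chain_bonds, w2$bonds),
              rbind(base$loop_springs,
                    base$loop_springs + n),
              rbind(base$angle_triplets, w2$angles),
              rbind(base$loop_table, lt2),
              centromere_springs = cent, n_chromatids = 2L,
              chromatid = rep(1:2, each = n))
}

#' Apply a global condensin knockout to a run configuration
#'
#' Condensin I depletion is modelled as longer loops (residual condensin II
#' looping) with half the bridges; condensin II depletion as shorter loops
#' (residual condensin I looping) with twice the bridges. Loop-length
#' factors are 2 and 0.5 of the control.
#'
#' @param config a [runConfig()]
#' @param scenario "control", "condI_KO" or "condII_KO"
#' @return modified `RunConfig`
#' @export
applyKnockout <- function(config, scenario = c("control", "condI_KO",
                                               "condII_KO")) {
  stopifnot(inherits(config, "RunConfig"))
  scenario <- match.arg(scenario)
  if (scenario == "control") return(config)
  factor <- if (scenario == "condI_KO") 2 else 0.5
  config$L_loop_beads <- as.integer(round(config$L_loop_beads * factor))
  config$n_bridges <- as.integer(round(
    config$n_bridges * (if (scenario == "condI_KO") 0.5 else 2)))
  config$scenario <- scenario
  validateRunConfig(config)
  config
}

#' Apply a local fragile-site perturbation to a topology
#'
#' `kind = "removal"` deletes the loop-closure springs of loops `locus` and
#' `locus + 1` (local loss of looping condensins; the anchors become plain
#' chromatin). `kind = "merge"` replaces loops `locus .. locus + 2` by a
#' single loop spanning all three (faulty local condensin recruitment);
#' interior anchors are retagged as chromatin. Bridge counts are unaffected.
#'
#' @param topo a `ChromosomeTopology`
#' @param kind "removal" or "merge"
#' @param locus loop index of the first affected loop
#' @return perturbed `ChromosomeTopology`
#' @export
applyCfsPerturbation <- function(topo, kind = c("removal", "merge"), locus) {
  stopifnot(inherits(topo, "ChromosomeTopology"))
  kind <- match.arg(kind)
  nl <- nrow(topo$loop_table)
  need <- if (kind == "removal") locus + 1L else locus + 2L
  if (locus < 1L || need > nl)
    stop("locus ", locus, " does not leave the required neighbour loops ",
         "inside the loop table (1..", nl, ")")
  lt <- topo$loop_table
  if (kind == "removal") {
    drop <- c(locus, locus + 1L)
    hit <- topo$loop_springs[, 1] %in% lt$anchor[drop]
    topo$loop_springs <- topo$loop_springs[!hit, , drop = FALSE]
    topo$species[lt$anchor[drop]] <- "chromatin"
    topo$loop_table <- lt[-drop, , drop = FALSE]
  } else {
    three <- locus:(locus + 2L)
    hit <- topo$loop_springs[, 1] %in% lt$anchor[three]
    topo$loop_springs <- topo$loop_springs[!hit, , drop = FALSE]
    newlen <- sum(lt$length[three])
    a <- lt$anchor[locus]
    topo$loop_springs <- rbind(topo$loop_springs,
                               cbind(a, a + newlen - 1L))
    o <- order(topo$loop_springs[, 1])
    topo$loop_springs <- topo$loop_springs[o, , drop = FALSE]
    topo$species[lt$anchor[three[-1]]] <- "chromatin"
    lt$length[locus] <- newlen
    topo$loop_table <- lt[-(three[-1]), , drop = FALSE]
  }
  rownames(topo$loop_table) <- NULL
  topo
}

#' Place diffusing bridge particles uniformly in the box
#'
#' @param n number of bridges (0 allowed)
#' @param box cubic box side in \eqn{\sigma}
#' @param seed integer seed
#' @return `n x 3` coordinate matrix
#' @export
placeBridges <- function(n, box, seed = 1L) {
  if (n < 0L) stop("n must be >= 0")
  if (n == 0L) return(matrix(numeric(0), 0, 3))
  withLocalSeed(seed, matrix(stats::runif(3 * n, 0, box), ncol = 3))
}
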