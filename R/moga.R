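# Elitist nondominated-sorting genetic algorithm (NSGA-II) over the
# restrictive code space: individuals are permutations of the 20 amino
# acids over the canonical blocks, transformed only by swap mutation.

#' Pareto dominance between objective vectors
#'
#' Under minimization, `a` dominates `b` when every component of `a` is
#' less than or equal to the corresponding component of `b` and at least
#' one is strictly smaller.
#'
#' @param a,b numeric vectors of equal length.
#' @return logical scalar.
#' @examples
#' dominates(c(1, 2), c(2, 3))  # TRUE
#' dominates(c(1, 3), c(3, 1))  # FALSE (mutually nondominated)
#' @export
dominates <- function(a, b) {
  if (length(a) != length(b))
    stop("objective vectors must have equal length")
  all(a <= b) && any(a < b)
}

# Rank matrix rows into nondominated layers. Pairwise O(n^2 k) dominance
# followed by peeling; exact and fast enough for populations of a few
# hundred.
.peelRanks <- function(obj) {
  n <- nrow(obj)
  if (n == 0L) return(integer(0))
  weak <- matrix(TRUE, n, n)
  strict <- matrix(FALSE, n, n)
  for (k in seq_len(ncol(obj))) {
    o <- obj[, k]
    cmp <- outer(o, o, "<=")
    weak <- weak & cmp
    strict <- strict | outer(o, o, "<")
  }
  dom <- weak & strict           # dom[i, j]: i dominates j
  nDominators <- colSums(dom)
  rank <- integer(n)
  layer <- 0L
  alive <- rep(TRUE, n)
  while (any(alive)) {
    layer <- layer + 1L
    front <- alive & nDominators == 0L
    if (!any(front)) stop("dominance relation is not acyclic")  # unreachable
    rank[front] <- layer
    alive[front] <- FALSE
    nDominators <- nDominators - colSums(dom[front, , drop = FALSE])
  }
  rank
}

#' Sort a population into nondominated layers
#'
#' Layer 1 holds the individuals dominated by nobody; layer k the ones
#' dominated only by members of earlier layers.
#'
#' @param objectiveMatrix numeric matrix, one row per individual, one
#'   column per objective (minimized).
#' @return integer vector of layer indices (rank 1 = nondominated).
#' @examples
#' nondominatedSort(rbind(c(1, 1), c(2, 2), c(0, 3)))
#' @export
nondominatedSort <- function(objectiveMatrix) {
  stopifnot(is.matrix(objectiveMatrix))
  .peelRanks(objectiveMatrix)
}

#' Crowding distance within one layer
#'
#' The standard NSGA-II diversity measure: per objective, the layer is
#' sorted, both extremes get infinite distance, and every interior member
#' accumulates the gap between its two neighbours normalized by the
#' objective's range. Larger distances mark more isolated (more diverse)
#' members.
#'
#' @param objectiveMatrix numeric matrix of the layer's objective values.
#' @return numeric vector of crowding distances (may contain `Inf`).
#' @export
crowdingDistance <- function(objectiveMatrix) {
  stopifnot(is.matrix(objectiveMatrix))
  n <- nrow(objectiveMatrix)
  if (n <= 2L) return(rep(Inf, n))
  d <- numeric(n)
  for (k in seq_len(ncol(objectiveMatrix))) {
    o <- objectiveMatrix[, k]
    ord <- order(o)
    d[ord[c(1L, n)]] <- Inf
    rng <- o[ord[n]] - o[ord[1L]]
    if (rng > 0) {
      inner <- ord[2:(n - 1L)]
      d[inner] <- d[inner] + (o[ord[3:n]] - o[ord[1:(n - 2L)]]) / rng
    }
  }
  d
}

# Crowded-comparison winner among candidate indices: lowest rank, then
# largest crowding, remaining ties broken uniformly at random.
.crowdedWinner <- function(idx, rank, crowd) {
  best <- idx[rank[idx] == min(rank[idx])]
  if (length(best) > 1L) best <- best[crowd[best] == max(crowd[best])]
  if (length(best) > 1L) best <- best[sample.int(length(best), 1L)]
  best
}

#' Tournament selection under the crowded comparison
#'
#' Draws `poolSize` individuals uniformly without replacement and returns
#' the index of the winner: lower nondomination rank wins, ties are broken
#' by larger crowding distance, remaining ties uniformly at random.
#'
#' @param rank integer vector of nondomination ranks.
#' @param crowding numeric vector of crowding distances.
#' @param poolSize tournament pool size (at least 2).
#' @return the selected individual's index.
#' @export
tournamentSelect <- function(rank, crowding, poolSize) {
  n <- length(rank)
  if (poolSize > n) stop("tournament pool larger than population")
  pool <- sample.int(n, poolSize)
  .crowdedWinner(pool, rank, crowding)
}

#' Swap mutation
#'
#' Chooses two distinct blocks uniformly at random and interchanges their
#' amino acids. The input is unchanged; the output is still a permutation,
#' and applying the same swap twice restores the original code.
#'
#' @param code a [GeneticCode-class] object.
#' @return a new [GeneticCode-class] object differing from `code` at
#'   exactly two blocks.
#' @examples
#' set.seed(1)
#' swapMutate(canonicalCode())
#' @export
swapMutate <- function(code) {
  stopifnot(is(code, "GeneticCode"))
  a <- assignment(code)
  ij <- sample.int(20L, 2L)
  a[ij] <- a[rev(ij)]
  new("GeneticCode", assignment = a)
}

#' Configuration of the multiobjective GA
#'
#' Defaults are the study settings: population 100, 1000 generations, swap
#' probability 0.5 per offspring per generation, tournament pool 3% of the
#' population (minimum 2), 10 independent runs.
#'
#' @param specList list of [ObjectiveSpec-class] objectives (minimized).
#' @param populationSize number of individuals (>= 2).
#' @param generations number of generations (0 gives the nondominated
#'   subset of the random initial population).
#' @param swapProb probability that an offspring undergoes one swap.
#' @param tournamentFraction fraction of the population drawn into each
#'   tournament pool.
#' @param runs number of independent runs merged by [nsga2()].
#' @param seed master seed; per-run sub-seeds are derived from it
#'   deterministically.
#' @param swapsPerOffspring number of swap events applied when an
#'   offspring mutates (default 1).
#' @return a validated list of class `gaConfig`.
#' @export
gaConfig <- function(specList, populationSize = 100L, generations = 1000L,
                     swapProb = 0.5, tournamentFraction = 0.03,
                     runs = 10L, seed = 1L, swapsPerOffspring = 1L) {
  if (!length(specList)) stop("at least one objective spec is required")
  stopifnot(populationSize >= 2L, generations >= 0L,
            swapProb >= 0, swapProb <= 1,
            tournamentFraction > 0, tournamentFraction <= 1,
            runs >= 1L, swapsPerOffspring >= 1L)
  structure(list(specList = specList,
                 populationSize = as.integer(populationSize),
                 generations = as.integer(generations),
                 swapProb = swapProb,
                 tournamentFraction = tournamentFraction,
                 runs = as.integer(runs), seed = as.integer(seed),
                 swapsPerOffspring = as.integer(swapsPerOffspring),
                 poolSize = max(2L, as.integer(round(
                   tournamentFraction * populationSize)))),
            class = "gaConfig")
}

.runSeeds <- function(config) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)
  sample.int(.Machine$integer.max - 1L, config$runs)
}

# environmental selection: keep whole layers; truncate the last one by
# crowding (descending), ties broken by objective-lexicographic order so
# runs are bit-reproducible.
.environmentalSelect <- function(obj, M) {
  rank <- .peelRanks(obj)
  keep <- integer(0)
  for (layer in sort(unique(rank))) {
    idx <- which(rank == layer)
    if (length(keep) + length(idx) <= M) {
      keep <- c(keep, idx)
    } else {
      cd <- crowdingDistance(obj[idx, , drop = FALSE])
      ord <- do.call(order, c(list(-cd),
                              lapply(seq_len(ncol(obj)),
                                     function(k) obj[idx, k])))
      keep <- c(keep, idx[ord[seq_len(M - length(keep))]])
      break
    }
  }
  keep
}

#' One NSGA-II run over the restrictive code space
#'
#' Starts from a uniformly random population of permutation codes. Each
#' generation builds an offspring population of equal size by tournament
#' selection followed by swap mutation (each offspring mutates with
#' probability `swapProb`, otherwise it is a copy of its parent), then
#' applies elitist environmental selection to parents plus offspring:
#' whole nondominated layers are kept, the last layer truncated by
#' crowding distance. The run is fully reproducible from its sub-seed.
#'
#' @param config a [gaConfig()] object.
#' @param runIndex which of the `config$runs` sub-seeds to use.
#' @return a [ParetoFront-class]: layer 1 of the final population, with
#'   duplicate assignments removed. Attribute `bestTrajectory` holds the
#'   per-generation best value of each objective (rows: generation 0..G).
#' @export
nsga2Run <- function(config, runIndex = 1L) {
  stopifnot(inherits(config, "gaConfig"),
            runIndex >= 1L, runIndex <= config$runs)
  seeds <- .runSeeds(config)
  set.seed(seeds[runIndex])
  M <- config$populationSize
  specList <- config$specList
  P <- .randomPermMatrix(M)
  objP <- .evaluatePermMatrix(P, specList)
  best <- apply(objP, 2L, min)
  traj <- matrix(best, 1L, ncol(objP),
                 dimnames = list(NULL, colnames(objP)))
  gen <- 0L
  while (gen < config$generations) {
    gen <- gen + 1L
    rank <- .peelRanks(objP)
    crowd <- numeric(M)
    for (layer in unique(rank)) {
      idx <- which(rank == layer)
      crowd[idx] <- crowdingDistance(objP[idx, , drop = FALSE])
    }
    Q <- matrix(0L, M, 20L)
    for (i in seq_len(M)) {
      child <- P[tournamentSelect(rank, crowd, config$poolSize), ]
      if (runif(1L) < config$swapProb) {
        for (s in seq_len(config$swapsPerOffspring)) {
          ij <- sample.int(20L, 2L)
          child[ij] <- child[rev(ij)]
        }
      }
      Q[i, ] <- child
    }
    objQ <- .evaluatePermMatrix(Q, specList)
    R <- rbind(P, Q)
    objR <- rbind(objP, objQ)
    keep <- .environmentalSelect(objR, M)
    P <- R[keep, , drop = FALSE]
    objP <- objR[keep, , drop = FALSE]
    newBest <- apply(objP, 2L, min)
    if (any(newBest > best + 1e-12))
      stop("elitism violated: per-objective best worsened")  # internal check
    best <- newBest
    traj <- rbind(traj, newBest)
  }
  front <- which(.peelRanks(objP) == 1L)
  out <- .makeFront(P[front, , drop = FALSE],
                    objP[front, , drop = FALSE], specList,
                    run = runIndex, generation = gen)
  attr(out, "bestTrajectory") <- unname(traj)
  attr(out, "seed") <- seeds[runIndex]
  out
}

.makeFront <- function(perms, obj, specList, run, generation) {
  key <- apply(perms, 1L, paste, collapse = " ")
  keep <- !duplicated(key)
  perms <- perms[keep, , drop = FALSE]
  obj <- obj[keep, , drop = FALSE]
  labs <- names(blocks(canonicalBlocks()))
  assignments <- matrix(AA3[perms], nrow(perms), 20L,
                        dimnames = list(NULL, labs))
  colnames(obj) <- vapply(specList, specLabel, "")
  prov <- data.frame(run = rep_len(run, nrow(perms)),
                     generation = rep_len(generation, nrow(perms)))
  ord <- do.call(order, lapply(seq_len(ncol(obj)), function(k) obj[, k]))
  new("ParetoFront", assignments = assignments[ord, , drop = FALSE],
      objectives = obj[ord, , drop = FALSE], specs = specList,
      provenance = prov[ord, , drop = FALSE])
}

#' Multi-run NSGA-II with Pareto-front merging
#'
#' Executes `config$runs` independent runs (each from its own
#' deterministic sub-seed) and merges their fronts with [mergeFronts()].
#'
#' @param config a [gaConfig()] object.
#' @return the merged [ParetoFront-class]; attribute `runFronts` holds the
#'   individual run fronts.
#' @export
nsga2 <- function(config) {
  fronts <- lapply(seq_len(config$runs), function(r) nsga2Run(config, r))
  merged <- mergeFronts(fronts)
  attr(merged, "runFronts") <- fronts
  merged
}

#' Merge Pareto fronts from several runs
#'
#' Takes the union of the members, removes duplicate assignments, keeps
#' only the mutually nondominated ones, and orders the result
#' lexicographically by objective values.
#'
#' @param fronts list of [ParetoFront-class] objects evaluated under
#'   identical objectives.
#' @return a [ParetoFront-class] object.
#' @export
mergeFronts <- function(fronts) {
  stopifnot(length(fronts) >= 1L,
            all(vapply(fronts, is, TRUE, "ParetoFront")))
  labs0 <- vapply(fronts[[1L]]@specs, specLabel, "")
  for (f in fronts)
    if (!identical(vapply(f@specs, specLabel, ""), labs0))
      stop("fronts were evaluated under different objectives")
  assignments <- do.call(rbind, lapply(fronts, slot, "assignments"))
  obj <- do.call(rbind, lapply(fronts, slot, "objectives"))
  prov <- do.call(rbind, lapply(fronts, slot, "provenance"))
  key <- apply(assignments, 1L, paste, collapse = " ")
  keep <- !duplicated(key)
  assignments <- assignments[keep, , drop = FALSE]
  obj <- obj[keep, , drop = FALSE]
  prov <- prov[keep, , drop = FALSE]
  nd <- .peelRanks(obj) == 1L
  ord <- do.call(order, lapply(seq_len(ncol(obj)),
                               function(k) obj[nd, k, drop = TRUE]))
  idx <- which(nd)[ord]
  new("ParetoFront", assignments = assignments[idx, , drop = FALSE],
      objectives = obj[idx, , drop = FALSE], specs = fronts[[1L]]@specs,
      provenance = prov[idx, , drop = FALSE])
}

#' Extract one member of a front as a genetic code
#'
#' @param front a [ParetoFront-class] object.
#' @param i member index.
#' @return a [GeneticCode-class] object.
#' @export
frontCode <- function(front, i) {
  stopifnot(is(front, "ParetoFront"), i >= 1L, i <= length(front))
  geneticCode(front@assignments[i, ])
}
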