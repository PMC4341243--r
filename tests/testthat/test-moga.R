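test_that("dominance follows the minimization definition", {
  expect_true(dominates(c(1, 2), c(2, 3)))
  expect_false(dominates(c(2, 3), c(1, 2)))
  expect_false(dominates(c(1, 3), c(3, 1)))
  expect_false(dominates(c(3, 1), c(1, 3)))
  expect_false(dominates(c(1, 2), c(1, 2)))   # equal: no strict improvement
  expect_true(dominates(c(1, 2), c(1, 3)))
  expect_error(dominates(c(1, 2), c(1, 2, 3)), "equal length")
  # a front member better on one objective only does not dominate canonical
  expect_false(dominates(c(5.380, 1550), c(5.193574, 2266.129)))
})

test_that("nondominated sorting matches the naive peeling oracle", {
  # degenerate layers
  same <- matrix(1, 7, 2)
  expect_identical(nondominatedSort(same), rep(1L, 7))
  chain <- cbind(1:5, 1:5)
  expect_identical(nondominatedSort(chain), 1:5)
  # random populations, two and three objectives
  set.seed(21)
  for (k in c(2L, 3L)) {
    for (n in c(10L, 60L, 200L)) {
      obj <- matrix(runif(n * k), n, k)
      expect_identical(nondominatedSort(obj), oraclePeel(obj))
    }
  }
  # with ties/duplicates
  obj <- matrix(sample(1:4, 120, replace = TRUE), 60, 2)
  obj <- apply(obj, 2L, as.numeric)
  expect_identical(nondominatedSort(obj), oraclePeel(obj))
})

test_that("crowding distance matches an independent implementation", {
  expect_identical(crowdingDistance(matrix(runif(4), 2, 2)), c(Inf, Inf))
  expect_identical(crowdingDistance(matrix(1, 1, 2)), Inf)
  ident <- matrix(2, 6, 2)
  d <- crowdingDistance(ident)
  expect_true(all(d[!is.infinite(d)] == 0))
  set.seed(22)
  obj <- matrix(runif(100), 50, 2)
  expect_equal(crowdingDistance(obj), oracleCrowding2(obj),
               tolerance = 1e-12)
})

test_that("tournament selection prefers lower rank, then larger crowding", {
  rank <- c(1L, 1L, 3L, 3L)
  crowd <- c(Inf, 0.2, 5, 1)
  set.seed(23)
  # pool containing layers 1 and 3: a layer-1 member must win
  for (i in 1:50) {
    w <- gcadapt:::.crowdedWinner(c(2L, 3L, 4L), rank, crowd)
    expect_identical(rank[w], 1L)
  }
  # equal ranks: the infinite-crowding member wins
  expect_identical(gcadapt:::.crowdedWinner(c(1L, 2L), rank, crowd), 1L)
  # selection pressure: layer-1 members win more often than their share
  set.seed(24)
  rank2 <- rep(c(1L, 2L), c(10L, 40L))
  crowd2 <- runif(50)
  wins <- replicate(10000, tournamentSelect(rank2, crowd2, 3L))
  expect_gt(mean(rank2[wins] == 1L), 10 / 50)
  expect_error(tournamentSelect(rank2, crowd2, 51L), "pool larger")
})

test_that("swap mutation is a pure involution touching two blocks", {
  set.seed(25)
  code <- canonicalCode()
  for (i in 1:50) {
    seedState <- .Random.seed
    m <- swapMutate(code)
    expect_identical(sum(assignment(m) != assignment(code)), 2L)
    # applying the same swap again restores the original
    assign(".Random.seed", seedState, globalenv())
    m2 <- swapMutate(m)
    expect_identical(assignment(m2), assignment(code))
    expect_setequal(unname(assignment(m)), unname(assignment(canonicalCode())))
  }
  # unordered position pairs are chosen ~ uniformly (1/190 each)
  set.seed(26)
  pairKey <- replicate(10000, {
    d <- which(assignment(swapMutate(code)) != assignment(code))
    paste(d, collapse = "-")
  })
  tab <- table(pairKey)
  expect_identical(length(tab), 190L)
  expect_gt(stats::chisq.test(tab)$p.value, 1e-4)
})

test_that("zero-generation runs return the nondominated initial subset", {
  specs <- list(objectiveSpec("ms", "pr"), objectiveSpec("ms", "hi"))
  cfg <- gaConfig(specs, populationSize = 30L, generations = 0L,
                  runs = 1L, seed = 31L)
  fr <- nsga2Run(cfg, 1L)
  expect_s4_class(fr, "ParetoFront")
  expect_lte(length(fr), 30L)
  # mutual nondominance (also enforced by the class validity)
  obj <- objectives(fr)
  expect_true(all(gcadapt:::.peelRanks(obj) == 1L))
})

test_that("runs are elitist, reproducible, and respect the encoding", {
  specs <- list(objectiveSpec("ms", "pr"), objectiveSpec("mst", "mv"))
  cfg <- gaConfig(specs, populationSize = 24L, generations = 40L,
                  runs = 2L, seed = 33L)
  f1 <- nsga2Run(cfg, 1L)
  f2 <- nsga2Run(cfg, 1L)
  expect_identical(objectives(f1), objectives(f2))
  expect_identical(f1@assignments, f2@assignments)
  fOther <- nsga2Run(cfg, 2L)
  expect_false(identical(objectives(f1), objectives(fOther)))
  # per-objective best never worsens across generations
  traj <- attr(f1, "bestTrajectory")
  expect_identical(nrow(traj), 41L)
  expect_true(all(diff(traj[, 1L]) <= 1e-12))
  expect_true(all(diff(traj[, 2L]) <= 1e-12))
  # every member is a permutation
  for (i in seq_len(length(f1)))
    expect_setequal(f1@assignments[i, ], unname(assignment(canonicalCode())))
  expect_lte(length(f1), cfg$populationSize)
})

test_that("front merging dedupes, filters dominance, keeps order stable", {
  specs <- list(objectiveSpec("ms", "pr"), objectiveSpec("ms", "hi"))
  mkFront <- function(objRows, seed) {
    n <- nrow(objRows)
    set.seed(seed)
    perms <- gcadapt:::.randomPermMatrix(n)
    gcadapt:::.makeFront(perms, objRows, specs, run = 1L, generation = 0L)
  }
  fA <- mkFront(rbind(c(1, 3), c(2, 2)), seed = 1)
  fB <- mkFront(rbind(c(1, 2)), seed = 2)
  m <- mergeFronts(list(fA, fB))
  expect_identical(unname(objectives(m)), rbind(c(1, 2)))
  fC <- mkFront(rbind(c(1, 3)), seed = 3)
  fD <- mkFront(rbind(c(3, 1)), seed = 4)
  m2 <- mergeFronts(list(fC, fD))
  expect_identical(nrow(objectives(m2)), 2L)
  # idempotence: merging a front with itself gives the same front
  m3 <- mergeFronts(list(fA, fA))
  expect_identical(objectives(m3), objectives(mergeFronts(list(fA))))
  # mixed objectives are rejected
  fE <- gcadapt:::.makeFront(gcadapt:::.randomPermMatrix(1),
                             matrix(c(1, 2), 1L),
                             list(objectiveSpec("ms", "pr"),
                                  objectiveSpec("mst", "hi")),
                             run = 1L, generation = 0L)
  expect_error(mergeFronts(list(fA, fE)), "different objectives")
})

test_that("config validation enforces the documented bounds", {
  specs <- list(objectiveSpec("ms", "pr"))
  expect_error(gaConfig(list()), "at least one")
  expect_error(gaConfig(specs, populationSize = 1L))
  expect_error(gaConfig(specs, swapProb = 1.5))
  cfg <- gaConfig(specs, populationSize = 100L, tournamentFraction = 0.03)
  expect_identical(cfg$poolSize, 3L)
  cfg2 <- gaConfig(specs, populationSize = 20L, tournamentFraction = 0.03)
  expect_identical(cfg2$poolSize, 2L)   # enforced minimum
})
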