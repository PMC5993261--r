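test_that("state library couples distinct block subsets as SPD correlations", {
  lib <- buildStateLibrary(2, 4, rep(c("A", "B"), each = 2),
                           couplingStrength = 0.8, seed = 1)
  S1 <- stateCovariances(lib)[[1]]
  S2 <- stateCovariances(lib)[[2]]
  ## state 1 couples block A, state 2 the complementary block B
  expect_gt(S1[1, 2], 0.7)
  expect_equal(S1[3, 4], 0)
  expect_equal(S1[1, 3], 0)
  expect_gt(S2[3, 4], 0.7)
  expect_equal(S2[1, 2], 0)
  expect_gt(sqrt(sum((S1 - S2)^2)), 0)
  for (S in stateCovariances(lib)) {
    expect_equal(diag(S), rep(1, 4))
    expect_gt(min(eigen(S, symmetric = TRUE, only.values = TRUE)$values), 0)
  }
})

test_that("a 6-state 44-node library over 8 subnetworks is numerically PD", {
  labels <- rep(c("Aud", "ECN", "DMN", "SM", "SN", "Visual",
                  "Cerebellar", "Other"), length.out = 44)
  lib <- buildStateLibrary(6, 44, labels, couplingStrength = 0.8, seed = 3)
  expect_length(stateCovariances(lib), 6)
  minEig <- vapply(stateCovariances(lib), function(S)
    min(eigen(S, symmetric = TRUE, only.values = TRUE)$values), numeric(1))
  expect_true(all(minEig > 0))
  ## each state is nearest to itself in edge space
  edges <- t(vapply(stateCovariances(lib), upperTriVec,
                    numeric(44 * 43 / 2)))
  D <- as.matrix(dist(edges))
  expect_true(all(D[upper.tri(D)] > 0))
})

test_that("degenerate or oversized library constructions are rejected", {
  expect_error(buildStateLibrary(2, 4, rep(c("A", "B"), each = 2),
                                 couplingStrength = 0),
               "couplingStrength")
  ## 2 blocks allow at most 3 distinct coupling patterns
  expect_error(buildStateLibrary(4, 4, rep(c("A", "B"), each = 2), 0.8),
               "distinct block coupling patterns")
})

test_that("state sequences follow the transition model", {
  ## absorbing chain: identity transitions freeze the start state
  frozen <- transitionModel(diag(3), initial = c(0, 1, 0))
  expect_equal(sampleStateSequence(frozen, 50, seed = 1), rep(2L, 50))
  ## forced alternation
  alt <- transitionModel(matrix(c(0, 1, 1, 0), 2, 2), initial = c(1, 0))
  s <- sampleStateSequence(alt, 100, seed = 1)
  expect_equal(s, rep(c(1L, 2L), 50))
  ## Monte-Carlo self-transition fraction, K = 4, self-prob 0.9
  m <- makeGroupTransition(4, 0.9)
  s <- sampleStateSequence(m, 100000, seed = 42)
  selfFrac <- mean(s[-1] == s[-length(s)])
  expect_lt(abs(selfFrac - 0.9), 0.01)
  ## empirical transition frequencies converge row-wise
  trans <- table(s[-length(s)], s[-1])
  emp <- trans / rowSums(trans)
  expect_lt(max(abs(emp - transitionMatrix(m))), 0.01)
})

test_that("emissions reproduce the active state's correlation structure", {
  lib <- buildStateLibrary(2, 4, rep(c("A", "B"), each = 2), 0.8, seed = 1)
  run <- generateSubjectRun(lib, rep(1L, 50000), noiseSd = 0, seed = 9)
  expect_lt(max(abs(cor(tsData(run)) - stateCovariances(lib)[[1]])), 0.02)
  ## noise dominance drives off-diagonal correlations to zero
  noisy <- generateSubjectRun(lib, rep(1L, 20000), noiseSd = 50, seed = 9)
  R <- cor(tsData(noisy))
  expect_lt(max(abs(R[upper.tri(R)])), 0.05)
  expect_error(generateSubjectRun(lib, integer(0)), "non-empty")
  expect_error(generateSubjectRun(lib, c(1L, 3L)), "missing from")
})

test_that("cohort generation is pure bookkeeping under a fixed seed", {
  lib <- buildStateLibrary(3, 6, rep(c("A", "B", "C"), each = 2), 0.8, 1)
  spec <- cohortSpec(lib, list(g1 = makeGroupTransition(3, 0.9),
                               g2 = makeGroupTransition(3, 0.8)),
                     nSubjectsPerGroup = 3, nRuns = 2, nVolumes = 40,
                     seed = 11)
  co <- generateCohort(spec)
  expect_length(co, 6)
  expect_equal(unname(vapply(co, function(s) length(s@runs), integer(1))),
               rep(2L, 6))
  expect_setequal(unique(vapply(co, function(s) s@group, character(1))),
                  c("g1", "g2"))
  for (s in co) {
    expect_length(s@stateLabels[[1]], 40)
    expect_true(all(unlist(s@stateLabels) %in% 1:3))
  }
  ## bit-identical regeneration
  co2 <- generateCohort(spec)
  expect_identical(lapply(co, function(s) s@stateLabels),
                   lapply(co2, function(s) s@stateLabels))
  expect_identical(tsData(co[[1]]@runs[[1]]), tsData(co2[[1]]@runs[[1]]))
})

test_that("stickier groups show fewer ground-truth transitions", {
  lib <- buildStateLibrary(4, 8, rep(c("A", "B", "C", "D"), each = 2),
                           0.8, 1)
  spec <- cohortSpec(lib, list(mobile = makeGroupTransition(4, 0.85),
                               sticky = makeGroupTransition(4, 0.97)),
                     nSubjectsPerGroup = 12, nRuns = 1, nVolumes = 200,
                     subjectConcentration = 50, rateSd = 0.25, seed = 5)
  co <- generateCohort(spec)
  tr <- vapply(co, function(s) countTransitions(s@stateLabels[[1]]),
               integer(1))
  grp <- vapply(co, function(s) s@group, character(1))
  expect_lt(mean(tr[grp == "sticky"]), mean(tr[grp == "mobile"]))
})

test_that("subject models stay row-stochastic and respect exclusions", {
  g <- makeGroupTransition(6, 0.9, excludeStates = c(1, 2, 4))
  expect_equal(rowSums(transitionMatrix(g)), rep(1, 6), tolerance = 1e-12)
  expect_equal(unname(colSums(transitionMatrix(g))[c(1, 2, 4)]), c(0, 0, 0))
  set.seed(1)
  for (i in 1:20) {
    m <- perturbTransition(g, kappa = 0.4)
    P <- transitionMatrix(m)
    expect_equal(rowSums(P), rep(1, 6), tolerance = 1e-12)
    expect_equal(unname(colSums(P)[c(1, 2, 4)]), c(0, 0, 0))
    long <- sampleStateSequence(m, 500, seed = i)
    expect_false(any(long %in% c(1, 2, 4)))
  }
})

test_that("group-exclusive states appear only in the permissive group", {
  lib <- buildStateLibrary(4, 8, rep(c("A", "B", "C", "D"), each = 2),
                           0.8, 1)
  spec <- cohortSpec(lib,
                     list(open = makeGroupTransition(4, 0.8),
                          restricted = makeGroupTransition(4, 0.8,
                                                           excludeStates = 4)),
                     nSubjectsPerGroup = 8, nRuns = 1, nVolumes = 300,
                     subjectConcentration = 5, seed = 3)
  co <- generateCohort(spec)
  grp <- vapply(co, function(s) s@group, character(1))
  seen4 <- vapply(co, function(s) any(unlist(s@stateLabels) == 4),
                  logical(1))
  expect_false(any(seen4[grp == "restricted"]))
  expect_true(any(seen4[grp == "open"]))
})

test_that("transition-count ground truth equals adjacent unequal labels", {
  expect_equal(countTransitions(c(1, 1, 1)), 0L)
  expect_equal(countTransitions(c(1, 2, 1, 2)), 3L)
  expect_equal(countTransitions(3L), 0L)
  set.seed(8)
  for (i in 1:10) {
    l <- sample.int(3, 50, replace = TRUE)
    expect_equal(countTransitions(l), sum(diff(l) != 0))
  }
})

test_that("stationary distribution matches the balance equations", {
  m <- makeGroupTransition(4, 0.9)
  pi0 <- stationaryDistribution(transitionMatrix(m))
  expect_equal(as.numeric(pi0 %*% transitionMatrix(m)), pi0,
               tolerance = 1e-10)
  expect_equal(pi0, rep(0.25, 4), tolerance = 1e-10)
})
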