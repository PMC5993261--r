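test_that("exemplar selection finds local maxima of window variance", {
  ## edge rows with controlled across-edge variance: row i ~ scaled noise
  set.seed(2)
  base <- matrix(rnorm(30 * 10), 30, 10)
  prof <- rep(1, 30); prof[12] <- 6           # single interior peak
  E <- base * prof
  ex <- selectExemplars(list(stackFromEdges(E, 5)))[[1]]
  expect_equal(ex[which.max(apply(E, 1, var)[ex])], 12)
  expect_true(12 %in% ex)
  ## monotone profile selects the boundary window
  EMono <- outer(seq(1, 4, length.out = 30), base[1, ])
  exMono <- selectExemplars(list(stackFromEdges(EMono, 5)))[[1]]
  expect_true(30 %in% exMono)
  expect_false(1 %in% exMono)
  ## flat stacks fall back to uniform subsampling with a warning
  flat <- matrix(1, 20, 10)
  expect_warning(exFlat <- selectExemplars(list(stackFromEdges(flat, 5))),
                 "uniform")
  expect_gt(length(exFlat[[1]]), 0)
})

test_that("exemplars bracket a mid-run state switch better than chance", {
  lib <- buildStateLibrary(2, 6, rep(c("A", "B"), each = 3), 0.8, 1)
  hits <- 0; trials <- 0
  for (seed in 1:25) {
    run <- generateSubjectRun(lib, rep(c(1L, 2L), each = 40),
                              noiseSd = 0.3, seed = seed)
    st <- dfcStack(run, windowParams(), requirePrep = FALSE)
    ex <- suppressWarnings(selectExemplars(list(st))[[1]])
    ## the true switch at volume 41 affects windows 27..40
    hits <- hits + any(ex >= 27 & ex <= 40)
    trials <- trials + 1
  }
  ## 14 of 66 windows overlap the switch; chance of >= 1 hit for a
  ## same-sized random draw is well below this observed rate
  expect_gt(hits / trials, 0.5)
})

test_that("k-means recovers exactly separable partitions", {
  A <- c(rep(0, 5), rep(10, 5))
  E <- cbind(A, A, A)                # 10 windows at 2 distinct points
  part <- suppressWarnings(
    clusterStates(list(stackFromEdges(E, 3)), k = 2, seed = 1))
  expect_equal(part@inertia, 0, tolerance = 1e-12)
  expect_setequal(split(seq_len(10), stateLabels(part)[[1]]) |> lengths(),
                  c(5, 5))
  cents <- stateCentroids(part)
  expect_setequal(cents[, 1], c(0, 10))
  ## duplicating every window leaves the partition unchanged
  both <- list(stackFromEdges(E, 3, subject = "S01"),
               stackFromEdges(E, 3, subject = "S02"))
  part2 <- suppressWarnings(clusterStates(both, k = 2, seed = 1))
  expect_equal(sort(stateCentroids(part2)[, 1]), sort(cents[, 1]))
  expect_equal(part2@inertia, 0, tolerance = 1e-12)
  ## labels are nearest-centroid assignments
  lab <- stateLabels(part)[[1]]
  d <- as.matrix(dist(rbind(E, cents)))[1:10, 11:12]
  expect_equal(lab, max.col(-d))
  ## contracts
  expect_error(clusterStates(list(stackFromEdges(E, 3)), k = 1), ">= 2")
  expect_error(suppressWarnings(
    clusterStates(list(stackFromEdges(E, 3)), k = 3)), "distinct windows")
  expect_error(clusterStates(list(stackFromEdges(E[1:2, ], 3)), k = 5),
               "window count")
})

test_that("clustering is deterministic for a fixed seed", {
  set.seed(99)
  E <- matrix(rnorm(40 * 6), 40, 6)
  s <- list(stackFromEdges(E, 4))
  p1 <- clusterStates(s, 3, seed = 7)
  p2 <- clusterStates(s, 3, seed = 7)
  expect_identical(stateLabels(p1), stateLabels(p2))
  expect_identical(stateCentroids(p1), stateCentroids(p2))
})

test_that("final inertia is bounded by (and often equals) the brute-force
          optimum on tiny problems", {
  set.seed(31)
  ## well-separated case: Lloyd from exemplar start finds the optimum
  Esep <- rbind(matrix(rnorm(5 * 2, 0), 5, 2),
                matrix(rnorm(5 * 2, 8), 5, 2))
  psep <- clusterStates(list(stackFromEdges(cbind(Esep, 0), 3)),
                        k = 2, seed = 1)
  expect_equal(psep@inertia, bfKmeansInertia(cbind(Esep, 0), 2),
               tolerance = 1e-8)
  ## generic cases: one-sided bound always holds
  for (i in 1:3) {
    E <- matrix(rnorm(7 * 3), 7, 3)
    p <- suppressWarnings(
      clusterStates(list(stackFromEdges(E, 3)), k = 3, seed = i))
    expect_gte(p@inertia + 1e-8, bfKmeansInertia(E, 3))
  }
})

test_that("state metrics count frequencies, dwells and transitions by hand", {
  m <- stateMetrics(c(3, 3, 5, 5), k = 5)
  expect_equal(unname(m$frequency[c(3, 5)]), c(0.5, 0.5))
  expect_equal(sum(m$frequency), 1)
  expect_equal(m$nTransitions, 1L)
  expect_equal(unname(m$meanDwell[c(3, 5)]), c(2, 2))
  expect_true(is.na(m$meanDwell[1]))
  ## constant sequence
  mc <- stateMetrics(rep(2L, 226), k = 3)
  expect_equal(mc$nTransitions, 0L)
  expect_equal(unname(mc$frequency[2]), 1)
  ## alternation
  ma <- stateMetrics(c(1, 2, 1, 2, 1), k = 2)
  expect_equal(ma$nTransitions, 4L)
  expect_equal(unname(ma$meanDwell), c(1, 1))
  ## dwell in seconds uses the window step duration
  ms <- stateMetrics(c(1, 1, 1, 2, 2, 2), k = 2, stepSeconds = 2)
  expect_equal(unname(ms$meanDwellSeconds), c(6, 6))
})

test_that("state-metric invariants hold for random label sequences", {
  set.seed(12)
  for (i in 1:20) {
    l <- sample.int(4, sample(5:60, 1), replace = TRUE)
    m <- stateMetrics(l, k = 4)
    expect_equal(sum(m$frequency), 1, tolerance = 1e-12)
    expect_lte(m$nTransitions, length(l) - 1)
    visits <- length(rle(l)$lengths)
    expect_equal(visits, m$nTransitions + 1L)
    ## label permutation symmetry
    perm <- sample(4)
    mp <- stateMetrics(perm[l], k = 4)
    expect_equal(unname(sort(mp$frequency)), unname(sort(m$frequency)))
    expect_equal(mp$nTransitions, m$nTransitions)
    expect_equal(unname(sort(mp$meanDwell, na.last = TRUE)),
                 unname(sort(m$meanDwell, na.last = TRUE)))
  }
})

test_that("window-majority ground truth breaks ties to the lowest label", {
  win <- data.frame(start = c(1, 4), end = c(4, 6))
  expect_equal(windowMajorityLabels(c(1, 1, 2, 2, 2, 2), win), c(1L, 2L))
  ## volumes 1..4 tie 3/3 vs 1/1 -> lowest label wins; 4..6 majority 3
  expect_equal(windowMajorityLabels(c(3, 3, 1, 1, 3, 3), win), c(1L, 3L))
})

test_that("occupancy scan covers the k range and applies its rule", {
  set.seed(5)
  ## two tight blobs plus sampling noise
  E <- rbind(matrix(rnorm(60 * 6, 0, 0.05), 60, 6),
             matrix(rnorm(60 * 6, 3, 0.05), 60, 6))
  sc <- occupancyScan(list(stackFromEdges(E, 4)), kRange = 2:8,
                      seed = 1, nReplicates = 3)
  expect_equal(nrow(sc$table), 7)
  expect_equal(sc$table$k, 2:8)
  expect_type(sc$table$flagged, "logical")
  expect_false(sc$table$flagged[sc$table$k == 2])
  if (any(!sc$table$flagged))
    expect_equal(sc$recommendedK, max(sc$table$k[!sc$table$flagged]))
  ## the flagging rule itself: more than half the states under the band
  expect_true(all(sc$table$flagged == (sc$table$nLowOccupancy >
                                         sc$table$k / 2)))
})

test_that("transitions-vs-k reports one tested row per k", {
  lib <- buildStateLibrary(2, 6, rep(c("A", "B"), each = 3), 0.8, 1)
  spec <- cohortSpec(lib, list(g1 = makeGroupTransition(2, 0.9),
                               g2 = makeGroupTransition(2, 0.9)),
                     nSubjectsPerGroup = 3, nRuns = 1, nVolumes = 50,
                     seed = 2)
  co <- generateCohort(spec)
  stacks <- lapply(co, function(s)
    dfcStack(s@runs[[1]], windowParams(), requirePrep = FALSE))
  groups <- stats::setNames(vapply(co, function(s) s@group, character(1)),
                            vapply(co, function(s) s@subjectId,
                                   character(1)))
  tvk <- transitionsVsK(stacks, groups, kRange = 2:4, seed = 1,
                        nReplicates = 2)
  expect_equal(nrow(tvk), 3)
  expect_equal(tvk$k, 2:4)
  expect_true(all(tvk$p.value >= 0 & tvk$p.value <= 1))
  expect_true(all(c("mean1", "se1", "mean2", "se2") %in% names(tvk)))
})
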