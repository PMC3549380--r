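test_that("strength sums absolute link weights", {
  aw <- matrix(0, 3, 3)
  aw[1, 2] <- aw[2, 1] <- -0.5
  aw[1, 3] <- aw[3, 1] <- 0.3
  net <- customNetwork(aw)
  expect_equal(nodeStrength(net), c(0.8, 0.5, 0.3))

  # isolated node
  aw4 <- matrix(0, 4, 4)
  aw4[1, 2] <- aw4[2, 1] <- -0.2
  expect_equal(nodeStrength(customNetwork(aw4))[4], 0)
})

test_that("weighted clustering is 1 on a uniform triangle and 0 on a path center", {
  tri <- matrix(c(0, 1, 1,
                  1, 0, -1,
                  1, -1, 0), 3, 3)  # all |w| = 1, mutually linked
  expect_equal(weightedClustering(customNetwork(tri)), c(1, 1, 1))

  path <- matrix(0, 3, 3)
  path[1, 2] <- path[2, 1] <- -0.4
  path[2, 3] <- path[3, 2] <- 0.2
  expect_equal(weightedClustering(customNetwork(path))[2], 0)
})

test_that("clustering handles covalent-only stars and zero-strength nodes", {
  # middle node linked only covalently to both ends: K = 2 but S = 0
  pot <- .testPotential()
  nd <- nodeTable(rbind(c(0, 0, 0), c(3.8, 0, 0), c(7.6, 0, 0)),
                  c("ALA", "LEU", "VAL"), resno = 1:3)
  net <- buildNetwork(nd, pot)
  cc <- weightedClustering(net)
  expect_true(all(is.finite(cc)))
  expect_true(all(cc >= 0 & cc <= 1))
})

test_that("shortest paths take indirect routes when they are shorter", {
  # 3-chain: end-to-end distance is the sum of the two edges
  d <- matrix(Inf, 3, 3); diag(d) <- 0
  d[1, 2] <- d[2, 1] <- 1
  d[2, 3] <- d[3, 2] <- 1
  sp <- shortestPathLengths(customDistanceMatrix(d))
  expect_equal(sp[1, 3], 2)
  expect_equal(averagePathLength(customDistanceMatrix(d))$L, 4 / 3)

  # direct repulsive edge loses to a two-hop attractive route
  d2 <- matrix(Inf, 3, 3); diag(d2) <- 0
  d2[1, 3] <- d2[3, 1] <- 1.76
  d2[1, 2] <- d2[2, 1] <- 0.46
  d2[2, 3] <- d2[3, 2] <- 0.46
  expect_equal(shortestPathLengths(customDistanceMatrix(d2))[1, 3], 0.92)

  # complete unit graph: L = 1
  d3 <- matrix(1, 4, 4); diag(d3) <- 0
  expect_equal(averagePathLength(customDistanceMatrix(d3))$L, 1)
})

test_that("disconnected pairs are Inf and the connected fraction is disclosed", {
  d <- matrix(Inf, 4, 4); diag(d) <- 0
  d[1, 2] <- d[2, 1] <- 1
  d[3, 4] <- d[4, 3] <- 2
  apl <- averagePathLength(customDistanceMatrix(d))
  expect_equal(apl$L, 1.5)
  expect_equal(apl$connectedFraction, 2 / 6)
})

test_that("betweenness matches hand enumerations on a path and a star", {
  d <- matrix(Inf, 3, 3); diag(d) <- 0
  d[1, 2] <- d[2, 1] <- 1
  d[2, 3] <- d[3, 2] <- 1
  expect_equal(betweennessCentrality(customDistanceMatrix(d)), c(0, 1, 0))

  star <- matrix(Inf, 4, 4); diag(star) <- 0
  star[1, 2] <- star[2, 1] <- 1
  star[1, 3] <- star[3, 1] <- 1
  star[1, 4] <- star[4, 1] <- 1
  expect_equal(betweennessCentrality(customDistanceMatrix(star)),
               c(3, 0, 0, 0))
})

test_that("tied shortest paths split the betweenness credit", {
  # diamond: 1-2-4 and 1-3-4 both have length 2
  d <- matrix(Inf, 4, 4); diag(d) <- 0
  d[1, 2] <- d[2, 1] <- 1
  d[1, 3] <- d[3, 1] <- 1
  d[2, 4] <- d[4, 2] <- 1
  d[3, 4] <- d[4, 3] <- 1
  b <- betweennessCentrality(customDistanceMatrix(d))
  expect_equal(b, c(0.5, 0.5, 0.5, 0.5))
})

test_that("betweenness Z-scores use the population convention and sum to zero", {
  z <- betweennessZScore(c(0, 0, 1))
  expect_equal(z, c(-1, -1, 2) / sqrt(2), tolerance = 1e-6)
  expect_equal(z[3], 1.414, tolerance = 1e-3)
  expect_equal(sum(z), 0)

  expect_warning(z0 <- betweennessZScore(c(2, 2, 2)), "zero")
  expect_equal(z0, c(0, 0, 0))

  zs <- betweennessZScore(c(0, 0, 1), sdType = "sample")
  expect_true(max(abs(zs)) < max(abs(z)))  # sample sd is larger
  for (seed in c(4, 9)) {
    b <- betweennessCentrality(distanceMatrix(randomTestNetwork(seed), 1))
    if (sd(b) > 0) expect_equal(sum(betweennessZScore(b)), 0, tolerance = 1e-9)
  }
})

test_that("strength, clustering, paths and betweenness match brute force on small networks", {
  for (seed in 1:12) {
    net <- randomTestNetwork(seed)
    dm <- distanceMatrix(net, 1)
    expect_equal(nodeStrength(net), oracleStrength(net), tolerance = 1e-12)
    expect_equal(weightedClustering(net), oracleClustering(net),
                 tolerance = 1e-12)
    ref <- oraclePathInfo(dm)
    expect_equal(shortestPathLengths(dm), ref$sp, tolerance = 1e-9)
    expect_equal(betweennessCentrality(dm), ref$betweenness,
                 tolerance = 1e-9)
  }
})

test_that("betweenness agrees with an independent graph-library implementation", {
  for (seed in c(2, 21, 33)) {
    net <- randomTestNetwork(seed)
    dm <- distanceMatrix(net, 1)
    d <- as.matrix(dm)
    idx <- which(is.finite(d) & upper.tri(d), arr.ind = TRUE)
    g <- igraph::make_empty_graph(n = nrow(d), directed = FALSE)
    g <- igraph::add_edges(g, t(idx), weight = d[idx])
    expect_equal(betweennessCentrality(dm),
                 igraph::betweenness(g, directed = FALSE),
                 tolerance = 1e-8)
  }
})

test_that("the small-world summary reports the random baselines and ratios", {
  pot <- .testPotential()
  net <- buildNetwork(makeCompactChain(80, seed = 6), pot)
  dm <- distanceMatrix(net, 1)
  s <- smallWorldSummary(net, dm)
  expect_equal(s$randomClustering, s$meanDegree / s$N)
  expect_equal(s$randomPath, log(s$N) / log(s$meanDegree))
  expect_equal(s$clusteringRatio, s$meanClustering / s$randomClustering)
  expect_equal(s$L, averagePathLength(dm)$L)
  expect_true(s$clusteringRatio > 1 && s$pathRatio < 5)

  # mean degree <= 1 leaves the random path length undefined
  aw <- matrix(0, 4, 4); aw[1, 2] <- aw[2, 1] <- -0.3
  tiny <- customNetwork(aw)
  stiny <- smallWorldSummary(tiny, distanceMatrix(tiny, 1))
  expect_true(is.na(stiny$randomPath))
})

test_that("uniform expansion never shortens definition-1 path lengths while links persist", {
  pot <- .testPotential()
  ch <- makeCompactChain(60, seed = 13)
  ser <- makeExpansionSeries(ch, seq(1, 1.3, length.out = 8))
  Ls <- vapply(frames(ser), function(fr) {
    averagePathLength(distanceMatrix(buildNetwork(fr, pot), 1))$L
  }, 0)
  expect_true(all(diff(Ls) >= -1e-9))
})

test_that("the per-node metrics table carries all per-residue quantities", {
  pot <- .testPotential()
  net <- buildNetwork(makeCompactChain(30, seed = 4), pot)
  met <- nodeMetrics(net, distanceMatrix(net, 1))
  expect_named(met, c("chain", "resnum", "type", "K", "S", "C", "B", "Z"))
  expect_equal(nrow(met), 30)
  expect_true(all(met$K >= 0) && all(met$S >= 0))
  expect_true(all(met$C >= 0 & met$C <= 1))
  expect_true(all(met$B >= 0))
  expect_equal(sum(met$Z), 0, tolerance = 1e-9)
})
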