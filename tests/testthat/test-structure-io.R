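test_that("a minimal three-residue file parses into ordered nodes with the defined centroids", {
  st <- readStructure(threeResiduePdb())
  nd <- nodes(st)
  expect_equal(nrow(nd), 3)
  expect_equal(nd$resType, c("ALA", "GLY", "VAL"))
  expect_equal(nd$seqIndex, 0:2)
  # alanine: centroid is CB itself
  expect_equal(unlist(nd[1, c("x", "y", "z")], use.names = FALSE),
               c(1.5, 2.5, 0.5))
  # glycine: no side-chain heavy atom, falls back to CA
  expect_equal(unlist(nd[2, c("x", "y", "z")], use.names = FALSE), c(4, 0, 0))
  # valine: mean of CB, CG1, CG2
  expect_equal(unlist(nd[3, c("x", "y", "z")], use.names = FALSE), c(1, 1, 10))
  expect_equal(nd$nSideChainAtoms, c(1L, 1L, 3L))
})

test_that("waters are never ligands, other HETATM groups are, hydrogens are dropped", {
  path <- threeResiduePdb(extra = c(
    pdbAtomLine("HETATM", 90, "O",  resn = "HOH", chain = "W", resno = 101,
                x = 8, y = 8, z = 8, element = "O"),
    pdbAtomLine("HETATM", 91, "C1", resn = "LIG", chain = "L", resno = 201,
                x = 3, y = 3, z = 3, element = "C"),
    pdbAtomLine("HETATM", 92, "H1", resn = "LIG", chain = "L", resno = 201,
                x = 3, y = 3, z = 4, element = "H"),
    pdbAtomLine("ATOM",  93, "HB1", resn = "ALA", chain = "A", resno = 1,
                x = 1, y = 2, z = 1, element = "H")))
  st <- readStructure(path)
  lg <- ligands(st)
  expect_false(any(lg$resid == "HOH"))
  expect_identical(unique(lg$resid), "LIG")
  expect_equal(nrow(lg), 1)                      # the ligand H is gone
  expect_false(any(atoms(st)$element == "H"))    # the protein H is gone
  expect_equal(nrow(nodes(st)), 3)               # ligand adds no node
})

test_that("altloc handling keeps the highest occupancy and prefers A on ties", {
  path <- writeFixturePdb(c(
    pdbAtomLine("ATOM", 1, "CA", alt = "A", resn = "GLY", resno = 1,
                x = 0, y = 0, z = 0, occ = 0.4),
    pdbAtomLine("ATOM", 2, "CA", alt = "B", resn = "GLY", resno = 1,
                x = 9, y = 0, z = 0, occ = 0.6),
    pdbAtomLine("ATOM", 3, "CA", alt = "A", resn = "GLY", resno = 2,
                x = 3, y = 0, z = 0, occ = 0.5),
    pdbAtomLine("ATOM", 4, "CA", alt = "B", resn = "GLY", resno = 2,
                x = 7, y = 0, z = 0, occ = 0.5)))
  nd <- nodes(readStructure(path))
  expect_equal(nd$x, c(9, 3))  # highest occupancy, then altloc A on the tie
})

test_that("multi-model files honour the requested MODEL number", {
  body1 <- c(pdbAtomLine("ATOM", 1, "CA", resn = "GLY", resno = 1, x = 0),
             pdbAtomLine("ATOM", 2, "CA", resn = "GLY", resno = 2, x = 3.8))
  body2 <- c(pdbAtomLine("ATOM", 1, "CA", resn = "GLY", resno = 1, x = 10),
             pdbAtomLine("ATOM", 2, "CA", resn = "GLY", resno = 2, x = 13.8))
  path <- tempfile(fileext = ".pdb")
  writeLines(c("MODEL        1", body1, "ENDMDL",
               "MODEL        2", body2, "ENDMDL", "END"), path)
  expect_equal(nodes(readStructure(path, model = 2))$x, c(10, 13.8))
  expect_equal(nodes(readStructure(path, model = 1))$x, c(0, 3.8))
  expect_error(readStructure(path, model = 7), "model 7")
})

test_that("conformer series apply stride, order frames by MODEL number, and check rosters", {
  mkbody <- function(x0) c(
    pdbAtomLine("ATOM", 1, "CA", resn = "GLY", resno = 1, x = x0),
    pdbAtomLine("ATOM", 2, "CA", resn = "ALA", resno = 2, x = x0 + 3.8),
    pdbAtomLine("ATOM", 3, "CB", resn = "ALA", resno = 2, x = x0 + 4.8))
  path <- tempfile(fileext = ".pdb")
  blocks <- unlist(lapply(1:10, function(m)
    c(sprintf("MODEL     %4d", m), mkbody(m), "ENDMDL")))
  writeLines(c(blocks, "END"), path)
  ser <- readConformerSeries(path, stride = 2)
  expect_equal(nFrames(ser), 5)
  expect_equal(frameLabels(ser), as.character(c(1, 3, 5, 7, 9)))

  # shuffled MODEL numbers come back sorted
  shuffled <- unlist(lapply(c(3, 1, 2), function(m)
    c(sprintf("MODEL     %4d", m), mkbody(m), "ENDMDL")))
  writeLines(c(shuffled, "END"), path)
  ser2 <- readConformerSeries(path)
  expect_equal(frameLabels(ser2), c("1", "2", "3"))
  expect_equal(nodes(frames(ser2)[[1]])$x[1], 1)

  # single-model file gives a one-frame series
  single <- writeFixturePdb(mkbody(0))
  expect_equal(nFrames(readConformerSeries(single)), 1)

  # diverging rosters are a hard error
  f1 <- writeFixturePdb(mkbody(0))
  f2 <- writeFixturePdb(c(
    pdbAtomLine("ATOM", 1, "CA", resn = "GLY", resno = 1, x = 0),
    pdbAtomLine("ATOM", 2, "CA", resn = "SER", resno = 2, x = 3.8)))
  expect_error(readConformerSeries(c(f1, f2)), "roster|diverge")
})

test_that("radius of gyration matches the definition in degenerate and general cases", {
  one <- aanet:::.beadStructure(matrix(c(0, 0, 0), 1, 3), "ALA")
  expect_equal(radiusOfGyration(one, "centroids"), 0)

  two <- aanet:::.beadStructure(rbind(c(0, 0, 0), c(2, 0, 0)), c("ALA", "GLY"))
  expect_equal(radiusOfGyration(two, "centroids"), 1.0)

  set.seed(11)
  pts <- matrix(rnorm(300, sd = 8), 100, 3)
  types <- sample(aanet:::.standardResidues, 100, replace = TRUE)
  st <- aanet:::.beadStructure(pts, types)
  expect_equal(radiusOfGyration(st, "centroids"), oracleRg(pts),
               tolerance = 1e-12)
  # atoms mode on carbon-only beads agrees with the mass-weighted oracle
  expect_equal(radiusOfGyration(st, "atoms"),
               oracleRg(pts, rep(12.011, 100)), tolerance = 1e-12)
})

test_that("radius of gyration scales linearly under coordinate scaling", {
  ch <- makeCompactChain(40, seed = 5)
  rg1 <- radiusOfGyration(ch, "centroids")
  scaled <- frames(makeExpansionSeries(ch, c(1, 1.7)))[[2]]
  expect_equal(radiusOfGyration(scaled, "centroids"), 1.7 * rg1,
               tolerance = 1e-9)
})

test_that("rigid motions leave inter-centroid distances and network metrics unchanged", {
  pot <- .testPotential()
  ch <- makeCompactChain(30, seed = 2)
  theta <- 0.7
  R <- matrix(c(cos(theta), -sin(theta), 0,
                sin(theta),  cos(theta), 0,
                0, 0, 1), 3, 3, byrow = TRUE)
  shift <- c(12, -5, 30)
  nd <- nodes(ch)
  moved <- as.matrix(nd[, c("x", "y", "z")]) %*% t(R) +
    matrix(shift, nrow(nd), 3, byrow = TRUE)
  st2 <- aanet:::.beadStructure(moved, nd$resType)
  net1 <- buildNetwork(ch, pot)
  net2 <- buildNetwork(st2, pot)
  expect_equal(centroidDistances(net2), centroidDistances(net1),
               tolerance = 1e-9)
  expect_identical(adjacency(net2), adjacency(net1))
  expect_equal(averagePathLength(distanceMatrix(net2, 1))$L,
               averagePathLength(distanceMatrix(net1, 1))$L,
               tolerance = 1e-9)
})

test_that("files with no protein content are rejected", {
  path <- writeFixturePdb(
    pdbAtomLine("HETATM", 1, "C1", resn = "LIG", resno = 1, element = "C"))
  expect_error(suppressWarnings(readStructure(path)), "no protein")
})
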