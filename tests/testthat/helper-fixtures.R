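# Fixtures built in code: PDB text writers, random small networks, and
# hand-crafted network/distance objects.

.testPotential <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- loadPotentialTable()
    cache
  }
})

pdbAtomLine <- function(type = "ATOM", serial = 1, name = "CA", alt = "",
                        resn = "ALA", chain = "A", resno = 1, icode = "",
                        x = 0, y = 0, z = 0, occ = 1, b = 0, element = NULL) {
  if (is.null(element)) element <- substr(trimws(name), 1, 1)
  nm <- if (nchar(name) < 4) sprintf(" %-3s", name) else name
  sprintf("%-6s%5d %4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          type, serial, nm, alt, resn, chain, resno, icode, x, y, z, occ, b,
          element)
}

writeFixturePdb <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), path)
  path
}

# Three residues with known geometry: ALA (centroid = CB), GLY (= CA),
# VAL (= mean of CB, CG1, CG2 = (1,1,10)).
threeResiduePdb <- function(extra = character()) {
  lines <- c(
    pdbAtomLine("ATOM", 1, "N",  resn = "ALA", resno = 1, x = 0, y = 1, z = 0, element = "N"),
    pdbAtomLine("ATOM", 2, "CA", resn = "ALA", resno = 1, x = 0, y = 0, z = 0),
    pdbAtomLine("ATOM", 3, "C",  resn = "ALA", resno = 1, x = 1, y = 0, z = 0),
    pdbAtomLine("ATOM", 4, "O",  resn = "ALA", resno = 1, x = 2, y = 0, z = 0, element = "O"),
    pdbAtomLine("ATOM", 5, "CB", resn = "ALA", resno = 1, x = 1.5, y = 2.5, z = 0.5),
    pdbAtomLine("ATOM", 6, "N",  resn = "GLY", resno = 2, x = 4, y = 1, z = 0, element = "N"),
    pdbAtomLine("ATOM", 7, "CA", resn = "GLY", resno = 2, x = 4, y = 0, z = 0),
    pdbAtomLine("ATOM", 8, "C",  resn = "GLY", resno = 2, x = 5, y = 0, z = 0),
    pdbAtomLine("ATOM", 9, "O",  resn = "GLY", resno = 2, x = 6, y = 0, z = 0, element = "O"),
    pdbAtomLine("ATOM", 10, "N",   resn = "VAL", resno = 3, x = 0, y = 1, z = 10, element = "N"),
    pdbAtomLine("ATOM", 11, "CA",  resn = "VAL", resno = 3, x = 0, y = 0, z = 10),
    pdbAtomLine("ATOM", 12, "C",   resn = "VAL", resno = 3, x = 1, y = 0, z = 10),
    pdbAtomLine("ATOM", 13, "O",   resn = "VAL", resno = 3, x = 2, y = 0, z = 10, element = "O"),
    pdbAtomLine("ATOM", 14, "CB",  resn = "VAL", resno = 3, x = 0, y = 0, z = 10),
    pdbAtomLine("ATOM", 15, "CG1", resn = "VAL", resno = 3, x = 3, y = 0, z = 10),
    pdbAtomLine("ATOM", 16, "CG2", resn = "VAL", resno = 3, x = 0, y = 3, z = 10),
    extra)
  writeFixturePdb(lines)
}

# A bare node table usable by buildNetwork(): positions, types, residue
# numbers (consecutive numbers make covalent pairs), no alpha carbons.
nodeTable <- function(xyz, types, resno = seq_len(nrow(xyz)), chain = "A") {
  xyz <- matrix(xyz, ncol = 3)
  data.frame(chain = chain, seqIndex = seq_len(nrow(xyz)) - 1L,
             pdbResnum = as.character(resno), resType = types,
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             caX = NA_real_, caY = NA_real_, caZ = NA_real_,
             resno = resno, nSideChainAtoms = 1L,
             stringsAsFactors = FALSE)
}

# Random sparse geometric network on 5-10 nodes (a chain backbone plus a
# few spatial contacts), small enough for exhaustive path enumeration.
randomTestNetwork <- function(seed, nRange = 5:10) {
  old <- if (exists(".Random.seed", envir = .GlobalEnv))
    get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv))
  set.seed(seed)
  n <- sample(nRange, 1)
  side <- if (n <= 6) 9 else 14
  pts <- matrix(runif(3 * n, 0, side), n, 3)
  types <- sample(aanet:::.standardResidues, n, replace = TRUE)
  buildNetwork(nodeTable(pts, types), .testPotential())
}

# Hand-crafted network from a weighted adjacency matrix (no covalent links:
# residue numbers are spaced out).
customNetwork <- function(aw, types = NULL) {
  n <- nrow(aw)
  a <- (aw != 0) * 1
  if (is.null(types)) types <- rep("ALA", n)
  nd <- nodeTable(matrix(0, n, 3), types, resno = seq_len(n) * 10L)
  new("AminoAcidNetwork", nodes = nd, cutoff = 6.5,
      centroidDist = matrix(0, n, n), adjacency = a,
      weightedAdjacency = aw, weights = ifelse(a == 1, aw, NA_real_))
}

# Hand-crafted distance matrix (Inf = no direct link, zero diagonal).
customDistanceMatrix <- function(d, definition = 1L) {
  new("DistanceMatrix", definitionId = as.integer(definition), d = d,
      normConstant = 2.19, clampEps = 1e-6, nClamped = 0L)
}
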