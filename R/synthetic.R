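#' Approximate natural amino-acid composition used by the generators
#' @keywords internal
.naturalComposition <- c(
  ALA = 8.3, ARG = 5.5, ASN = 4.1, ASP = 5.4, CYS = 1.4, GLN = 3.9,
  GLU = 6.8, GLY = 7.1, HIS = 2.3, ILE = 5.9, LEU = 9.7, LYS = 5.8,
  MET = 2.4, PHE = 3.9, PRO = 4.7, SER = 6.6, THR = 5.4, TRP = 1.1,
  TYR = 2.9, VAL = 6.9)

# Assemble a single-pseudo-atom ProteinStructure from bead coordinates.
.beadStructure <- function(pts, types, chain = "A", ligand = NULL) {
  n <- nrow(pts)
  nd <- data.frame(chain = chain, seqIndex = seq_len(n) - 1L,
                   pdbResnum = as.character(seq_len(n)), resType = types,
                   x = pts[, 1], y = pts[, 2], z = pts[, 3],
                   caX = pts[, 1], caY = pts[, 2], caZ = pts[, 3],
                   resno = seq_len(n), nSideChainAtoms = 1L,
                   stringsAsFactors = FALSE)
  at <- data.frame(chain = chain, resno = seq_len(n), insert = "",
                   resid = types, elety = "CA", element = "C",
                   x = pts[, 1], y = pts[, 2], z = pts[, 3],
                   stringsAsFactors = FALSE)
  lg <- if (is.null(ligand)) {
    data.frame(ligand = character(), resid = character(),
               chain = character(), resno = integer(), elety = character(),
               element = character(), x = numeric(), y = numeric(),
               z = numeric(), stringsAsFactors = FALSE)
  } else ligand
  new("ProteinStructure", nodes = nd, atoms = at, ligands = lg,
      modelId = 1L)
}

#' Generate a compact self-avoiding chain
#'
#' Deterministic (per seed) bead chain with one pseudo-atom per residue:
#' consecutive beads 3.8 Angstrom apart, a minimum separation between all
#' bead pairs, and a random walk biased toward the running centroid so the
#' chain packs into a globule whose radius of gyration approximates the
#' empirical scaling for folded proteins (about 2.5 n^0.38 Angstrom).
#' Residue types are sampled from an approximate natural composition (or a
#' supplied sequence/weighting). The bead serves as both the alpha carbon
#' and the side-chain centroid, so the full pipeline runs on the result.
#'
#' @param n number of residues (>= 3).
#' @param seed integer seed; the same spec and seed give bit-identical
#'   coordinates.
#' @param composition either a character vector of length `n` (explicit
#'   sequence) or a named numeric vector of sampling weights over the 20
#'   standard types (default: approximate natural abundance).
#' @param bondLength consecutive-bead distance in Angstrom.
#' @param minSeparation minimum distance between any two beads.
#' @param compactness multiplier on the target radius (1 = empirical
#'   globular scaling; larger is looser).
#' @param maxTries placement attempts per bead before giving up.
#' @return a [ProteinStructure-class] object.
#' @export
makeCompactChain <- function(n, seed = 1L, composition = NULL,
                             bondLength = 3.8, minSeparation = 3.4,
                             compactness = 1.0, maxTries = 500L) {
  stopifnot(n >= 3, bondLength > 0, minSeparation > 0,
            minSeparation <= bondLength)
  types <- .sampleTypes(n, composition, seed = seed + 1L)
  targetR <- compactness * 2.5 * n^0.38 * sqrt(5 / 3)
  pts <- withLocalSeed(seed, {
    p <- matrix(NA_real_, n, 3)
    p[1, ] <- c(0, 0, 0)
    p[2, ] <- p[1, ] + bondLength * c(1, 0, 0)
    k <- 3L
    backtracks <- 0L
    while (k <= n) {
      ctr <- colMeans(p[seq_len(k - 1), , drop = FALSE])
      placed <- FALSE
      for (try in seq_len(maxTries)) {
        inward <- ctr - p[k - 1, ]
        dCtr <- sqrt(sum(inward^2))
        bias <- if (dCtr > 1e-8) (dCtr / targetR)^2 * inward / dCtr else c(0, 0, 0)
        v <- rnorm(3) + bias
        v <- v / sqrt(sum(v^2))
        cand <- p[k - 1, ] + bondLength * v
        dPrev <- sqrt(rowSums(sweep(p[seq_len(k - 2), , drop = FALSE], 2,
                                    cand)^2))
        if (!length(dPrev) || min(dPrev) >= minSeparation) {
          p[k, ] <- cand
          placed <- TRUE
          break
        }
      }
      if (placed) {
        k <- k + 1L
      } else {
        # walked into a dead end: undo a few beads and regrow
        backtracks <- backtracks + 1L
        if (backtracks > 50L * n)
          stop(sprintf(
            "could not place bead %d after %d backtracks; increase 'compactness'",
            k, backtracks))
        drop <- min(k - 3L, 5L)
        if (drop > 0) p[(k - drop):k, ] <- NA_real_
        k <- max(3L, k - drop)
      }
    }
    p
  })
  .beadStructure(pts, types)
}

.sampleTypes <- function(n, composition, seed) {
  if (is.character(composition)) {
    stopifnot(length(composition) == n)
    return(mapResidueCode(composition, strict = TRUE))
  }
  wts <- if (is.null(composition)) .naturalComposition else composition
  stopifnot(!is.null(names(wts)), all(names(wts) %in% .standardResidues))
  withLocalSeed(seed,
    sample(names(wts), n, replace = TRUE, prob = wts / sum(wts)))
}

#' Uniform expansion series
#'
#' Emulates progressive loosening of a structure: frame k carries the base
#' coordinates scaled about their centroid by `factors[k]`, so the radius of
#' gyration scales exactly by the factor and spatial links break
#' monotonically as the structure expands.
#'
#' @param base a [ProteinStructure-class] object.
#' @param factors nondecreasing scale factors, all >= 1.
#' @return a [ConformerSeries-class] object with labels `scale=<factor>`.
#' @export
makeExpansionSeries <- function(base, factors) {
  stopifnot(is(base, "ProteinStructure"), all(factors >= 1),
            !is.unsorted(factors))
  ctr <- colMeans(as.matrix(nodes(base)[, c("x", "y", "z")]))
  scaleStructure <- function(s, f) {
    if (f == 1) return(s)
    sc <- function(df, cols) {
      for (ci in seq_along(cols))
        df[[cols[ci]]] <- ctr[ci] + f * (df[[cols[ci]]] - ctr[ci])
      df
    }
    s@nodes <- sc(sc(s@nodes, c("x", "y", "z")), c("caX", "caY", "caZ"))
    s@atoms <- sc(s@atoms, c("x", "y", "z"))
    if (nrow(s@ligands)) s@ligands <- sc(s@ligands, c("x", "y", "z"))
    s
  }
  new("ConformerSeries",
      frames = lapply(factors, function(f) scaleStructure(base, f)),
      frameLabels = sprintf("scale=%.4f", factors))
}

#' Toy protein-ligand complex
#'
#' A compact chain plus a small multi-atom HETATM ligand placed against a
#' surface residue, guaranteeing at least one residue with direct ligand
#' atom contacts while residues linked to it but farther from the ligand
#' provide one-hop cases for the contact classification.
#'
#' @param seed integer seed.
#' @param n chain length.
#' @param contactCutoff cutoff the construction guarantees direct contacts
#'   under.
#' @return a [ProteinStructure-class] object with a ligand named `LIG_L900`.
#' @export
makeToyComplex <- function(seed = 1L, n = 40L, contactCutoff = 4.5) {
  chain <- makeCompactChain(n, seed = seed)
  pts <- as.matrix(nodes(chain)[, c("x", "y", "z")])
  ctr <- colMeans(pts)
  surf <- which.max(rowSums(sweep(pts, 2, ctr)^2))
  outward <- pts[surf, ] - ctr
  outward <- outward / sqrt(sum(outward^2))
  base <- pts[surf, ] + 2.8 * outward
  offs <- rbind(c(0, 0, 0), c(1.4, 0, 0), c(0, 1.4, 0), c(0, 0, 1.4),
                c(1.0, 1.0, 0), c(-1.2, 0.6, 0.6))
  # orient offsets along the outward direction so the ligand sits outside
  lpts <- sweep(offs, 2, base, "+") + 0.6 * matrix(outward, nrow(offs), 3,
                                                   byrow = TRUE)
  lig <- data.frame(ligand = "LIG_L900", resid = "LIG", chain = "L",
                    resno = 900L,
                    elety = paste0("C", seq_len(nrow(lpts))),
                    element = "C",
                    x = lpts[, 1], y = lpts[, 2], z = lpts[, 3],
                    stringsAsFactors = FALSE)
  .beadStructure(pts, nodes(chain)$resType, ligand = lig)
}

#' Write a structure as PDB
#'
#' Protein atoms as ATOM records and ligand atoms as HETATM records, in a
#' file [readStructure()] reads back with zero node loss.
#'
#' @param structure a [ProteinStructure-class] object.
#' @param path output PDB path.
#' @return `path`, invisibly.
#' @export
writeStructurePDB <- function(structure, path) {
  at <- atoms(structure)
  lg <- ligands(structure)
  type <- c(rep("ATOM", nrow(at)), rep("HETATM", nrow(lg)))
  xyz <- rbind(as.matrix(at[, c("x", "y", "z")]),
               as.matrix(lg[, c("x", "y", "z")]))
  bio3d::write.pdb(file = path,
                   xyz = as.vector(t(xyz)),
                   type = type,
                   resno = c(at$resno, lg$resno),
                   resid = c(at$resid, lg$resid),
                   chain = c(at$chain, lg$chain),
                   elety = c(at$elety, lg$elety),
                   elesy = c(at$element, lg$element),
                   eleno = seq_len(nrow(xyz)))
  invisible(path)
}

#' Write a conformer series as a multi-model PDB
#'
#' @param series a [ConformerSeries-class] object.
#' @param path output PDB path.
#' @return `path`, invisibly.
#' @export
writeConformerSeriesPDB <- function(series, path) {
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp))
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  for (k in seq_len(nFrames(series))) {
    writeStructurePDB(frames(series)[[k]], tmp)
    body <- readLines(tmp)
    body <- body[!startsWith(body, "END")]
    writeLines(sprintf("MODEL     %4d", k), con)
    writeLines(body, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
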