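.backboneAtoms <- c("N", "CA", "C", "O", "OXT")
.waterResids   <- c("HOH", "WAT", "DOD", "H2O")

.atomicMass <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
                 P = 30.974, SE = 78.971, F = 18.998, CL = 35.45,
                 BR = 79.904, I = 126.904, FE = 55.845, ZN = 65.38,
                 MG = 24.305, CA = 40.078, MN = 54.938, "NA" = 22.99,
                 K = 39.098)

# Element symbol per atom; uses the PDB element column when present and
# falls back to bio3d's name-based assignment.
.atomElements <- function(atom) {
  ele <- toupper(trimws(as.character(atom$elesy)))
  bad <- is.na(ele) | ele == ""
  if (any(bad))
    ele[bad] <- toupper(bio3d::atom2ele(atom$elety[bad]))
  ele
}

# Highest-occupancy altloc filter; ties resolved toward altloc "A", then
# file order. Operates on a bio3d atom data.frame.
.filterAltloc <- function(atom) {
  alt <- as.character(atom$alt)
  alt[is.na(alt)] <- ""
  if (all(alt == "")) return(atom)
  occ <- atom$o
  occ[is.na(occ)] <- 1
  key <- paste(atom$chain, atom$resno, atom$insert, atom$resid, atom$elety,
               sep = "|")
  ord <- order(key, -occ, alt != "A", seq_len(nrow(atom)))
  keep <- !duplicated(key[ord])
  atom[sort(seq_len(nrow(atom))[ord][keep]), , drop = FALSE]
}

#' Side-chain geometric center of one residue
#'
#' Unweighted mean of the heavy side-chain atom coordinates (all atoms except
#' backbone N, CA, C, O and terminal OXT; hydrogens are assumed removed).
#' Glycine, or any residue whose side-chain heavy atoms are unresolved, falls
#' back to the alpha-carbon position.
#'
#' @param elety atom names of one residue's heavy atoms.
#' @param xyz matrix (one row per atom) of their coordinates.
#' @return list with `centroid` (length-3 numeric), `nAtoms` used, and `ca`
#'   (CA coordinate or NA).
#' @export
sideChainCentroid <- function(elety, xyz) {
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  elety <- trimws(as.character(elety))
  ca <- if ("CA" %in% elety) xyz[match("CA", elety), ] else rep(NA_real_, 3)
  side <- !(elety %in% .backboneAtoms)
  if (any(side)) {
    list(centroid = colMeans(xyz[side, , drop = FALSE]),
         nAtoms = sum(side), ca = ca)
  } else if (!anyNA(ca)) {
    list(centroid = ca, nAtoms = 1L, ca = ca)
  } else {
    list(centroid = colMeans(xyz), nAtoms = nrow(xyz), ca = ca)
  }
}

#' Read a protein structure from a PDB file
#'
#' Parses ATOM/HETATM records into residue nodes (side-chain geometric
#' centers), protein heavy atoms and non-water ligand groups. Hydrogens are
#' discarded; for alternate locations the highest-occupancy conformer is
#' kept (ties resolved toward altloc A). Nonstandard residue names are
#' mapped through a small alias table (MSE to MET, HSD/HSE to HIS, ...); in
#' lenient mode anything unmappable is skipped with a warning, in strict
#' mode it is an error.
#'
#' @param path a PDB file.
#' @param model model number to extract from multi-model files (default 1;
#'   matched against the file's MODEL record numbers).
#' @param chainFilter optional character vector of chain identifiers to keep.
#' @param strict error on unmappable residue types instead of skipping.
#' @return a [ProteinStructure-class] object.
#' @export
readStructure <- function(path, model = 1, chainFilter = NULL,
                          strict = FALSE) {
  pdb <- tryCatch(
    bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE, verbose = FALSE),
    error = function(e) stop("cannot parse PDB file '", path, "': ",
                             conditionMessage(e)))
  nModels <- if (is.matrix(pdb$xyz)) nrow(pdb$xyz) else 1L
  modelNumbers <- .pdbModelNumbers(path, nModels)
  idx <- match(model, modelNumbers)
  if (is.na(idx))
    stop(sprintf("model %s not present in '%s' (models: %s)", model, path,
                 paste(modelNumbers, collapse = ", ")))
  atom <- pdb$atom
  if (nModels > 1) {
    xyz <- matrix(pdb$xyz[idx, ], ncol = 3, byrow = TRUE)
    atom$x <- xyz[, 1]; atom$y <- xyz[, 2]; atom$z <- xyz[, 3]
  }
  .structureFromAtoms(atom, modelId = as.integer(model),
                      chainFilter = chainFilter, strict = strict)
}

# MODEL record numbers in file order (length n); 1 when absent.
.pdbModelNumbers <- function(path, n) {
  ln <- readLines(path, warn = FALSE)
  mn <- suppressWarnings(as.integer(substr(ln[startsWith(ln, "MODEL")], 11, 14)))
  mn <- mn[!is.na(mn)]
  if (length(mn) >= n) mn[seq_len(n)] else seq_len(n)
}

.structureFromAtoms <- function(atom, modelId = 1L, chainFilter = NULL,
                                strict = FALSE) {
  atom$chain[is.na(atom$chain)] <- " "
  atom$insert[is.na(atom$insert)] <- ""
  if (!is.null(chainFilter))
    atom <- atom[atom$chain %in% chainFilter, , drop = FALSE]
  atom <- .filterAltloc(atom)
  ele <- .atomElements(atom)
  keep <- ele != "H" & ele != "D"
  atom <- atom[keep, , drop = FALSE]
  ele <- ele[keep]
  isWater <- atom$resid %in% .waterResids
  mapped <- suppressWarnings(mapResidueCode(atom$resid))
  isProt <- !is.na(mapped) & atom$type == "ATOM"
  # residues like MSE arrive as HETATM but are part of the chain
  isProt <- isProt | (!is.na(mapped) & atom$type == "HETATM" &
                        atom$resid %in% names(.residueAliases))
  unmappable <- !isProt & !isWater & atom$type == "ATOM"
  if (any(unmappable)) {
    bad <- unique(atom$resid[unmappable])
    if (strict)
      stop("unmappable residue type(s) in ATOM records: ",
           paste(bad, collapse = ", "))
    warning("skipping unmappable ATOM residue(s): ",
            paste(bad, collapse = ", "))
  }
  prot <- atom[isProt, , drop = FALSE]
  if (!nrow(prot)) stop("no protein residues found")
  protEle <- ele[isProt]
  lig <- atom[!isProt & !isWater & !unmappable, , drop = FALSE]
  ligEle <- ele[!isProt & !isWater & !unmappable]

  key <- paste(prot$chain, prot$resno, prot$insert, sep = "|")
  ord <- order(prot$chain, match(key, unique(key)))
  prot <- prot[ord, , drop = FALSE]
  protEle <- protEle[ord]
  key <- key[ord]
  first <- !duplicated(key)
  resKeys <- key[first]
  nd <- lapply(seq_along(resKeys), function(i) {
    rows <- which(key == resKeys[i])
    sc <- sideChainCentroid(prot$elety[rows],
                            cbind(prot$x[rows], prot$y[rows], prot$z[rows]))
    data.frame(chain = prot$chain[rows[1]],
               pdbResnum = paste0(prot$resno[rows[1]],
                                  trimws(prot$insert[rows[1]])),
               resType = mapResidueCode(prot$resid[rows[1]]),
               x = sc$centroid[1], y = sc$centroid[2], z = sc$centroid[3],
               caX = sc$ca[1], caY = sc$ca[2], caZ = sc$ca[3],
               resno = prot$resno[rows[1]],
               nSideChainAtoms = sc$nAtoms,
               stringsAsFactors = FALSE)
  })
  nd <- do.call(rbind, nd)
  nd$seqIndex <- seq_len(nrow(nd)) - 1L
  nd <- nd[, c("chain", "seqIndex", "pdbResnum", "resType",
               "x", "y", "z", "caX", "caY", "caZ", "resno",
               "nSideChainAtoms")]
  rownames(nd) <- NULL

  atomsDf <- data.frame(chain = prot$chain, resno = prot$resno,
                        insert = trimws(prot$insert), resid = prot$resid,
                        elety = trimws(prot$elety), element = protEle,
                        x = prot$x, y = prot$y, z = prot$z,
                        stringsAsFactors = FALSE)
  ligDf <- if (nrow(lig)) {
    data.frame(ligand = paste0(lig$resid, "_", lig$chain, lig$resno),
               resid = lig$resid, chain = lig$chain, resno = lig$resno,
               elety = trimws(lig$elety), element = ligEle,
               x = lig$x, y = lig$y, z = lig$z, stringsAsFactors = FALSE)
  } else {
    data.frame(ligand = character(), resid = character(),
               chain = character(), resno = integer(), elety = character(),
               element = character(), x = numeric(), y = numeric(),
               z = numeric(), stringsAsFactors = FALSE)
  }
  new("ProteinStructure", nodes = nd, atoms = atomsDf, ligands = ligDf,
      modelId = as.integer(modelId))
}

#' Read a conformer series
#'
#' Builds an ordered [ConformerSeries-class] from one multi-model PDB file
#' (frames ordered by MODEL number) or a vector of single-model files (file
#' order). All frames must share one residue roster.
#'
#' @param paths one multi-model PDB file, or several PDB files.
#' @param stride keep every stride-th frame (default 1).
#' @param chainFilter,strict passed to [readStructure()].
#' @return a [ConformerSeries-class] object.
#' @export
readConformerSeries <- function(paths, stride = 1L, chainFilter = NULL,
                                strict = FALSE) {
  stopifnot(stride >= 1)
  if (length(paths) == 1) {
    pdb <- bio3d::read.pdb(paths, multi = TRUE, rm.alt = FALSE,
                           verbose = FALSE)
    nModels <- if (is.matrix(pdb$xyz)) nrow(pdb$xyz) else 1L
    nums <- sort(.pdbModelNumbers(paths, nModels))
    frames <- lapply(nums, function(m)
      readStructure(paths, model = m, chainFilter = chainFilter,
                    strict = strict))
    labels <- as.character(nums)
  } else {
    frames <- lapply(paths, readStructure, chainFilter = chainFilter,
                     strict = strict)
    labels <- basename(paths)
  }
  keep <- seq(1L, length(frames), by = stride)
  out <- new("ConformerSeries", frames = frames[keep],
             frameLabels = labels[keep])
  validObject(out)
  out
}

#' Radius of gyration
#'
#' Root-mean-square distance of points from their center: over all heavy
#' atoms with atomic-mass weighting (`mode = "atoms"`), or unweighted over
#' the residue side-chain centroids (`mode = "centroids"`).
#'
#' @param structure a [ProteinStructure-class] object.
#' @param mode `"atoms"` or `"centroids"`.
#' @return radius of gyration in Angstrom.
#' @export
radiusOfGyration <- function(structure, mode = c("atoms", "centroids")) {
  mode <- match.arg(mode)
  if (mode == "centroids") {
    pts <- as.matrix(nodes(structure)[, c("x", "y", "z")])
    w <- rep(1, nrow(pts))
  } else {
    at <- atoms(structure)
    pts <- as.matrix(at[, c("x", "y", "z")])
    w <- .atomicMass[at$element]
    w[is.na(w)] <- 12.011
  }
  if (!nrow(pts)) stop("no points to compute a radius of gyration from")
  ctr <- colSums(pts * w) / sum(w)
  sqrt(sum(w * rowSums(sweep(pts, 2, ctr)^2)) / sum(w))
}

#' Write the residue-node table
#'
#' Tab-separated export of the node roster: chain, residue number, type and
#' side-chain centroid coordinates.
#'
#' @param structure a [ProteinStructure-class] object.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeNodesTable <- function(structure, path) {
  nd <- nodes(structure)
  out <- nd[, c("chain", "pdbResnum", "resType", "x", "y", "z")]
  names(out) <- c("chain", "resnum", "type", "x", "y", "z")
  write.table(format(out, digits = 10, trim = TRUE), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}
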