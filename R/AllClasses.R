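#' Contact potential table
#'
#' A symmetric 20 x 20 matrix of pairwise residue contact energies in RT
#' units, indexed by three-letter residue codes. Negative entries are
#' attractive ("similar" weights); positive entries are repulsive
#' ("dissimilar" weights).
#'
#' @slot energies named numeric matrix, 20 x 20, symmetric.
#' @slot provenance one-line description of where the table came from.
#' @exportClass ContactPotential
setClass("ContactPotential",
  representation(energies = "matrix", provenance = "character"))

setValidity("ContactPotential", function(object) {
  e <- object@energies
  msg <- character()
  if (!is.numeric(e) || nrow(e) != 20L || ncol(e) != 20L)
    msg <- c(msg, "energies must be a numeric 20 x 20 matrix")
  else {
    if (is.null(rownames(e)) || is.null(colnames(e)) ||
        !identical(rownames(e), colnames(e)))
      msg <- c(msg, "row and column names must be identical residue codes")
    if (anyNA(e) || any(!is.finite(e)))
      msg <- c(msg, "energies must be finite")
    else if (max(abs(e - t(e))) > 1e-9)
      msg <- c(msg, "energies must be symmetric to 1e-9")
  }
  if (length(msg)) msg else TRUE
})

#' Parsed protein structure
#'
#' Residue nodes (one per amino acid, positioned at the side-chain geometric
#' center), all protein heavy atoms, and non-water HETATM ligand groups.
#'
#' @slot nodes data.frame with one row per residue: chain, seqIndex (0-based
#'   position along the parsed roster), pdbResnum (author numbering plus
#'   insertion code), resType, x/y/z side-chain centroid (Angstrom),
#'   caX/caY/caZ alpha-carbon coordinates (NA when absent),
#'   nSideChainAtoms.
#' @slot atoms data.frame of protein heavy atoms (chain, resno, insert,
#'   resid, elety, element, x, y, z).
#' @slot ligands data.frame of ligand heavy atoms (ligand, resid, chain,
#'   resno, elety, element, x, y, z); waters are never included.
#' @slot modelId integer conformer index (1 for single-model files).
#' @exportClass ProteinStructure
setClass("ProteinStructure",
  representation(nodes = "data.frame", atoms = "data.frame",
                 ligands = "data.frame", modelId = "integer"))

setValidity("ProteinStructure", function(object) {
  nd <- object@nodes
  msg <- character()
  need <- c("chain", "seqIndex", "pdbResnum", "resType", "x", "y", "z",
            "nSideChainAtoms")
  if (!all(need %in% names(nd)))
    msg <- c(msg, paste("nodes lacks columns:",
                        paste(setdiff(need, names(nd)), collapse = ", ")))
  else {
    if (nrow(nd) && any(!is.finite(as.matrix(nd[, c("x", "y", "z")]))))
      msg <- c(msg, "node centroids must be finite")
    if (nrow(nd) && any(nd$nSideChainAtoms < 1L))
      msg <- c(msg, "every node must average at least one atom")
  }
  if (nrow(object@ligands) &&
      any(object@ligands$resid %in% c("HOH", "WAT", "DOD", "H2O")))
    msg <- c(msg, "ligands must not contain waters")
  if (length(msg)) msg else TRUE
})

#' Conformer series
#'
#' An ordered list of [ProteinStructure] frames sharing one residue roster,
#' e.g. snapshots extracted from a trajectory or the models of a multi-model
#' PDB file.
#'
#' @slot frames list of ProteinStructure objects.
#' @slot frameLabels character annotations (model numbers, times, file names).
#' @exportClass ConformerSeries
setClass("ConformerSeries",
  representation(frames = "list", frameLabels = "character"))

setValidity("ConformerSeries", function(object) {
  if (!length(object@frames)) return("series must contain at least one frame")
  if (length(object@frameLabels) != length(object@frames))
    return("frameLabels must match the number of frames")
  roster <- function(s) s@nodes[, c("chain", "resType")]
  ref <- roster(object@frames[[1]])
  for (k in seq_along(object@frames)) {
    cur <- roster(object@frames[[k]])
    if (nrow(cur) != nrow(ref) || !isTRUE(all.equal(ref, cur,
                                                    check.attributes = FALSE))) {
      i <- if (nrow(cur) != nrow(ref)) 1L else
        which(ref$chain != cur$chain | ref$resType != cur$resType)[1]
      return(sprintf(
        "frame %d diverges from frame 1 at roster position %d", k, i))
    }
  }
  TRUE
})

#' Weighted amino acid network
#'
#' Unweighted and weighted adjacency built from residue nodes: a link exists
#' when the inter-centroid distance is below the cutoff, and sequence
#' neighbours are always linked with weight zero (covalent backbone link).
#'
#' @slot nodes the residue roster (as in [ProteinStructure]).
#' @slot cutoff link cutoff r_c in Angstrom.
#' @slot centroidDist symmetric matrix of inter-centroid distances (Angstrom).
#' @slot adjacency symmetric 0/1 matrix; zero diagonal.
#' @slot weightedAdjacency symmetric matrix; contact energy on spatial links,
#'   zero on covalent sequence-neighbour links.
#' @slot weights contact energy w_ij for every linked pair (covalent links
#'   included, before the covalent zeroing); NA where no link.
#' @exportClass AminoAcidNetwork
setClass("AminoAcidNetwork",
  representation(nodes = "data.frame", cutoff = "numeric",
                 centroidDist = "matrix", adjacency = "matrix",
                 weightedAdjacency = "matrix", weights = "matrix"))

setValidity("AminoAcidNetwork", function(object) {
  a <- object@adjacency; aw <- object@weightedAdjacency
  msg <- character()
  if (any(diag(a) != 0)) msg <- c(msg, "adjacency diagonal must be zero")
  if (!isTRUE(all.equal(a, t(a)))) msg <- c(msg, "adjacency must be symmetric")
  if (max(abs(aw - t(aw))) > 1e-12)
    msg <- c(msg, "weighted adjacency must be symmetric")
  if (!all(a %in% c(0, 1))) msg <- c(msg, "adjacency must be 0/1")
  if (object@cutoff <= 0) msg <- c(msg, "cutoff must be positive")
  if (length(msg)) msg else TRUE
})

#' Graph distance matrix
#'
#' Per-link graph distances under one of the three weight-to-distance
#' definitions; unlinked pairs carry Inf, the diagonal is zero.
#'
#' @slot definitionId 1, 2 or 3.
#' @slot d symmetric matrix of link distances (dimensionless).
#' @slot normConstant the definition-2 divisor (default 2.19).
#' @slot clampEps floor applied to non-positive definition-2 distances.
#' @slot nClamped number of link distances clamped to clampEps.
#' @exportClass DistanceMatrix
setClass("DistanceMatrix",
  representation(definitionId = "integer", d = "matrix",
                 normConstant = "numeric", clampEps = "numeric",
                 nClamped = "integer"))

setValidity("DistanceMatrix", function(object) {
  d <- object@d
  msg <- character()
  if (!object@definitionId %in% 1:3)
    msg <- c(msg, "definitionId must be 1, 2 or 3")
  if (any(diag(d) != 0)) msg <- c(msg, "diagonal must be zero")
  fin <- is.finite(d) & upper.tri(d)
  if (any(d[fin] <= 0))
    msg <- c(msg, "all finite off-diagonal distances must be positive")
  if (max(abs(d - t(d)), na.rm = TRUE) > 1e-12)
    msg <- c(msg, "distance matrix must be symmetric")
  if (length(msg)) msg else TRUE
})
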