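#' Build the weighted amino acid network
#'
#' Links every pair of residues whose side-chain centers lie strictly within
#' the cutoff (default 6.5 Angstrom, the cutoff used when the contact
#' potential itself was derived). Sequence neighbours within a chain are
#' covalently bonded: any link between them carries weight zero. When their
#' centers fall outside the cutoff the covalent link is still forced to
#' exist, unless the geometry contradicts an intact backbone bond
#' (alpha-carbons more than 4.5 Angstrom apart) or the numbering has a gap
#' -- both mark a chain break. All other links are weighted by the contact
#' energy of the residue-type pair.
#'
#' @param x a [ProteinStructure-class] or a node data.frame (as in
#'   `nodes()`).
#' @param table a [ContactPotential-class] object.
#' @param cutoff link cutoff r_c in Angstrom (default 6.5; comparison is
#'   strict, a pair exactly at the cutoff is not linked).
#' @return an [AminoAcidNetwork-class] object.
#' @examples
#' pot <- loadPotentialTable()
#' chain <- makeCompactChain(60, seed = 1)
#' net <- buildNetwork(chain, pot)
#' net
#' @export
buildNetwork <- function(x, table, cutoff = 6.5) {
  stopifnot(is(table, "ContactPotential"), cutoff > 0)
  nd <- if (is(x, "ProteinStructure")) nodes(x) else x
  if (nrow(nd) < 2) stop("need at least two residue nodes")
  types <- mapResidueCode(nd$resType)
  if (anyNA(types)) {
    nd <- nd[!is.na(types), , drop = FALSE]
    types <- types[!is.na(types)]
    if (nrow(nd) < 2) stop("fewer than two mappable residue nodes")
  }
  n <- nrow(nd)
  pts <- as.matrix(nd[, c("x", "y", "z")])
  r <- as.matrix(dist(pts))
  dimnames(r) <- NULL

  a <- (r < cutoff) * 1
  diag(a) <- 0

  w <- energies(table)[cbind(rep(types, times = n),
                             rep(types, each = n))]
  w <- matrix(w, n, n)

  cov <- .covalentPairs(nd)
  for (k in seq_len(nrow(cov$forced))) {
    i <- cov$forced[k, 1]; j <- cov$forced[k, 2]
    a[i, j] <- a[j, i] <- 1
  }
  aw <- a * w
  for (k in seq_len(nrow(cov$neighbours))) {
    i <- cov$neighbours[k, 1]; j <- cov$neighbours[k, 2]
    aw[i, j] <- aw[j, i] <- 0
  }
  wLinked <- ifelse(a == 1, w, NA_real_)
  net <- new("AminoAcidNetwork", nodes = nd, cutoff = cutoff,
             centroidDist = r, adjacency = a, weightedAdjacency = aw,
             weights = wLinked)
  validObject(net)
  net
}

# Sequence-neighbour pairs (i, j = i+1 in roster order): same chain,
# consecutive (or insertion-coded equal) numbering. `neighbours` always get
# zero link weight; `forced` is the subset whose link is created even beyond
# the cutoff -- only where the geometry supports an intact backbone bond
# (CA-CA <= 4.5 Angstrom, or alpha carbons unavailable).
.covalentPairs <- function(nd) {
  n <- nrow(nd)
  if (n < 2) {
    e <- matrix(integer(), ncol = 2)
    return(list(neighbours = e, forced = e))
  }
  i <- seq_len(n - 1); j <- i + 1
  same <- nd$chain[i] == nd$chain[j]
  gap <- nd$resno[j] - nd$resno[i]
  consec <- !is.na(gap) & gap %in% c(0L, 1L)
  nb <- same & consec
  hasCA <- !is.na(nd$caX[i]) & !is.na(nd$caX[j])
  caD <- sqrt((nd$caX[j] - nd$caX[i])^2 + (nd$caY[j] - nd$caY[i])^2 +
                (nd$caZ[j] - nd$caZ[i])^2)
  forced <- nb & (!hasCA | (caD <= 4.5))
  list(neighbours = cbind(i[nb], j[nb]),
       forced = cbind(i[forced], j[forced]))
}

#' Weight-to-distance conversion
#'
#' Turns the weighted network into per-link graph distances under one of
#' three definitions. With `definition = 1` (the recommended one) attractive
#' links (w < 0, similar weight) get d = 1/(1 - w) < 1, covalent links
#' (w = 0) get d = 1, and repulsive links (w > 0, dissimilar weight) get
#' d = 1 + w. `definition = 2` treats every weight as dissimilar:
#' d = (1 + w)/normConstant; weights at or below -1 would make this
#' non-positive, so such distances are clamped to `clampEps` (the clamp
#' count is recorded in the object). `definition = 3` treats every weight
#' as similar: d = 1/(1 - w), which stretches strongly repulsive links.
#' Unlinked pairs are Inf; the diagonal is zero.
#'
#' @param network an [AminoAcidNetwork-class] object.
#' @param definition 1, 2 or 3.
#' @param normConstant the definition-2 divisor (default 2.19).
#' @param clampEps positive floor for definition-2 distances (default 1e-6).
#' @return a [DistanceMatrix-class] object.
#' @export
distanceMatrix <- function(network, definition = 1, normConstant = 2.19,
                           clampEps = 1e-6) {
  stopifnot(is(network, "AminoAcidNetwork"),
            definition %in% 1:3, normConstant > 0, clampEps > 0)
  a <- adjacency(network)
  w <- weightedAdjacency(network)  # covalent links already carry w = 0
  linked <- a == 1
  d <- matrix(Inf, nrow(a), ncol(a))
  nClamped <- 0L
  if (definition == 1) {
    d[linked] <- ifelse(w[linked] < 0, 1 / (1 - w[linked]),
                        ifelse(w[linked] > 0, 1 + w[linked], 1))
  } else if (definition == 2) {
    v <- (1 + w[linked]) / normConstant
    nClamped <- as.integer(sum(v <= 0) / 2)
    v[v <= 0] <- clampEps
    d[linked] <- v
  } else {
    if (any(w[linked] >= 1))
      stop("definition 3 is singular for weights >= 1")
    d[linked] <- 1 / (1 - w[linked])
  }
  diag(d) <- 0
  out <- new("DistanceMatrix", definitionId = as.integer(definition), d = d,
             normConstant = normConstant, clampEps = clampEps,
             nClamped = nClamped)
  validObject(out)
  out
}

#' Export the link list
#'
#' Tab-separated edge list: one row per unordered linked pair with the
#' inter-centroid distance, the link weight and (optionally) the graph
#' distance under a chosen definition.
#'
#' @param network an [AminoAcidNetwork-class] object.
#' @param path output TSV path.
#' @param dm optional [DistanceMatrix-class] computed from `network`.
#' @return `path`, invisibly.
#' @export
exportEdgeList <- function(network, path, dm = NULL) {
  a <- adjacency(network)
  nd <- nodes(network)
  idx <- which(a == 1 & upper.tri(a), arr.ind = TRUE)
  out <- data.frame(
    chain_i = nd$chain[idx[, 1]], resnum_i = nd$pdbResnum[idx[, 1]],
    chain_j = nd$chain[idx[, 2]], resnum_j = nd$pdbResnum[idx[, 2]],
    r_ij = centroidDistances(network)[idx],
    w_ij = weightedAdjacency(network)[idx])
  if (!is.null(dm)) out$d_ij <- as.matrix(dm)[idx]
  write.table(format(out, digits = 8, trim = TRUE), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export the adjacency matrix in Matrix Market format
#'
#' @param network an [AminoAcidNetwork-class] object.
#' @param path output `.mtx` path.
#' @param weighted export the weighted adjacency instead of the 0/1 one.
#' @return `path`, invisibly.
#' @export
exportAdjacency <- function(network, path, weighted = FALSE) {
  m <- if (weighted) weightedAdjacency(network) else adjacency(network)
  Matrix::writeMM(methods::as(Matrix::Matrix(m, sparse = TRUE),
                              "generalMatrix"), path)
  invisible(path)
}
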