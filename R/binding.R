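#' Heavy-atom contact counts
#'
#' Counts heavy-atom pairs within a spatial cutoff (default 4.5 Angstrom):
#' between every residue and every ligand group, and between every residue
#' pair (raw counts; sequence neighbours are not excluded). Residue atoms
#' include backbone atoms; ligand atoms are all non-hydrogen HETATM atoms.
#'
#' @param structure a [ProteinStructure-class] object.
#' @param contactCutoff contact cutoff in Angstrom.
#' @return list with `contactCutoff`, `residueLigand` (vector of per-residue
#'   ligand contact counts, one entry per node), `residueLigandByGroup`
#'   (matrix residue x ligand group) and `residueResidue` (symmetric count
#'   matrix).
#' @export
atomContacts <- function(structure, contactCutoff = 4.5) {
  stopifnot(is(structure, "ProteinStructure"), contactCutoff > 0)
  nd <- nodes(structure)
  at <- atoms(structure)
  lg <- ligands(structure)
  n <- nrow(nd)
  resKey <- paste(nd$chain, nd$pdbResnum, sep = "|")
  atomRes <- match(paste(at$chain, paste0(at$resno, at$insert), sep = "|"),
                   resKey)
  keep <- !is.na(atomRes)
  at <- at[keep, , drop = FALSE]; atomRes <- atomRes[keep]
  pa <- as.matrix(at[, c("x", "y", "z")])

  groups <- unique(lg$ligand)
  rlg <- matrix(0L, n, length(groups),
                dimnames = list(NULL, groups))
  if (!length(groups))
    warning("structure has no ligand; residue-ligand contact counts are zero")
  for (g in groups) {
    pl <- as.matrix(lg[lg$ligand == g, c("x", "y", "z"), drop = FALSE])
    dd <- .crossDist(pa, pl)
    hit <- dd < contactCutoff
    if (any(hit))
      rlg[, g] <- as.integer(tapply(rowSums(hit), factor(atomRes, levels = seq_len(n)),
                                    sum, default = 0L))
  }
  rr <- matrix(0L, n, n)
  dd <- .crossDist(pa, pa)
  hit <- dd < contactCutoff
  if (any(hit)) {
    idx <- which(hit, arr.ind = TRUE)
    ri <- atomRes[idx[, 1]]; rj <- atomRes[idx[, 2]]
    off <- ri != rj
    if (any(off)) {
      tab <- table(factor(ri[off], levels = seq_len(n)),
                   factor(rj[off], levels = seq_len(n)))
      rr <- matrix(as.integer(tab), n, n)
    }
  }
  list(contactCutoff = contactCutoff,
       residueLigand = as.integer(rowSums(rlg)),
       residueLigandByGroup = rlg,
       residueResidue = rr)
}

.crossDist <- function(a, b) {
  if (!nrow(a) || !nrow(b)) return(matrix(numeric(), nrow(a), nrow(b)))
  aa <- rowSums(a^2); bb <- rowSums(b^2)
  d2 <- outer(aa, bb, "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

#' Classify residues by ligand-contact topology
#'
#' `direct`: the residue itself has heavy-atom contacts with a ligand;
#' `one-hop`: no direct contact, but a network neighbour (unweighted
#' adjacency) has; `unconnected`: neither. The classes are exhaustive and
#' mutually exclusive.
#'
#' @param contacts output of [atomContacts()].
#' @param network the [AminoAcidNetwork-class] built from the same
#'   structure.
#' @return data.frame per residue: classification, ligandContacts, mediator
#'   (roster index of the best-connected contacting neighbour, NA
#'   otherwise), mediatorContacts (heavy-atom contacts with that mediator),
#'   mediatorLigandContacts.
#' @export
classifyLigandContacts <- function(contacts, network) {
  a <- adjacency(network)
  n <- nrow(a)
  stopifnot(length(contacts$residueLigand) == n)
  rl <- contacts$residueLigand
  cls <- rep("unconnected", n)
  med <- rep(NA_integer_, n)
  medC <- rep(NA_integer_, n)
  medL <- rep(NA_integer_, n)
  cls[rl > 0] <- "direct"
  for (i in which(rl == 0)) {
    nbrs <- which(a[i, ] == 1 & rl > 0)
    if (length(nbrs)) {
      cls[i] <- "one-hop"
      # mediator: the contacting neighbour sharing the most atom contacts
      best <- nbrs[which.max(contacts$residueResidue[i, nbrs])]
      med[i] <- best
      medC[i] <- contacts$residueResidue[i, best]
      medL[i] <- rl[best]
    }
  }
  data.frame(classification = cls, ligandContacts = rl,
             mediator = med, mediatorContacts = medC,
             mediatorLigandContacts = medL, stringsAsFactors = FALSE)
}

#' Hot-spot report
#'
#' Residues whose betweenness Z-score reaches the significance threshold
#' (default 3.0), each classified by its contact topology relative to the
#' bound ligand: in direct heavy-atom contact with the drug, one network
#' hop from a contacting residue (the mediator and its contact counts are
#' reported), or unconnected.
#'
#' @param metrics per-node metrics from [nodeMetrics()].
#' @param contacts output of [atomContacts()] on the same structure.
#' @param network the [AminoAcidNetwork-class] for the same structure.
#' @param zThreshold significance bound on the Z-score (default 3.0).
#' @return data.frame, one row per hot-spot candidate: chain, resnum, type,
#'   Z, classification, ligandContacts, mediator residue label,
#'   mediatorContacts, mediatorLigandContacts. Zero rows when no residue
#'   reaches the threshold.
#' @examples
#' pot <- loadPotentialTable()
#' cplx <- makeToyComplex(seed = 1)
#' net <- buildNetwork(cplx, pot)
#' met <- nodeMetrics(net, distanceMatrix(net, 1))
#' hotspotReport(met, atomContacts(cplx), net, zThreshold = 2)
#' @export
hotspotReport <- function(metrics, contacts, network, zThreshold = 3.0) {
  nd <- nodes(network)
  stopifnot(nrow(metrics) == nrow(nd))
  cls <- classifyLigandContacts(contacts, network)
  sel <- which(metrics$Z >= zThreshold)
  lab <- paste0(nd$resType, nd$pdbResnum)
  out <- data.frame(chain = nd$chain[sel], resnum = nd$pdbResnum[sel],
                    type = nd$resType[sel], Z = metrics$Z[sel],
                    classification = cls$classification[sel],
                    ligandContacts = cls$ligandContacts[sel],
                    mediator = ifelse(is.na(cls$mediator[sel]), NA_character_,
                                      lab[cls$mediator[sel]]),
                    mediatorContacts = cls$mediatorContacts[sel],
                    mediatorLigandContacts = cls$mediatorLigandContacts[sel],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
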