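#' @name aanet-accessors
#' @title Accessors for aanet classes
#' @description Slot accessors; user code should use these rather than `@`.
#' @param x an aanet object.
#' @param object an aanet object.
#' @param ... unused.
NULL

#' @rdname aanet-accessors
#' @export
setGeneric("energies", function(x) standardGeneric("energies"))
#' @rdname aanet-accessors
#' @export
setGeneric("residueCodes", function(x) standardGeneric("residueCodes"))
#' @rdname aanet-accessors
#' @export
setGeneric("nodes", function(x) standardGeneric("nodes"))
#' @rdname aanet-accessors
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))
#' @rdname aanet-accessors
#' @export
setGeneric("ligands", function(x) standardGeneric("ligands"))
#' @rdname aanet-accessors
#' @export
setGeneric("nNodes", function(x) standardGeneric("nNodes"))
#' @rdname aanet-accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))
#' @rdname aanet-accessors
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))
#' @rdname aanet-accessors
#' @export
setGeneric("frameLabels", function(x) standardGeneric("frameLabels"))
#' @rdname aanet-accessors
#' @export
setGeneric("adjacency", function(x) standardGeneric("adjacency"))
#' @rdname aanet-accessors
#' @export
setGeneric("weightedAdjacency", function(x) standardGeneric("weightedAdjacency"))
#' @rdname aanet-accessors
#' @export
setGeneric("centroidDistances", function(x) standardGeneric("centroidDistances"))
#' @rdname aanet-accessors
#' @export
setGeneric("linkCutoff", function(x) standardGeneric("linkCutoff"))
#' @rdname aanet-accessors
#' @export
setGeneric("linkWeights", function(x) standardGeneric("linkWeights"))
#' @rdname aanet-accessors
#' @export
setGeneric("definitionId", function(x) standardGeneric("definitionId"))
#' @rdname aanet-accessors
#' @export
setGeneric("clampCount", function(x) standardGeneric("clampCount"))

setMethod("energies", "ContactPotential", function(x) x@energies)
setMethod("residueCodes", "ContactPotential", function(x) rownames(x@energies))
setMethod("nodes", "ProteinStructure", function(x) x@nodes)
setMethod("atoms", "ProteinStructure", function(x) x@atoms)
setMethod("ligands", "ProteinStructure", function(x) x@ligands)
setMethod("nNodes", "ProteinStructure", function(x) nrow(x@nodes))
setMethod("nodes", "AminoAcidNetwork", function(x) x@nodes)
setMethod("nNodes", "AminoAcidNetwork", function(x) nrow(x@nodes))
setMethod("frames", "ConformerSeries", function(x) x@frames)
setMethod("nFrames", "ConformerSeries", function(x) length(x@frames))
setMethod("frameLabels", "ConformerSeries", function(x) x@frameLabels)
setMethod("adjacency", "AminoAcidNetwork", function(x) x@adjacency)
setMethod("weightedAdjacency", "AminoAcidNetwork", function(x) x@weightedAdjacency)
setMethod("centroidDistances", "AminoAcidNetwork", function(x) x@centroidDist)
setMethod("linkCutoff", "AminoAcidNetwork", function(x) x@cutoff)
setMethod("linkWeights", "AminoAcidNetwork", function(x) x@weights)
setMethod("definitionId", "DistanceMatrix", function(x) x@definitionId)
setMethod("clampCount", "DistanceMatrix", function(x) x@nClamped)

#' @rdname aanet-accessors
#' @export
setMethod("as.matrix", "DistanceMatrix", function(x, ...) x@d)

setMethod("show", "ContactPotential", function(object) {
  e <- object@energies
  cat("ContactPotential: 20 residue types,",
      sprintf("energy range [%.2f, %.2f] RT\n", min(e), max(e)))
  cat(" ", object@provenance, "\n")
})

setMethod("show", "ProteinStructure", function(object) {
  nd <- object@nodes
  cat(sprintf("ProteinStructure: %d residues (%d chain%s), %d atoms",
              nrow(nd), length(unique(nd$chain)),
              if (length(unique(nd$chain)) == 1) "" else "s",
              nrow(object@atoms)))
  if (nrow(object@ligands))
    cat(sprintf(", ligands: %s",
                paste(unique(object@ligands$ligand), collapse = ", ")))
  cat(sprintf(" [model %d]\n", object@modelId))
})

setMethod("show", "ConformerSeries", function(object) {
  cat(sprintf("ConformerSeries: %d frames x %d residues\n",
              length(object@frames), nrow(object@frames[[1]]@nodes)))
})

setMethod("show", "AminoAcidNetwork", function(object) {
  a <- object@adjacency
  cat(sprintf(
    "AminoAcidNetwork: %d nodes, %d links (cutoff %.2f A), <K> = %.2f\n",
    nrow(a), sum(a) / 2, object@cutoff, mean(rowSums(a))))
})

setMethod("show", "DistanceMatrix", function(object) {
  fin <- is.finite(object@d) & upper.tri(object@d)
  cat(sprintf(
    "DistanceMatrix (definition %d): %d nodes, %d direct links%s\n",
    object@definitionId, nrow(object@d), sum(fin),
    if (object@nClamped) sprintf(", %d clamped", object@nClamped) else ""))
})
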