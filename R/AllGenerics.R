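#' Accessors for histomix classes
#'
#' Small accessor generics so downstream code never touches slots
#' directly.
#'
#' @param object a histomix S4 object
#' @return the requested component
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("countsMatrix", function(object) standardGeneric("countsMatrix"))
#' @rdname accessors
#' @export
setGeneric("sizeFactors", function(object) standardGeneric("sizeFactors"))
#' @rdname accessors
#' @export
setGeneric("spotIds", function(object) standardGeneric("spotIds"))
#' @rdname accessors
#' @export
setGeneric("geneIds", function(object) standardGeneric("geneIds"))
#' @rdname accessors
#' @export
setGeneric("molecularY", function(object) standardGeneric("molecularY"))
#' @rdname accessors
#' @export
setGeneric("imageV", function(object) standardGeneric("imageV"))
#' @rdname accessors
#' @export
setGeneric("cellTypes", function(object) standardGeneric("cellTypes"))
#' @rdname accessors
#' @export
setGeneric("cellTotals", function(object) standardGeneric("cellTotals"))
#' @rdname accessors
#' @export
setGeneric("spotCoords", function(object) standardGeneric("spotCoords"))
#' @rdname accessors
#' @export
setGeneric("adjacencyMatrix", function(object)
  standardGeneric("adjacencyMatrix"))
#' @rdname accessors
#' @export
setGeneric("zDraws", function(object) standardGeneric("zDraws"))
#' @rdname accessors
#' @export
setGeneric("omegaDraws", function(object) standardGeneric("omegaDraws"))
#' @rdname accessors
#' @export
setGeneric("domainLabels", function(object) standardGeneric("domainLabels"))
#' @rdname accessors
#' @export
setGeneric("marginalProbs", function(object) standardGeneric("marginalProbs"))
#' @rdname accessors
#' @export
setGeneric("boundarySpots", function(object) standardGeneric("boundarySpots"))
#' @rdname accessors
#' @export
setGeneric("interactiveZones", function(object)
  standardGeneric("interactiveZones"))

#' @rdname accessors
#' @export
setMethod("countsMatrix", "SpatialCounts", function(object) object@counts)
#' @rdname accessors
#' @export
setMethod("sizeFactors", "SpatialCounts", function(object)
  setNames(object@sizeFactors, object@spotIds))
#' @rdname accessors
#' @export
setMethod("spotIds", "SpatialCounts", function(object) object@spotIds)
#' @rdname accessors
#' @export
setMethod("geneIds", "SpatialCounts", function(object) object@geneIds)
#' @rdname accessors
#' @export
setMethod("spotIds", "MolecularProfile", function(object) object@spotIds)
#' @rdname accessors
#' @export
setMethod("molecularY", "MolecularProfile", function(object) object@Y)
#' @rdname accessors
#' @export
setMethod("imageV", "ImageProfile", function(object) object@V)
#' @rdname accessors
#' @export
setMethod("cellTypes", "ImageProfile", function(object) object@cellTypes)
#' @rdname accessors
#' @export
setMethod("cellTotals", "ImageProfile", function(object)
  setNames(object@totals, object@spotIds))
#' @rdname accessors
#' @export
setMethod("spotIds", "ImageProfile", function(object) object@spotIds)
#' @rdname accessors
#' @export
setMethod("spotCoords", "GeospatialProfile", function(object) object@coords)
#' @rdname accessors
#' @export
setMethod("adjacencyMatrix", "GeospatialProfile", function(object)
  object@adjacency)
#' @rdname accessors
#' @export
setMethod("spotIds", "GeospatialProfile", function(object) object@spotIds)
#' @rdname accessors
#' @export
setMethod("zDraws", "DomainChain", function(object) object@zDraws)
#' @rdname accessors
#' @export
setMethod("omegaDraws", "DomainChain", function(object) object@omega)
#' @rdname accessors
#' @export
setMethod("cellTypes", "DomainChain", function(object) object@cellTypes)
#' @rdname accessors
#' @export
setMethod("spotIds", "DomainChain", function(object) object@spotIds)
#' @rdname accessors
#' @export
setMethod("adjacencyMatrix", "DomainChain", function(object) object@adjacency)
#' @rdname accessors
#' @export
setMethod("domainLabels", "DomainCall", function(object)
  setNames(object@zHat, object@spotIds))
#' @rdname accessors
#' @export
setMethod("marginalProbs", "DomainCall", function(object)
  object@marginalProbs)
#' @rdname accessors
#' @export
setMethod("boundarySpots", "DomainCall", function(object)
  setNames(object@boundary, object@spotIds))
#' @rdname accessors
#' @export
setMethod("interactiveZones", "DomainCall", function(object) object@zones)
#' @rdname accessors
#' @export
setMethod("spotIds", "DomainCall", function(object) object@spotIds)

setMethod("show", "SpatialCounts", function(object) {
  cat("SpatialCounts:", length(object@spotIds), "spots x",
      length(object@geneIds), "genes\n")
  cat("  median size factor:", stats::median(object@sizeFactors), "\n")
})

setMethod("show", "MolecularProfile", function(object) {
  cat("MolecularProfile:", nrow(object@Y), "spots x", ncol(object@Y),
      "components (", object@method, ")\n")
})

setMethod("show", "ImageProfile", function(object) {
  cat("ImageProfile:", nrow(object@V), "spots x", ncol(object@V),
      "cell types (", sum(object@totals), "cells )\n")
  cat("  types:", paste(object@cellTypes, collapse = ", "), "\n")
})

setMethod("show", "GeospatialProfile", function(object) {
  cat("GeospatialProfile:", nrow(object@coords), "spots,",
      object@lattice, "lattice,",
      sum(object@adjacency) / 2, "edges\n")
})

setMethod("show", "DomainChain", function(object) {
  cat("DomainChain: K =", object@K, ",", nrow(object@zDraws),
      "post-burn-in draws over", length(object@spotIds), "spots\n")
  cat("  w =", object@w, ", f =", object@f, ", covariance =",
      object@covariance,
      if (object@relabeled) ", relabeled" else ", not relabeled", "\n")
})

setMethod("show", "DomainCall", function(object) {
  cat("DomainCall:", length(object@zHat), "spots,",
      ncol(object@marginalProbs), "domains\n")
  cat("  boundary spots:", sum(object@boundary),
      "( threshold", object@threshold, ")\n")
  cat("  interactive zones:", length(object@zones),
      "( +", length(object@singletons), "singletons )\n")
})
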