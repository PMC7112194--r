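#' Accessors for operonclade classes
#'
#' Small accessor generics so downstream code never touches slots directly.
#'
#' @param x an operonclade object.
#' @return the corresponding component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("clusterMembers", function(x) standardGeneric("clusterMembers"))

#' @rdname accessors
#' @export
setGeneric("unclusteredLabels",
           function(x) standardGeneric("unclusteredLabels"))

#' @rdname accessors
#' @export
setGeneric("clusterCutoff", function(x) standardGeneric("clusterCutoff"))

#' @rdname accessors
#' @export
setGeneric("epsType", function(x) standardGeneric("epsType"))

#' @rdname accessors
#' @export
setGeneric("familyOrder", function(x) standardGeneric("familyOrder"))

#' @rdname accessors
#' @export
setGeneric("synthaseFamilies",
           function(x) standardGeneric("synthaseFamilies"))

#' @rdname accessors
#' @export
setGeneric("operonLoci", function(x) standardGeneric("operonLoci"))

#' @rdname accessors
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))

#' @rdname accessors
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))

#' @rdname accessors
#' @export
setGeneric("cladeOf", function(x) standardGeneric("cladeOf"))

#' @rdname accessors
#' @export
setGeneric("qualityTrace", function(x) standardGeneric("qualityTrace"))

#' @rdname accessors
#' @export
setGeneric("selectedClustering",
           function(x) standardGeneric("selectedClustering"))

#' @rdname accessors
#' @export
setGeneric("seedLabels", function(x) standardGeneric("seedLabels"))

#' @rdname accessors
setMethod("clusterMembers", "PhyloClustering", function(x) x@clusters)

#' @rdname accessors
setMethod("unclusteredLabels", "PhyloClustering", function(x) x@unclustered)

#' @rdname accessors
setMethod("clusterCutoff", "PhyloClustering", function(x) x@cutoff)

#' @rdname accessors
setMethod("epsType", "ReferenceOperon", function(x) x@epsType)

#' @rdname accessors
setMethod("epsType", "OperonCall", function(x) x@epsType)

#' @rdname accessors
setMethod("epsType", "ProximityNetwork", function(x) x@epsType)

#' @rdname accessors
setMethod("familyOrder", "ReferenceOperon", function(x) x@familyOrder)

#' @rdname accessors
setMethod("synthaseFamilies", "ReferenceOperon",
          function(x) x@synthaseFamilies)

#' @rdname accessors
setMethod("operonLoci", "OperonCall", function(x) x@loci)

#' @rdname accessors
setMethod("networkNodes", "ProximityNetwork", function(x) x@nodes)

#' @rdname accessors
setMethod("networkEdges", "ProximityNetwork", function(x) x@edges)

#' @rdname accessors
setMethod("cladeOf", "CladeAssignment", function(x) x@cladeOfLabel)

#' @rdname accessors
setMethod("qualityTrace", "SweepResult", function(x) x@trace)

#' @rdname accessors
setMethod("selectedClustering", "SweepResult", function(x) x@selected)

#' @rdname accessors
setMethod("seedLabels", "SeedSet", function(x) x@labels)

setMethod("show", "PhyloClustering", function(object) {
  cat(sprintf(
    "PhyloClustering: %d cluster(s), %d unclustered of %d labels at cutoff %g\n",
    length(object@clusters), length(object@unclustered),
    length(object@labels), object@cutoff))
})

setMethod("show", "ClusterQuality", function(object) {
  if (!object@valid) {
    cat("ClusterQuality: invalid (fewer than 2 clusters)\n")
  } else {
    cat(sprintf(
      "ClusterQuality: p=%.4g s_avg=%.4g DI=%.4g | Q1=%.4g Q2=%.4g Q3=%.4g%s\n",
      object@p, object@sAvg, object@DI, object@Q1, object@Q2, object@Q3,
      if (object@DIDegenerate) " (DI degenerate)" else ""))
  }
})

setMethod("show", "SweepResult", function(object) {
  cat(sprintf(
    "SweepResult (%s, step %g): %d cutoffs evaluated; selected %g with %d clusters\n",
    object@scheme, object@step, nrow(object@trace), object@selectedCutoff,
    length(object@selected@clusters)))
})

setMethod("show", "CladeAssignment", function(object) {
  cat(sprintf("CladeAssignment for family '%s': %d clade(s), %d singleton(s); reference '%s' in clade %s\n",
    object@family, length(object@cladeOfCluster),
    length(object@clustering@unclustered), object@referenceLabel,
    object@cladeOfLabel[[object@referenceLabel]]))
})

setMethod("show", "ReferenceOperon", function(object) {
  cat(sprintf("ReferenceOperon '%s': %s (synthase: %s), span %g bp\n",
    object@epsType, paste(object@familyOrder, collapse = "-"),
    paste(object@synthaseFamilies, collapse = ","), object@referenceSpan))
})

setMethod("show", "OperonCall", function(object) {
  cat(sprintf(
    "OperonCall %s [%s %s]: %d loci (%s), span %g bp, strand %s%s%s\n",
    object@operonId, object@genomeId, object@repliconId,
    length(unique(object@loci$protein_id)),
    paste(unique(object@loci$family), collapse = ","), object@span,
    object@orientation, if (object@fusionFlag) ", fusion" else "",
    if (!is.na(object@cladeCombination))
      paste0(", clades ", object@cladeCombination) else ""))
})

setMethod("show", "ProximityNetwork", function(object) {
  cat(sprintf("ProximityNetwork '%s': %d node(s), %d edge(s)\n",
    object@epsType, nrow(object@nodes), nrow(object@edges)))
})

setMethod("show", "SeedSet", function(object) {
  cat(sprintf("SeedSet: %d of %d requested seeds from '%s'%s\n",
    length(object@labels), object@targetN, object@reference,
    if (object@shortfall) " (candidates exhausted)" else ""))
})
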