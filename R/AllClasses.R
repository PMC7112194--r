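#' @import methods
NULL

#' Threshold clustering of a patristic distance matrix
#'
#' A partition of sequence labels obtained by single-linkage transitive
#' closure of the relation \eqn{d(i,j) < \mathrm{cutoff}} (strict
#' inequality). Connected components of size >= 2 are clusters; singleton
#' components are recorded as unclustered labels, following the convention
#' that "sequences identified in clusters" excludes singletons.
#'
#' @slot cutoff evolutionary-distance cutoff, substitutions/site.
#' @slot clusters list of character vectors, each of length >= 2; members
#'   sorted, clusters ordered by their first member so the representation
#'   is canonical regardless of input label order.
#' @slot unclustered character vector of singleton labels.
#' @slot labels all labels of the clustered distance matrix.
#' @exportClass PhyloClustering
setClass("PhyloClustering",
  representation(
    cutoff      = "numeric",
    clusters    = "list",
    unclustered = "character",
    labels      = "character"
  )
)

setValidity("PhyloClustering", function(object) {
  msgs <- character()
  memb <- unlist(object@clusters, use.names = FALSE)
  if (any(lengths(object@clusters) < 2L))
    msgs <- c(msgs, "every cluster must have >= 2 members")
  all_lab <- c(memb, object@unclustered)
  if (anyDuplicated(all_lab))
    msgs <- c(msgs, "clusters and unclustered labels must be disjoint")
  if (!setequal(all_lab, object@labels))
    msgs <- c(msgs, "clusters + unclustered must cover exactly all labels")
  if (length(object@cutoff) != 1L || is.na(object@cutoff) || object@cutoff < 0)
    msgs <- c(msgs, "cutoff must be a single non-negative number")
  if (length(msgs)) msgs else TRUE
})

#' Cluster-quality scores at one cutoff
#'
#' Holds the proportion clustered p, per-sequence silhouette scores, the
#' mean silhouette, the Dunn index, and the three composite schemes
#' Q1 = s_avg + DI, Q2 = p + s_avg + DI, Q3 = p * (s_avg + DI). When a
#' clustering has fewer than two clusters the metrics are undefined and
#' \code{valid} is \code{FALSE}; such entries are skipped (not scored 0)
#' when selecting an optimum.
#'
#' @slot p proportion of sequences in clusters, in [0, 1].
#' @slot perSeqSilhouette named numeric, s(i) per clustered label.
#' @slot sAvg mean silhouette over clustered labels.
#' @slot DI Dunn index (min inter-cluster distance / max cluster diameter).
#' @slot Q1,Q2,Q3 composite scores.
#' @slot valid FALSE iff fewer than 2 clusters (metrics undefined).
#' @slot DIDegenerate TRUE when every cluster has diameter 0 and DI was
#'   computed against the epsilon floor (see \code{\link{dunnIndex}}).
#' @exportClass ClusterQuality
setClass("ClusterQuality",
  representation(
    p = "numeric", perSeqSilhouette = "numeric", sAvg = "numeric",
    DI = "numeric", Q1 = "numeric", Q2 = "numeric", Q3 = "numeric",
    valid = "logical", DIDegenerate = "logical"
  ),
  prototype(valid = FALSE, DIDegenerate = FALSE)
)

#' Result of a cutoff sweep
#'
#' @slot scheme one of "Q1", "Q2", "Q3".
#' @slot step cutoff increment, substitutions/site.
#' @slot trace data.frame with one row per evaluated cutoff: cutoff, m,
#'   n_clustered, p, s_avg, DI, Q1, Q2, Q3, valid.
#' @slot selectedCutoff the smallest cutoff maximising the scheme among
#'   valid entries.
#' @slot selected the \linkS4class{PhyloClustering} at that cutoff.
#' @slot selectedQuality the \linkS4class{ClusterQuality} at that cutoff.
#' @exportClass SweepResult
setClass("SweepResult",
  representation(
    scheme = "character", step = "numeric", trace = "data.frame",
    selectedCutoff = "numeric", selected = "PhyloClustering",
    selectedQuality = "ClusterQuality"
  )
)

#' Clade labels for the clusters of one locus family
#'
#' Clusters are numbered 1..m by increasing average patristic distance of
#' their members to a designated reference sequence; the cluster containing
#' the reference is clade 1 by construction. Unclustered singletons receive
#' suffix codes "S1", "S2", ... ordered by distance to the reference, so
#' every label has a total clade assignment.
#'
#' @slot family locus-family name.
#' @slot referenceLabel label of the reference sequence.
#' @slot clustering the underlying \linkS4class{PhyloClustering}.
#' @slot cladeOfCluster integer vector: clade number of cluster k.
#' @slot cladeOfLabel named character: clade code ("1".."m", "S1"...) per label.
#' @exportClass CladeAssignment
setClass("CladeAssignment",
  representation(
    family = "character", referenceLabel = "character",
    clustering = "PhyloClustering", cladeOfCluster = "integer",
    cladeOfLabel = "character"
  )
)

#' Reference operon definition
#'
#' @slot epsType name of the exopolysaccharide system (e.g. "cellulose").
#' @slot familyOrder ordered character vector of locus-family names in the
#'   canonical (reference) operon order.
#' @slot synthaseFamilies subset of \code{familyOrder} encoding the
#'   polysaccharide synthase subunit(s) that anchor operon calls.
#' @slot referenceSpan reference operon span in base pairs (> 0); the
#'   proximity prefilter window is twice this span.
#' @slot referenceLabels named character, family -> reference sequence label.
#' @exportClass ReferenceOperon
setClass("ReferenceOperon",
  representation(
    epsType = "character", familyOrder = "character",
    synthaseFamilies = "character", referenceSpan = "numeric",
    referenceLabels = "character"
  )
)

setValidity("ReferenceOperon", function(object) {
  msgs <- character()
  if (!all(object@synthaseFamilies %in% object@familyOrder))
    msgs <- c(msgs, "synthaseFamilies must be a subset of familyOrder")
  if (length(object@referenceSpan) != 1L || object@referenceSpan <= 0)
    msgs <- c(msgs, "referenceSpan must be a single positive number")
  if (anyDuplicated(object@familyOrder))
    msgs <- c(msgs, "familyOrder must not contain duplicates")
  if (length(msgs)) msgs else TRUE
})

#' A predicted operon
#'
#' One chained run of significant locus hits on a single replicon that
#' satisfies the composition rule (>= 1 synthase-family locus plus >= 1
#' locus of another family, >= 2 loci in total) with all consecutive
#' intergenic gaps <= the chaining threshold.
#'
#' @slot operonId identifier, unique within a call set.
#' @slot genomeId,repliconId source genome and replicon.
#' @slot epsType exopolysaccharide system of the reference used.
#' @slot loci data.frame of hit rows (protein_id, family, start, end,
#'   strand, evalue, bitscore, second_round) ordered by start; a
#'   multi-family (fusion) protein contributes one row per family.
#' @slot span base pairs from min start to max end.
#' @slot orientation majority strand, "+" or "-".
#' @slot fusionFlag TRUE when any locus matches >= 2 families.
#' @slot cladeCombination colon-joined clade string, NA until clades are
#'   assigned.
#' @exportClass OperonCall
setClass("OperonCall",
  representation(
    operonId = "character", genomeId = "character", repliconId = "character",
    epsType = "character", loci = "data.frame", span = "numeric",
    orientation = "character", fusionFlag = "logical",
    cladeCombination = "character"
  ),
  prototype(cladeCombination = NA_character_, fusionFlag = FALSE)
)

setValidity("OperonCall", function(object) {
  msgs <- character()
  if (length(unique(object@loci$protein_id)) < 2L)
    msgs <- c(msgs, "an operon must contain >= 2 loci")
  if (is.unsorted(object@loci$start))
    msgs <- c(msgs, "loci must be ordered by start")
  if (length(msgs)) msgs else TRUE
})

#' Genomic-proximity network over phylogenetic clusters
#'
#' Nodes are per-family phylogenetic clusters (with clade label, member
#' count and taxonomy composition); an edge links two clusters whose loci
#' co-occur in at least one genome, weighted by the average nearest-boundary
#' genomic distance and binned for display (< 100 bp; 100 bp - 5 kb;
#' > 5 kb).
#'
#' @slot epsType exopolysaccharide system.
#' @slot nodes data.frame: node_id, family, clade, member_count, discovery;
#'   plus a list-column \code{composition} of named taxon-fraction vectors
#'   summing to 1.
#' @slot edges data.frame: node_a, node_b, mean_distance, bin, support.
#' @exportClass ProximityNetwork
setClass("ProximityNetwork",
  representation(epsType = "character", nodes = "data.frame",
                 edges = "data.frame")
)

setValidity("ProximityNetwork", function(object) {
  msgs <- character()
  e <- object@edges
  if (nrow(e)) {
    if (any(e$node_a == e$node_b)) msgs <- c(msgs, "self-edges not allowed")
    key <- paste(pmin(e$node_a, e$node_b), pmax(e$node_a, e$node_b))
    if (anyDuplicated(key))
      msgs <- c(msgs, "at most one edge per unordered node pair")
    if (!all(c(e$node_a, e$node_b) %in% object@nodes$node_id))
      msgs <- c(msgs, "edge endpoints must exist in the node set")
    if (any(e$support < 1L)) msgs <- c(msgs, "edge support must be >= 1")
  }
  if (nrow(object@nodes)) {
    s <- vapply(object@nodes$composition, function(x) sum(unlist(x)), 0)
    if (any(abs(s - 1) > 1e-9))
      msgs <- c(msgs, "taxonomy composition must sum to 1")
    if (any(object@nodes$member_count < 1L))
      msgs <- c(msgs, "member_count must be >= 1")
  }
  if (length(msgs)) msgs else TRUE
})

#' Seed set selected for HMM training
#'
#' @slot labels ordered selected labels, reference first.
#' @slot targetN requested number of seeds.
#' @slot reference the reference label.
#' @slot shortfall TRUE when candidates were exhausted before targetN.
#' @exportClass SeedSet
setClass("SeedSet",
  representation(labels = "character", targetN = "numeric",
                 reference = "character", shortfall = "logical")
)
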