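#' Single-linkage threshold clustering at a distance cutoff
#'
#' Places two sequences in the same cluster when they can be linked by a
#' chain of pairwise evolutionary distances each strictly less than
#' \code{cutoff} (transitive closure of \eqn{d(i,j) < cutoff}). Connected
#' components of size >= 2 become clusters; singletons are reported as
#' unclustered. At cutoff 0 nothing clusters (strict inequality); once the
#' cutoff exceeds the largest pairwise distance all sequences fall into a
#' single component.
#'
#' @param d labelled symmetric distance matrix (substitutions/site).
#' @param cutoff non-negative distance cutoff.
#' @return a \linkS4class{PhyloClustering}. The representation is
#'   canonical: members sorted within clusters, clusters ordered by their
#'   first member, so the result is invariant to label order.
#' @export
thresholdCluster <- function(d, cutoff) {
  validateDistanceMatrix(d)
  stopifnot(is.numeric(cutoff), length(cutoff) == 1L, cutoff >= 0)
  labs <- rownames(d)
  n <- length(labs)
  adj <- d < cutoff
  diag(adj) <- FALSE
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    cid <- cid + 1L
    frontier <- i
    comp[i] <- cid
    while (length(frontier)) {
      hit <- which(is.na(comp) &
                   colSums(adj[frontier, , drop = FALSE]) > 0)
      comp[hit] <- cid
      frontier <- hit
    }
  }
  groups <- split(labs, comp)
  sizes <- lengths(groups)
  clusters <- lapply(groups[sizes >= 2L], function(x) sort(x))
  ord <- order(vapply(clusters, `[`, "", 1L))
  clusters <- unname(clusters[ord])
  unclust <- sort(unlist(groups[sizes == 1L], use.names = FALSE))
  if (is.null(unclust)) unclust <- character()
  methods::new("PhyloClustering", cutoff = as.numeric(cutoff),
               clusters = clusters, unclustered = unclust, labels = labs)
}

#' Per-sequence silhouette scores of a clustering
#'
#' For each clustered sequence i, a(i) is the mean distance to the other
#' members of its cluster and b(i) the smallest mean distance to any other
#' cluster; s(i) = (b(i) - a(i)) / max(a(i), b(i)). Unclustered singletons
#' take no part (neither scored nor used as neighbour clusters). When
#' a(i) = b(i) = 0 (identical sequences in identical clusters) s(i) is 0.
#'
#' @param d labelled distance matrix.
#' @param clustering a \linkS4class{PhyloClustering} over the same labels
#'   with at least two clusters.
#' @return named numeric vector, s(i) in [-1, 1] for every clustered label.
#' @export
silhouetteScores <- function(d, clustering) {
  stopifnot(methods::is(clustering, "PhyloClustering"))
  cl <- clustering@clusters
  if (length(cl) < 2L)
    stop("silhouette undefined for fewer than 2 clusters", call. = FALSE)
  out <- numeric(0)
  for (k in seq_along(cl)) {
    members <- cl[[k]]
    others <- cl[-k]
    for (lab in members) {
      a <- mean(d[lab, setdiff(members, lab)])
      b <- min(vapply(others, function(o) mean(d[lab, o]), 0))
      denom <- max(a, b)
      out[[lab]] <- if (denom == 0) 0 else (b - a) / denom
    }
  }
  out
}

#' Dunn index of a clustering
#'
#' Ratio of the minimum inter-cluster distance (smallest pairwise distance
#' between members of two different components) to the maximum cluster
#' diameter (largest intra-cluster pairwise distance). Higher values mean
#' compact, well-separated clusters. Threshold clustering partitions all
#' sequences into connected components, so the index is evaluated over the
#' complete partition: unclustered singletons take part as size-1
#' components in the inter-cluster minimum (their zero diameter cannot
#' affect the denominator). This keeps the index honest about isolated
#' sequences sitting right next to a cluster — a partition that merely
#' trims a boundary sequence into a singleton gains nothing. At least two
#' proper (size >= 2) clusters are required, matching the validity rule of
#' the cutoff sweep. When every cluster has diameter 0 (all duplicates)
#' the ratio is taken against an epsilon floor of 1e-9 and flagged,
#' preserving the higher-is-better ordering without a division by zero.
#'
#' @inheritParams silhouetteScores
#' @return list with elements \code{DI} (>= 0) and \code{degenerate}
#'   (logical: epsilon floor used).
#' @export
dunnIndex <- function(d, clustering) {
  stopifnot(methods::is(clustering, "PhyloClustering"))
  cl <- clustering@clusters
  if (length(cl) < 2L)
    stop("Dunn index undefined for fewer than 2 clusters", call. = FALSE)
  diam <- vapply(cl, function(m) max(d[m, m]), 0)
  comps <- c(cl, as.list(clustering@unclustered))
  npairs <- utils::combn(length(comps), 2L)
  delta <- apply(npairs, 2L, function(ij)
    min(d[comps[[ij[1L]]], comps[[ij[2L]]]]))
  minDelta <- min(delta)
  maxDiam <- max(diam)
  if (maxDiam == 0) {
    list(DI = minDelta / 1e-9, degenerate = TRUE)
  } else {
    list(DI = minDelta / maxDiam, degenerate = FALSE)
  }
}

#' Composite cluster-quality scores
#'
#' Computes the proportion of sequences clustered p, the mean silhouette
#' s_avg, the Dunn index DI, and the three composite schemes
#' Q1 = s_avg + DI, Q2 = p + s_avg + DI, Q3 = p * (s_avg + DI). A
#' clustering with fewer than two clusters is flagged invalid rather than
#' scored, so a cutoff sweep can pass over degenerate partitions without
#' the trivial all-in-one clustering ever winning.
#'
#' @inheritParams silhouetteScores
#' @return a \linkS4class{ClusterQuality}.
#' @export
clusterQuality <- function(d, clustering) {
  stopifnot(methods::is(clustering, "PhyloClustering"))
  m <- length(clustering@clusters)
  if (m < 2L) {
    return(methods::new("ClusterQuality",
      p = NA_real_, perSeqSilhouette = numeric(0), sAvg = NA_real_,
      DI = NA_real_, Q1 = NA_real_, Q2 = NA_real_, Q3 = NA_real_,
      valid = FALSE, DIDegenerate = FALSE))
  }
  nclustered <- sum(lengths(clustering@clusters))
  p <- nclustered / length(clustering@labels)
  sil <- silhouetteScores(d, clustering)
  sAvg <- mean(sil)
  di <- dunnIndex(d, clustering)
  methods::new("ClusterQuality",
    p = p, perSeqSilhouette = sil, sAvg = sAvg, DI = di$DI,
    Q1 = sAvg + di$DI, Q2 = p + sAvg + di$DI, Q3 = p * (sAvg + di$DI),
    valid = TRUE, DIDegenerate = di$degenerate)
}

#' Sweep distance cutoffs and select the optimal clustering
#'
#' Evaluates cutoffs 0, step, 2*step, ... up to the maximum pairwise
#' distance plus one step, scores each resulting clustering, and returns
#' the valid clustering maximising the chosen scheme. Consecutive cutoffs
#' yielding the identical partition are computed once and the scores
#' shared, which leaves the result unchanged while avoiding redundant
#' silhouette evaluations. Ties on the scheme score go to the smallest
#' cutoff (the finest clustering).
#'
#' @param d labelled distance matrix.
#' @param scheme "Q1", "Q2" or "Q3".
#' @param step cutoff increment in substitutions/site (default 0.01).
#' @return a \linkS4class{SweepResult}.
#' @export
sweepCutoffs <- function(d, scheme = c("Q2", "Q1", "Q3"), step = 0.01) {
  validateDistanceMatrix(d)
  scheme <- match.arg(scheme)
  stopifnot(step > 0)
  dv <- sort(unique(d[upper.tri(d)]))
  maxD <- max(d)
  nsteps <- ceiling(maxD / step) + 1L
  cutoffs <- step * (0:nsteps)
  # partition identity is fixed by the set of distances below the cutoff
  key <- vapply(cutoffs, function(co) sum(dv < co), 0L)
  firstOfKey <- !duplicated(key)
  cache <- list()
  for (i in which(firstOfKey)) {
    clu <- thresholdCluster(d, cutoffs[i])
    q <- clusterQuality(d, clu)
    cache[[as.character(key[i])]] <- list(clustering = clu, quality = q)
  }
  rows <- lapply(seq_along(cutoffs), function(i) {
    e <- cache[[as.character(key[i])]]
    q <- e$quality
    data.frame(cutoff = cutoffs[i], m = length(e$clustering@clusters),
               n_clustered = sum(lengths(e$clustering@clusters)),
               p = q@p, s_avg = q@sAvg, DI = q@DI,
               Q1 = q@Q1, Q2 = q@Q2, Q3 = q@Q3, valid = q@valid)
  })
  trace <- do.call(rbind, rows)
  score <- trace[[scheme]]
  score[!trace$valid] <- NA_real_
  if (all(is.na(score)))
    stop("no valid clustering (>= 2 clusters) at any cutoff", call. = FALSE)
  sel <- which.max(score)   # first maximum = smallest cutoff on ties
  selEntry <- cache[[as.character(key[sel])]]
  selected <- methods::new("PhyloClustering", cutoff = cutoffs[sel],
                           clusters = selEntry$clustering@clusters,
                           unclustered = selEntry$clustering@unclustered,
                           labels = selEntry$clustering@labels)
  methods::new("SweepResult", scheme = scheme, step = step, trace = trace,
               selectedCutoff = cutoffs[sel], selected = selected,
               selectedQuality = selEntry$quality)
}

#' Assign clade numbers to clusters by distance to a reference sequence
#'
#' Clusters are ranked by the mean patristic distance of their members to
#' the reference sequence; the cluster containing the reference is clade 1
#' by construction, remaining clusters take clades 2..m in ascending mean
#' distance. Ties go to the larger cluster, then to the lexicographically
#' smallest member. Unclustered singletons receive suffix codes "S1",
#' "S2", ... ordered by their distance to the reference, so clade codes
#' are total over all labels.
#'
#' @param d labelled distance matrix.
#' @param clustering a \linkS4class{PhyloClustering} of d's labels.
#' @param referenceLabel label of the reference operon member; must be one
#'   of d's labels.
#' @param family locus-family name recorded in the assignment.
#' @return a \linkS4class{CladeAssignment}.
#' @export
assignClades <- function(d, clustering, referenceLabel,
                         family = NA_character_) {
  validateDistanceMatrix(d)
  stopifnot(methods::is(clustering, "PhyloClustering"))
  if (!referenceLabel %in% rownames(d))
    stop("reference label '", referenceLabel, "' not in distance matrix",
         call. = FALSE)
  cl <- clustering@clusters
  m <- length(cl)
  meanDist <- vapply(cl, function(mm) mean(d[mm, referenceLabel]), 0)
  hasRef <- vapply(cl, function(mm) referenceLabel %in% mm, TRUE)
  size <- lengths(cl)
  firstMember <- vapply(cl, `[`, "", 1L)
  ord <- order(!hasRef, meanDist, -size, firstMember)
  cladeOfCluster <- integer(m)
  cladeOfCluster[ord] <- seq_len(m)
  cladeOfLabel <- character(0)
  for (k in seq_len(m))
    cladeOfLabel[cl[[k]]] <- as.character(cladeOfCluster[k])
  un <- clustering@unclustered
  if (length(un)) {
    uord <- order(d[un, referenceLabel], un)
    cladeOfLabel[un[uord]] <- paste0("S", seq_along(un))
  }
  methods::new("CladeAssignment", family = as.character(family),
               referenceLabel = referenceLabel, clustering = clustering,
               cladeOfCluster = cladeOfCluster,
               cladeOfLabel = cladeOfLabel)
}

#' Clade-combination string of an operon
#'
#' Renders an operon as the colon-joined clade codes of its loci in the
#' reference operon's family order (e.g. "1:1:1:1" for a canonical operon
#' whose loci all sit in reference clusters, or "1:3:5:3" for divergent
#' members); families absent from the operon are rendered "-". When a
#' family appears more than once the locus first in genomic order is used.
#'
#' @param operon an \linkS4class{OperonCall}.
#' @param assignments named list, family -> \linkS4class{CladeAssignment}.
#' @param reference the \linkS4class{ReferenceOperon} giving family order.
#' @return a single string.
#' @export
cladeCombination <- function(operon, assignments, reference) {
  stopifnot(methods::is(operon, "OperonCall"),
            methods::is(reference, "ReferenceOperon"))
  loci <- operon@loci
  parts <- vapply(reference@familyOrder, function(fam) {
    rows <- loci[loci$family == fam, , drop = FALSE]
    if (!nrow(rows)) return("-")
    lab <- rows$protein_id[which.min(rows$start)]
    asg <- assignments[[fam]]
    if (is.null(asg))
      stop("no clade assignment for family '", fam, "'", call. = FALSE)
    clade <- asg@cladeOfLabel[lab]
    if (is.na(clade))
      stop("label '", lab, "' has no clade in family '", fam, "'",
           call. = FALSE)
    unname(clade)
  }, "")
  paste(parts, collapse = ":")
}

#' Write per-label cluster/clade assignments as TSV
#'
#' One row per label: label, family, cluster_id (0 for unclustered),
#' clade, cutoff, and the quality scores of the selected clustering.
#'
#' @param assignment a \linkS4class{CladeAssignment}.
#' @param quality the matching \linkS4class{ClusterQuality}.
#' @param path output file.
#' @param header optional extra '#' header lines.
#' @return \code{path}, invisibly.
#' @export
writeClusterTable <- function(assignment, quality, path, header = NULL) {
  clu <- assignment@clustering
  rows <- list()
  for (k in seq_along(clu@clusters)) {
    for (lab in clu@clusters[[k]]) {
      rows[[length(rows) + 1L]] <- data.frame(
        label = lab, family = assignment@family, cluster_id = k,
        clade = assignment@cladeOfLabel[[lab]])
    }
  }
  for (lab in clu@unclustered) {
    rows[[length(rows) + 1L]] <- data.frame(
      label = lab, family = assignment@family, cluster_id = 0L,
      clade = assignment@cladeOfLabel[[lab]])
  }
  tab <- do.call(rbind, rows)
  tab$cutoff <- clu@cutoff
  tab$p <- quality@p; tab$s_avg <- quality@sAvg; tab$DI <- quality@DI
  tab$Q1 <- quality@Q1; tab$Q2 <- quality@Q2; tab$Q3 <- quality@Q3
  writeTsv(tab, path, header = header)
}

#' Write the cutoff-sweep trace as TSV
#'
#' @param sweep a \linkS4class{SweepResult}.
#' @param path output file.
#' @param header optional extra '#' header lines.
#' @return \code{path}, invisibly.
#' @export
writeSweepTrace <- function(sweep, path, header = NULL) {
  writeTsv(sweep@trace, path,
           header = c(sprintf("scheme=%s step=%g selected_cutoff=%.10g",
                              sweep@scheme, sweep@step,
                              sweep@selectedCutoff), header))
}
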