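# Independent brute-force oracles and small fixture builders. The oracles
# never call the functions they check.

# patristic oracle: shortest path over the tree graph (igraph), summing
# branch lengths edge by edge
oraclePatristic <- function(tree) {
  n <- length(tree$tip.label)
  edges <- tree$edge
  g <- igraph::graph_from_edgelist(apply(edges, 2, as.character),
                                   directed = FALSE)
  igraph::E(g)$weight <- tree$edge.length
  ids <- as.character(seq_len(n))
  d <- igraph::distances(g, v = ids, to = ids)
  dimnames(d) <- list(tree$tip.label, tree$tip.label)
  d
}

# silhouette oracle: explicit double loops over the cluster list
oracleSilhouette <- function(d, clusterList) {
  out <- numeric(0)
  for (k in seq_along(clusterList)) {
    for (lab in clusterList[[k]]) {
      own <- setdiff(clusterList[[k]], lab)
      a <- sum(vapply(own, function(o) d[lab, o], 0)) / length(own)
      b <- Inf
      for (j in seq_along(clusterList)) {
        if (j == k) next
        bj <- sum(vapply(clusterList[[j]], function(o) d[lab, o], 0)) /
          length(clusterList[[j]])
        if (bj < b) b <- bj
      }
      out[[lab]] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
    }
  }
  out
}

# Dunn oracle over the complete partition: label -> component map, loops
# over all label pairs
oracleDunn <- function(d, clusterList, singletons) {
  compOf <- character(0)
  for (k in seq_along(clusterList)) compOf[clusterList[[k]]] <-
      paste0("c", k)
  for (s in singletons) compOf[s] <- paste0("s", s)
  labs <- names(compOf)
  minDelta <- Inf; maxDiam <- -Inf
  for (i in seq_along(labs)) {
    for (j in seq_along(labs)) {
      if (i >= j) next
      same <- compOf[labs[i]] == compOf[labs[j]]
      if (same) maxDiam <- max(maxDiam, d[labs[i], labs[j]])
      else minDelta <- min(minDelta, d[labs[i], labs[j]])
    }
  }
  if (all(lengths(clusterList) == 0) || maxDiam < 0) maxDiam <- 0
  if (maxDiam == 0) minDelta / 1e-9 else minDelta / maxDiam
}

randomDistanceMatrix <- function(n, scale = 1) {
  labs <- sprintf("L%02d", seq_len(n))
  d <- matrix(0, n, n, dimnames = list(labs, labs))
  v <- stats::runif(n * (n - 1) / 2, 0.01, scale)
  d[upper.tri(d)] <- v
  d <- d + t(d)
  d
}

# random partition with >= 2 clusters of size >= 2 plus possible singletons
randomClustering <- function(labs, cutoff = 0.5) {
  repeat {
    perm <- sample(labs)
    ks <- 2:max(2, min(4, floor(length(labs) / 2)))
    k <- ks[sample.int(length(ks), 1)]
    sizes <- rep(2, k)
    left <- length(labs) - sum(sizes)
    if (left > 0) {
      extra <- sample(0:left, 1)
      while (extra > 0) {
        j <- sample(k, 1)
        sizes[j] <- sizes[j] + 1
        extra <- extra - 1
      }
    }
    idx <- 1
    clusters <- list()
    for (j in seq_len(k)) {
      clusters[[j]] <- sort(perm[idx:(idx + sizes[j] - 1)])
      idx <- idx + sizes[j]
    }
    single <- sort(perm[seq(idx, length.out = length(labs) - idx + 1)])
    if (length(single) == 0) single <- character()
    ord <- order(vapply(clusters, `[`, "", 1))
    return(methods::new("PhyloClustering", cutoff = cutoff,
                        clusters = unname(clusters[ord]),
                        unclustered = single, labels = labs))
  }
}

# block-structured matrix: intra-block 0.05; between blocks i and j,
# 1 + 0.5 * max(i, j), so mean distance to a block-1 reference increases
# with block index
blockMatrix <- function(blocks, intra = 0.05) {
  labs <- unlist(blocks, use.names = FALSE)
  n <- length(labs)
  blockOf <- rep(seq_along(blocks), lengths(blocks))
  d <- matrix(0, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      d[i, j] <- if (blockOf[i] == blockOf[j]) intra else
        1 + 0.5 * max(blockOf[i], blockOf[j])
    }
  }
  d
}

# minimal hit-row constructor
hitRow <- function(genome, protein, family, start, end, strand = "+",
                   evalue = 1e-10, bitscore = 500, replicon = "chr1") {
  data.frame(genome_id = genome, replicon_id = replicon,
             protein_id = protein, family = family, start = start,
             end = end, strand = strand, evalue = evalue,
             bitscore = bitscore, second_round = FALSE,
             stringsAsFactors = FALSE)
}

# build an OperonCall directly from hit rows (bypassing prediction), for
# event-caller unit tests
mkOperon <- function(rows, epsType = "cellulose", orientation = NULL,
                     id = "op1") {
  loci <- do.call(rbind, rows)
  loci <- loci[order(loci$start, loci$end, loci$protein_id, loci$family), ]
  rownames(loci) <- NULL
  if (is.null(orientation)) {
    u <- loci[!duplicated(loci$protein_id), ]
    orientation <- if (sum(u$strand == "-") > sum(u$strand == "+"))
      "-" else "+"
  }
  methods::new("OperonCall", operonId = id,
               genomeId = loci$genome_id[1], repliconId = loci$replicon_id[1],
               epsType = epsType, loci = loci,
               span = max(loci$end) - min(loci$start) + 1,
               orientation = orientation,
               fusionFlag = anyDuplicated(loci$protein_id) > 0)
}

ariAgainstPlanted <- function(clustering, planted) {
  got <- integer(length(planted))
  names(got) <- names(planted)
  cl <- clusterMembers(clustering)
  for (k in seq_along(cl)) got[cl[[k]]] <- k
  un <- unclusteredLabels(clustering)
  got[un] <- max(got, 0L) + seq_along(un)
  mclust::adjustedRandIndex(got[names(planted)], planted)
}

cannedReference <- function() celluloseReference()
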