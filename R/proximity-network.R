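#' Bin an edge distance for display
#'
#' Genomic-proximity edges are coloured by average intergenic distance:
#' below 100 bp ("lt100"), 100 bp to 5 kb inclusive ("b100to5k"), above
#' 5 kb ("gt5k"). The boundary values 100 and 5000 fall in the middle bin.
#'
#' @param meanDistance numeric vector of distances in bp (>= 0).
#' @return character vector of bin codes.
#' @export
binEdgeDistance <- function(meanDistance) {
  stopifnot(all(meanDistance >= 0))
  ifelse(meanDistance < 100, "lt100",
         ifelse(meanDistance <= 5000, "b100to5k", "gt5k"))
}

#' Build the genomic-proximity network over phylogenetic clusters
#'
#' One node per (family, clade) of the supplied clade assignments,
#' annotated with member count, taxonomy composition of the genomes
#' contributing member sequences, and a discovery flag (iterative when all
#' of a node's operon loci came from a second search round). One edge per
#' unordered node pair whose loci co-occur in at least one genome; its
#' weight is the mean nearest-boundary distance over all co-occurring
#' locus pairs (overlaps counted as 0) and its support the number of
#' genomes involved. Co-occurrences beyond the operon scale still create
#' edges: long-range (> 5 kb) links between same-genome operon copies are
#' exactly the signal that exposes horizontally acquired second copies.
#'
#' @param operons list of \linkS4class{OperonCall} (one system).
#' @param assignments named list, family -> \linkS4class{CladeAssignment}.
#' @param taxonomy named character vector, genome_id -> taxon; genomes
#'   absent from it are reported as "unknown".
#' @param reference optional \linkS4class{ReferenceOperon}; when given,
#'   nodes carry the family's rank in the canonical operon order (for
#'   vertical layout).
#' @return a \linkS4class{ProximityNetwork}.
#' @export
buildProximityNetwork <- function(operons, assignments, taxonomy = NULL,
                                  reference = NULL) {
  epsType <- if (length(operons)) operons[[1L]]@epsType else NA_character_
  loci <- do.call(rbind, c(list(data.frame()), lapply(operons, function(op)
    cbind(op@loci, operon_id = op@operonId))))
  if (nrow(loci)) {
    bad <- vapply(seq_len(nrow(loci)), function(i) {
      asg <- assignments[[loci$family[i]]]
      is.null(asg) || is.na(asg@cladeOfLabel[loci$protein_id[i]])
    }, TRUE)
    if (any(bad))
      stop("no cluster assignment for label(s): ",
           paste(unique(loci$protein_id[bad]), collapse = ", "),
           call. = FALSE)
  }
  taxonOf <- function(genomes) {
    if (is.null(taxonomy)) return(rep("unknown", length(genomes)))
    t <- taxonomy[genomes]
    t[is.na(t)] <- "unknown"
    unname(t)
  }
  # nodes: every clade (cluster or singleton) of every assigned family
  nodeRows <- list()
  for (fam in names(assignments)) {
    asg <- assignments[[fam]]
    clu <- asg@clustering
    codes <- c(as.character(asg@cladeOfCluster),
               unique(asg@cladeOfLabel[clu@unclustered]))
    sizes <- c(lengths(clu@clusters), rep(1L, length(clu@unclustered)))
    memberSets <- c(clu@clusters, as.list(sort(clu@unclustered)))
    # align singleton codes with their member label order
    if (length(clu@unclustered)) {
      sCodes <- asg@cladeOfLabel[sort(clu@unclustered)]
      codes <- c(as.character(asg@cladeOfCluster), unname(sCodes))
    }
    for (k in seq_along(codes)) {
      members <- memberSets[[k]]
      inOp <- loci[loci$family == fam & loci$protein_id %in% members, ,
                   drop = FALSE]
      comp <- if (nrow(inOp)) {
        gm <- unique(inOp[, c("protein_id", "genome_id")])
        tab <- table(taxonOf(gm$genome_id))
        as.list(stats::setNames(as.numeric(tab) / sum(tab), names(tab)))
      } else list(unknown = 1)
      discovery <- if (nrow(inOp) && all(inOp$second_round))
        "iterative" else "first-pass"
      nodeRows[[length(nodeRows) + 1L]] <- data.frame(
        node_id = paste0(fam, "|", codes[k]), family = fam,
        clade = codes[k], member_count = sizes[k],
        family_rank = if (!is.null(reference))
          match(fam, reference@familyOrder) else NA_integer_,
        discovery = discovery, stringsAsFactors = FALSE)
      nodeRows[[length(nodeRows)]]$composition <- list(comp)
    }
  }
  nodes <- if (length(nodeRows)) do.call(rbind, nodeRows) else
    data.frame(node_id = character(), family = character(),
               clade = character(), member_count = integer(),
               family_rank = integer(), discovery = character(),
               composition = I(list()))
  nodes <- nodes[order(nodes$node_id), , drop = FALSE]
  rownames(nodes) <- NULL
  # edges: all same-genome locus pairs, any distance
  acc <- new.env(parent = emptyenv())
  if (nrow(loci)) {
    loci$node <- vapply(seq_len(nrow(loci)), function(i)
      paste0(loci$family[i], "|",
             assignments[[loci$family[i]]]@cladeOfLabel[[
               loci$protein_id[i]]]), "")
    for (g in unique(loci$genome_id)) {
      sub <- loci[loci$genome_id == g, , drop = FALSE]
      sub <- sub[!duplicated(paste(sub$protein_id, sub$family)), ,
                 drop = FALSE]
      if (nrow(sub) < 2L) next
      pairs <- utils::combn(nrow(sub), 2L)
      for (c2 in seq_len(ncol(pairs))) {
        i <- pairs[1L, c2]; j <- pairs[2L, c2]
        if (sub$node[i] == sub$node[j]) next
        gap <- if (!identical(sub$replicon_id[i], sub$replicon_id[j]))
          NA_real_ else
          boundaryGap(sub$start[i], sub$end[i], sub$start[j], sub$end[j])
        if (is.na(gap)) next  # cross-replicon pairs carry no distance
        key <- paste(min(sub$node[i], sub$node[j]),
                     max(sub$node[i], sub$node[j]), sep = "\r")
        prev <- acc[[key]]
        if (is.null(prev)) prev <- list(gaps = numeric(), genomes = character())
        prev$gaps <- c(prev$gaps, gap)
        prev$genomes <- union(prev$genomes, g)
        acc[[key]] <- prev
      }
    }
  }
  keys <- sort(ls(acc))
  edges <- if (length(keys)) {
    do.call(rbind, lapply(keys, function(k) {
      ab <- strsplit(k, "\r", fixed = TRUE)[[1L]]
      md <- mean(acc[[k]]$gaps)
      data.frame(node_a = ab[1L], node_b = ab[2L], mean_distance = md,
                 bin = binEdgeDistance(md),
                 support = length(acc[[k]]$genomes),
                 stringsAsFactors = FALSE)
    }))
  } else data.frame(node_a = character(), node_b = character(),
                    mean_distance = numeric(), bin = character(),
                    support = integer())
  rownames(edges) <- NULL
  methods::new("ProximityNetwork", epsType = as.character(epsType),
               nodes = nodes, edges = edges)
}

compositionToString <- function(comp) {
  comp <- unlist(comp)
  paste(names(comp), sprintf("%.10g", comp), sep = ":", collapse = ";")
}

compositionFromString <- function(s) {
  if (!nzchar(s)) return(list())
  parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1L]], ":", fixed = TRUE)
  stats::setNames(as.list(as.numeric(vapply(parts, `[`, "", 2L))),
                  vapply(parts, `[`, "", 1L))
}

#' Export a proximity network
#'
#' Formats: "graphml" (Cytoscape-importable, node size/family
#' rank/taxonomy composition and edge bin/support as attributes), "sif"
#' (interaction file plus node and edge attribute TSVs written next to
#' it), or "json" (lossless round-trip).
#'
#' @param net a \linkS4class{ProximityNetwork}.
#' @param path output file; for "sif", \code{<path>.nodes.tsv} and
#'   \code{<path>.edges.tsv} are written alongside.
#' @param format "graphml", "sif" or "json".
#' @return character vector of files written, invisibly.
#' @export
exportNetwork <- function(net, path, format = c("graphml", "sif", "json")) {
  stopifnot(methods::is(net, "ProximityNetwork"))
  format <- match.arg(format)
  nodes <- net@nodes; edges <- net@edges
  if (format == "json") {
    obj <- list(
      eps_type = net@epsType,
      nodes = lapply(seq_len(nrow(nodes)), function(i) list(
        node_id = nodes$node_id[i], family = nodes$family[i],
        clade = nodes$clade[i], member_count = nodes$member_count[i],
        family_rank = nodes$family_rank[i],
        discovery = nodes$discovery[i],
        composition = nodes$composition[[i]])),
      edges = lapply(seq_len(nrow(edges)), function(i) list(
        node_a = edges$node_a[i], node_b = edges$node_b[i],
        mean_distance = edges$mean_distance[i], bin = edges$bin[i],
        support = edges$support[i])))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         null = "null", na = "null")
    return(invisible(path))
  }
  if (format == "graphml") {
    vdf <- data.frame(name = nodes$node_id, family = nodes$family,
                      clade = nodes$clade,
                      member_count = as.numeric(nodes$member_count),
                      family_rank = ifelse(is.na(nodes$family_rank), 0,
                                           as.numeric(nodes$family_rank)),
                      discovery = nodes$discovery,
                      composition = vapply(nodes$composition,
                                           compositionToString, ""),
                      stringsAsFactors = FALSE)
    g <- igraph::graph_from_data_frame(
      d = if (nrow(edges))
        data.frame(from = edges$node_a, to = edges$node_b,
                   mean_distance = edges$mean_distance, bin = edges$bin,
                   support = as.numeric(edges$support))
      else data.frame(from = character(), to = character()),
      directed = FALSE, vertices = vdf)
    igraph::write_graph(g, path, format = "graphml")
    return(invisible(path))
  }
  # sif + attribute tables
  sifLines <- if (nrow(edges))
    paste(edges$node_a, edges$bin, edges$node_b, sep = "\t") else character()
  lonely <- setdiff(nodes$node_id, c(edges$node_a, edges$node_b))
  writeLines(c(sifLines, lonely), path)
  ntab <- nodes
  ntab$composition <- vapply(nodes$composition, compositionToString, "")
  writeTsv(ntab, paste0(path, ".nodes.tsv"))
  writeTsv(edges, paste0(path, ".edges.tsv"))
  invisible(c(path, paste0(path, ".nodes.tsv"), paste0(path, ".edges.tsv")))
}

#' Import a proximity network written by \code{\link{exportNetwork}}
#'
#' @param path file to read.
#' @param format "graphml" or "json".
#' @return a \linkS4class{ProximityNetwork}.
#' @export
importNetwork <- function(path, format = c("graphml", "json")) {
  format <- match.arg(format)
  if (format == "json") {
    obj <- jsonlite::read_json(path)
    nodes <- do.call(rbind, lapply(obj$nodes, function(n) {
      df <- data.frame(node_id = n$node_id, family = n$family,
                       clade = as.character(n$clade),
                       member_count = as.integer(n$member_count),
                       family_rank = if (is.null(n$family_rank))
                         NA_integer_ else as.integer(n$family_rank),
                       discovery = n$discovery, stringsAsFactors = FALSE)
      df$composition <- list(lapply(n$composition, as.numeric))
      df
    }))
    edges <- do.call(rbind, lapply(obj$edges, function(e)
      data.frame(node_a = e$node_a, node_b = e$node_b,
                 mean_distance = as.numeric(e$mean_distance), bin = e$bin,
                 support = as.integer(e$support), stringsAsFactors = FALSE)))
    if (is.null(nodes))
      nodes <- data.frame(node_id = character(), family = character(),
                          clade = character(), member_count = integer(),
                          family_rank = integer(), discovery = character(),
                          composition = I(list()))
    if (is.null(edges))
      edges <- data.frame(node_a = character(), node_b = character(),
                          mean_distance = numeric(), bin = character(),
                          support = integer())
    et <- if (is.null(obj$eps_type)) NA_character_ else obj$eps_type
    return(methods::new("ProximityNetwork", epsType = et, nodes = nodes,
                        edges = edges))
  }
  g <- igraph::read_graph(path, format = "graphml")
  va <- igraph::vertex_attr(g)
  nodes <- data.frame(node_id = va$name, family = va$family,
                      clade = va$clade,
                      member_count = as.integer(va$member_count),
                      family_rank = {
                        fr <- as.integer(va$family_rank)
                        fr[fr == 0L] <- NA_integer_
                        fr
                      },
                      discovery = va$discovery, stringsAsFactors = FALSE)
  nodes$composition <- lapply(va$composition, compositionFromString)
  ord <- order(nodes$node_id)
  nodes <- nodes[ord, , drop = FALSE]
  rownames(nodes) <- NULL
  ea <- igraph::edge_attr(g)
  el <- igraph::as_edgelist(g)
  edges <- if (nrow(el)) {
    data.frame(node_a = pmin(el[, 1L], el[, 2L]),
               node_b = pmax(el[, 1L], el[, 2L]),
               mean_distance = as.numeric(ea$mean_distance), bin = ea$bin,
               support = as.integer(ea$support), stringsAsFactors = FALSE)
  } else data.frame(node_a = character(), node_b = character(),
                    mean_distance = numeric(), bin = character(),
                    support = integer())
  edges <- edges[order(edges$node_a, edges$node_b), , drop = FALSE]
  rownames(edges) <- NULL
  methods::new("ProximityNetwork", epsType = NA_character_, nodes = nodes,
               edges = edges)
}
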