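hitColumns <- c("genome_id", "replicon_id", "protein_id", "family",
                "start", "end", "strand", "evalue", "bitscore")

validateHits <- function(hits) {
  miss <- setdiff(hitColumns, names(hits))
  if (length(miss))
    stop("hit table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(hits)) {
    if (any(hits$start < 1L)) stop("coordinates are 1-based: start >= 1")
    if (any(hits$end < hits$start)) stop("end must be >= start")
    if (any(hits$evalue < 0)) stop("E-values must be >= 0")
    if (!all(hits$strand %in% c("+", "-")))
      stop("strand must be '+' or '-'")
  }
  if (is.null(hits$second_round)) hits$second_round <- FALSE
  hits
}

# nearest-boundary distance between two 1-based inclusive intervals;
# overlapping or book-ended loci count as 0
boundaryGap <- function(s1, e1, s2, e2) {
  pmax(0, pmax(s1, s2) - pmin(e1, e2) - 1)
}

#' Read locus-hit tables
#'
#' Reads homology hits in the native tab-separated layout (columns
#' genome_id, replicon_id, protein_id, family, start, end, strand, evalue,
#' bitscore) or in HMMER per-sequence tabular (\code{--tblout}) format.
#' The HMMER dialect carries no coordinates, so it requires a companion
#' coordinate table (protein_id, genome_id, replicon_id, start, end,
#' strand); the HMM query name becomes the locus family. A protein hit by
#' several family models yields one row per family, all sharing the
#' protein's coordinates.
#'
#' @param path hit file.
#' @param dialect "native" or "hmmer".
#' @param coordinates path to the coordinate sidecar TSV (hmmer dialect
#'   only).
#' @param secondRound logical flag recorded on every row (hits from an
#'   iterative HMM search round are tracked but treated identically by the
#'   operon rules).
#' @return data.frame of hit rows, one per (protein, family).
#' @export
readLocusHits <- function(path, dialect = c("native", "hmmer"),
                          coordinates = NULL, secondRound = FALSE) {
  dialect <- match.arg(dialect)
  if (dialect == "native") {
    hits <- readTsv(path)
    hits <- validateHits(hits)
  } else {
    lines <- readLines(path)
    lines <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
    if (!length(lines)) {
      hits <- data.frame(genome_id = character(), replicon_id = character(),
                         protein_id = character(), family = character(),
                         start = integer(), end = integer(),
                         strand = character(), evalue = numeric(),
                         bitscore = numeric())
      return(validateHits(hits))
    }
    fields <- strsplit(trimws(lines), "[ \t]+")
    short <- lengths(fields) < 6L
    if (any(short))
      stop("malformed HMMER tabular row(s): ",
           paste(which(short), collapse = ", "), call. = FALSE)
    tab <- data.frame(
      protein_id = vapply(fields, `[`, "", 1L),
      family     = vapply(fields, `[`, "", 3L),
      evalue     = as.numeric(vapply(fields, `[`, "", 5L)),
      bitscore   = as.numeric(vapply(fields, `[`, "", 6L)))
    if (is.null(coordinates))
      stop("hmmer dialect requires a coordinate table", call. = FALSE)
    co <- readTsv(coordinates)
    need <- c("protein_id", "genome_id", "replicon_id", "start", "end",
              "strand")
    miss <- setdiff(need, names(co))
    if (length(miss))
      stop("coordinate table missing column(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    idx <- match(tab$protein_id, co$protein_id)
    if (anyNA(idx))
      stop("no coordinates for protein(s): ",
           paste(unique(tab$protein_id[is.na(idx)]), collapse = ", "),
           call. = FALSE)
    hits <- cbind(co[idx, c("genome_id", "replicon_id")],
                  tab[, c("protein_id", "family", "evalue", "bitscore")],
                  co[idx, c("start", "end", "strand")])
    hits <- validateHits(hits[, hitColumns])
  }
  # keep the best E-value when the same protein/family pair repeats
  key <- paste(hits$protein_id, hits$family)
  hits <- hits[order(key, hits$evalue), , drop = FALSE]
  hits <- hits[!duplicated(paste(hits$protein_id, hits$family)), ,
               drop = FALSE]
  hits <- hits[order(hits$genome_id, hits$replicon_id, hits$start,
                     hits$family), , drop = FALSE]
  rownames(hits) <- NULL
  hits$second_round <- rep(isTRUE(secondRound), nrow(hits))
  hits
}

#' Merge a second-round (iterative search) hit table into a first-round one
#'
#' Rows whose (protein, family) pair already exists in the first-round
#' table are dropped; the rest are appended with their second_round flag
#' preserved.
#'
#' @param hits first-round hit table.
#' @param more second-round hit table (e.g. read with
#'   \code{readLocusHits(..., secondRound = TRUE)}).
#' @return combined hit table.
#' @export
mergeHitRounds <- function(hits, more) {
  hits <- validateHits(hits); more <- validateHits(more)
  keep <- !(paste(more$protein_id, more$family) %in%
            paste(hits$protein_id, hits$family))
  out <- rbind(hits, more[keep, , drop = FALSE])
  out <- out[order(out$genome_id, out$replicon_id, out$start, out$family), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Keep significant hits only
#'
#' Retains per-family matches with E-value <= \code{evalueMax} (inclusive
#' boundary); proteins whose matches all fail the threshold disappear.
#'
#' @param hits hit table.
#' @param evalueMax significance threshold (default 1e-5).
#' @return filtered hit table.
#' @export
filterSignificant <- function(hits, evalueMax = 1e-5) {
  hits <- validateHits(hits)
  out <- hits[hits$evalue <= evalueMax, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Drop isolated hits far from any partner
#'
#' A hit is retained only if another hit of the same system exists on the
#' same replicon of the same genome whose nearest boundary lies within
#' \code{spanFactor} times the reference operon span. Isolated singletons
#' (including lone hits on a replicon) are removed before chaining.
#'
#' @param hits hit table (one exopolysaccharide system).
#' @param reference \linkS4class{ReferenceOperon} supplying the span.
#' @param spanFactor window multiplier (default 2).
#' @return filtered hit table.
#' @export
proximityPrefilter <- function(hits, reference, spanFactor = 2) {
  hits <- validateHits(hits)
  stopifnot(methods::is(reference, "ReferenceOperon"))
  window <- spanFactor * reference@referenceSpan
  keep <- logical(nrow(hits))
  grp <- paste(hits$genome_id, hits$replicon_id, sep = "\r")
  for (g in unique(grp)) {
    idx <- which(grp == g)
    prot <- hits[idx, , drop = FALSE]
    u <- !duplicated(prot$protein_id)
    ps <- prot$start[u]; pe <- prot$end[u]; pid <- prot$protein_id[u]
    ok <- vapply(seq_along(pid), function(i) {
      if (length(pid) < 2L) return(FALSE)
      gaps <- boundaryGap(ps[i], pe[i], ps[-i], pe[-i])
      any(gaps <= window)
    }, TRUE)
    keep[idx] <- prot$protein_id %in% pid[ok]
  }
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Chain neighbouring loci into candidate operons
#'
#' Greedy left-to-right chaining of loci (distinct proteins) sorted by
#' start within each replicon: the intergenic gap between consecutive loci
#' is start(next) - end(prev) - 1; a gap of at most \code{maxGap} extends
#' the chain, a larger gap starts a new one. Overlapping loci (negative
#' gap) always chain. Input order is irrelevant; sorting is internal.
#'
#' @param hits hit table.
#' @param maxGap chaining threshold in bp (default 5000).
#' @return list of hit-table chunks, one per chain, each ordered by start.
#' @export
chainLoci <- function(hits, maxGap = 5000) {
  hits <- validateHits(hits)
  chains <- list()
  grp <- paste(hits$genome_id, hits$replicon_id, sep = "\r")
  for (g in unique(grp)) {
    sub <- hits[grp == g, , drop = FALSE]
    prot <- sub[!duplicated(sub$protein_id),
                c("protein_id", "start", "end"), drop = FALSE]
    prot <- prot[order(prot$start, prot$end, prot$protein_id), ,
                 drop = FALSE]
    cid <- 1L
    chain_id <- integer(nrow(prot))
    chain_id[1L] <- cid
    if (nrow(prot) > 1L) {
      for (i in 2:nrow(prot)) {
        gap <- prot$start[i] - prot$end[i - 1L] - 1L
        if (gap > maxGap) cid <- cid + 1L
        chain_id[i] <- cid
      }
    }
    for (k in seq_len(cid)) {
      ids <- prot$protein_id[chain_id == k]
      chunk <- sub[sub$protein_id %in% ids, , drop = FALSE]
      chunk <- chunk[order(chunk$start, chunk$end, chunk$protein_id,
                           chunk$family), , drop = FALSE]
      rownames(chunk) <- NULL
      chains[[length(chains) + 1L]] <- chunk
    }
  }
  chains
}

majorityStrand <- function(loci, reference) {
  u <- loci[!duplicated(loci$protein_id), , drop = FALSE]
  nplus <- sum(u$strand == "+"); nminus <- sum(u$strand == "-")
  if (nplus > nminus) return("+")
  if (nminus > nplus) return("-")
  synRows <- loci$family %in% reference@synthaseFamilies
  if (any(synRows)) loci$strand[which(synRows)[1L]] else "+"
}

#' Call operons from chained loci
#'
#' A chain becomes an operon when it holds at least two loci, at least one
#' locus matching a synthase family and at least one locus of another
#' family (families contributed by multi-family fusion proteins count).
#' Rejected chains are returned in the "rejected" attribute with a reason.
#'
#' @param chains list of hit-table chunks from \code{\link{chainLoci}}.
#' @param reference \linkS4class{ReferenceOperon}.
#' @return list of \linkS4class{OperonCall}; attribute "rejected" is a
#'   data.frame (genome_id, replicon_id, n_loci, reason).
#' @export
callOperons <- function(chains, reference) {
  stopifnot(methods::is(reference, "ReferenceOperon"))
  calls <- list()
  rej <- list()
  counter <- new.env(parent = emptyenv())
  for (chunk in chains) {
    fams <- unique(chunk$family)
    nloci <- length(unique(chunk$protein_id))
    reason <- NULL
    if (nloci < 2L) reason <- "fewer than 2 loci"
    else if (!any(fams %in% reference@synthaseFamilies))
      reason <- "no synthase-family locus"
    else if (!any(!(fams %in% reference@synthaseFamilies)))
      reason <- "no companion-family locus"
    g <- chunk$genome_id[1L]; r <- chunk$replicon_id[1L]
    if (!is.null(reason)) {
      rej[[length(rej) + 1L]] <- data.frame(
        genome_id = g, replicon_id = r, n_loci = nloci, reason = reason)
      next
    }
    key <- paste(g, r, sep = "\r")
    k <- (if (is.null(counter[[key]])) 0L else counter[[key]]) + 1L
    counter[[key]] <- k
    famPerProt <- tapply(chunk$family, chunk$protein_id,
                         function(f) length(unique(f)))
    multi <- any(famPerProt >= 2L)
    calls[[length(calls) + 1L]] <- methods::new("OperonCall",
      operonId = sprintf("%s|%s|op%d", g, r, k),
      genomeId = g, repliconId = r, epsType = reference@epsType,
      loci = chunk, span = max(chunk$end) - min(chunk$start) + 1,
      orientation = majorityStrand(chunk, reference),
      fusionFlag = multi)
  }
  attr(calls, "rejected") <- if (length(rej)) do.call(rbind, rej) else
    data.frame(genome_id = character(), replicon_id = character(),
               n_loci = integer(), reason = character())
  calls
}

#' Predict operons from raw hits in one call
#'
#' Convenience wrapper applying, in order, the significance filter
#' (E-value <= \code{evalueMax}), the proximity prefilter (partner within
#' \code{spanFactor} x reference span), chaining (gaps <= \code{maxGap})
#' and the composition rule.
#'
#' @param hits hit table.
#' @param reference \linkS4class{ReferenceOperon}.
#' @param evalueMax significance threshold (default 1e-5).
#' @param maxGap chaining threshold, bp (default 5000).
#' @param spanFactor prefilter window multiplier (default 2).
#' @return list of \linkS4class{OperonCall} (see \code{\link{callOperons}}).
#' @export
predictOperons <- function(hits, reference, evalueMax = 1e-5,
                           maxGap = 5000, spanFactor = 2) {
  sig <- filterSignificant(hits, evalueMax)
  near <- proximityPrefilter(sig, reference, spanFactor)
  callOperons(chainLoci(near, maxGap), reference)
}

#' Write operon calls as a per-locus TSV
#'
#' @param operons list of \linkS4class{OperonCall}.
#' @param path output file.
#' @param params named parameter list recorded in the '#' header.
#' @return \code{path}, invisibly.
#' @export
writeOperonCalls <- function(operons, path, params = list()) {
  rows <- lapply(operons, function(op) {
    cbind(data.frame(operon_id = op@operonId, eps_type = op@epsType,
                     span = op@span, orientation = op@orientation,
                     fusion = op@fusionFlag,
                     clade_combination = op@cladeCombination),
          op@loci)
  })
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(operon_id = character(), eps_type = character(),
               span = numeric(), orientation = character(),
               fusion = logical(), clade_combination = character(),
               genome_id = character(), replicon_id = character(),
               protein_id = character(), family = character(),
               start = integer(), end = integer(), strand = character(),
               evalue = numeric(), bitscore = numeric(),
               second_round = logical())
  writeTsv(tab, path, params = params)
}

#' Read operon calls written by \code{\link{writeOperonCalls}}
#'
#' @param path operon-call TSV.
#' @return list of \linkS4class{OperonCall}.
#' @export
readOperonCalls <- function(path) {
  tab <- readTsv(path)
  if (!nrow(tab)) return(list())
  out <- lapply(split(tab, tab$operon_id), function(sub) {
    sub <- sub[order(sub$start, sub$end, sub$protein_id, sub$family), ,
               drop = FALSE]
    loci <- sub[, c(hitColumns, "second_round")]
    rownames(loci) <- NULL
    methods::new("OperonCall", operonId = sub$operon_id[1L],
                 genomeId = sub$genome_id[1L],
                 repliconId = sub$replicon_id[1L],
                 epsType = sub$eps_type[1L], loci = loci,
                 span = sub$span[1L], orientation = sub$orientation[1L],
                 fusionFlag = as.logical(sub$fusion[1L]),
                 cladeCombination = {
                   cc <- as.character(sub$clade_combination[1L])
                   if (is.na(cc) || !nzchar(cc)) NA_character_ else cc
                 })
  })
  ord <- order(vapply(out, function(o) o@operonId, ""))
  unname(out[ord])
}

#' Read a reference-operon definition file
#'
#' Flat key = value format with comma-separated lists, e.g.:
#' \preformatted{
#' eps_type = cellulose
#' family_order = bcsA,bcsB,bcsZ,bcsC
#' synthase_families = bcsA
#' reference_span = 8000
#' reference_labels = bcsA:P37653,bcsB:P37652
#' }
#'
#' @param path definition file.
#' @return a \linkS4class{ReferenceOperon}.
#' @export
readReferenceOperon <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(trimws(lines), "#") & nzchar(trimws(lines))]
  kv <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    if (length(parts) < 2L)
      stop("malformed reference line: ", ln, call. = FALSE)
    kv[[trimws(parts[1L])]] <- trimws(paste(parts[-1L], collapse = "="))
  }
  need <- c("eps_type", "family_order", "synthase_families",
            "reference_span")
  miss <- setdiff(need, names(kv))
  if (length(miss))
    stop("reference definition missing: ", paste(miss, collapse = ", "),
         call. = FALSE)
  labs <- character()
  if (!is.null(kv$reference_labels) && nzchar(kv$reference_labels)) {
    pairs <- strsplit(strsplit(kv$reference_labels, ",")[[1L]], ":")
    labs <- vapply(pairs, function(p) trimws(p[2L]), "")
    names(labs) <- vapply(pairs, function(p) trimws(p[1L]), "")
  }
  methods::new("ReferenceOperon",
    epsType = kv$eps_type,
    familyOrder = trimws(strsplit(kv$family_order, ",")[[1L]]),
    synthaseFamilies = trimws(strsplit(kv$synthase_families, ",")[[1L]]),
    referenceSpan = as.numeric(kv$reference_span),
    referenceLabels = labs)
}

#' Write a reference-operon definition file
#'
#' @param reference a \linkS4class{ReferenceOperon}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeReferenceOperon <- function(reference, path) {
  stopifnot(methods::is(reference, "ReferenceOperon"))
  lines <- c(
    paste("eps_type =", reference@epsType),
    paste("family_order =", paste(reference@familyOrder, collapse = ",")),
    paste("synthase_families =",
          paste(reference@synthaseFamilies, collapse = ",")),
    paste("reference_span =", format(reference@referenceSpan, digits = 15)))
  if (length(reference@referenceLabels))
    lines <- c(lines, paste("reference_labels =",
      paste(names(reference@referenceLabels), reference@referenceLabels,
            sep = ":", collapse = ",")))
  writeLines(lines, path)
  invisible(path)
}
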