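eventTypes <- c("loss", "locus_duplication", "fusion", "rearrangement",
                "operon_duplication")

emptyEvents <- function() {
  data.frame(event_type = character(), genome_id = character(),
             eps_type = character(), operon_ids = character(),
             families = character(), detail = character(),
             stringsAsFactors = FALSE)
}

eventRow <- function(type, operon, families, detail = "",
                     operon_ids = NULL) {
  data.frame(event_type = type, genome_id = operon@genomeId,
             eps_type = operon@epsType,
             operon_ids = if (is.null(operon_ids)) operon@operonId else
               operon_ids,
             families = paste(families, collapse = "+"), detail = detail,
             stringsAsFactors = FALSE)
}

#' Call locus losses of an operon against its reference
#'
#' One loss record per reference family with no significant hit anywhere
#' in the operon. A family detected only inside a fusion locus counts as
#' present, not lost.
#'
#' @param operon an \linkS4class{OperonCall}.
#' @param reference matching \linkS4class{ReferenceOperon}.
#' @return events data.frame (possibly empty).
#' @export
callLosses <- function(operon, reference) {
  stopifnot(methods::is(operon, "OperonCall"),
            methods::is(reference, "ReferenceOperon"))
  lost <- setdiff(reference@familyOrder, unique(operon@loci$family))
  if (!length(lost)) return(emptyEvents())
  do.call(rbind, lapply(lost, function(f)
    eventRow("loss", operon, f, "reference family not detected")))
}

#' Call within-operon locus duplications
#'
#' A family duplicated when two or more distinct loci in the operon match
#' the same family model with a nearest-boundary distance below
#' \code{dupDistance} (default 10 kb, strict); one record per family.
#'
#' @param operon an \linkS4class{OperonCall}.
#' @param dupDistance distance ceiling in bp (default 10000).
#' @return events data.frame.
#' @export
callLocusDuplications <- function(operon, dupDistance = 10000) {
  stopifnot(methods::is(operon, "OperonCall"))
  loci <- operon@loci
  out <- emptyEvents()
  for (fam in unique(loci$family)) {
    sub <- loci[loci$family == fam, , drop = FALSE]
    sub <- sub[!duplicated(sub$protein_id), , drop = FALSE]
    if (nrow(sub) < 2L) next
    pairs <- utils::combn(nrow(sub), 2L)
    gaps <- apply(pairs, 2L, function(ij)
      boundaryGap(sub$start[ij[1L]], sub$end[ij[1L]],
                  sub$start[ij[2L]], sub$end[ij[2L]]))
    if (any(gaps < dupDistance))
      out <- rbind(out, eventRow("locus_duplication", operon, fam,
        paste("loci:", paste(sort(sub$protein_id), collapse = ","))))
  }
  out
}

#' Call locus fusions
#'
#' One record per locus (protein) that is a significant hit to two or
#' more family models.
#'
#' @param operon an \linkS4class{OperonCall}.
#' @return events data.frame.
#' @export
callFusions <- function(operon) {
  stopifnot(methods::is(operon, "OperonCall"))
  loci <- operon@loci
  out <- emptyEvents()
  for (pid in unique(loci$protein_id)) {
    fams <- unique(loci$family[loci$protein_id == pid])
    if (length(fams) >= 2L)
      out <- rbind(out, eventRow("fusion", operon, sort(fams),
                                 paste("locus:", pid)))
  }
  out
}

# family tokens of an operon in transcription order: loci in genomic
# order, reversed when the majority strand is '-'; fusion loci expand to
# their families in reference order; duplicated families reduce to their
# first occurrence
observedFamilyOrder <- function(operon, reference) {
  loci <- operon@loci
  prot <- loci[!duplicated(loci$protein_id), , drop = FALSE]
  prot <- prot[order(prot$start, prot$end, prot$protein_id), , drop = FALSE]
  ids <- prot$protein_id
  if (operon@orientation == "-") ids <- rev(ids)
  seqfam <- unlist(lapply(ids, function(pid) {
    fams <- unique(loci$family[loci$protein_id == pid])
    fams <- fams[fams %in% reference@familyOrder]
    fams[order(match(fams, reference@familyOrder))]
  }), use.names = FALSE)
  seqfam[!duplicated(seqfam)]
}

#' Call an operon rearrangement
#'
#' Projects the operon's loci onto their reference families in genomic
#' order, normalises for transcriptional direction by the majority strand,
#' reduces duplicated families to their first occurrence, and compares the
#' result with the reference family order restricted to the families
#' present (so a loss alone never also scores as a rearrangement). Needs
#' at least two distinct reference families in the operon.
#'
#' @param operon an \linkS4class{OperonCall}.
#' @param reference matching \linkS4class{ReferenceOperon}.
#' @return events data.frame with 0 or 1 row.
#' @export
callRearrangement <- function(operon, reference) {
  stopifnot(methods::is(operon, "OperonCall"),
            methods::is(reference, "ReferenceOperon"))
  obs <- observedFamilyOrder(operon, reference)
  if (length(obs) < 2L) return(emptyEvents())
  expected <- reference@familyOrder[reference@familyOrder %in% obs]
  if (identical(obs, expected)) return(emptyEvents())
  eventRow("rearrangement", operon, obs,
           paste("observed:", paste(obs, collapse = ","),
                 "reference:", paste(expected, collapse = ",")))
}

#' Call whole-operon duplications within genomes
#'
#' One record per unordered pair of same-system operons of one genome
#' whose nearest-boundary distance is at least \code{dupDistance}
#' (default 10 kb, inclusive); pairs on different replicons always count.
#'
#' @param operons list of \linkS4class{OperonCall} (any genomes).
#' @param dupDistance distance floor in bp (default 10000).
#' @return events data.frame.
#' @export
callOperonDuplications <- function(operons, dupDistance = 10000) {
  out <- emptyEvents()
  if (length(operons) < 2L) return(out)
  key <- vapply(operons, function(o) paste(o@genomeId, o@epsType,
                                           sep = "\r"), "")
  for (g in unique(key)) {
    ops <- operons[key == g]
    if (length(ops) < 2L) next
    pairs <- utils::combn(length(ops), 2L)
    for (c2 in seq_len(ncol(pairs))) {
      a <- ops[[pairs[1L, c2]]]; b <- ops[[pairs[2L, c2]]]
      far <- if (!identical(a@repliconId, b@repliconId)) TRUE else {
        gap <- boundaryGap(min(a@loci$start), max(a@loci$end),
                           min(b@loci$start), max(b@loci$end))
        gap >= dupDistance
      }
      if (far)
        out <- rbind(out, eventRow("operon_duplication", a,
          unique(c(a@loci$family, b@loci$family)),
          detail = "same-genome same-type pair",
          operon_ids = paste(sort(c(a@operonId, b@operonId)),
                             collapse = ",")))
    }
  }
  out
}

#' Call all five evolutionary event types over a set of operons
#'
#' @param operons list of \linkS4class{OperonCall}.
#' @param reference matching \linkS4class{ReferenceOperon}.
#' @param dupDistance duplication distance threshold in bp (default 10000):
#'   locus duplications must be closer than it, operon duplications at
#'   least it apart.
#' @return events data.frame with one row per event.
#' @export
callEvents <- function(operons, reference, dupDistance = 10000) {
  per <- lapply(operons, function(op) rbind(
    callLosses(op, reference),
    callLocusDuplications(op, dupDistance),
    callFusions(op),
    callRearrangement(op, reference)))
  out <- do.call(rbind, c(list(emptyEvents()), per))
  out <- rbind(out, callOperonDuplications(operons, dupDistance))
  rownames(out) <- NULL
  out
}

#' Summarise called events
#'
#' @param events events data.frame from \code{\link{callEvents}}.
#' @param operons the operon list the events were called on.
#' @return list with counts per event type, per-family loss counts, the
#'   number of operons, mean losses per operon, and the proportion of
#'   operons with at least one loss.
#' @export
summarizeEvents <- function(events, operons) {
  counts <- vapply(eventTypes,
                   function(t) sum(events$event_type == t), 0L)
  losses <- events[events$event_type == "loss", , drop = FALSE]
  lossByFamily <- if (nrow(losses)) {
    tab <- table(losses$families)
    stats::setNames(as.integer(tab), names(tab))
  } else integer(0)
  nOp <- length(operons)
  opWithLoss <- length(unique(losses$operon_ids))
  list(counts = counts,
       lossByFamily = lossByFamily,
       nOperons = nOp,
       meanLossesPerOperon = if (nOp) nrow(losses) / nOp else 0,
       propOperonsWithLoss = if (nOp) opWithLoss / nOp else 0,
       eventsPerOperonMean = if (nOp) nrow(events) / nOp else 0)
}

#' Write an events table as TSV
#'
#' @param events events data.frame.
#' @param path output file.
#' @param params named parameter list for the '#' header.
#' @return \code{path}, invisibly.
#' @export
writeEventsTable <- function(events, path, params = list()) {
  writeTsv(events, path, params = params)
}
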