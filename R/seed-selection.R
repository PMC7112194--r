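#' Read a pairwise identity table
#'
#' Long-format TSV (label_a, label_b, pid, and optionally score) as
#' produced from all-vs-all protein alignment searches; symmetrised into
#' matrices. Missing pairs default to pid 0 (and score 0); the diagonal is
#' fixed at pid 100.
#'
#' @param path identity TSV.
#' @return list with \code{labels}, \code{pid} (symmetric percent-identity
#'   matrix) and \code{score} (symmetric ranking-score matrix; equals
#'   \code{pid} when no score column is present).
#' @export
readIdentityTable <- function(path) {
  tab <- readTsv(path)
  need <- c("label_a", "label_b", "pid")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("identity table missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  labels <- sort(unique(c(tab$label_a, tab$label_b)))
  n <- length(labels)
  pid <- matrix(0, n, n, dimnames = list(labels, labels))
  score <- matrix(0, n, n, dimnames = list(labels, labels))
  hasScore <- "score" %in% names(tab)
  for (i in seq_len(nrow(tab))) {
    a <- tab$label_a[i]; b <- tab$label_b[i]
    pid[a, b] <- pid[b, a] <- tab$pid[i]
    s <- if (hasScore) tab$score[i] else tab$pid[i]
    score[a, b] <- score[b, a] <- s
  }
  diag(pid) <- 100
  if (any(pid < 0 | pid > 100)) stop("pid values must lie in [0, 100]")
  list(labels = labels, pid = pid, score = score)
}

#' Incremental non-redundant seed selection
#'
#' Starting from the reference sequence, repeatedly selects the
#' highest-scoring match of the most recently selected sequence whose
#' percent identity to every already-selected sequence is below
#' \code{maxPid}, until \code{n} sequences are selected or candidates are
#' exhausted (a shortfall, recorded on the result). Enforcing
#' non-redundancy against all previous selections (not only the last)
#' guarantees the final set is pairwise non-redundant. Score ties break
#' lexicographically.
#'
#' @param table identity table from \code{\link{readIdentityTable}} (or a
#'   list with the same shape).
#' @param reference starting label, must be present.
#' @param n target number of seeds (default 20).
#' @param maxPid redundancy ceiling in percent identity (default 97,
#'   strict: candidates at or above it are skipped).
#' @return a \linkS4class{SeedSet}.
#' @export
selectSeeds <- function(table, reference, n = 20, maxPid = 97) {
  stopifnot(n >= 1)
  labels <- table$labels
  if (!reference %in% labels)
    stop("reference label '", reference, "' not in identity table",
         call. = FALSE)
  selected <- reference
  repeat {
    if (length(selected) >= n) break
    last <- selected[length(selected)]
    cand <- setdiff(labels, selected)
    if (length(cand)) {
      ok <- vapply(cand, function(cc)
        all(table$pid[cc, selected] < maxPid), TRUE)
      cand <- cand[ok]
    }
    if (!length(cand)) break
    sc <- table$score[last, cand]
    pick <- cand[order(-sc, cand)][1L]
    selected <- c(selected, pick)
  }
  methods::new("SeedSet", labels = selected, targetN = as.numeric(n),
               reference = reference, shortfall = length(selected) < n)
}

#' Greedy identity-threshold dereplication
#'
#' Desk-scale greedy representative picking over a percent-identity table:
#' labels are visited longest-first (ties lexicographic); a label joins
#' the first existing representative it matches at or above
#' \code{threshold} percent identity, otherwise it founds a new
#' representative.
#'
#' @param table identity table (see \code{\link{readIdentityTable}}).
#' @param threshold identity threshold in percent (default 90, inclusive).
#' @param lengths optional named numeric vector of sequence lengths used
#'   for the longest-first ordering; equal lengths assumed when absent.
#' @return list with \code{representatives} (character) and \code{members}
#'   (named character: label -> its representative).
#' @export
greedyDereplicate <- function(table, threshold = 90, lengths = NULL) {
  labels <- table$labels
  if (is.null(lengths)) lengths <- stats::setNames(rep(0, length(labels)),
                                                   labels)
  ord <- order(-lengths[labels], labels)
  reps <- character()
  members <- stats::setNames(character(length(labels)), labels)
  for (lab in labels[ord]) {
    hit <- NA_character_
    for (r in reps) {
      if (table$pid[lab, r] >= threshold) { hit <- r; break }
    }
    if (is.na(hit)) {
      reps <- c(reps, lab)
      members[lab] <- lab
    } else {
      members[lab] <- hit
    }
  }
  list(representatives = reps, members = members)
}

#' Write a seed list as TSV
#'
#' @param seeds a \linkS4class{SeedSet}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeSeedSet <- function(seeds, path) {
  writeTsv(data.frame(rank = seq_along(seeds@labels),
                      label = seeds@labels),
           path,
           params = list(reference = seeds@reference, n = seeds@targetN),
           header = if (seeds@shortfall) "shortfall=TRUE" else NULL)
}
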