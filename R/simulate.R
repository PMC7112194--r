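# Synthetic fixtures with planted ground truth: clade-structured trees for
# the clustering stages and genome surveys for the operon/event stages.

withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Canonical cellulose reference operon (bcsABZC)
#'
#' The four-locus cellulose operon of enterobacteria: synthase bcsA,
#' membrane subunit bcsB, periplasmic hydrolase bcsZ and outer membrane
#' pore bcsC, with a nominal 8 kb span. Used as the default reference in
#' examples and simulations.
#'
#' @return a \linkS4class{ReferenceOperon}.
#' @export
celluloseReference <- function() {
  methods::new("ReferenceOperon", epsType = "cellulose",
    familyOrder = c("bcsA", "bcsB", "bcsZ", "bcsC"),
    synthaseFamilies = "bcsA", referenceSpan = 8000,
    referenceLabels = c(bcsA = "ref_bcsA", bcsB = "ref_bcsB",
                        bcsZ = "ref_bcsZ", bcsC = "ref_bcsC"))
}

#' Simulate a tree with planted clades
#'
#' Generates one random coalescent-shaped subtree per clade, rescaled so
#' every leaf sits \code{intraScale / 2} from its clade root (maximum
#' intra-clade patristic distance = \code{intraScale}), joins the clade
#' roots by branches of \code{interScale / 2}, then multiplies every
#' branch by independent log-normal noise with log-sd \code{noiseSd}. At
#' zero noise the construction guarantees that every intra-clade distance
#' is below every inter-clade distance.
#'
#' @param kClades number of clades (>= 2).
#' @param nPerClade leaves per clade (>= 2).
#' @param intraScale intra-clade depth scale, substitutions/site.
#' @param interScale inter-clade branch scale, substitutions/site; must
#'   exceed \code{intraScale}.
#' @param noiseSd log-sd of multiplicative branch noise (0 = none).
#' @param seed integer random seed.
#' @return list with \code{tree} (phylo), \code{partition} (named integer:
#'   leaf -> planted clade) and \code{seed}.
#' @export
simulateCladeTree <- function(kClades = 3, nPerClade = 5,
                              intraScale = 0.05, interScale = 1.0,
                              noiseSd = 0, seed = 1) {
  stopifnot(kClades >= 2, nPerClade >= 2, intraScale > 0,
            interScale > intraScale, noiseSd >= 0)
  withSeed(seed, {
    subs <- vapply(seq_len(kClades), function(k) {
      tr <- ape::rcoal(nPerClade,
                       tip.label = sprintf("c%d_t%d", k,
                                           seq_len(nPerClade)))
      depth <- max(ape::node.depth.edgelength(tr))
      tr$edge.length <- tr$edge.length * (intraScale / 2) / depth
      sub <- ape::write.tree(tr)
      sub("\\);$", "", sub("^\\(", "(", sub(";$", "", sub)))
    }, "")
    nwk <- paste0("(",
                  paste0(subs, ":", format(interScale / 2, digits = 15),
                         collapse = ","),
                  ");")
    tree <- ape::read.tree(text = nwk)
    if (noiseSd > 0)
      tree$edge.length <- tree$edge.length *
        exp(stats::rnorm(length(tree$edge.length), 0, noiseSd))
    partition <- as.integer(sub("^c(\\d+)_.*$", "\\1", tree$tip.label))
    names(partition) <- tree$tip.label
    list(tree = tree, partition = partition, seed = seed)
  })
}

# deterministic event targets, chosen so any combination of planted events
# remains recoverable exactly:
#   loss            -> last family (the outer-membrane-pore slot in bcsABZC)
#   duplication     -> tandem copy of the synthase (first family)
#   fusion          -> families 2 and 3 merged into one protein
#   rearrangement   -> family 2 moved to the end; when fused, the fusion
#                      locus moved to the front instead
plantOperonTokens <- function(fams, ev) {
  tokens <- lapply(fams, function(f) f)
  if (ev[["fusion"]]) {
    tokens <- c(tokens[1L], list(c(fams[2L], fams[3L])),
                if (length(fams) > 3L) tokens[4:length(fams)])
  }
  if (ev[["rearrangement"]]) {
    if (ev[["fusion"]]) {
      tokens <- c(tokens[2L], tokens[1L],
                  if (length(tokens) > 2L) tokens[3:length(tokens)])
    } else {
      tokens <- c(tokens[1L], if (length(tokens) > 2L)
        tokens[3:length(tokens)], tokens[2L])
    }
  }
  if (ev[["locus_duplication"]]) {
    at <- which(vapply(tokens, function(t) fams[1L] %in% t, TRUE))[1L]
    tokens <- append(tokens, tokens[at], after = at)
  }
  if (ev[["loss"]]) {
    lossFam <- fams[length(fams)]
    keep <- vapply(tokens, function(t) !identical(t, lossFam), TRUE)
    tokens <- tokens[keep]
  }
  tokens
}

#' Simulate a genome survey with planted operons and events
#'
#' Every genome receives one reference-derived operon on a 5 Mb synthetic
#' replicon, independently mutated by each of the five event types with
#' the probabilities in \code{eventMenu}; with the operon-duplication
#' probability a second canonical copy is placed 20-50 kb downstream.
#' Event targets are fixed (loss removes the last reference family,
#' duplication tandem-copies the synthase, fusion merges families 2 and 3,
#' rearrangement relocates family 2 or the fused locus) so that planted
#' combinations never mask one another and the event caller can recover
#' every planting exactly. \code{decoyRate} isolated single-family hits
#' per genome are scattered at least twice the reference span from any
#' operon and from each other, so no decoy can seed or join an operon.
#'
#' @param reference \linkS4class{ReferenceOperon} with >= 4 families.
#' @param nGenomes number of genomes.
#' @param eventMenu named list of probabilities for loss,
#'   locus_duplication, fusion, rearrangement, operon_duplication
#'   (missing entries default to 0).
#' @param decoyRate decoy hits per genome (integer, at most 10).
#' @param seed integer random seed.
#' @return list with \code{hits} (hit table), \code{taxonomy} (named
#'   genome -> taxon), \code{reference}, \code{truth} (list: operon table,
#'   planted event records, per-type counts) and \code{seed}.
#' @export
simulateSurvey <- function(reference, nGenomes = 50,
                           eventMenu = list(), decoyRate = 0, seed = 1) {
  stopifnot(methods::is(reference, "ReferenceOperon"),
            length(reference@familyOrder) >= 4L,
            decoyRate <= 10)
  menu <- stats::setNames(rep(0, 5L), eventTypes)
  for (nm in names(eventMenu)) {
    stopifnot(nm %in% eventTypes,
              eventMenu[[nm]] >= 0, eventMenu[[nm]] <= 1)
    menu[nm] <- eventMenu[[nm]]
  }
  fams <- reference@familyOrder
  taxa <- c("Gammaproteobacteria", "Alphaproteobacteria",
            "Betaproteobacteria", "Firmicutes")
  withSeed(seed, {
    hitRows <- list(); truthOps <- list(); truthEv <- list()
    taxonomy <- character()
    for (gi in seq_len(nGenomes)) {
      gid <- sprintf("g%04d", gi)
      taxonomy[gid] <- taxa[(gi - 1L) %% length(taxa) + 1L]
      ev <- stats::setNames(stats::runif(5L) < menu, eventTypes)
      pidCounter <- 0L
      placeOperon <- function(tokens, startPos) {
        rows <- list(); pos <- startPos; prots <- character()
        for (tk in tokens) {
          len <- sample(900:2400, 1L)
          pidCounter <<- pidCounter + 1L
          pid <- sprintf("%s_p%02d", gid, pidCounter)
          prots <- c(prots, pid)
          for (f in tk) {
            rows[[length(rows) + 1L]] <- data.frame(
              genome_id = gid, replicon_id = "chr1", protein_id = pid,
              family = f, start = pos, end = pos + len - 1L,
              strand = "+",
              evalue = 10^-stats::runif(1L, 8, 30),
              bitscore = round(stats::runif(1L, 200, 1500), 1L),
              stringsAsFactors = FALSE)
          }
          pos <- pos + len + sample(50:500, 1L)
        }
        list(rows = rows, endPos = pos, proteins = prots)
      }
      tokens <- plantOperonTokens(fams, ev)
      start1 <- sample(100000:4000000, 1L)
      op1 <- placeOperon(tokens, start1)
      hitRows <- c(hitRows, op1$rows)
      opTab <- do.call(rbind, op1$rows)
      truthOps[[length(truthOps) + 1L]] <- data.frame(
        genome_id = gid, replicon_id = "chr1",
        start = min(opTab$start), end = max(opTab$end),
        proteins = paste(op1$proteins, collapse = ","),
        families = paste(unique(opTab$family), collapse = ","),
        stringsAsFactors = FALSE)
      recordEvent <- function(type, famsInvolved)
        truthEv[[length(truthEv) + 1L]] <<- data.frame(
          event_type = type, genome_id = gid,
          families = paste(famsInvolved, collapse = "+"),
          stringsAsFactors = FALSE)
      if (ev[["loss"]]) recordEvent("loss", fams[length(fams)])
      if (ev[["locus_duplication"]])
        recordEvent("locus_duplication", fams[1L])
      if (ev[["fusion"]]) recordEvent("fusion", sort(fams[2:3]))
      if (ev[["rearrangement"]]) recordEvent("rearrangement", fams[2L])
      if (ev[["operon_duplication"]]) {
        start2 <- op1$endPos + sample(20000:50000, 1L)
        op2 <- placeOperon(lapply(fams, function(f) f), start2)
        hitRows <- c(hitRows, op2$rows)
        op2Tab <- do.call(rbind, op2$rows)
        truthOps[[length(truthOps) + 1L]] <- data.frame(
          genome_id = gid, replicon_id = "chr1",
          start = min(op2Tab$start), end = max(op2Tab$end),
          proteins = paste(op2$proteins, collapse = ","),
          families = paste(unique(op2Tab$family), collapse = ","),
          stringsAsFactors = FALSE)
        recordEvent("operon_duplication", fams)
      }
      if (decoyRate > 0) {
        for (k in seq_len(decoyRate)) {
          pidCounter <- pidCounter + 1L
          pos <- 4500000L + (k - 1L) * 40000L
          len <- sample(900:2400, 1L)
          hitRows[[length(hitRows) + 1L]] <- data.frame(
            genome_id = gid, replicon_id = "chr1",
            protein_id = sprintf("%s_p%02d", gid, pidCounter),
            family = sample(fams, 1L), start = pos,
            end = pos + len - 1L, strand = "+",
            evalue = 10^-stats::runif(1L, 8, 30),
            bitscore = round(stats::runif(1L, 200, 1500), 1L),
            stringsAsFactors = FALSE)
        }
      }
    }
    hits <- do.call(rbind, hitRows)
    hits$second_round <- FALSE
    hits <- hits[order(hits$genome_id, hits$replicon_id, hits$start,
                       hits$family), , drop = FALSE]
    rownames(hits) <- NULL
    events <- if (length(truthEv)) do.call(rbind, truthEv) else
      data.frame(event_type = character(), genome_id = character(),
                 families = character())
    counts <- vapply(eventTypes,
                     function(t) sum(events$event_type == t), 0L)
    list(hits = hits, taxonomy = taxonomy, reference = reference,
         truth = list(operons = do.call(rbind, truthOps),
                      events = events, counts = counts),
         seed = seed)
  })
}

#' Simulate per-family trees consistent with a survey
#'
#' For every locus family of the survey's reference, builds a tree over
#' the protein labels hitting that family plus the family's reference
#' sequence label, with a planted clade structure: genomes are assigned
#' round-robin to \code{kClades} groups (the reference sits in group 1),
#' leaves of one group sit \code{intraScale / 2} below their group node
#' and groups join over branches of \code{interScale / 2}. Groups that
#' would end up with a single leaf are folded into group 1. The planted
#' partition is returned alongside each tree.
#'
#' @param survey result of \code{\link{simulateSurvey}}.
#' @param kClades number of planted clades per family.
#' @param intraScale,interScale intra-/inter-clade scales,
#'   substitutions/site (inter must exceed intra).
#' @return named list (per family) of lists with \code{tree} (phylo) and
#'   \code{partition} (named integer).
#' @export
simulateFamilyTrees <- function(survey, kClades = 2, intraScale = 0.05,
                                interScale = 1.0) {
  stopifnot(kClades >= 1, interScale > intraScale, intraScale > 0)
  reference <- survey$reference
  hits <- survey$hits
  genomes <- sort(unique(hits$genome_id))
  groupOfGenome <- stats::setNames(
    (match(genomes, genomes) - 1L) %% kClades + 1L, genomes)
  out <- list()
  for (fam in reference@familyOrder) {
    labs <- sort(unique(hits$protein_id[hits$family == fam]))
    refLab <- unname(reference@referenceLabels[fam])
    grp <- groupOfGenome[sub("_p\\d+$", "", labs)]
    names(grp) <- labs
    grp[is.na(grp)] <- 1L
    grp[refLab] <- 1L
    tab <- table(grp)
    lonely <- as.integer(names(tab)[tab < 2L])
    grp[grp %in% lonely] <- 1L
    half <- format(intraScale / 2, digits = 15)
    joins <- format(interScale / 2, digits = 15)
    subs <- vapply(sort(unique(grp)), function(k) {
      members <- sort(names(grp)[grp == k])
      paste0("(", paste0(members, ":", half, collapse = ","), ")")
    }, "")
    nwk <- if (length(subs) == 1L) paste0(subs, ";") else
      paste0("(", paste0(subs, ":", joins, collapse = ","), ");")
    out[[fam]] <- list(tree = ape::read.tree(text = nwk),
                       partition = grp)
  }
  out
}

#' Write a simulated survey to disk in the pipeline's native formats
#'
#' Emits hits.tsv, taxonomy.tsv, reference.ref, truth_operons.tsv,
#' truth_events.tsv and truth.json under \code{dir}.
#'
#' @param survey result of \code{\link{simulateSurvey}}.
#' @param dir output directory (created if needed).
#' @return named character vector of files written, invisibly.
#' @export
writeSurvey <- function(survey, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  f <- c(hits = file.path(dir, "hits.tsv"),
         taxonomy = file.path(dir, "taxonomy.tsv"),
         reference = file.path(dir, "reference.ref"),
         truth_operons = file.path(dir, "truth_operons.tsv"),
         truth_events = file.path(dir, "truth_events.tsv"),
         truth = file.path(dir, "truth.json"))
  writeTsv(survey$hits, f[["hits"]], params = list(seed = survey$seed))
  writeTsv(data.frame(genome_id = names(survey$taxonomy),
                      taxon = unname(survey$taxonomy)), f[["taxonomy"]])
  writeReferenceOperon(survey$reference, f[["reference"]])
  writeTsv(survey$truth$operons, f[["truth_operons"]])
  writeTsv(survey$truth$events, f[["truth_events"]])
  jsonlite::write_json(list(seed = survey$seed,
                            counts = as.list(survey$truth$counts)),
                       f[["truth"]], auto_unbox = TRUE, digits = NA)
  invisible(f)
}
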