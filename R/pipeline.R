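#' Read a flat key = value run configuration
#'
#' Recognised keys: \code{hits}, \code{reference}, \code{taxonomy},
#' \code{trees_dir} (per-family \code{<family>.nwk}) or
#' \code{distances_dir} (per-family \code{<family>.tsv}), \code{scheme}
#' (Q1/Q2/Q3, default Q2), \code{step} (0.01), \code{evalue} (1e-5),
#' \code{max_gap} (5000), \code{dup_distance} (10000), \code{span_factor}
#' (2), \code{seed}. Unknown keys are kept verbatim.
#'
#' @param path configuration file.
#' @return named list with numeric defaults filled in.
#' @export
readRunConfig <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(trimws(lines), "#") & nzchar(trimws(lines))]
  cfg <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    if (length(parts) < 2L) stop("malformed config line: ", ln)
    cfg[[trimws(parts[1L])]] <- trimws(paste(parts[-1L], collapse = "="))
  }
  defaults <- list(scheme = "Q2", step = 0.01, evalue = 1e-5,
                   max_gap = 5000, dup_distance = 10000, span_factor = 2,
                   seed = 1)
  for (nm in names(defaults))
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  for (nm in c("step", "evalue", "max_gap", "dup_distance", "span_factor",
               "seed"))
    cfg[[nm]] <- as.numeric(cfg[[nm]])
  stopifnot(cfg$scheme %in% c("Q1", "Q2", "Q3"),
            cfg$step > 0, cfg$evalue > 0, cfg$max_gap > 0,
            cfg$dup_distance > 0, cfg$span_factor > 0)
  cfg
}

stageLog <- function(name, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
  message(sprintf("[operonclade] stage %-10s %.2fs", name,
                  proc.time()[["elapsed"]] - t0))
  res
}

#' Run the full classification pipeline
#'
#' Executes, in order: operon prediction from hits; evolutionary-event
#' calling against the reference; per-family cutoff-sweep clustering of
#' patristic distances; clade assignment against the reference sequence
#' labels; clade-combination labelling of each operon; and
#' genomic-proximity network construction and export. Writes
#' \code{operons.tsv}, \code{events.tsv}, \code{event_summary.json},
#' \code{sweep_<family>.tsv}, \code{clusters.tsv}, \code{network.graphml},
#' \code{network.json} and a \code{manifest.json} describing every stage,
#' its parameters and outputs. Outputs are deterministic: rerunning the
#' same configuration reproduces every file byte for byte.
#'
#' @param config a configuration list (see \code{\link{readRunConfig}}) or
#'   the path to a configuration file.
#' @param outDir output directory, created if needed.
#' @return path of the manifest file, invisibly.
#' @export
runPipeline <- function(config, outDir) {
  if (is.character(config)) config <- readRunConfig(config)
  for (nm in c("hits", "reference"))
    if (is.null(config[[nm]]))
      stop("config is missing required key '", nm, "'", call. = FALSE)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  params <- config[c("scheme", "step", "evalue", "max_gap",
                     "dup_distance", "span_factor", "seed")]
  manifest <- list(tool = "operonclade", version = toolVersion(),
                   parameters = params, stages = list())
  addStage <- function(name, inputs, outputs)
    manifest$stages[[length(manifest$stages) + 1L]] <<-
      list(stage = name, inputs = inputs,
           outputs = basename(outputs))  # relative: reruns compare equal

  reference <- readReferenceOperon(config$reference)
  hits <- readLocusHits(config$hits, dialect = "native")

  opPath <- file.path(outDir, "operons.tsv")
  operons <- stageLog("operons", {
    ops <- predictOperons(hits, reference, evalueMax = config$evalue,
                          maxGap = config$max_gap,
                          spanFactor = config$span_factor)
    writeOperonCalls(ops, opPath, params = params)
    ops
  })
  addStage("operons", config$hits, opPath)

  evPath <- file.path(outDir, "events.tsv")
  sumPath <- file.path(outDir, "event_summary.json")
  events <- stageLog("events", {
    ev <- callEvents(operons, reference,
                     dupDistance = config$dup_distance)
    writeEventsTable(ev, evPath, params = params)
    jsonlite::write_json(summarizeEvents(ev, operons), sumPath,
                         auto_unbox = TRUE, digits = NA)
    ev
  })
  addStage("events", basename(opPath), c(evPath, sumPath))

  treeFor <- function(fam) {
    if (!is.null(config$trees_dir)) {
      p <- file.path(config$trees_dir, paste0(fam, ".nwk"))
      if (!file.exists(p)) stop("no tree file for family '", fam, "': ", p)
      patristicDistances(readNewickTree(p))
    } else if (!is.null(config$distances_dir)) {
      p <- file.path(config$distances_dir, paste0(fam, ".tsv"))
      if (!file.exists(p))
        stop("no distance file for family '", fam, "': ", p)
      readDistanceMatrix(p)
    } else stop("config needs trees_dir or distances_dir", call. = FALSE)
  }
  sweeps <- stageLog("cluster", {
    out <- list()
    for (fam in reference@familyOrder) {
      D <- treeFor(fam)
      sw <- sweepCutoffs(D, scheme = config$scheme, step = config$step)
      writeSweepTrace(sw, file.path(outDir,
                                    paste0("sweep_", fam, ".tsv")))
      out[[fam]] <- list(D = D, sweep = sw)
    }
    out
  })
  addStage("cluster",
           if (!is.null(config$trees_dir)) config$trees_dir else
             config$distances_dir,
           file.path(outDir, paste0("sweep_", reference@familyOrder,
                                    ".tsv")))

  cluPath <- file.path(outDir, "clusters.tsv")
  assignments <- stageLog("clades", {
    asg <- list()
    tabs <- list()
    for (fam in reference@familyOrder) {
      refLab <- unname(reference@referenceLabels[fam])
      if (is.na(refLab) || is.null(refLab))
        stop("reference has no sequence label for family '", fam, "'")
      a <- assignClades(sweeps[[fam]]$D,
                        selectedClustering(sweeps[[fam]]$sweep),
                        refLab, family = fam)
      asg[[fam]] <- a
      tmp <- tempfile()
      writeClusterTable(a, sweeps[[fam]]$sweep@selectedQuality, tmp)
      tabs[[fam]] <- readTsv(tmp)
      unlink(tmp)
    }
    writeTsv(do.call(rbind, tabs), cluPath, params = params)
    asg
  })
  addStage("clades", "sweep tables", cluPath)

  operons <- stageLog("combine", {
    ops <- lapply(operons, function(op) {
      op@cladeCombination <- cladeCombination(op, assignments, reference)
      op
    })
    writeOperonCalls(ops, opPath, params = params)
    ops
  })
  addStage("combine", basename(cluPath), opPath)

  netFiles <- c(file.path(outDir, "network.graphml"),
                file.path(outDir, "network.json"))
  stageLog("network", {
    taxonomy <- NULL
    if (!is.null(config$taxonomy)) {
      tx <- readTsv(config$taxonomy)
      taxonomy <- stats::setNames(tx$taxon, tx$genome_id)
    }
    net <- buildProximityNetwork(operons, assignments, taxonomy,
                                 reference = reference)
    exportNetwork(net, netFiles[1L], format = "graphml")
    exportNetwork(net, netFiles[2L], format = "json")
    net
  })
  addStage("network", basename(c(opPath, cluPath)), netFiles)

  manifestPath <- file.path(outDir, "manifest.json")
  jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE,
                       digits = NA)
  invisible(manifestPath)
}
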