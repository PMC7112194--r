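writeNativeHits <- function(rows) {
  f <- tempfile(fileext = ".tsv")
  tab <- do.call(rbind, rows)
  tab$second_round <- NULL
  utils::write.table(tab, f, sep = "\t", quote = FALSE, row.names = FALSE)
  f
}

test_that("native hit TSVs parse and per-protein families merge", {
  f <- writeNativeHits(list(
    hitRow("g1", "p1", "bcsA", 100, 1000),
    hitRow("g1", "p2", "bcsZ", 1200, 2000),
    hitRow("g1", "p2", "bcsC", 1200, 2000),
    hitRow("g1", "p3", "bcsB", 2100, 3000)))
  hits <- readLocusHits(f, "native")
  expect_equal(nrow(hits), 4)
  expect_equal(sort(unique(hits$protein_id)), c("p1", "p2", "p3"))
  expect_setequal(hits$family[hits$protein_id == "p2"], c("bcsZ", "bcsC"))
})

test_that("HMMER tabular hits join their coordinate sidecar", {
  f <- tempfile()
  writeLines(c(
    "# comment line",
    "p1 - bcsA PF001 1e-40 321.5 0.1 1e-39 300 0.1 1 1 0 0 1 1 - desc",
    "p2 - bcsB PF002 2e-12 88.2 0.0 3e-12 80 0.0 1 1 0 0 1 1 - desc"), f)
  co <- tempfile()
  utils::write.table(data.frame(
    protein_id = c("p1", "p2"), genome_id = "g1", replicon_id = "chr1",
    start = c(100L, 1500L), end = c(1000L, 2400L), strand = "+"),
    co, sep = "\t", quote = FALSE, row.names = FALSE)
  hits <- readLocusHits(f, "hmmer", coordinates = co)
  expect_equal(nrow(hits), 2)
  expect_equal(hits$family, c("bcsA", "bcsB"))
  expect_equal(hits$evalue, c(1e-40, 2e-12))
  expect_equal(hits$start, c(100L, 1500L))

  # missing coordinates must name the offending proteins
  co2 <- tempfile()
  utils::write.table(data.frame(
    protein_id = "p1", genome_id = "g1", replicon_id = "chr1",
    start = 100L, end = 1000L, strand = "+"),
    co2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readLocusHits(f, "hmmer", coordinates = co2), "p2")
  expect_error(readLocusHits(f, "hmmer"), "coordinate")
  expect_error(readLocusHits(f, "tblout"), "arg")
})

test_that("significance filtering honours the inclusive 1e-5 boundary", {
  hits <- rbind(hitRow("g1", "p1", "bcsA", 1, 10, evalue = 1e-5),
                hitRow("g1", "p2", "bcsB", 20, 30, evalue = 1.1e-5),
                hitRow("g1", "p3", "bcsZ", 40, 50, evalue = 1e-3))
  kept <- filterSignificant(hits, 1e-5)
  expect_equal(kept$protein_id, "p1")
  expect_equal(nrow(filterSignificant(hits[0, ], 1e-5)), 0)
})

test_that("the proximity prefilter keeps partnered hits within 2x span", {
  ref <- cannedReference()  # span 8000, window 16000
  paired <- rbind(hitRow("g1", "p1", "bcsA", 1000, 2000),
                  hitRow("g1", "p2", "bcsB", 3000, 4000))     # 1 kb apart
  expect_equal(nrow(proximityPrefilter(paired, ref)), 2)

  farApart <- rbind(hitRow("g1", "p1", "bcsA", 1000, 2000),
                    hitRow("g1", "p2", "bcsB", 52000, 53000)) # 50 kb gap
  expect_equal(nrow(proximityPrefilter(farApart, ref)), 0)

  lone <- hitRow("g1", "p1", "bcsA", 1000, 2000)
  expect_equal(nrow(proximityPrefilter(lone, ref)), 0)

  # partners must share a replicon
  split <- rbind(hitRow("g1", "p1", "bcsA", 1000, 2000, replicon = "chr1"),
                 hitRow("g1", "p2", "bcsB", 2500, 3500, replicon = "p1"))
  expect_equal(nrow(proximityPrefilter(split, ref)), 0)
})

test_that("chaining breaks strictly above 5 kb and tolerates overlap", {
  mk <- function(gaps) {
    start <- 1000; rows <- list(hitRow("g1", "p1", "bcsA", 1000, 2000))
    pos <- 2000
    for (i in seq_along(gaps)) {
      s <- pos + gaps[i] + 1
      rows[[i + 1]] <- hitRow("g1", paste0("p", i + 1),
                              c("bcsB", "bcsZ", "bcsC")[i], s, s + 900)
      pos <- s + 900
    }
    do.call(rbind, rows)
  }
  expect_length(chainLoci(mk(c(200, 300))), 1)
  expect_length(chainLoci(mk(c(5000))), 1)      # inclusive boundary
  expect_length(chainLoci(mk(c(5001))), 2)      # exclusive above
  # overlapping loci (negative gap) always chain
  ov <- rbind(hitRow("g1", "p1", "bcsA", 1000, 2000),
              hitRow("g1", "p2", "bcsB", 1500, 2500))
  expect_length(chainLoci(ov), 1)
  # order invariance
  h <- mk(c(200, 5001, 300))
  expect_equal(lapply(chainLoci(h[sample(nrow(h)), ]), function(x)
    x$protein_id),
    lapply(chainLoci(h), function(x) x$protein_id))
})

test_that("operon calls enforce the synthase-plus-companion rule", {
  ref <- cannedReference()
  ok <- chainLoci(rbind(
    hitRow("g1", "p1", "bcsA", 1000, 2000),
    hitRow("g1", "p2", "bcsB", 2200, 3000),
    hitRow("g1", "p3", "bcsZ", 3100, 4000),
    hitRow("g1", "p4", "bcsC", 4100, 5000)))
  calls <- callOperons(ok, ref)
  expect_length(calls, 1)
  expect_s4_class(calls[[1]], "OperonCall")
  expect_equal(epsType(calls[[1]]), "cellulose")
  expect_equal(calls[[1]]@span, 4001)

  noSynthase <- chainLoci(rbind(
    hitRow("g1", "p2", "bcsB", 2200, 3000),
    hitRow("g1", "p3", "bcsZ", 3100, 4000)))
  out <- callOperons(noSynthase, ref)
  expect_length(out, 0)
  expect_match(attr(out, "rejected")$reason, "synthase")

  aloneOrDouble <- chainLoci(rbind(
    hitRow("g1", "p1", "bcsA", 1000, 2000),
    hitRow("g2", "p9", "bcsA", 1000, 2000),
    hitRow("g2", "p10", "bcsA", 2500, 3200)))
  out2 <- callOperons(aloneOrDouble, ref)
  expect_length(out2, 0)
  expect_setequal(attr(out2, "rejected")$reason,
                  c("fewer than 2 loci", "no companion-family locus"))
})

test_that("fusion proteins satisfy composition and raise the flag", {
  ref <- cannedReference()
  fused <- chainLoci(rbind(
    hitRow("g1", "p1", "bcsA", 1000, 2000),
    hitRow("g1", "p2", "bcsZ", 2200, 3500),
    hitRow("g1", "p2", "bcsC", 2200, 3500)))
  calls <- callOperons(fused, ref)
  expect_length(calls, 1)
  expect_true(calls[[1]]@fusionFlag)
})

test_that("raising max_gap never removes loci from operons", {
  set.seed(7)
  sv <- simulateSurvey(cannedReference(), nGenomes = 12,
                       eventMenu = list(loss = 0.4, rearrangement = 0.4),
                       decoyRate = 2, seed = 7)
  nIn <- function(gap) {
    ops <- predictOperons(sv$hits, cannedReference(), maxGap = gap)
    sum(vapply(ops, function(o) length(unique(o@loci$protein_id)), 0L))
  }
  counts <- vapply(c(500, 2000, 5000, 20000), nIn, 0L)
  expect_true(all(diff(counts) >= 0))
})

test_that("operon calls round-trip through the TSV writer", {
  ref <- cannedReference()
  sv <- simulateSurvey(ref, nGenomes = 6,
                       eventMenu = list(fusion = 0.5,
                                        operon_duplication = 0.5),
                       seed = 3)
  ops <- predictOperons(sv$hits, ref)
  f <- tempfile(fileext = ".tsv")
  writeOperonCalls(ops, f, params = list(evalue = 1e-5))
  back <- readOperonCalls(f)
  expect_equal(length(back), length(ops))
  ids <- vapply(ops, function(o) o@operonId, "")
  for (i in seq_along(back)) {
    orig <- ops[[which(ids == back[[i]]@operonId)]]
    expect_equal(back[[i]]@loci$protein_id, orig@loci$protein_id)
    expect_equal(back[[i]]@span, orig@span)
    expect_equal(back[[i]]@orientation, orig@orientation)
  }
})

test_that("reference definitions round-trip through the config format", {
  ref <- cannedReference()
  f <- tempfile(fileext = ".ref")
  writeReferenceOperon(ref, f)
  back <- readReferenceOperon(f)
  expect_equal(familyOrder(back), familyOrder(ref))
  expect_equal(synthaseFamilies(back), synthaseFamilies(ref))
  expect_equal(back@referenceSpan, ref@referenceSpan)
  expect_equal(back@referenceLabels, ref@referenceLabels)
  expect_error(readReferenceOperon(writeLines2 <- {
    g <- tempfile(); writeLines("eps_type = x", g); g
  }), "missing")
})

test_that("second-round hits merge without displacing first-pass rows", {
  first <- rbind(hitRow("g1", "p1", "bcsA", 1000, 2000),
                 hitRow("g1", "p2", "bcsB", 2200, 3000))
  second <- rbind(hitRow("g1", "p2", "bcsB", 2200, 3000),
                  hitRow("g1", "p3", "bcsZ", 3100, 4000))
  second$second_round <- TRUE
  merged <- mergeHitRounds(first, second)
  expect_equal(nrow(merged), 3)
  expect_equal(merged$second_round[merged$protein_id == "p3"], TRUE)
  expect_equal(merged$second_round[merged$protein_id == "p2"], FALSE)
})
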