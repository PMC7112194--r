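# two tight pairs separated by a large distance: the worked micro-example
pairMatrix <- function() {
  labs <- c("A", "B", "C", "D")
  d <- matrix(1, 4, 4, dimnames = list(labs, labs))
  diag(d) <- 0
  d["A", "B"] <- d["B", "A"] <- 0.10
  d["C", "D"] <- d["D", "C"] <- 0.10
  d
}

test_that("threshold clustering is the strict single-linkage closure", {
  d <- pairMatrix()
  cl <- thresholdCluster(d, 0.11)
  expect_equal(clusterMembers(cl), list(c("A", "B"), c("C", "D")))
  expect_length(unclusteredLabels(cl), 0)

  # strict inequality: at 0 (and at a tie value) nothing merges
  expect_length(clusterMembers(thresholdCluster(d, 0)), 0)
  expect_length(clusterMembers(thresholdCluster(d, 0.10)), 0)
  expect_equal(unclusteredLabels(thresholdCluster(d, 0)),
               c("A", "B", "C", "D"))

  # beyond the largest distance everything is one component
  expect_equal(clusterMembers(thresholdCluster(d, 1.01)),
               list(c("A", "B", "C", "D")))

  # transitivity: chain a-b-c links a and c even when d(a,c) is large
  labs <- c("a", "b", "c")
  d3 <- matrix(c(0, .1, .9, .1, 0, .1, .9, .1, 0), 3, 3,
               dimnames = list(labs, labs))
  expect_equal(clusterMembers(thresholdCluster(d3, 0.2)),
               list(c("a", "b", "c")))
})

test_that("clustering representation is invariant to label order", {
  d <- pairMatrix()
  perm <- c("D", "B", "A", "C")
  cl1 <- thresholdCluster(d, 0.11)
  cl2 <- thresholdCluster(d[perm, perm], 0.11)
  expect_equal(clusterMembers(cl1), clusterMembers(cl2))
})

test_that("silhouette matches the formula on the worked example and the
           zero-intra convention", {
  d <- pairMatrix()
  cl <- thresholdCluster(d, 0.11)
  s <- silhouetteScores(d, cl)
  expect_equal(unname(s[c("A", "B", "C", "D")]), rep(0.9, 4))

  # duplicates: a(i) = 0, b(i) > 0 gives s(i) = 1
  labs <- c("x1", "x2", "y1", "y2")
  dd <- matrix(1, 4, 4, dimnames = list(labs, labs))
  diag(dd) <- 0
  dd["x1", "x2"] <- dd["x2", "x1"] <- 0
  dd["y1", "y2"] <- dd["y2", "y1"] <- 0.2
  cl2 <- thresholdCluster(dd, 0.3)
  s2 <- silhouetteScores(dd, cl2)
  expect_equal(unname(s2["x1"]), 1)

  # a(i) = b(i) = 0 gives 0 by convention
  dz <- matrix(0, 4, 4, dimnames = list(labs, labs))
  clz <- methods::new("PhyloClustering", cutoff = 0.1,
                      clusters = list(c("x1", "x2"), c("y1", "y2")),
                      unclustered = character(), labels = labs)
  expect_equal(unname(silhouetteScores(dz, clz)), rep(0, 4))

  expect_error(silhouetteScores(d, thresholdCluster(d, 1.01)), "fewer")
})

test_that("Dunn index matches hand values and handles degeneracy", {
  d <- pairMatrix()
  di <- dunnIndex(d, thresholdCluster(d, 0.11))
  expect_equal(di$DI, 10)
  expect_false(di$degenerate)

  # poorly separated construction: min inter 0.2 < max diameter 0.5
  labs <- c("A", "B", "C", "D")
  dd <- matrix(0.6, 4, 4, dimnames = list(labs, labs))
  diag(dd) <- 0
  dd["A", "B"] <- dd["B", "A"] <- 0.5
  dd["C", "D"] <- dd["D", "C"] <- 0.5
  dd["B", "C"] <- dd["C", "B"] <- 0.2
  clu <- methods::new("PhyloClustering", cutoff = 0.55,
                      clusters = list(c("A", "B"), c("C", "D")),
                      unclustered = character(), labels = labs)
  expect_equal(dunnIndex(dd, clu)$DI, 0.4)

  # all-duplicate clusters hit the epsilon floor and are flagged
  dz <- matrix(1, 4, 4, dimnames = list(labs, labs))
  diag(dz) <- 0
  dz["A", "B"] <- dz["B", "A"] <- 0
  dz["C", "D"] <- dz["D", "C"] <- 0
  diz <- dunnIndex(dz, thresholdCluster(dz, 0.5))
  expect_true(diz$degenerate)
  expect_equal(diz$DI, 1 / 1e-9)

  expect_error(dunnIndex(d, thresholdCluster(d, 1.01)), "fewer")
})

test_that("singleton components participate in the Dunn inter-cluster
           minimum", {
  labs <- c("a1", "a2", "a3", "b1", "b2")
  d <- matrix(1, 5, 5, dimnames = list(labs, labs))
  diag(d) <- 0
  d["a1", "a2"] <- d["a2", "a1"] <- 0.05
  d["a1", "a3"] <- d["a3", "a1"] <- 0.08   # a3 sits just outside the pair
  d["a2", "a3"] <- d["a3", "a2"] <- 0.08
  d["b1", "b2"] <- d["b2", "b1"] <- 0.05
  trimmed <- methods::new("PhyloClustering", cutoff = 0.06,
                          clusters = list(c("a1", "a2"), c("b1", "b2")),
                          unclustered = "a3", labels = labs)
  expect_equal(dunnIndex(d, trimmed)$DI, 0.08 / 0.05)
  full <- thresholdCluster(d, 0.09)
  expect_equal(dunnIndex(d, full)$DI, 1 / 0.08)
})

test_that("silhouette and Dunn match brute-force oracles on random
           instances", {
  set.seed(97)
  for (i in 1:200) {
    n <- sample(5:12, 1)
    d <- randomDistanceMatrix(n)
    cl <- randomClustering(rownames(d))
    s <- silhouetteScores(d, cl)
    sOracle <- oracleSilhouette(d, clusterMembers(cl))
    expect_lt(max(abs(s[names(sOracle)] - sOracle)), 1e-9)
    di <- dunnIndex(d, cl)$DI
    diOracle <- oracleDunn(d, clusterMembers(cl), unclusteredLabels(cl))
    expect_lt(abs(di - diOracle), 1e-9 * max(1, diOracle))
  }
})

test_that("composite scores follow their definitions", {
  d <- pairMatrix()
  q <- clusterQuality(d, thresholdCluster(d, 0.11))
  expect_true(q@valid)
  expect_equal(q@p, 1.0)
  expect_equal(q@sAvg, 0.9)
  expect_equal(q@DI, 10)
  expect_equal(q@Q1, 10.9)
  expect_equal(q@Q2, 11.9)
  expect_equal(q@Q3, 10.9)

  # proportion counts clustered sequences over all labels
  labs <- c("a", "b", "c")
  d3 <- matrix(c(0, .05, 2, .05, 0, 2, 2, 2, 0), 3, 3,
               dimnames = list(labs, labs))
  cl3 <- methods::new("PhyloClustering", cutoff = 0.1,
                      clusters = list(c("a", "b")), unclustered = "c",
                      labels = labs)
  # m = 1 is flagged invalid, not an error
  q3 <- clusterQuality(d3, cl3)
  expect_false(q3@valid)
  labs4 <- c("a", "b", "c", "x")
  d4 <- rbind(cbind(d3, x = c(2, 2, 1)), x = c(2, 2, 1, 0))
  dimnames(d4) <- list(labs4, labs4)
  cl4 <- methods::new("PhyloClustering", cutoff = 1.2,
                      clusters = list(c("a", "b"), c("c", "x")),
                      unclustered = character(), labels = labs4)
  expect_equal(clusterQuality(d4, cl4)@p, 1)
  cl4b <- methods::new("PhyloClustering", cutoff = 0.1,
                       clusters = list(c("a", "b")),
                       unclustered = c("c", "x"), labels = labs4)
  expect_equal(sum(lengths(clusterMembers(cl4b))) / 4, 0.5)
})

test_that("the Q2 sweep selects cutoff 0.11 on the worked example", {
  d <- pairMatrix()
  sw <- sweepCutoffs(d, scheme = "Q2", step = 0.01)
  expect_equal(sw@selectedCutoff, 0.11, tolerance = 1e-12)
  expect_equal(clusterMembers(selectedClustering(sw)),
               list(c("A", "B"), c("C", "D")))
  q <- sw@selectedQuality
  expect_equal(q@p, 1.0)
  expect_equal(q@sAvg, 0.9)
  expect_equal(q@DI, 10)
  expect_equal(q@Q2, 11.9)
  # the plateau 0.11..1.00 shares one score; smallest cutoff wins the tie
  tr <- qualityTrace(sw)
  plateau <- tr[tr$valid, ]
  expect_true(all(abs(plateau$Q2 - 11.9) < 1e-12))
  expect_equal(min(plateau$cutoff), 0.11, tolerance = 1e-12)
})

test_that("sweep on a 2-label matrix raises the no-optimum error", {
  labs <- c("A", "B")
  d <- matrix(c(0, 0.5, 0.5, 0), 2, 2, dimnames = list(labs, labs))
  expect_error(sweepCutoffs(d, "Q2"), "no valid clustering")
})

test_that("single-linkage sweep properties: nestedness, monotone p,
           planted blocks", {
  set.seed(31)
  for (rep in 1:10) {
    d <- randomDistanceMatrix(9)
    cuts <- sort(runif(4, 0.01, 1.1))
    prev <- NULL
    prevP <- -1
    prevComp <- Inf
    for (co in cuts) {
      cl <- thresholdCluster(d, co)
      ncomp <- length(clusterMembers(cl)) + length(unclusteredLabels(cl))
      p <- sum(lengths(clusterMembers(cl))) / 9
      expect_gte(p, prevP)
      expect_lte(ncomp, prevComp)
      if (!is.null(prev)) {
        for (cc in clusterMembers(prev)) {
          holder <- vapply(clusterMembers(cl), function(big)
            all(cc %in% big), TRUE)
          expect_equal(sum(holder), 1)
        }
      }
      prev <- cl; prevP <- p; prevComp <- ncomp
    }
  }
  # k planted blocks: any cutoff in (a, b] recovers them with DI = b/a
  blocks <- list(paste0("u", 1:3), paste0("v", 1:3), paste0("w", 1:3))
  d <- blockMatrix(blocks, intra = 0.05)
  d[d > 0.05] <- 1.0   # uniform inter-block distance
  for (co in c(0.06, 0.5, 1.0)) {
    cl <- thresholdCluster(d, co)
    expect_equal(length(clusterMembers(cl)), 3)
    expect_equal(dunnIndex(d, cl)$DI, 1.0 / 0.05)
  }
})

test_that("clade assignment ranks clusters by distance to the reference", {
  # blocks at increasing distance from the block-1 reference
  blocks <- list(c("ref", "m1", "m2"), c("n1", "n2"), c("q1", "q2"))
  d <- blockMatrix(blocks)
  cl <- thresholdCluster(d, 0.06)
  asg <- assignClades(d, cl, "ref", family = "bcsA")
  expect_equal(unname(cladeOf(asg)[c("ref", "m1")]), c("1", "1"))
  expect_equal(unname(cladeOf(asg)["n1"]), "2")
  expect_equal(unname(cladeOf(asg)["q1"]), "3")

  # invariant to label order
  perm <- sample(rownames(d))
  asg2 <- assignClades(d[perm, perm], thresholdCluster(d[perm, perm], 0.06),
                       "ref", family = "bcsA")
  expect_identical(cladeOf(asg2)[names(cladeOf(asg))], cladeOf(asg))

  # unclustered labels get S-codes ordered by distance to the reference
  labs <- c("ref", "r2", "n1", "n2", "far", "near")
  dd <- matrix(5, 6, 6, dimnames = list(labs, labs))
  diag(dd) <- 0
  dd["ref", "r2"] <- dd["r2", "ref"] <- 0.05
  dd["n1", "n2"] <- dd["n2", "n1"] <- 0.05
  dd["ref", "n1"] <- dd["n1", "ref"] <- 1
  dd["ref", "n2"] <- dd["n2", "ref"] <- 1
  dd["ref", "near"] <- dd["near", "ref"] <- 2
  dd["ref", "far"] <- dd["far", "ref"] <- 4
  cl2 <- thresholdCluster(dd, 0.06)
  asg3 <- assignClades(dd, cl2, "ref")
  expect_equal(unname(cladeOf(asg3)[c("near", "far")]), c("S1", "S2"))

  expect_error(assignClades(d, cl, "absent"), "not in")
})

test_that("equal-distance clusters tie-break by size then first member", {
  labs <- c("ref", "r2", "b1", "b2", "b3", "a1", "a2")
  d <- matrix(0, 7, 7, dimnames = list(labs, labs))
  grp <- c(1, 1, 2, 2, 2, 3, 3)
  for (i in 1:7) for (j in 1:7)
    if (i != j) d[i, j] <- if (grp[i] == grp[j]) 0.05 else 1
  cl <- thresholdCluster(d, 0.06)
  asg <- assignClades(d, cl, "ref")
  # both non-reference clusters are at mean distance 1; the size-3 cluster
  # outranks the size-2 one
  expect_equal(unname(cladeOf(asg)["b1"]), "2")
  expect_equal(unname(cladeOf(asg)["a1"]), "3")
})

test_that("clade combinations render canonical, lost and divergent loci", {
  ref <- cannedReference()
  mkAsg <- function(fam, ownClade, nClades) {
    blocks <- lapply(seq_len(nClades), function(k)
      c(sprintf("%s_k%d_x", fam, k), sprintf("%s_k%d_y", fam, k)))
    blocks[[1]] <- c(paste0("ref_", fam), blocks[[1]])
    d <- blockMatrix(blocks)
    assignClades(d, thresholdCluster(d, 0.06), paste0("ref_", fam),
                 family = fam)
  }
  asg <- list(bcsA = mkAsg("bcsA", 1, 2), bcsB = mkAsg("bcsB", 3, 3),
              bcsZ = mkAsg("bcsZ", 5, 5), bcsC = mkAsg("bcsC", 3, 3))
  canonical <- mkOperon(list(
    hitRow("g1", "bcsA_k1_x", "bcsA", 1000, 2000),
    hitRow("g1", "bcsB_k1_x", "bcsB", 2100, 3000),
    hitRow("g1", "bcsZ_k1_x", "bcsZ", 3100, 4000),
    hitRow("g1", "bcsC_k1_x", "bcsC", 4100, 5000)))
  expect_equal(cladeCombination(canonical, asg, ref), "1:1:1:1")

  missingC <- mkOperon(list(
    hitRow("g1", "bcsA_k1_x", "bcsA", 1000, 2000),
    hitRow("g1", "bcsB_k1_x", "bcsB", 2100, 3000),
    hitRow("g1", "bcsZ_k1_x", "bcsZ", 3100, 4000)))
  expect_equal(cladeCombination(missingC, asg, ref), "1:1:1:-")

  divergent <- mkOperon(list(
    hitRow("g1", "bcsA_k1_x", "bcsA", 1000, 2000),
    hitRow("g1", "bcsB_k3_x", "bcsB", 2100, 3000),
    hitRow("g1", "bcsZ_k5_x", "bcsZ", 3100, 4000),
    hitRow("g1", "bcsC_k3_x", "bcsC", 4100, 5000)))
  expect_equal(cladeCombination(divergent, asg, ref), "1:3:5:3")
})
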