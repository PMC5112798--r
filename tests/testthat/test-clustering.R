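test_that("Hamming distance counts differing contacts", {
  universe <- sprintf("A:%d|B:1", 1:40)
  a <- fingerprint("a", universe[1:25])
  b <- fingerprint("b", universe[11:35])     # shares 15 of 25
  d <- hammingDistances(list(a, b))
  expect_equal(distanceValues(d), 20)
  expect_identical(distanceValues(
    hammingDistances(list(a, fingerprint("a2", universe[1:25])))), 0)
  dj <- hammingDistances(list(fingerprint("x", universe[1:7]),
                              fingerprint("y", universe[8:20])))
  expect_equal(distanceValues(dj), 7 + 13)
  expect_error(hammingDistances(list(a)), "two")
})

test_that("Hamming distances satisfy the metric axioms", {
  set.seed(13)
  for (rep in 1:10) {
    fps <- randomFingerprints(8)
    D <- ClustConsrank:::distanceMatrix(hammingDistances(fps))
    expect_true(isSymmetric(D))
    expect_true(all(diag(D) == 0))
    n <- nrow(D)
    triangleOk <- all(vapply(seq_len(n), function(k)
      all(D <= outer(D[, k], D[k, ], "+") + 1e-9), logical(1)))
    expect_true(triangleOk)
    # identity of indiscernibles on fingerprints
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
      if (D[i, j] == 0)
        expect_identical(contacts(fps[[i]]), contacts(fps[[j]]))
  }
})

test_that("three-point linkage follows the single/complete formulas", {
  d <- new("CondensedDistances", values = c(1, 5, 4),
           labels = c("p1", "p2", "p3"), metric = "contact_hamming")
  ts <- linkageTree(d, "single")
  expect_equal(mergeHeights(ts), c(1, 4))
  tc <- linkageTree(d, "complete")
  expect_equal(mergeHeights(tc), c(1, 5))
  # both first merge p1, p2
  expect_equal(sort(ts@merge[1, ]), c(-2L, -1L))
})

test_that("two models produce a single merge at their distance", {
  d <- new("CondensedDistances", values = 7, labels = c("a", "b"),
           metric = "contact_hamming")
  for (meth in c("single", "complete")) {
    tr <- linkageTree(d, meth)
    expect_equal(mergeHeights(tr), 7)
    expect_equal(tr@counts, 2L)
  }
})

test_that("linkage equals the naive agglomerative oracle on random instances", {
  set.seed(19)
  for (rep in 1:30) {
    n <- sample(4:25, 1)
    d <- randomDistances(n, integerValued = (rep %% 2 == 0))
    D <- ClustConsrank:::distanceMatrix(d)
    for (meth in c("single", "complete")) {
      tree <- linkageTree(d, meth)
      expect_equal(treeMergeSteps(tree), oracleLinkage(D, meth),
                   tolerance = 1e-9)
    }
  }
})

test_that("linkage heights match stats::hclust on tie-free distances", {
  set.seed(23)
  for (rep in 1:10) {
    n <- sample(5:30, 1)
    d <- randomDistances(n, integerValued = FALSE)
    for (meth in c("single", "complete")) {
      tree <- linkageTree(d, meth)
      hc <- stats::hclust(structure(distanceValues(d), Size = n,
                                    Labels = modelLabels(d), Diag = FALSE,
                                    Upper = FALSE, class = "dist"),
                          method = meth)
      expect_equal(mergeHeights(tree), hc$height)
      expect_equal(as.matrix(stats::cophenetic(asHclust(tree))),
                   as.matrix(stats::cophenetic(hc)))
    }
  }
})

test_that("distance cuts behave at the extremes", {
  d <- randomDistances(12)
  tree <- linkageTree(d, "complete")
  h <- mergeHeights(tree)
  below <- cutDistance(tree, min(h) / 2)
  expect_equal(nrow(clusterTable(below)), 12L)
  above <- cutDistance(tree, max(h))
  expect_equal(nrow(clusterTable(above)), 1L)
})

test_that("single-linkage distance cut equals threshold-graph components", {
  set.seed(29)
  for (rep in 1:15) {
    n <- sample(5:40, 1)
    d <- randomDistances(n)
    D <- ClustConsrank:::distanceMatrix(d)
    tree <- linkageTree(d, "single")
    for (t in c(2, 5, 9)) {
      part <- cutDistance(tree, t)
      expect_true(samePartition(unname(membership(part)),
                                componentsAtThreshold(D, t)))
    }
  }
})

test_that("maxclust matches an exhaustive scan over cut heights", {
  set.seed(37)
  for (rep in 1:15) {
    n <- sample(4:30, 1)
    d <- randomDistances(n)
    D <- ClustConsrank:::distanceMatrix(d)
    for (meth in c("single", "complete")) {
      tree <- linkageTree(d, meth)
      steps <- oracleLinkage(D, meth)
      h <- vapply(steps, `[[`, numeric(1), "height")
      for (t in unique(c(1, 2, sample.int(n, 2), n))) {
        part <- cutMaxclust(tree, t)
        got <- length(unique(membership(part)))
        # oracle: all prefixes achievable by a horizontal cut
        ks <- Filter(function(k) {
          if (k == n - 1) TRUE
          else if (k == 0) h[1] > 0
          else h[k + 1] > h[k]
        }, 0:(n - 1))
        counts <- n - ks
        bestCount <- max(counts[counts <= t])
        expect_equal(got, bestCount)
        expect_lte(got, t)
        # the partition itself matches the oracle's flat cut at that prefix
        kStar <- n - bestCount
        expect_true(samePartition(unname(membership(part)),
                                  oracleFlat(steps, n, kStar)))
      }
    }
  }
})

test_that("maxclust extremes: t = n gives singletons, t = 1 one cluster", {
  d <- randomDistances(9, integerValued = FALSE)  # distinct heights
  tree <- linkageTree(d, "complete")
  expect_equal(nrow(clusterTable(cutMaxclust(tree, 9))), 9L)
  expect_equal(nrow(clusterTable(cutMaxclust(tree, 1))), 1L)
  expect_error(cutMaxclust(tree, 0), ">= 1")
  # exactly t clusters whenever heights are distinct
  for (t in 2:8)
    expect_equal(nrow(clusterTable(cutMaxclust(tree, t))), t)
})

test_that("clusters are ranked by population with stated tie-breaks", {
  u <- sprintf("A:%d|B:%d", rep(1:20, 4), rep(1:4, each = 20))
  fps <- list(
    # cluster 1 ("z"): population 4
    fingerprint("z1", u[1:5]), fingerprint("z2", u[1:5]),
    fingerprint("z3", u[1:5]), fingerprint("z4", u[1:5]),
    # cluster 2 ("x"): population 3, identical members -> best score 1
    fingerprint("x1", u[11:15]), fingerprint("x2", u[11:15]),
    fingerprint("x3", u[11:15]),
    # cluster 3 ("w"): population 3, one deviant -> best score 2/3 < 1
    fingerprint("w1", u[21:23]), fingerprint("w2", u[21:23]),
    fingerprint("w3", u[31:33]),
    # two singletons: tie broken by model id (v < y after score tie at 1)
    fingerprint("y1", u[41:42]), fingerprint("v1", u[51:52]))
  mem <- setNames(c(1L, 1L, 1L, 1L, 2L, 2L, 2L, 3L, 3L, 3L, 4L, 5L),
                  vapply(fps, modelId, character(1)))
  sizes <- table(mem)
  part <- new("ClusterPartition", membership = mem,
              clusters = data.frame(cluster = as.integer(names(sizes)),
                                    rank = NA_integer_,
                                    size = as.integer(sizes)),
              criterion = "manual")
  ranked <- clusterTable(rankClusters(part, fps))
  expect_equal(ranked$size, c(4L, 3L, 3L, 1L, 1L))
  # population tie between x and w broken by best local score (x wins)
  expect_equal(ranked$cluster[2:3], c(2L, 3L))
  # singleton tie (both scores 1) broken by lowest member model id: v1 < y1
  expect_equal(ranked$cluster[4:5], c(5L, 4L))
})

test_that("renaming the models does not change ranked populations", {
  set.seed(43)
  fps <- randomFingerprints(20)
  renamed <- lapply(fps, function(fp)
    fingerprint(paste0("zz_", modelId(fp)), contacts(fp)))
  part1 <- clusterEnsemble(fps, preset = "MC/10")
  part2 <- clusterEnsemble(renamed, preset = "MC/10")
  expect_equal(clusterTable(part1)$size, clusterTable(part2)$size)
  expect_equal(sort(unname(table(membership(part1)))),
               sort(unname(table(membership(part2)))))
})

test_that("ligand-RMSD distances: identity, rigid motion, pure translation", {
  native <- makeNative(complexSpec(receptorLength = 30, ligandLength = 15,
                                   axisSeparation = 9, seed = 5))
  same <- initialize(native, modelId = "copy")
  rot <- transformModel(native, angle = 0.9, shift = c(4, 4, -1), id = "rot")
  a <- atoms(native)
  a$x[a$chain == "B"] <- a$x[a$chain == "B"] + 3
  trans <- new("StructureModel", modelId = "trans", atoms = a,
               partnerOf = partnerMap(native))
  d <- ligandRmsdDistances(list(native, same, rot, trans))
  expect_equal(distanceMetric(d), "ligand_rmsd")
  D <- ClustConsrank:::distanceMatrix(d)
  expect_equal(D["native", "copy"], 0, tolerance = 1e-8)
  expect_equal(D["native", "rot"], 0, tolerance = 1e-6)
  expect_equal(D["native", "trans"], 3, tolerance = 1e-6)
  # cross-check a non-trivial pair against the quaternion oracle
  expect_equal(D["rot", "trans"], oracleLigandRmsd(trans, rot),
               tolerance = 1e-6)
})

test_that("presets resolve to the tested configurations", {
  expect_equal(resolvePreset("S25", 100),
               list(method = "single", criterion = "distance",
                    threshold = 25, label = "S25"))
  expect_equal(resolvePreset("C80", 100)$threshold, 80)
  expect_equal(resolvePreset("MC200", 2000)$threshold, 200L)
  expect_equal(resolvePreset("MC200", 150)$threshold, 150L)
  expect_equal(resolvePreset("MC/5", 600)$threshold, 120L)
  expect_equal(resolvePreset("MC/10", 600)$threshold, 60L)
  expect_equal(resolvePreset("MC/10", 45)$threshold, 10L)  # floor of 10
  expect_error(resolvePreset("MC/3", 100), "valid presets")
})

test_that("negative or NaN distances are rejected by linkage", {
  bad <- new("CondensedDistances", values = c(1, 2, 3),
             labels = c("a", "b", "c"), metric = "contact_hamming")
  bad@values[2] <- NaN
  expect_error(linkageTree(bad, "single"), "finite")
})
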