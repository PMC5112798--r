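test_that("ten mutually distant models select as ten singleton champions", {
  u <- sprintf("A:%d|B:%d", rep(1:20, 10), rep(1:10, each = 20))
  fps <- lapply(1:10, function(i)
    fingerprint(sprintf("s%02d", i), u[(20 * (i - 1) + 1):(20 * i - 10)]))
  sel <- clustConsrankSelect(fps, preset = NULL, method = "complete",
                             criterion = "maxclust", threshold = 10)
  df <- selectedModels(sel)
  expect_equal(nrow(df), 10L)
  expect_setequal(df$model_id, vapply(fps, modelId, character(1)))
  expect_true(all(df$cluster_size == 1L))
  expect_equal(df$cluster_rank, 1:10)
})

test_that("fewer clusters than the limit triggers round-robin filling", {
  u <- sprintf("A:%d|B:%d", rep(1:30, 3), rep(1:3, each = 30))
  fam <- function(prefix, n, keys) lapply(seq_len(n), function(i)
    fingerprint(sprintf("%s%d", prefix, i), keys))
  fps <- c(fam("a", 3, u[1:20]), fam("b", 3, u[31:50]), fam("c", 2, u[61:80]))
  sel <- clustConsrankSelect(fps, preset = NULL, method = "complete",
                             criterion = "maxclust", threshold = 3)
  df <- selectedModels(sel)
  expect_equal(nrow(df), 8L)                      # pool exhausted below 10
  expect_setequal(df$model_id, vapply(fps, modelId, character(1)))
  # champions first (cluster ranks 1..3), then depth-2 round robin, etc.
  expect_equal(df$within_cluster_rank[1:3], c(1L, 1L, 1L))
  expect_equal(df$cluster_rank[1:3], 1:3)
  expect_equal(df$within_cluster_rank[4:6], c(2L, 2L, 2L))
  expect_equal(df$cluster_rank[4:6], 1:3)
})

test_that("a 12-model planted ensemble reproduces a hand-executed trace", {
  # 3 planted pose families as fingerprints; trace the whole pipeline with
  # the independent oracles: linkage -> maxclust cut -> population ranking
  # -> per-cluster naive consensus -> champion per cluster.
  u <- sprintf("A:%d|B:%d", rep(1:30, 3), rep(1:3, each = 30))
  fps <- list(
    fingerprint("f01", u[c(1:8)]),   fingerprint("f02", u[c(1:7, 9)]),
    fingerprint("f03", u[c(1:6, 9:10)]), fingerprint("f04", u[c(1:8)]),
    fingerprint("f05", u[c(1:5, 11:13)]),
    fingerprint("g01", u[31:40]), fingerprint("g02", u[c(31:38, 41:42)]),
    fingerprint("g03", u[31:40]), fingerprint("g04", u[c(31:39, 43)]),
    fingerprint("h01", u[61:75]), fingerprint("h02", u[c(61:74, 76)]),
    fingerprint("h03", u[c(61:73, 77:78)]))
  ids <- vapply(fps, modelId, character(1))
  sets <- setNames(lapply(fps, contacts), ids)

  t <- 3L
  sel <- clustConsrankSelect(fps, preset = NULL, method = "complete",
                             criterion = "maxclust", threshold = t,
                             limit = 3L)

  # oracle trace
  D <- ClustConsrank:::distanceMatrix(hammingDistances(fps))
  steps <- oracleLinkage(D, "complete")
  h <- vapply(steps, `[[`, numeric(1), "height")
  n <- length(fps)
  ks <- Filter(function(k) k == n - 1 || (k == 0 && h[1] > 0) ||
                 (k > 0 && h[k + 1] > h[k]), 0:(n - 1))
  kStar <- n - max((n - ks)[(n - ks) <= t])
  flat <- oracleFlat(steps, n, kStar)
  champions <- character(0)
  pops <- sort(table(flat), decreasing = TRUE)
  for (cid in names(pops)[1:min(3, length(pops))]) {
    members <- ids[flat == as.integer(cid)]
    champions <- c(champions, oracleConsrank(sets[members])$model_id[1])
  }
  expect_equal(selectedModels(sel)$model_id, champions)
})

test_that("each champion maximizes the cluster-local consensus score", {
  sim <- smallScenario(seed = 21, nModels = 80)
  fps <- ensembleFingerprints(sim$ensemble)
  sel <- clustConsrankSelect(fps, preset = "MC/10")
  part <- clusterEnsemble(fps, preset = "MC/10")
  mem <- membership(part)
  cl <- clusterTable(part)
  fpOf <- setNames(fps, vapply(fps, modelId, character(1)))
  df <- selectedModels(sel)
  for (r in which(df$within_cluster_rank == 1)) {
    cid <- cl$cluster[cl$rank == df$cluster_rank[r]]
    members <- names(mem)[mem == cid]
    local <- rankEnsemble(fpOf[members])
    expect_equal(df$model_id[r], local$model_id[1])
    expect_equal(df$score[r], local$score[1])
  }
  expect_lte(nrow(df), 10L)
  expect_false(anyDuplicated(df$model_id) > 0)
  expect_true(all(df$model_id %in% names(mem)))
})

test_that("with one all-encompassing cluster the first pick is plain CONSRANK's", {
  set.seed(55)
  fps <- randomFingerprints(15)
  sel <- clustConsrankSelect(fps, preset = NULL, method = "complete",
                             criterion = "maxclust", threshold = 1)
  plain <- rankEnsemble(fps)
  expect_equal(selectedModels(sel)$model_id[1], plain$model_id[1])
})

test_that("redundancy removal with no redundant pairs is plain top-10", {
  u <- sprintf("A:%d|B:%d", rep(1:40, 10), rep(1:10, each = 40))
  fps <- lapply(1:12, function(i)
    fingerprint(sprintf("m%02d", i), u[(30 * (i - 1) + 1):(30 * (i - 1) + 20)]))
  sel <- redundancySelect(fps, threshold = 25)
  expect_equal(selectedModels(sel)$model_id,
               topModels(rankEnsemble(fps), 10))
})

test_that("total redundancy collapses the selection to one model", {
  keys <- sprintf("A:%d|B:1", 1:20)
  fps <- lapply(1:6, function(i) fingerprint(sprintf("m%d", i), keys))
  sel <- redundancySelect(fps, threshold = 25)
  expect_equal(nrow(selectedModels(sel)), 1L)
  expect_equal(selectedModels(sel)$model_id, "m1")
})

test_that("redundancy removal equals the independent greedy oracle", {
  set.seed(67)
  for (rep in 1:30) {
    fps <- randomFingerprints(sample(5:20, 1))
    sets <- setNames(lapply(fps, contacts),
                     vapply(fps, modelId, character(1)))
    thr <- sample(c(2, 5, 10, 25), 1)
    got <- selectedModels(redundancySelect(fps, threshold = thr))$model_id
    expect_equal(got, oracleRedundancy(sets, thr))
  }
})

test_that("empty ensembles are rejected by both selectors", {
  expect_error(clustConsrankSelect(list()), "empty")
  expect_error(redundancySelect(list(), 25), "empty")
})
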