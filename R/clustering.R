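#' @include AllClasses.R contacts.R
NULL

#' Contact Hamming distances between all model pairs
#'
#' The distance between two models is the absolute number of inter-residue
#' contacts by which they differ (the cardinality of the symmetric
#' difference of their contact sets): two 25-contact models sharing 15
#' contacts are at distance 20. Values are returned in canonical condensed
#' order (pair (i, j), i < j, ordered by i then j).
#'
#' @param fingerprints list of >= 2 [ContactFingerprint-class] objects with
#'   harmonized residue keys.
#' @return a [CondensedDistances-class] with metric
#'   \code{"contact_hamming"}.
#' @examples
#' a <- fingerprint("a", paste0("r", 1:25, "|l1"))
#' b <- fingerprint("b", paste0("r", 11:35, "|l1"))
#' distanceValues(hammingDistances(list(a, b)))  # 20
#' @export
hammingDistances <- function(fingerprints) {
  n <- length(fingerprints)
  if (n < 2L) stop("need at least two fingerprints", call. = FALSE)
  M <- incidenceMatrix(fingerprints)
  common <- tcrossprod(M * 1)
  sizes <- diag(common)
  D <- outer(sizes, sizes, "+") - 2 * common
  # column-major lower triangle == canonical condensed order (i, then j)
  new("CondensedDistances", values = as.numeric(D[lower.tri(D)]),
      labels = rownames(M), metric = "contact_hamming")
}

#' Ligand-RMSD distances between all model pairs
#'
#' For each pair, the receptor backbones (N, CA, C, O) are optimally
#' superimposed (least-squares/Kabsch) and the RMSD is computed over the
#' ligand backbone atoms -- the distance variant of the clustering step.
#'
#' @param models list of >= 2 [StructureModel-class] objects (harmonized).
#' @return a [CondensedDistances-class] with metric \code{"ligand_rmsd"}.
#' @export
ligandRmsdDistances <- function(models) {
  n <- length(models)
  if (n < 2L) stop("need at least two models", call. = FALSE)
  vals <- numeric(n * (n - 1) / 2)
  k <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      k <- k + 1L
      vals[k] <- ligandRmsd(models[[j]], models[[i]])
    }
  }
  new("CondensedDistances", values = vals,
      labels = vapply(models, modelId, character(1)),
      metric = "ligand_rmsd")
}

#' Agglomerative hierarchical clustering (single or complete linkage)
#'
#' Repeatedly merges the two closest clusters, with the inter-cluster
#' distance being the minimum (single linkage, nearest point) or maximum
#' (complete linkage, farthest point) distance over member pairs. Ties are
#' broken deterministically by the lowest canonical condensed pair index,
#' clusters being keyed by their smallest original member, so results are
#' reproducible and oracle-testable.
#'
#' @param dist a [CondensedDistances-class].
#' @param method \code{"single"} or \code{"complete"}.
#' @return a [LinkageTree-class].
#' @export
linkageTree <- function(dist, method = c("single", "complete")) {
  method <- match.arg(method)
  vals <- distanceValues(dist)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("distances must be finite and non-negative", call. = FALSE)
  n <- length(modelLabels(dist))
  if (n < 2L) stop("need at least two models", call. = FALSE)
  W <- distanceMatrix(dist)
  W[lower.tri(W, diag = TRUE)] <- Inf    # only pairs i < j are scanned
  comb <- if (method == "single") pmin else pmax
  node <- integer(n)                     # 0 = still a singleton
  size <- rep(1L, n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  counts <- integer(n - 1L)
  tvec <- seq_len(n)
  for (k in seq_len(n - 1L)) {
    m <- min(W)
    pos <- which(W == m)
    pi <- (pos - 1L) %% n + 1L
    pj <- (pos - 1L) %/% n + 1L
    best <- order(pi, pj)[1L]            # lowest condensed index on ties
    i <- pi[best]; j <- pj[best]
    height[k] <- m
    counts[k] <- size[i] + size[j]
    a <- if (node[i] == 0L) -i else node[i]
    b <- if (node[j] == 0L) -j else node[j]
    merge[k, ] <- if ((a < 0 && b < 0 && a > b) || (a > 0 && b > 0 && a > b) ||
                      (a > 0 && b < 0)) c(b, a) else c(a, b)
    # Lance-Williams update of cluster i against every other cluster t
    dti <- ifelse(tvec < i, W[cbind(tvec, i)], W[cbind(i, tvec)])
    dtj <- ifelse(tvec < j, W[cbind(tvec, j)], W[cbind(j, tvec)])
    dnew <- comb(dti, dtj)
    lo <- which(tvec < i)
    if (length(lo)) W[cbind(lo, i)] <- dnew[lo]
    hi <- which(tvec > i & tvec != j)
    if (length(hi)) W[cbind(i, hi)] <- dnew[hi]
    W[i, i] <- Inf
    W[j, ] <- Inf
    W[, j] <- Inf
    size[i] <- size[i] + size[j]
    node[i] <- k
  }
  new("LinkageTree", merge = merge, height = height, counts = counts,
      labels = modelLabels(dist), method = method)
}

#' Convert a LinkageTree to an hclust object
#'
#' Allows plotting and interoperation with the standard stats machinery
#' (e.g. \code{cutree}, \code{cophenetic}).
#'
#' @param tree a [LinkageTree-class].
#' @return an object of class \code{hclust}.
#' @export
asHclust <- function(tree) {
  n <- length(tree@labels)
  # leaf order by depth-first traversal
  ord <- integer(0)
  walk <- function(node) {
    if (node < 0) return(-node)
    c(walk(tree@merge[node, 1]), walk(tree@merge[node, 2]))
  }
  structure(list(merge = tree@merge, height = tree@height,
                 order = walk(n - 1L), labels = tree@labels,
                 method = tree@method, call = match.call(),
                 dist.method = "precomputed"),
            class = "hclust")
}

# Partition obtained by applying the first k merges of the tree.
partitionFromPrefix <- function(tree, k, criterion) {
  n <- length(tree@labels)
  labels <- seq_len(n)
  repOfRow <- integer(max(n - 1L, 1L))
  for (r in seq_len(n - 1L)) {
    a <- tree@merge[r, 1]; b <- tree@merge[r, 2]
    ra <- if (a < 0) -a else repOfRow[a]
    rb <- if (b < 0) -b else repOfRow[b]
    repOfRow[r] <- min(ra, rb)
    if (r <= k) labels[labels == labels[rb]] <- labels[ra]
  }
  # consecutive labels in order of first member
  lab <- match(labels, unique(labels))
  names(lab) <- tree@labels
  sizes <- table(lab)
  clusters <- data.frame(cluster = as.integer(names(sizes)),
                         rank = NA_integer_,
                         size = as.integer(sizes))
  new("ClusterPartition", membership = lab, clusters = clusters,
      criterion = criterion)
}

#' Flat clusters by distance threshold
#'
#' Cuts the tree so that merges up to height \code{t} (inclusive) are
#' applied: every within-cluster cophenetic distance is at most \code{t}.
#' For single linkage this equals the connected components of the graph
#' joining models at distance <= t. Thresholds used for contact Hamming
#' distances in practice: 25 and 30 (single), 40, 50, 60 and 80 (complete).
#'
#' @param tree a [LinkageTree-class].
#' @param t distance threshold, > 0.
#' @return an (unranked) [ClusterPartition-class]; see [rankClusters()].
#' @export
cutDistance <- function(tree, t) {
  stopifnot(t > 0)
  k <- sum(tree@height <= t)
  partitionFromPrefix(tree, k, sprintf("distance t=%g", t))
}

#' Flat clusters by maximum cluster count (maxclust)
#'
#' Finds the smallest cut height at which at most \code{t} flat clusters are
#' formed; among the cluster counts <= \code{t} achievable by a horizontal
#' cut, the largest is returned. With distinct merge heights this yields
#' exactly \code{t} clusters for any 1 <= t <= n.
#'
#' @param tree a [LinkageTree-class].
#' @param t maximum number of clusters, 1 <= t <= n.
#' @return an (unranked) [ClusterPartition-class].
#' @export
cutMaxclust <- function(tree, t) {
  n <- length(tree@labels)
  if (t < 1L) stop("t must be >= 1", call. = FALSE)
  t <- min(t, n)
  h <- tree@height
  # prefix k (number of merges applied) is achievable by a horizontal cut
  # iff no merge is split off from equal-height merges
  achievable <- function(k) {
    if (k == n - 1L) return(TRUE)
    if (k == 0L) return(h[1] > 0)
    h[k + 1L] > h[k]
  }
  for (k in 0:(n - 1L)) {
    if (n - k <= t && achievable(k))
      return(partitionFromPrefix(tree, k, sprintf("maxclust t=%d", t)))
  }
  partitionFromPrefix(tree, n - 1L, sprintf("maxclust t=%d", t))
}

#' Rank clusters by population
#'
#' Orders clusters by decreasing population. Ties are broken by the better
#' best-within-cluster CONSRANK score (computed on each cluster's own
#' conservation profile) when fingerprints are supplied, then by the
#' lexicographically smallest member model id.
#'
#' @param partition a [ClusterPartition-class].
#' @param fingerprints optional list of [ContactFingerprint-class] covering
#'   the partition's models, used for the score tie-break.
#' @return the partition with its cluster table ranked (rank 1 = most
#'   populated).
#' @export
rankClusters <- function(partition, fingerprints = NULL) {
  mem <- membership(partition)
  cl <- clusterTable(partition)
  fpOf <- NULL
  if (!is.null(fingerprints)) {
    fpOf <- setNames(fingerprints,
                     vapply(fingerprints, modelId, character(1)))
  }
  bestScore <- rep(0, nrow(cl))
  bestMember <- character(nrow(cl))
  for (r in seq_len(nrow(cl))) {
    ids <- names(mem)[mem == cl$cluster[r]]
    bestMember[r] <- min(ids)
    if (!is.null(fpOf)) {
      rk <- rankEnsemble(fpOf[ids])
      bestScore[r] <- rk$score[1]
    }
  }
  ord <- order(-cl$size, -bestScore, bestMember)
  cl <- cl[ord, , drop = FALSE]
  cl$rank <- seq_len(nrow(cl))
  rownames(cl) <- NULL
  initialize(partition, clusters = cl)
}

#' Clustering presets
#'
#' The named clustering configurations explored for docking-model
#' ensembles: \code{S25}, \code{S30} (single linkage, distance cut at 25 and
#' 30 differing contacts), \code{C40}, \code{C50}, \code{C60}, \code{C80}
#' (complete linkage, distance cut), \code{MC200} (complete linkage,
#' maxclust at 200 clusters), and the size-relative \code{MC/5} and
#' \code{MC/10} (maxclust at 1/5 and 1/10 of the number of models, floored,
#' with a minimum of 10 so that 10 clusters remain selectable).
#'
#' @param preset preset name (see above).
#' @param n number of models in the ensemble (needed by the maxclust
#'   presets).
#' @return list with \code{method}, \code{criterion}, \code{threshold} and
#'   \code{label}.
#' @export
resolvePreset <- function(preset, n) {
  presets <- clusterPresets()
  if (!preset %in% presets)
    stop("unknown preset '", preset, "'; valid presets: ",
         paste(presets, collapse = ", "), call. = FALSE)
  cfg <- switch(preset,
    "S25" = list(method = "single", criterion = "distance", threshold = 25),
    "S30" = list(method = "single", criterion = "distance", threshold = 30),
    "C40" = list(method = "complete", criterion = "distance", threshold = 40),
    "C50" = list(method = "complete", criterion = "distance", threshold = 50),
    "C60" = list(method = "complete", criterion = "distance", threshold = 60),
    "C80" = list(method = "complete", criterion = "distance", threshold = 80),
    "MC200" = list(method = "complete", criterion = "maxclust",
                   threshold = min(200L, n)),
    "MC/5" = list(method = "complete", criterion = "maxclust",
                  threshold = max(10L, n %/% 5L)),
    "MC/10" = list(method = "complete", criterion = "maxclust",
                   threshold = max(10L, n %/% 10L)))
  cfg$label <- preset
  cfg
}

#' @rdname resolvePreset
#' @export
clusterPresets <- function() {
  c("S25", "S30", "C40", "C50", "C60", "C80", "MC200", "MC/5", "MC/10")
}

#' Cluster an ensemble of fingerprints (or a distance object) in one call
#'
#' Convenience wrapper: computes contact Hamming distances (unless a
#' [CondensedDistances-class] is supplied), builds the linkage tree, cuts it
#' by the requested criterion and ranks the clusters by population.
#'
#' @param fingerprints list of [ContactFingerprint-class], used for the
#'   distances (when \code{dist} is NULL) and for cluster-ranking
#'   tie-breaks.
#' @param method linkage method, \code{"single"} or \code{"complete"}.
#' @param criterion \code{"distance"} or \code{"maxclust"}.
#' @param threshold the distance threshold or maximum cluster count.
#' @param preset optional preset name overriding method/criterion/threshold
#'   (see [resolvePreset()]).
#' @param dist optional precomputed [CondensedDistances-class] (e.g. the
#'   ligand-RMSD variant from [ligandRmsdDistances()]).
#' @return a ranked [ClusterPartition-class].
#' @export
clusterEnsemble <- function(fingerprints, method = "complete",
                            criterion = "maxclust", threshold = NULL,
                            preset = NULL, dist = NULL) {
  n <- if (is.null(dist)) length(fingerprints) else length(modelLabels(dist))
  if (!is.null(preset)) {
    cfg <- resolvePreset(preset, n)
  } else {
    if (is.null(threshold)) stop("supply a threshold or a preset",
                                 call. = FALSE)
    cfg <- list(method = method, criterion = criterion,
                threshold = threshold)
  }
  if (is.null(dist)) dist <- hammingDistances(fingerprints)
  tree <- linkageTree(dist, cfg$method)
  part <- if (cfg$criterion == "distance") cutDistance(tree, cfg$threshold)
          else cutMaxclust(tree, cfg$threshold)
  rankClusters(part, fingerprints)
}

#' Write a cluster partition to TSV
#'
#' @param partition a ranked [ClusterPartition-class].
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writePartition <- function(partition, path) {
  mem <- membership(partition)
  cl <- clusterTable(partition)
  idx <- match(mem, cl$cluster)
  df <- data.frame(model_id = names(mem), cluster_label = unname(mem),
                   cluster_rank = cl$rank[idx], cluster_size = cl$size[idx])
  df <- df[order(df$cluster_rank, df$model_id), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
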