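#' @include AllClasses.R clustering.R consrank.R
NULL

#' Clust-CONSRANK model selection
#'
#' The clustering-then-consensus selection: models are clustered (contact
#' Hamming distances by default), clusters are ranked by population, and for
#' each of the top \code{limit} clusters CONSRANK is run on that cluster's
#' members alone -- the conservation profile is recomputed from the cluster
#' -- and the cluster's top-ranked model is selected. If fewer clusters than
#' \code{limit} exist, remaining slots are filled round-robin with the
#' next-best unselected members of the clusters in rank order.
#'
#' @param fingerprints list of [ContactFingerprint-class] (harmonized keys).
#' @param preset clustering preset name (default \code{"MC/10"}, the best
#'   performing configuration); see [resolvePreset()].
#' @param method,criterion,threshold explicit clustering configuration used
#'   when \code{preset} is NULL; see [clusterEnsemble()].
#' @param dist optional precomputed [CondensedDistances-class] to cluster on
#'   (e.g. ligand RMSD); scoring always uses the contact fingerprints.
#' @param limit maximum number of selected models; default 10 (the CAPRI
#'   submission limit).
#' @return a [SelectionResult-class]; provenance columns record each pick's
#'   cluster rank, cluster size and within-cluster rank.
#' @export
clustConsrankSelect <- function(fingerprints, preset = "MC/10",
                                method = "complete", criterion = "maxclust",
                                threshold = NULL, dist = NULL, limit = 10L) {
  if (!length(fingerprints)) stop("empty ensemble", call. = FALSE)
  part <- clusterEnsemble(fingerprints, method = method,
                          criterion = criterion, threshold = threshold,
                          preset = preset, dist = dist)
  mem <- membership(part)
  cl <- clusterTable(part)
  fpOf <- setNames(fingerprints,
                   vapply(fingerprints, modelId, character(1)))
  topCl <- cl[cl$rank <= min(limit, nrow(cl)), , drop = FALSE]
  # within-cluster CONSRANK rankings, profile local to each cluster
  rankings <- lapply(seq_len(nrow(topCl)), function(r) {
    ids <- names(mem)[mem == topCl$cluster[r]]
    rankEnsemble(fpOf[ids])
  })
  rows <- list()
  for (r in seq_len(nrow(topCl))) {
    rk <- rankings[[r]]
    rows[[length(rows) + 1L]] <-
      data.frame(model_id = rk$model_id[1], score = rk$score[1],
                 cluster_rank = topCl$rank[r], cluster_size = topCl$size[r],
                 within_cluster_rank = 1L)
  }
  # round-robin fill from clusters' next-best members when < limit clusters
  depth <- 2L
  while (length(rows) < limit) {
    added <- FALSE
    for (r in seq_len(nrow(topCl))) {
      if (length(rows) >= limit) break
      rk <- rankings[[r]]
      if (nrow(rk) >= depth) {
        rows[[length(rows) + 1L]] <-
          data.frame(model_id = rk$model_id[depth], score = rk$score[depth],
                     cluster_rank = topCl$rank[r],
                     cluster_size = topCl$size[r],
                     within_cluster_rank = depth)
        added <- TRUE
      }
    }
    if (!added) break                    # every cluster exhausted
    depth <- depth + 1L
  }
  sel <- do.call(rbind, rows)
  sel <- data.frame(slot = seq_len(nrow(sel)), sel, row.names = NULL)
  new("SelectionResult", selected = sel,
      method = paste0("clust-consrank ",
                      if (!is.null(preset)) preset else cutCriterion(part)))
}

#' Redundancy-removal baseline selection
#'
#' The non-clustering baseline: models are ranked by plain CONSRANK over the
#' whole ensemble; the best remaining model is accepted and every model
#' within \code{threshold} contact Hamming distance of it is discarded,
#' repeating until \code{limit} models are accepted or the pool is
#' exhausted. Thresholds from 25 to 80 differing contacts are the presets
#' explored in practice.
#'
#' @param fingerprints list of [ContactFingerprint-class].
#' @param threshold Hamming distance at or below which a model is redundant
#'   with an accepted one.
#' @param limit maximum selections; default 10.
#' @return a [SelectionResult-class] with \code{global_rank} provenance.
#' @export
redundancySelect <- function(fingerprints, threshold, limit = 10L) {
  if (!length(fingerprints)) stop("empty ensemble", call. = FALSE)
  stopifnot(threshold >= 0)
  ranking <- rankEnsemble(fingerprints)
  if (length(fingerprints) == 1L) {
    sel <- data.frame(slot = 1L, model_id = ranking$model_id,
                      score = ranking$score, global_rank = 1L)
    return(new("SelectionResult", selected = sel,
               method = sprintf("redundancy t=%g", threshold)))
  }
  D <- distanceMatrix(hammingDistances(fingerprints))
  alive <- setNames(rep(TRUE, nrow(ranking)), ranking$model_id)
  rows <- list()
  for (r in seq_len(nrow(ranking))) {
    id <- ranking$model_id[r]
    if (!alive[[id]]) next
    rows[[length(rows) + 1L]] <-
      data.frame(model_id = id, score = ranking$score[r], global_rank = r)
    alive[names(which(D[id, ] <= threshold))] <- FALSE
    alive[[id]] <- FALSE
    if (length(rows) >= limit) break
  }
  sel <- do.call(rbind, rows)
  sel <- data.frame(slot = seq_len(nrow(sel)), sel, row.names = NULL)
  new("SelectionResult", selected = sel,
      method = sprintf("redundancy t=%g", threshold))
}

#' Plain CONSRANK top-10 selection
#'
#' The unclustered reference selection: the \code{limit} top-ranked models
#' of the whole-ensemble CONSRANK ranking.
#'
#' @param fingerprints list of [ContactFingerprint-class].
#' @param limit maximum selections; default 10.
#' @return a [SelectionResult-class].
#' @export
consrankSelect <- function(fingerprints, limit = 10L) {
  if (!length(fingerprints)) stop("empty ensemble", call. = FALSE)
  ranking <- rankEnsemble(fingerprints)
  keep <- utils::head(ranking, limit)
  sel <- data.frame(slot = seq_len(nrow(keep)), model_id = keep$model_id,
                    score = keep$score, global_rank = keep$rank)
  new("SelectionResult", selected = sel, method = "consrank top-10")
}

#' Write a selection to TSV
#'
#' @param selection a [SelectionResult-class].
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeSelection <- function(selection, path) {
  utils::write.table(selectedModels(selection), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
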