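#' @import methods
NULL

#' StructureModel: one docking model of a binary complex
#'
#' Holds the ATOM records of a single 3D model of a two-partner protein
#' complex, together with the receptor/ligand assignment of its chains.
#' The receptor is, by convention, the larger interactor.
#'
#' @slot modelId character(1), identifier of the model (usually the file
#'   basename without extension).
#' @slot atoms data.frame with one row per atom and columns \code{chain},
#'   \code{resno} (integer), \code{insert} (character, \code{""} if none),
#'   \code{resid} (3-letter residue code), \code{elety} (atom name),
#'   \code{elesy} (element symbol), \code{isHeavy} (logical; FALSE for H/D),
#'   \code{x}, \code{y}, \code{z} (Angstrom).
#' @slot partnerOf named character vector mapping each chain id to
#'   \code{"receptor"} or \code{"ligand"}.
#'
#' @seealso [readModel()], [assignPartners()], [contactFingerprint()]
#' @export
setClass("StructureModel",
  representation(modelId = "character", atoms = "data.frame",
                 partnerOf = "character"),
  validity = function(object) {
    msg <- character()
    need <- c("chain", "resno", "insert", "resid", "elety", "elesy",
              "isHeavy", "x", "y", "z")
    if (!all(need %in% names(object@atoms)))
      msg <- c(msg, paste("atoms must have columns:",
                          paste(need, collapse = ", ")))
    else {
      xyz <- as.matrix(object@atoms[, c("x", "y", "z")])
      if (nrow(xyz) && !all(is.finite(xyz)))
        msg <- c(msg, "atom positions must be finite")
      bad <- object@atoms$isHeavy == (object@atoms$elesy %in% c("H", "D"))
      if (any(bad))
        msg <- c(msg, "isHeavy must be FALSE exactly for H/D atoms")
    }
    if (length(object@partnerOf)) {
      if (!all(object@partnerOf %in% c("receptor", "ligand")))
        msg <- c(msg, "partnerOf values must be 'receptor' or 'ligand'")
      if (!all(unique(object@atoms$chain) %in% names(object@partnerOf)))
        msg <- c(msg, "every chain must appear in partnerOf")
    }
    if (length(msg)) msg else TRUE
  })

#' ModelEnsemble: a set of docking models of the same complex
#'
#' @slot models list of [StructureModel-class] objects.
#' @slot harmonized logical(1); TRUE after [harmonizeNumbering()] has made
#'   residue keys comparable across models.
#' @export
setClass("ModelEnsemble",
  representation(models = "list", harmonized = "logical"),
  prototype(harmonized = FALSE),
  validity = function(object) {
    if (!all(vapply(object@models, is, logical(1), "StructureModel")))
      return("all elements of 'models' must be StructureModel objects")
    ids <- vapply(object@models, function(m) m@modelId, character(1))
    if (anyDuplicated(ids)) return("model ids must be unique")
    TRUE
  })

#' ContactFingerprint: the intermolecular contacts of one model
#'
#' A contact is an (ordered) receptor-residue/ligand-residue pair with any
#' two heavy atoms within the cutoff (default 5 Angstrom). Contacts are
#' encoded as strings \code{"<receptor key>|<ligand key>"} where a residue
#' key is \code{"chain:resno"} (plus insertion code if present).
#'
#' @slot modelId character(1).
#' @slot contacts character vector of unique, sorted contact keys; may be
#'   empty for a non-touching pose.
#' @export
setClass("ContactFingerprint",
  representation(modelId = "character", contacts = "character"),
  validity = function(object) {
    if (anyDuplicated(object@contacts)) return("duplicate contact keys")
    if (is.unsorted(object@contacts)) return("contacts must be sorted")
    TRUE
  })

#' ConservationProfile: per-contact frequency over an ensemble
#'
#' The consensus-map values: for every contact observed in at least one
#' model, the fraction of models that contain it.
#'
#' @slot frequency named numeric vector in (0, 1]; names are contact keys in
#'   universe order (model order of first appearance, contacts sorted
#'   within each model).
#' @slot ensembleSize integer(1), number of fingerprints the profile was
#'   built from.
#' @export
setClass("ConservationProfile",
  representation(frequency = "numeric", ensembleSize = "integer"),
  validity = function(object) {
    f <- object@frequency
    if (length(f) && (is.null(names(f)) || anyDuplicated(names(f))))
      return("frequency must be uniquely named by contact key")
    if (length(f) && (any(f <= 0) || any(f > 1)))
      return("frequencies must lie in (0, 1]")
    if (object@ensembleSize < 1L) return("ensembleSize must be >= 1")
    TRUE
  })

#' CondensedDistances: pairwise model distances in condensed form
#'
#' Stores the n(n-1)/2 pairwise distances between n models in the canonical
#' condensed order (pair (i, j), i < j, ordered by i then j -- the layout of
#' [stats::dist]).
#'
#' @slot values numeric vector of length n(n-1)/2, all >= 0.
#' @slot labels character vector of the n model ids, in matrix order.
#' @slot metric character(1), \code{"contact_hamming"} or
#'   \code{"ligand_rmsd"}.
#' @export
setClass("CondensedDistances",
  representation(values = "numeric", labels = "character",
                 metric = "character"),
  validity = function(object) {
    n <- length(object@labels)
    if (length(object@values) != n * (n - 1) / 2)
      return("values must have length n(n-1)/2")
    if (any(!is.finite(object@values)) || any(object@values < 0))
      return("distances must be finite and >= 0")
    TRUE
  })

#' LinkageTree: agglomerative hierarchical clustering result
#'
#' The n-1 merges of a single- or complete-linkage agglomeration, in
#' \code{hclust} encoding: negative entries of \code{merge} are original
#' observations, positive entries refer to earlier merge rows.
#'
#' @slot merge integer matrix (n-1) x 2.
#' @slot height numeric vector of merge heights (non-decreasing for the
#'   monotone single and complete linkages).
#' @slot counts integer vector, member count of the cluster formed at each
#'   merge.
#' @slot labels character vector of model ids.
#' @slot method character(1), \code{"single"} or \code{"complete"}.
#' @seealso [linkageTree()], [cutDistance()], [cutMaxclust()], [asHclust()]
#' @export
setClass("LinkageTree",
  representation(merge = "matrix", height = "numeric", counts = "integer",
                 labels = "character", method = "character"),
  validity = function(object) {
    n <- length(object@labels)
    if (nrow(object@merge) != n - 1L || length(object@height) != n - 1L)
      return("merge/height must describe n-1 merges")
    if (object@counts[n - 1L] != n)
      return("final merge must contain all n members")
    if (!object@method %in% c("single", "complete"))
      return("method must be 'single' or 'complete'")
    TRUE
  })

#' ClusterPartition: flat clusters with population ranking
#'
#' @slot membership named integer vector mapping model id to cluster label.
#' @slot clusters data.frame with one row per cluster: \code{cluster}
#'   (label), \code{rank} (1 = most populated), \code{size}; ranked rows
#'   are ordered by rank. Populated by [rankClusters()]; before ranking,
#'   rank is NA and rows are in label order.
#' @slot criterion character(1), e.g. \code{"distance t=30"} or
#'   \code{"maxclust t=60"}.
#' @export
setClass("ClusterPartition",
  representation(membership = "integer", clusters = "data.frame",
                 criterion = "character"),
  validity = function(object) {
    if (is.null(names(object@membership)))
      return("membership must be named by model id")
    tab <- table(object@membership)
    cl <- object@clusters
    if (!setequal(cl$cluster, as.integer(names(tab))))
      return("clusters table must list exactly the membership labels")
    if (!all(cl$size[match(as.integer(names(tab)), cl$cluster)] ==
             as.integer(tab)))
      return("cluster sizes must match membership")
    TRUE
  })

#' SelectionResult: the predicted-positive models (at most 10)
#'
#' @slot selected data.frame with one row per selected model, columns
#'   \code{slot} (1-based selection order), \code{model_id}, \code{score}
#'   (CONSRANK score used for the pick), plus provenance columns:
#'   \code{global_rank} (redundancy/plain selection) or
#'   \code{cluster_rank}, \code{cluster_size}, \code{within_cluster_rank}
#'   (Clust-CONSRANK).
#' @slot method character(1) description (preset name or redundancy
#'   threshold).
#' @export
setClass("SelectionResult",
  representation(selected = "data.frame", method = "character"),
  validity = function(object) {
    sel <- object@selected
    if (anyDuplicated(sel$model_id)) return("selected model ids must be unique")
    TRUE
  })
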