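#' @include AllClasses.R
NULL

#' Accessors for ClustConsrank classes
#'
#' Small accessor generics so slots are never reached into directly:
#' \code{modelId} returns the model identifier of a [StructureModel-class]
#' or [ContactFingerprint-class]; \code{atoms} the atom table; \code{contacts}
#' the contact keys; \code{models} the list of models in a
#' [ModelEnsemble-class]; \code{isHarmonized} its harmonization flag;
#' \code{contactFrequency} the named frequency vector of a
#' [ConservationProfile-class]; \code{ensembleSize} its model count;
#' \code{distanceValues}, \code{distanceMetric} and \code{modelLabels} the
#' contents of a [CondensedDistances-class]; \code{mergeHeights} and
#' \code{linkageMethod} those of a [LinkageTree-class]; \code{membership},
#' \code{clusterTable} and \code{cutCriterion} those of a
#' [ClusterPartition-class]; \code{selectedModels} and
#' \code{selectionMethod} those of a [SelectionResult-class].
#'
#' @param x an object of the relevant class.
#' @return the slot contents described above.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("modelId", function(x) standardGeneric("modelId"))
#' @rdname accessors
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))
#' @rdname accessors
#' @export
setGeneric("partnerMap", function(x) standardGeneric("partnerMap"))
#' @rdname accessors
#' @export
setGeneric("contacts", function(x) standardGeneric("contacts"))
#' @rdname accessors
#' @export
setGeneric("models", function(x) standardGeneric("models"))
#' @rdname accessors
#' @export
setGeneric("isHarmonized", function(x) standardGeneric("isHarmonized"))
#' @rdname accessors
#' @export
setGeneric("contactFrequency", function(x) standardGeneric("contactFrequency"))
#' @rdname accessors
#' @export
setGeneric("ensembleSize", function(x) standardGeneric("ensembleSize"))
#' @rdname accessors
#' @export
setGeneric("distanceValues", function(x) standardGeneric("distanceValues"))
#' @rdname accessors
#' @export
setGeneric("distanceMetric", function(x) standardGeneric("distanceMetric"))
#' @rdname accessors
#' @export
setGeneric("modelLabels", function(x) standardGeneric("modelLabels"))
#' @rdname accessors
#' @export
setGeneric("mergeHeights", function(x) standardGeneric("mergeHeights"))
#' @rdname accessors
#' @export
setGeneric("linkageMethod", function(x) standardGeneric("linkageMethod"))
#' @rdname accessors
#' @export
setGeneric("membership", function(x) standardGeneric("membership"))
#' @rdname accessors
#' @export
setGeneric("clusterTable", function(x) standardGeneric("clusterTable"))
#' @rdname accessors
#' @export
setGeneric("cutCriterion", function(x) standardGeneric("cutCriterion"))
#' @rdname accessors
#' @export
setGeneric("selectedModels", function(x) standardGeneric("selectedModels"))
#' @rdname accessors
#' @export
setGeneric("selectionMethod", function(x) standardGeneric("selectionMethod"))

#' @rdname accessors
#' @export
setMethod("modelId", "StructureModel", function(x) x@modelId)
#' @rdname accessors
#' @export
setMethod("modelId", "ContactFingerprint", function(x) x@modelId)
#' @rdname accessors
#' @export
setMethod("atoms", "StructureModel", function(x) x@atoms)
#' @rdname accessors
#' @export
setMethod("partnerMap", "StructureModel", function(x) x@partnerOf)
#' @rdname accessors
#' @export
setMethod("contacts", "ContactFingerprint", function(x) x@contacts)
#' @rdname accessors
#' @export
setMethod("models", "ModelEnsemble", function(x) x@models)
#' @rdname accessors
#' @export
setMethod("isHarmonized", "ModelEnsemble", function(x) x@harmonized)
#' @rdname accessors
#' @export
setMethod("contactFrequency", "ConservationProfile", function(x) x@frequency)
#' @rdname accessors
#' @export
setMethod("ensembleSize", "ConservationProfile", function(x) x@ensembleSize)
#' @rdname accessors
#' @export
setMethod("distanceValues", "CondensedDistances", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("distanceMetric", "CondensedDistances", function(x) x@metric)
#' @rdname accessors
#' @export
setMethod("modelLabels", "CondensedDistances", function(x) x@labels)
#' @rdname accessors
#' @export
setMethod("modelLabels", "LinkageTree", function(x) x@labels)
#' @rdname accessors
#' @export
setMethod("mergeHeights", "LinkageTree", function(x) x@height)
#' @rdname accessors
#' @export
setMethod("linkageMethod", "LinkageTree", function(x) x@method)
#' @rdname accessors
#' @export
setMethod("membership", "ClusterPartition", function(x) x@membership)
#' @rdname accessors
#' @export
setMethod("clusterTable", "ClusterPartition", function(x) x@clusters)
#' @rdname accessors
#' @export
setMethod("cutCriterion", "ClusterPartition", function(x) x@criterion)
#' @rdname accessors
#' @export
setMethod("selectedModels", "SelectionResult", function(x) x@selected)
#' @rdname accessors
#' @export
setMethod("selectionMethod", "SelectionResult", function(x) x@method)

#' Number of models / contacts
#'
#' \code{length} of a [ModelEnsemble-class] is its number of models; of a
#' [ContactFingerprint-class], its number of contacts.
#'
#' @param x the object.
#' @export
setMethod("length", "ModelEnsemble", function(x) length(x@models))
#' @rdname length-ModelEnsemble-method
#' @export
setMethod("length", "ContactFingerprint", function(x) length(x@contacts))

setMethod("show", "StructureModel", function(object) {
  a <- object@atoms
  nres <- length(unique(residueKeys(object)))
  cat("StructureModel '", object@modelId, "': ", nrow(a), " atoms, ",
      nres, " residues\n", sep = "")
  for (role in c("receptor", "ligand")) {
    ch <- names(object@partnerOf)[object@partnerOf == role]
    cat("  ", role, ": chain(s) ", paste(ch, collapse = ","), "\n", sep = "")
  }
})

setMethod("show", "ModelEnsemble", function(object) {
  cat("ModelEnsemble of ", length(object@models), " models (harmonized: ",
      object@harmonized, ")\n", sep = "")
})

setMethod("show", "ContactFingerprint", function(object) {
  cat("ContactFingerprint '", object@modelId, "': ",
      length(object@contacts), " intermolecular contacts\n", sep = "")
})

setMethod("show", "ConservationProfile", function(object) {
  cat("ConservationProfile over ", object@ensembleSize, " models: ",
      length(object@frequency), " contacts in universe",
      if (length(object@frequency))
        sprintf(", max frequency %.3f", max(object@frequency)) else "",
      "\n", sep = "")
})

setMethod("show", "CondensedDistances", function(object) {
  cat("CondensedDistances (", object@metric, "): ", length(object@labels),
      " models, ", length(object@values), " pairs\n", sep = "")
})

setMethod("show", "LinkageTree", function(object) {
  cat("LinkageTree (", object@method, " linkage): ", length(object@labels),
      " models, merge heights [", format(min(object@height), digits = 4),
      ", ", format(max(object@height), digits = 4), "]\n", sep = "")
})

setMethod("show", "ClusterPartition", function(object) {
  cat("ClusterPartition (", object@criterion, "): ",
      nrow(object@clusters), " clusters over ",
      length(object@membership), " models\n", sep = "")
  top <- utils::head(object@clusters[order(-object@clusters$size), ], 5L)
  cat("  top populations:", paste(top$size, collapse = ", "), "\n")
})

setMethod("show", "SelectionResult", function(object) {
  cat("SelectionResult (", object@method, "): ", nrow(object@selected),
      " models selected\n", sep = "")
})
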