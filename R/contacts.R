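#' @include AllClasses.R utils.R
NULL

#' Intermolecular residue contacts of a model
#'
#' Two residues on opposite partners are in contact when any pair of their
#' heavy atoms lies within \code{cutoff} Angstrom (inclusive). Hydrogens and
#' deuteriums never contribute; intra-partner pairs are never contacts.
#'
#' @param model a [StructureModel-class] with partners assigned.
#' @param cutoff heavy-atom distance cutoff in Angstrom; default 5.
#' @return a [ContactFingerprint-class] whose keys are
#'   \code{"<receptor residue>|<ligand residue>"}.
#' @examples
#' native <- makeNative(complexSpec(seed = 1))
#' fp <- contactFingerprint(native)
#' length(fp)
#' @export
contactFingerprint <- function(model, cutoff = 5.0) {
  a <- atoms(model)
  pm <- partnerMap(model)
  if (!length(pm)) stop("model has no partner assignment", call. = FALSE)
  role <- pm[a$chain]
  recSel <- which(role == "receptor" & a$isHeavy)
  ligSel <- which(role == "ligand" & a$isHeavy)
  if (!length(recSel) || !length(ligSel)) {
    warning("model '", modelId(model), "' has no heavy atoms on one partner")
    return(new("ContactFingerprint", modelId = modelId(model),
               contacts = character()))
  }
  R <- as.matrix(a[recSel, c("x", "y", "z")])
  L <- as.matrix(a[ligSel, c("x", "y", "z")])
  # squared cross-distances: |r|^2 + |l|^2 - 2 r.l
  d2 <- outer(rowSums(R^2), rowSums(L^2), "+") - 2 * tcrossprod(R, L)
  hit <- which(d2 <= cutoff^2 + 1e-12, arr.ind = TRUE)
  if (!nrow(hit))
    return(new("ContactFingerprint", modelId = modelId(model),
               contacts = character()))
  rk <- makeResidueKey(a$chain[recSel], a$resno[recSel], a$insert[recSel])
  lk <- makeResidueKey(a$chain[ligSel], a$resno[ligSel], a$insert[ligSel])
  keys <- unique(paste0(rk[hit[, 1]], "|", lk[hit[, 2]]))
  new("ContactFingerprint", modelId = modelId(model), contacts = sort(keys))
}

#' Construct a contact fingerprint directly from contact keys
#'
#' Convenience constructor for synthetic fingerprints (tests, worked
#' examples): keys are deduplicated and sorted.
#'
#' @param modelId model identifier.
#' @param keys character vector of \code{"receptor|ligand"} contact keys.
#' @return a [ContactFingerprint-class].
#' @export
fingerprint <- function(modelId, keys) {
  new("ContactFingerprint", modelId = modelId,
      contacts = sort(unique(as.character(keys))))
}

# The contact universe of a fingerprint list: every key observed in >= 1
# model, ordered by model of first appearance (contacts sorted per model).
contactUniverse <- function(fingerprints) {
  unique(unlist(lapply(fingerprints, contacts), use.names = FALSE))
}

# n x U logical incidence matrix of fingerprints over the universe.
incidenceMatrix <- function(fingerprints, universe = NULL) {
  if (is.null(universe)) universe <- contactUniverse(fingerprints)
  n <- length(fingerprints)
  M <- matrix(FALSE, n, length(universe),
              dimnames = list(vapply(fingerprints, modelId, character(1)),
                              universe))
  for (i in seq_len(n))
    M[i, match(contacts(fingerprints[[i]]), universe)] <- TRUE
  M
}

#' Contact conservation profile of an ensemble
#'
#' For every contact observed in at least one fingerprint, the fraction of
#' fingerprints containing it -- the values of a consensus map.
#'
#' @param fingerprints list of [ContactFingerprint-class] objects.
#' @return a [ConservationProfile-class].
#' @export
conservationProfile <- function(fingerprints) {
  if (!length(fingerprints)) stop("empty fingerprint list", call. = FALSE)
  universe <- contactUniverse(fingerprints)
  counts <- integer(length(universe))
  names(counts) <- universe
  for (fp in fingerprints) {
    idx <- match(contacts(fp), universe)
    counts[idx] <- counts[idx] + 1L
  }
  new("ConservationProfile",
      frequency = counts / length(fingerprints),
      ensembleSize = length(fingerprints))
}

#' Consensus map as a receptor x ligand matrix
#'
#' @param profile a [ConservationProfile-class] (a single-model profile gives
#'   a plain binary contact map).
#' @return numeric matrix, rows = receptor residue keys, columns = ligand
#'   residue keys, entries = conservation frequencies (0 where no contact).
#' @export
consensusMatrix <- function(profile) {
  f <- contactFrequency(profile)
  if (!length(f))
    return(matrix(numeric(0), 0, 0))
  parts <- splitContactKey(names(f))
  rres <- unique(parts$receptor)
  lres <- unique(parts$ligand)
  M <- matrix(0, length(rres), length(lres), dimnames = list(rres, lres))
  M[cbind(match(parts$receptor, rres), match(parts$ligand, lres))] <- f
  M
}

#' Export a consensus (or contact) map
#'
#' Writes the receptor x ligand frequency matrix as TSV, and optionally a
#' grey-scale PNG in which darker dots mark more conserved contacts.
#'
#' @param profile a [ConservationProfile-class].
#' @param path output TSV path.
#' @param image optional PNG path for the grey-scale rendering.
#' @return invisibly, the TSV path.
#' @export
exportConsensusMap <- function(profile, path, image = NULL) {
  M <- consensusMatrix(profile)
  df <- data.frame(receptor = rownames(M), M, check.names = FALSE)
  ok <- tryCatch(
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE),
    error = function(e) stop("cannot write '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  if (!is.null(image) && nrow(M) && ncol(M)) {
    grDevices::png(image, width = 480, height = 480)
    on.exit(grDevices::dev.off(), add = TRUE)
    graphics::image(seq_len(nrow(M)), seq_len(ncol(M)), M,
                    col = grDevices::grey(seq(1, 0, length.out = 64)),
                    xlab = "receptor residue", ylab = "ligand residue",
                    main = sprintf("consensus map (%d models)",
                                   ensembleSize(profile)))
  }
  invisible(path)
}

#' Contact fingerprints for every model of an ensemble
#'
#' @param ensemble a [ModelEnsemble-class] (harmonized for cross-model
#'   comparability) or a list of [StructureModel-class] objects.
#' @param cutoff contact cutoff in Angstrom; default 5.
#' @return list of [ContactFingerprint-class], in model order.
#' @export
ensembleFingerprints <- function(ensemble, cutoff = 5.0) {
  mods <- if (is(ensemble, "ModelEnsemble")) models(ensemble) else ensemble
  lapply(mods, contactFingerprint, cutoff = cutoff)
}
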