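#' @include AllClasses.R contacts.R utils.R
NULL

#' Fraction of native contacts (f_nat)
#'
#' The fraction of the reference structure's inter-residue contacts that a
#' model reproduces: |model contacts intersect reference contacts| divided
#' by |reference contacts|.
#'
#' @param fp the model's [ContactFingerprint-class].
#' @param reference the reference (e.g. X-ray) structure's
#'   [ContactFingerprint-class]; must be non-empty.
#' @return numeric in [0, 1].
#' @export
fnat <- function(fp, reference) {
  ref <- contacts(reference)
  if (!length(ref))
    stop("reference structure has no contacts; cannot compute f_nat",
         call. = FALSE)
  length(intersect(contacts(fp), ref)) / length(ref)
}

# Backbone (N, CA, C, O) atom table of one partner, keyed by residue + atom.
backboneTable <- function(model, role) {
  a <- atoms(model)
  pm <- partnerMap(model)
  sel <- pm[a$chain] == role & a$elety %in% c("N", "CA", "C", "O")
  sub <- a[sel, , drop = FALSE]
  key <- paste0(makeResidueKey(sub$chain, sub$resno, sub$insert), "@",
                sub$elety)
  sub <- sub[!duplicated(key), , drop = FALSE]
  rownames(sub) <- NULL
  list(keys = key[!duplicated(key)],
       xyz = as.matrix(sub[, c("x", "y", "z")]))
}

#' Ligand RMSD after receptor superposition (L-RMSD)
#'
#' The receptor backbones (N, CA, C, O atoms shared between the two models,
#' matched by residue key and atom name) are superimposed by least squares
#' (Kabsch), and the RMSD is then computed over the shared ligand backbone
#' atoms.
#'
#' @param model a [StructureModel-class].
#' @param reference the reference [StructureModel-class] (same residue-key
#'   space; run [harmonizeNumbering()] first if needed).
#' @return RMSD in Angstrom.
#' @export
ligandRmsd <- function(model, reference) {
  recM <- backboneTable(model, "receptor")
  recR <- backboneTable(reference, "receptor")
  shared <- intersect(recM$keys, recR$keys)
  if (length(shared) < 3L)
    stop("fewer than 3 shared receptor backbone atoms; cannot superimpose",
         call. = FALSE)
  ligM <- backboneTable(model, "ligand")
  ligR <- backboneTable(reference, "ligand")
  sharedL <- intersect(ligM$keys, ligR$keys)
  if (!length(sharedL))
    stop("no shared ligand backbone atoms", call. = FALSE)
  # assemble fixed (reference) and mobile (model) coordinate vectors
  fixedXyz <- as.numeric(t(rbind(recR$xyz[match(shared, recR$keys), ],
                                 ligR$xyz[match(sharedL, ligR$keys), ])))
  mobileXyz <- as.numeric(t(rbind(recM$xyz[match(shared, recM$keys), ],
                                  ligM$xyz[match(sharedL, ligM$keys), ])))
  nRec <- length(shared)
  recInds <- seq_len(3L * nRec)
  fitted <- bio3d::fit.xyz(fixedXyz, mobileXyz, fixed.inds = recInds,
                           mobile.inds = recInds)
  ligInds <- 3L * nRec + seq_len(3L * length(sharedL))
  dd <- matrix(fitted[ligInds] - fixedXyz[ligInds], ncol = 3, byrow = TRUE)
  sqrt(mean(rowSums(dd^2)))
}

#' Interface RMSD (I-RMSD)
#'
#' RMSD over the backbone atoms of the reference interface residues (those
#' with any heavy atom within \code{interfaceCutoff} of the other partner in
#' the reference), after superposing the two models on those same atoms.
#' Optional in CAPRI classification; off by default.
#'
#' @param model a [StructureModel-class].
#' @param reference the reference [StructureModel-class].
#' @param interfaceCutoff heavy-atom distance defining interface residues in
#'   the reference; default 10 Angstrom.
#' @return RMSD in Angstrom.
#' @export
interfaceRmsd <- function(model, reference, interfaceCutoff = 10.0) {
  ifp <- contactFingerprint(reference, cutoff = interfaceCutoff)
  parts <- splitContactKey(contacts(ifp))
  ifaceRes <- unique(c(parts$receptor, parts$ligand))
  if (!length(ifaceRes)) stop("reference has no interface residues",
                              call. = FALSE)
  bbOf <- function(m) {
    rec <- backboneTable(m, "receptor"); lig <- backboneTable(m, "ligand")
    keys <- c(rec$keys, lig$keys)
    xyz <- rbind(rec$xyz, lig$xyz)
    res <- sub("@.*$", "", keys)
    keep <- res %in% ifaceRes
    list(keys = keys[keep], xyz = xyz[keep, , drop = FALSE])
  }
  bm <- bbOf(model); br <- bbOf(reference)
  shared <- intersect(bm$keys, br$keys)
  if (length(shared) < 3L)
    stop("fewer than 3 shared interface backbone atoms", call. = FALSE)
  fixedXyz <- as.numeric(t(br$xyz[match(shared, br$keys), ]))
  mobileXyz <- as.numeric(t(bm$xyz[match(shared, bm$keys), ]))
  fitted <- bio3d::fit.xyz(fixedXyz, mobileXyz,
                           fixed.inds = seq_along(fixedXyz),
                           mobile.inds = seq_along(mobileXyz))
  dd <- matrix(fitted - fixedXyz, ncol = 3, byrow = TRUE)
  sqrt(mean(rowSums(dd^2)))
}

#' CAPRI quality class of a model
#'
#' Standard CAPRI criteria: \strong{High} if f_nat >= 0.5 and (L-RMSD <= 1
#' or I-RMSD <= 1); \strong{Medium} if f_nat >= 0.3 and (L-RMSD <= 5 or
#' I-RMSD <= 2); \strong{Acceptable} if f_nat >= 0.1 and (L-RMSD <= 10 or
#' I-RMSD <= 4); otherwise \strong{Incorrect}. A model with f_nat < 0.1 is
#' always Incorrect. When I-RMSD is missing (NA) the L-RMSD clause alone
#' decides. Vectorized.
#'
#' @param fnat fraction(s) of native contacts, in [0, 1].
#' @param lrmsd ligand RMSD(s), Angstrom.
#' @param irmsd optional interface RMSD(s), Angstrom (NA = not used).
#' @return character vector of \code{"High"}, \code{"Medium"},
#'   \code{"Acceptable"} or \code{"Incorrect"}.
#' @export
capriClassify <- function(fnat, lrmsd, irmsd = NA_real_) {
  if (any(fnat < 0 | fnat > 1))
    stop("f_nat must lie in [0, 1]", call. = FALSE)
  k <- max(length(fnat), length(lrmsd), length(irmsd))
  fnat <- rep_len(fnat, k); lrmsd <- rep_len(lrmsd, k)
  irmsd <- rep_len(irmsd, k)
  rmsdOk <- function(l, i) (lrmsd <= l) | (!is.na(irmsd) & irmsd <= i)
  out <- rep("Incorrect", k)
  out[fnat >= 0.1 & rmsdOk(10, 4)] <- "Acceptable"
  out[fnat >= 0.3 & rmsdOk(5, 2)] <- "Medium"
  out[fnat >= 0.5 & rmsdOk(1, 1)] <- "High"
  out
}

#' Evaluate every model of an ensemble against a reference structure
#'
#' Computes f_nat, ligand RMSD and the CAPRI class per model.
#'
#' @param ensemble a [ModelEnsemble-class] or list of
#'   [StructureModel-class].
#' @param reference the reference [StructureModel-class].
#' @param cutoff contact cutoff, Angstrom; default 5.
#' @param withInterfaceRmsd also compute I-RMSD (slower); default FALSE.
#' @return data.frame with columns \code{model_id}, \code{fnat},
#'   \code{lrmsd}, (optionally \code{irmsd}) and \code{class}.
#' @export
evaluateEnsemble <- function(ensemble, reference, cutoff = 5.0,
                             withInterfaceRmsd = FALSE) {
  mods <- if (is(ensemble, "ModelEnsemble")) models(ensemble) else ensemble
  refFp <- contactFingerprint(reference, cutoff = cutoff)
  fn <- vapply(mods, function(m)
    fnat(contactFingerprint(m, cutoff = cutoff), refFp), numeric(1))
  lr <- vapply(mods, ligandRmsd, numeric(1), reference = reference)
  ir <- if (withInterfaceRmsd)
    vapply(mods, interfaceRmsd, numeric(1), reference = reference)
  else rep(NA_real_, length(mods))
  df <- data.frame(model_id = vapply(mods, modelId, character(1)),
                   fnat = fn, lrmsd = lr,
                   class = capriClassify(fn, lr, ir),
                   stringsAsFactors = FALSE)
  if (withInterfaceRmsd) df$irmsd <- ir
  df
}

# normalize label spellings to the one-letter H/M/A/I/R code
normalizeLabels <- function(labels) {
  map <- c(H = "H", HIGH = "H", M = "M", MEDIUM = "M", A = "A",
           ACCEPTABLE = "A", I = "I", INCORRECT = "I", R = "R",
           REMOVED = "R")
  out <- map[toupper(as.character(labels))]
  if (anyNA(out))
    stop("unknown quality label(s): ",
         paste(unique(labels[is.na(out)]), collapse = ", "), call. = FALSE)
  unname(out)
}

#' Summarize the quality composition of an ensemble
#'
#' Counts High, Medium, Acceptable, Incorrect and Removed models;
#' native-like (NL) is H + M + A, and percent NL is reported to two
#' significant figures (the convention of CAPRI benchmark tables).
#'
#' @param labels character vector of per-model classes (H/M/A/I/R, full
#'   words accepted), or a data.frame with a \code{class} column such as
#'   [evaluateEnsemble()] returns.
#' @return list with \code{counts} (named H/M/A/I/R), \code{total},
#'   \code{NL}, \code{percentNL} (exact) and \code{percentNLReported}
#'   (2 significant figures).
#' @export
summarizeEnsemble <- function(labels) {
  if (is.data.frame(labels)) {
    if (anyNA(labels$class))
      stop("unlabeled model(s): ",
           paste(labels$model_id[is.na(labels$class)], collapse = ", "),
           call. = FALSE)
    labels <- labels$class
  }
  lab <- normalizeLabels(labels)
  counts <- vapply(c("H", "M", "A", "I", "R"), function(k) sum(lab == k),
                   integer(1))
  total <- sum(counts)
  nl <- sum(counts[c("H", "M", "A")])
  scored <- total
  pct <- if (scored > 0) 100 * nl / scored else {
    warning("no models to summarize; percent NL undefined, reported as 0")
    0
  }
  list(counts = counts, total = total, NL = nl, percentNL = pct,
       percentNLReported = signif(pct, 2))
}

#' Summarize a selection against quality labels
#'
#' The per-selection bookkeeping of benchmark tables: how many of the
#' selected models are native-like (NL = H/M/A) and how many are of
#' high/medium quality, the \code{"NL/H+M"} cell, plus the success flags
#' used to tally methods across interfaces (at least one NL; at least one
#' H or M).
#'
#' @param selection a [SelectionResult-class] or character vector of
#'   selected model ids.
#' @param labels named character vector mapping model id to class, or a
#'   data.frame with \code{model_id} and \code{class} columns.
#' @return list with \code{nNL}, \code{nHM}, \code{cell} (e.g.
#'   \code{"3/1"}), \code{success}, \code{hqSuccess}.
#' @export
summarizeSelection <- function(selection, labels) {
  ids <- if (is(selection, "SelectionResult"))
    selectedModels(selection)$model_id else as.character(selection)
  if (is.data.frame(labels))
    labels <- setNames(labels$class, labels$model_id)
  if (!all(ids %in% names(labels)))
    stop("selection references unlabeled model(s): ",
         paste(setdiff(ids, names(labels)), collapse = ", "), call. = FALSE)
  lab <- normalizeLabels(labels[ids])
  nNL <- sum(lab %in% c("H", "M", "A"))
  nHM <- sum(lab %in% c("H", "M"))
  list(nNL = nNL, nHM = nHM, cell = sprintf("%d/%d", nNL, nHM),
       success = nNL >= 1L, hqSuccess = nHM >= 1L)
}

#' Read / write a model quality-label table
#'
#' TSV with columns \code{model_id} and \code{class} (H/M/A/I/R), the format
#' of benchmark classification lists.
#'
#' @param path file path.
#' @return data.frame with \code{model_id} and \code{class}.
#' @export
readLabelTable <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  stopifnot(all(c("model_id", "class") %in% names(df)))
  df$class <- normalizeLabels(df$class)
  df
}

#' @rdname readLabelTable
#' @param labels data.frame with \code{model_id} and \code{class} columns.
#' @export
writeLabelTable <- function(labels, path) {
  utils::write.table(labels[, c("model_id", "class")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-target quality counts of the CAPRI scoring benchmarks
#'
#' Loads the bundled table of per-target model-quality counts for the 20
#' target/interface ensembles of the public CAPRI scoring benchmarks
#' (SCORE_SET and the CAPRI Round 30 homodimers): columns \code{target},
#' \code{n_models}, \code{H}, \code{M}, \code{A}, \code{I}, \code{R}.
#'
#' @return data.frame of counts, one row per target/interface.
#' @export
readBenchmarkCounts <- function() {
  path <- system.file("extdata", "capri_scoring_benchmark_counts.tsv",
                      package = "ClustConsrank", mustWork = TRUE)
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}
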