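#' @include AllClasses.R utils.R
NULL

# Build the atoms data.frame from a bio3d atom table: keep ATOM records,
# drop waters, resolve alternate locations by occupancy (ties: first seen),
# flag hydrogens/deuteriums.
standardizeAtoms <- function(at, path = "<memory>") {
  at <- at[at$type == "ATOM" & !(at$resid %in% c("HOH", "WAT", "DOD")), ,
           drop = FALSE]
  if (!nrow(at))
    stop("no ATOM records found in '", path, "'", call. = FALSE)
  xyz <- as.matrix(at[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) {
    bad <- which(!apply(is.finite(xyz), 1, all))
    stop("malformed coordinates in '", path, "' (e.g. atom serial ",
         at$eleno[bad[1]], ")", call. = FALSE)
  }
  insert <- at$insert
  insert[is.na(insert) | insert == " "] <- ""
  elesy <- at$elesy
  blank <- is.na(elesy) | elesy == "" | elesy == " "
  elesy[blank] <- elementFromName(at$elety[blank])
  elesy <- toupper(trimws(elesy))
  alt <- at$alt
  alt[is.na(alt)] <- ""
  occ <- at$o
  occ[is.na(occ)] <- 1
  df <- data.frame(chain = as.character(at$chain), resno = as.integer(at$resno),
                   insert = insert, resid = as.character(at$resid),
                   elety = trimws(as.character(at$elety)), elesy = elesy,
                   isHeavy = !(elesy %in% c("H", "D")),
                   x = at$x, y = at$y, z = at$z,
                   stringsAsFactors = FALSE)
  if (any(alt != "")) {
    # one altloc per (residue, atom name): highest occupancy, first on ties
    key <- paste(df$chain, df$resno, df$insert, df$elety, sep = "\r")
    ord <- order(match(key, unique(key)), -occ,
                 seq_len(nrow(df)))
    df <- df[ord, , drop = FALSE]
    df <- df[!duplicated(paste(df$chain, df$resno, df$insert, df$elety,
                               sep = "\r")), , drop = FALSE]
    rownames(df) <- NULL
  }
  df
}

#' Read one docking model from a PDB file
#'
#' Parses the ATOM records of a PDB file into a [StructureModel-class].
#' HETATM records and waters are excluded; hydrogens are retained but
#' flagged non-heavy (contact detection ignores them); alternate locations
#' are resolved to the highest-occupancy conformer (first encountered on
#' ties). Receptor/ligand roles are assigned with [assignPartners()].
#'
#' @param path path to a PDB file.
#' @param receptorChains optional character vector naming the receptor
#'   chains; remaining chains become the ligand. Required when the file has
#'   more than two chains.
#' @param modelId identifier for the model; defaults to the file basename
#'   without extension.
#' @return a [StructureModel-class].
#' @examples
#' native <- makeNative(complexSpec(seed = 1))
#' f <- tempfile(fileext = ".pdb")
#' writeModel(native, f)
#' m <- readModel(f)
#' m
#' @export
readModel <- function(path, receptorChains = NULL,
                      modelId = tools::file_path_sans_ext(basename(path))) {
  if (!file.exists(path)) stop("cannot read '", path, "'", call. = FALSE)
  checkCoordinateColumns(path)
  pdb <- tryCatch(bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE),
                  error = function(e) diagnoseParseFailure(path, e))
  df <- standardizeAtoms(pdb$atom, path)
  m <- new("StructureModel", modelId = modelId, atoms = df,
           partnerOf = character())
  assignPartners(m, receptorChains)
}

# The fixed coordinate columns (31-54) of every ATOM record must parse as
# numbers; permissive downstream parsers can otherwise coerce garbage to 0.
checkCoordinateColumns <- function(path) {
  lines <- readLines(path, warn = FALSE)
  atom <- which(grepl("^ATOM", lines))
  if (!length(atom)) return(invisible())
  fields <- cbind(substr(lines[atom], 31, 38), substr(lines[atom], 39, 46),
                  substr(lines[atom], 47, 54))
  bad <- !apply(matrix(is.finite(suppressWarnings(as.numeric(fields))),
                       nrow = length(atom)), 1, all)
  if (any(bad))
    stop("malformed coordinate fields in '", path, "' at line ",
         atom[which(bad)[1]], call. = FALSE)
  invisible()
}

# On a bio3d parse failure, scan the raw lines for an ATOM record with
# non-numeric coordinate fields so the error can name the line.
diagnoseParseFailure <- function(path, err) {
  lines <- tryCatch(readLines(path, warn = FALSE), error = function(e) NULL)
  if (!is.null(lines)) {
    atom <- grepl("^(ATOM|HETATM)", lines)
    for (i in which(atom)) {
      flds <- c(substr(lines[i], 31, 38), substr(lines[i], 39, 46),
                substr(lines[i], 47, 54))
      if (any(is.na(suppressWarnings(as.numeric(flds)))))
        stop("malformed coordinate fields in '", path, "' at line ", i,
             call. = FALSE)
    }
  }
  stop("failed to parse '", path, "': ", conditionMessage(err),
       call. = FALSE)
}

#' Assign receptor and ligand roles to the chains of a model
#'
#' The receptor is the larger interactor. If \code{receptorChains} is given,
#' those chains are the receptor and all others the ligand; otherwise, for a
#' two-chain model, the chain with more residues is the receptor, with the
#' alphabetically first chain winning ties (homodimers).
#'
#' @param model a [StructureModel-class].
#' @param receptorChains optional character vector of receptor chain ids.
#' @return the model with its partner map set.
#' @export
assignPartners <- function(model, receptorChains = NULL) {
  a <- atoms(model)
  chains <- sort(unique(a$chain))
  if (!is.null(receptorChains)) {
    missing <- setdiff(receptorChains, chains)
    if (length(missing))
      stop("receptor chain(s) not present: ", paste(missing, collapse = ","),
           call. = FALSE)
    lig <- setdiff(chains, receptorChains)
    if (!length(lig))
      stop("all chains assigned to the receptor; no ligand left",
           call. = FALSE)
    pm <- setNames(ifelse(chains %in% receptorChains, "receptor", "ligand"),
                   chains)
  } else {
    if (length(chains) < 2L)
      stop("model '", modelId(model), "' has fewer than two chains and no ",
           "receptor chains were supplied", call. = FALSE)
    if (length(chains) > 2L)
      stop("model '", modelId(model), "' has ", length(chains), " chains; ",
           "supply receptorChains to define the two partners", call. = FALSE)
    keys <- makeResidueKey(a$chain, a$resno, a$insert)
    nres <- vapply(chains, function(ch)
      length(unique(keys[a$chain == ch])), integer(1))
    # larger interactor is the receptor; alphabetical tie-break
    rec <- chains[order(-nres, chains)][1L]
    pm <- setNames(ifelse(chains == rec, "receptor", "ligand"), chains)
  }
  initialize(model, partnerOf = pm)
}

#' Write a model to a PDB file
#'
#' Writes standard fixed-column ATOM records. Round-tripping through
#' [readModel()] preserves residue keys, elements and coordinates to three
#' decimals.
#'
#' @param model a [StructureModel-class].
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @export
writeModel <- function(model, path) {
  a <- atoms(model)
  if (any(a$resno > 9999L))
    stop("residue numbers exceed 9999; cannot be represented in PDB ",
         "fixed columns", call. = FALSE)
  ins <- a$insert
  ins[ins == ""] <- ""
  ok <- tryCatch({
    bio3d::write.pdb(file = path,
                     xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                     type = rep("ATOM", nrow(a)),
                     resno = a$resno, resid = a$resid,
                     eleno = seq_len(nrow(a)), elety = a$elety,
                     chain = a$chain, insert = ins,
                     o = rep(1, nrow(a)), b = rep(0, nrow(a)),
                     elesy = a$elesy)
    TRUE
  }, error = function(e) {
    stop("cannot write '", path, "': ", conditionMessage(e), call. = FALSE)
  })
  invisible(path)
}

#' Read an ensemble of docking models
#'
#' @param paths either a directory containing \code{.pdb} files or a
#'   character vector of PDB file paths.
#' @param receptorChains optional receptor chain ids applied to every model.
#' @return a [ModelEnsemble-class] (not yet harmonized).
#' @seealso [harmonizeNumbering()]
#' @export
readEnsemble <- function(paths, receptorChains = NULL) {
  if (length(paths) == 1L && dir.exists(paths))
    paths <- sort(list.files(paths, pattern = "\\.pdb$", full.names = TRUE))
  if (!length(paths)) stop("no PDB files found", call. = FALSE)
  mods <- lapply(paths, readModel, receptorChains = receptorChains)
  new("ModelEnsemble", models = mods, harmonized = FALSE)
}

#' Write every model of an ensemble to a directory
#'
#' @param ensemble a [ModelEnsemble-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
writeEnsemble <- function(ensemble, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(models(ensemble), function(m) {
    p <- file.path(dir, paste0(modelId(m), ".pdb"))
    writeModel(m, p)
    p
  }, character(1))
  invisible(paths)
}

# Per-chain sequence (1-letter) of a model, residues in (resno, insert) order.
chainSequences <- function(model) {
  a <- atoms(model)
  out <- list()
  for (ch in sort(unique(a$chain))) {
    sub <- a[a$chain == ch, , drop = FALSE]
    key <- makeResidueKey(sub$chain, sub$resno, sub$insert)
    first <- !duplicated(key)
    ord <- order(sub$resno[first], sub$insert[first])
    out[[ch]] <- list(keys = key[first][ord],
                      seq = paste(aa321(sub$resid[first][ord]),
                                  collapse = ""))
  }
  out
}

# Global (Needleman-Wunsch) alignment of two 1-letter sequences; returns
# percent identity over the shorter sequence, per-sequence coverage, and the
# mapping from positions of s1 to positions of s2 (NA where unaligned).
alignPair <- function(s1, s2) {
  if (!nchar(s1) || !nchar(s2))
    stop("cannot align a zero-length sequence", call. = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(s1), Biostrings::AAString(s2), type = "global",
    substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5)
  p1 <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  p2 <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  i1 <- cumsum(p1 != "-")
  i2 <- cumsum(p2 != "-")
  both <- p1 != "-" & p2 != "-"
  nAligned <- sum(both)
  nMatch <- sum(both & p1 == p2)
  map <- rep(NA_integer_, nchar(s1))
  map[i1[both]] <- i2[both]
  list(identity = nMatch / min(nchar(s1), nchar(s2)),
       coverage1 = nAligned / nchar(s1),
       coverage2 = nAligned / nchar(s2),
       map = map)
}

#' Harmonize residue numbering across an ensemble
#'
#' Makes corresponding residues share the same number and chain id in every
#' model, the prerequisite for comparing contacts across models. Chain
#' sequences are grouped by greedy single-linkage clustering of pairwise
#' global-alignment identity/coverage; within a group every chain is aligned
#' to the group's longest sequence (the reference) and each residue is
#' renumbered by the reference position it aligns to (1-based). Residues
#' aligning to a gap in the reference are kept but renumbered past the
#' reference range so they never collide with shared keys. Chain ids within
#' a group are unified to the reference chain's id. Coordinates are never
#' modified.
#'
#' @param ensemble a [ModelEnsemble-class].
#' @param identityThreshold minimum fractional sequence identity (over the
#'   shorter sequence) for two chains to be grouped; default 0.70.
#' @param coverageThreshold minimum fractional alignment coverage of each
#'   sequence; default 0.9.
#' @return the harmonized [ModelEnsemble-class] (\code{isHarmonized()} TRUE).
#' @export
harmonizeNumbering <- function(ensemble, identityThreshold = 0.70,
                               coverageThreshold = 0.9) {
  mods <- models(ensemble)
  if (!length(mods)) stop("empty ensemble", call. = FALSE)

  # collect every (model, chain) sequence, with its atom row indices
  entries <- list()
  for (mi in seq_along(mods)) {
    seqs <- chainSequences(mods[[mi]])
    a <- atoms(mods[[mi]])
    for (ch in names(seqs))
      entries[[length(entries) + 1L]] <-
        list(model = mi, chain = ch, seq = seqs[[ch]]$seq,
             keys = seqs[[ch]]$keys, rows = which(a$chain == ch),
             role = partnerMap(mods[[mi]])[[ch]])
  }

  matches <- function(a, b) {
    al <- alignPair(a, b)
    al$identity >= identityThreshold &&
      al$coverage1 >= coverageThreshold && al$coverage2 >= coverageThreshold
  }

  # Greedy single-linkage grouping over *unique* sequences (decoy ensembles
  # repeat the same two sequences hundreds of times; identical sequences are
  # trivially co-grouped at any threshold), in first-appearance order.
  seqs <- vapply(entries, `[[`, character(1), "seq")
  uniq <- unique(seqs)
  seqGroups <- list()
  for (s in uniq) {
    hit <- which(vapply(seqGroups, function(g)
      any(vapply(g, matches, logical(1), b = s)), logical(1)))
    if (!length(hit)) {
      seqGroups[[length(seqGroups) + 1L]] <- s
    } else {
      if (length(hit) > 1L) {        # merging bridges earlier groups
        seqGroups[[hit[1]]] <- unlist(seqGroups[hit])
        seqGroups[hit[-1]] <- NULL
      }
      seqGroups[[hit[1]]] <- c(seqGroups[[hit[1]]], s)
    }
  }
  groupOfSeq <- integer(length(uniq))
  for (gi in seq_along(seqGroups))
    groupOfSeq[match(seqGroups[[gi]], uniq)] <- gi
  groups <- lapply(seq_along(seqGroups), function(gi)
    entries[groupOfSeq[match(seqs, uniq)] == gi])
  loneSeq <- vapply(groups, function(g)
    length(unique(vapply(g, `[[`, character(1), "seq"))), integer(1)) == 1L &
    vapply(groups, length, integer(1)) == 1L
  if (any(loneSeq) && length(entries) > 1L)
    warning(sum(loneSeq), " chain(s) matched no other chain at the identity/",
            "coverage thresholds and were left in their own group")

  # Assign chain ids per group. A model may contribute several chains to one
  # group (homodimers): those keep distinct ids, in alphabetical chain order,
  # drawn from the group's id slots (slot 1 = reference chain's id if free).
  usedIds <- character()
  newAtoms <- lapply(mods, atoms)
  newRoles <- replicate(length(mods), character(), simplify = FALSE)
  for (g in groups) {
    lens <- vapply(g, function(e) nchar(e$seq), integer(1))
    ref <- g[[which.max(lens)]]          # ties: first encountered
    mapOf <- list()                      # one alignment per unique sequence
    nSlots <- max(table(vapply(g, `[[`, integer(1), "model")))
    slotIds <- character(nSlots)
    for (s in seq_len(nSlots)) {
      cand <- if (s == 1L && !(ref$chain %in% usedIds)) ref$chain
              else setdiff(c(LETTERS, letters, as.character(0:9)), usedIds)[1L]
      slotIds[s] <- cand
      usedIds <- c(usedIds, cand)
    }
    byModel <- split(seq_along(g), vapply(g, `[[`, integer(1), "model"))
    for (idx in byModel) {
      ord <- order(vapply(g[idx], `[[`, character(1), "chain"))
      for (s in seq_along(idx)) {
        e <- g[[idx[ord[s]]]]
        gid <- slotIds[s]
        map <- mapOf[[e$seq]]
        if (is.null(map)) {
          map <- if (e$seq == ref$seq) seq_len(nchar(ref$seq))
                 else alignPair(e$seq, ref$seq)$map
          # residues unaligned to the reference get numbers past its range
          extra <- which(is.na(map))
          map[extra] <- nchar(ref$seq) + seq_along(extra)
          mapOf[[e$seq]] <- map
        }
        a0 <- atoms(mods[[e$model]])
        keys <- makeResidueKey(a0$chain[e$rows], a0$resno[e$rows],
                               a0$insert[e$rows])
        pos <- match(keys, e$keys)
        newAtoms[[e$model]]$resno[e$rows] <- map[pos]
        newAtoms[[e$model]]$insert[e$rows] <- ""
        newAtoms[[e$model]]$chain[e$rows] <- gid
        newRoles[[e$model]][gid] <- e$role
      }
    }
  }
  newMods <- lapply(seq_along(mods), function(mi)
    initialize(mods[[mi]], atoms = newAtoms[[mi]],
               partnerOf = newRoles[[mi]]))
  new("ModelEnsemble", models = newMods, harmonized = TRUE)
}
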