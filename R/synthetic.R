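#' @include AllClasses.R structio.R contacts.R evaluation.R utils.R
NULL

#' Specification of a synthetic two-chain complex
#'
#' Parameters of the pseudo-protein native complex used by the decoy
#' simulator: two idealized helical backbone traces (CA radius 2.3 Angstrom,
#' rise 1.5 Angstrom, 100 degrees per residue, consecutive CA about 3.8
#' Angstrom apart) with full N, CA, C, O backbones, packed side by side so
#' the interface carries a substantial number of 5-Angstrom contacts. The
#' receptor (chain A) is the longer chain.
#'
#' @param receptorLength,ligandLength residue counts (>= 10); receptor must
#'   not be shorter than the ligand.
#' @param axisSeparation distance between the two helix axes, Angstrom;
#'   default 9.5 (non-clashing, contact-rich).
#' @param seed integer seed fixing the residue sequences.
#' @return a list of class \code{"complexSpec"}.
#' @export
complexSpec <- function(receptorLength = 60L, ligandLength = 35L,
                        axisSeparation = 9.5, seed = 1L) {
  stopifnot(receptorLength >= 10L, ligandLength >= 10L,
            receptorLength >= ligandLength)
  structure(list(receptorLength = as.integer(receptorLength),
                 ligandLength = as.integer(ligandLength),
                 axisSeparation = axisSeparation, seed = as.integer(seed)),
            class = "complexSpec")
}

# Idealized helical backbone: returns an atoms data.frame with N, CA, C, O
# per residue. CA on a helix (radius 2.3 A, rise 1.5 A, 100 deg/res); N and
# C placed along the local chain direction, O offset radially from C.
helixBackbone <- function(nres, chain, seqCodes, origin = c(0, 0, 0)) {
  i <- seq_len(nres)
  theta <- (i - 1) * 100 * pi / 180
  ca <- cbind(2.3 * cos(theta), 2.3 * sin(theta), 1.5 * (i - 1))
  # local chain direction (unit tangent along the trace)
  tangent <- rbind(ca[2, ] - ca[1, ],
                   if (nres > 2) ca[3:nres, ] - ca[1:(nres - 2), ]
                   else NULL,
                   ca[nres, ] - ca[nres - 1, ])
  tangent <- tangent / sqrt(rowSums(tangent^2))
  nPos <- ca - 1.46 * tangent
  cPos <- ca + 1.52 * tangent
  radial <- cbind(cos(theta), sin(theta), 0)
  oPos <- cPos + 1.23 * radial
  xyz <- rbind(nPos, ca, cPos, oPos)
  ord <- as.vector(t(matrix(seq_len(4 * nres), nres, 4)))  # N,CA,C,O per res
  xyz <- sweep(xyz[ord, ], 2, -origin)
  data.frame(chain = chain, resno = rep(i, each = 4), insert = "",
             resid = rep(seqCodes, each = 4),
             elety = rep(c("N", "CA", "C", "O"), nres),
             elesy = rep(c("N", "C", "C", "O"), nres),
             isHeavy = TRUE,
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             stringsAsFactors = FALSE)
}

#' Build the native complex of a synthetic specification
#'
#' Deterministic in (spec, seed): repeated calls return the identical
#' structure. The native is validated to be non-clashing (no intermolecular
#' heavy-atom pair under 2.5 Angstrom) and to carry at least 15
#' intermolecular contacts at 5 Angstrom.
#'
#' @param spec a [complexSpec()].
#' @return a [StructureModel-class] (chains A = receptor, B = ligand); its
#'   reference fingerprint is \code{contactFingerprint(makeNative(spec))}.
#' @export
makeNative <- function(spec) {
  stopifnot(inherits(spec, "complexSpec"))
  aa <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL")
  seqs <- withSeed(spec$seed, list(
    rec = sample(aa, spec$receptorLength, replace = TRUE),
    lig = sample(aa, spec$ligandLength, replace = TRUE)))
  recOffset <- (spec$receptorLength - spec$ligandLength) / 2 * 1.5
  atoms <- rbind(
    helixBackbone(spec$receptorLength, "A", seqs$rec),
    helixBackbone(spec$ligandLength, "B", seqs$lig,
                  origin = c(spec$axisSeparation, 0, recOffset)))
  m <- new("StructureModel", modelId = "native", atoms = atoms,
           partnerOf = c(A = "receptor", B = "ligand"))
  fp <- contactFingerprint(m)
  if (length(fp) < 15L)
    stop("native geometry yields only ", length(fp), " intermolecular ",
         "contacts (need >= 15); increase chain lengths or reduce ",
         "axisSeparation", call. = FALSE)
  a <- atoms(m)
  rec <- as.matrix(a[a$chain == "A", c("x", "y", "z")])
  lig <- as.matrix(a[a$chain == "B", c("x", "y", "z")])
  d2 <- outer(rowSums(rec^2), rowSums(lig^2), "+") - 2 * tcrossprod(rec, lig)
  if (min(d2) < 2.5^2)
    stop("native geometry clashes (closest intermolecular atoms ",
         sprintf("%.2f", sqrt(max(min(d2), 0))), " Angstrom)", call. = FALSE)
  m
}

#' Rigid pose anchor
#'
#' A family anchor transform: rotate the whole ligand rigidly about the
#' receptor center (axis/angle), optionally rotate the ligand about its own
#' centroid, then translate. Used to park decoy families at false
#' interfaces.
#'
#' @param aboutReceptorAxis,aboutReceptorAngle axis (3-vector) and angle
#'   (degrees) of a rotation of the ligand about the receptor centroid.
#' @param selfAxis,selfAngle axis and angle (degrees) of a rotation of the
#'   ligand about its own centroid.
#' @param translation 3-vector, Angstrom.
#' @return a list of class \code{"poseAnchor"}.
#' @export
poseAnchor <- function(aboutReceptorAxis = c(0, 0, 1),
                       aboutReceptorAngle = 0,
                       selfAxis = c(0, 0, 1), selfAngle = 0,
                       translation = c(0, 0, 0)) {
  structure(list(recAxis = aboutReceptorAxis,
                 recAngle = aboutReceptorAngle * pi / 180,
                 selfAxis = selfAxis, selfAngle = selfAngle * pi / 180,
                 translation = translation),
            class = "poseAnchor")
}

#' Decoy-ensemble recipe
#'
#' Describes a synthetic rigid-body decoy set: a near-native family (poses
#' perturbed around the native ligand placement), further anchored families
#' (false-interface pose clouds), and uniform random poses filling the
#' remainder. Fractions must sum to at most 1.
#'
#' @param nModels total number of models (>= 2).
#' @param nearNativeFraction fraction of near-native poses.
#' @param nearNativeSigmaTrans,nearNativeSigmaRot perturbation scales of the
#'   near-native family: per-axis Gaussian translation sigma (Angstrom) and
#'   rotation-angle sigma (degrees, uniform random axis).
#' @param families list of family descriptions, each a list with
#'   \code{name}, \code{anchor} (a [poseAnchor()]), \code{fraction},
#'   \code{sigmaTrans}, \code{sigmaRot}.
#' @param seed integer seed; all randomness flows through it.
#' @return a list of class \code{"ensembleRecipe"}.
#' @export
ensembleRecipe <- function(nModels = 200L, nearNativeFraction = 0.06,
                           nearNativeSigmaTrans = 0.8,
                           nearNativeSigmaRot = 4,
                           families = list(), seed = 1L) {
  stopifnot(nModels >= 2L)
  fr <- nearNativeFraction +
    sum(vapply(families, `[[`, numeric(1), "fraction"))
  if (fr > 1) stop("family fractions sum to ", fr, " (> 1)", call. = FALSE)
  structure(list(nModels = as.integer(nModels),
                 nearNativeFraction = nearNativeFraction,
                 nearNativeSigmaTrans = nearNativeSigmaTrans,
                 nearNativeSigmaRot = nearNativeSigmaRot,
                 families = families, seed = as.integer(seed)),
            class = "ensembleRecipe")
}

# random rotation: uniform axis, angle ~ N(0, sigma); sigma in radians
randomRotation <- function(sigma) {
  ax <- stats::rnorm(3)
  rotationMatrix(ax / sqrt(sum(ax^2)), stats::rnorm(1, 0, sigma))
}

# Translate a (re-oriented) ligand along direction u from the receptor
# center until its closest approach to the receptor equals `clearance`
# (bisection on the placement distance). Docked decoys touch the receptor:
# a floating pose is not a realistic scoring-set model.
placeTouching <- function(rec, lig, recCenter, u, clearance) {
  base <- recCenter - colMeans(lig)
  # pairwise offset vectors r_i - (s_j + base) as three matrices
  dx <- outer(rec[, 1], lig[, 1] + base[1], "-")
  dy <- outer(rec[, 2], lig[, 2] + base[2], "-")
  dz <- outer(rec[, 3], lig[, 3] + base[3], "-")
  A <- dx^2 + dy^2 + dz^2
  B <- dx * u[1] + dy * u[2] + dz * u[3]
  minDist <- function(d) sqrt(max(min(A - 2 * d * B + d * d), 0))
  loD <- 0; hiD <- 2 * (max(sqrt(rowSums(sweep(rec, 2, recCenter)^2))) +
                        max(sqrt(rowSums(sweep(lig, 2, colMeans(lig))^2))) +
                        clearance)
  for (it in 1:40) {
    mid <- (loD + hiD) / 2
    if (minDist(mid) < clearance) loD <- mid else hiD <- mid
  }
  sweep(lig, 2, -(base + u * hiD))
}

# apply an anchor + a random perturbation to the native ligand coordinates
poseLigand <- function(lig, recCenter, anchor, sigmaTrans, sigmaRot) {
  ligCenter <- colMeans(lig)
  out <- applyRigid(lig, rotationMatrix(anchor$selfAxis, anchor$selfAngle),
                    center = ligCenter)
  out <- applyRigid(out, rotationMatrix(anchor$recAxis, anchor$recAngle),
                    center = recCenter)
  out <- sweep(out, 2, -anchor$translation)
  # random perturbation about the (moved) ligand centroid
  out <- applyRigid(out, randomRotation(sigmaRot * pi / 180),
                    t = stats::rnorm(3, 0, sigmaTrans),
                    center = colMeans(out))
  out
}

#' Generate a synthetic decoy ensemble with ground truth
#'
#' Every model shares the native receptor; the ligand of each model is
#' placed by its family's anchor transform composed with a small random
#' perturbation (uniform-axis rotation with Gaussian angle, Gaussian
#' translation). Unassigned models get uniform random poses: a random
#' orientation, parked in a random direction at receptor-contact range. The
#' truth table records each model's family and its CAPRI quality against
#' the native (computed with [evaluateEnsemble()]).
#'
#' @param native the native [StructureModel-class] from [makeNative()].
#' @param recipe an [ensembleRecipe()].
#' @return list with \code{ensemble} (a harmonized [ModelEnsemble-class],
#'   models named \code{model_0001}...) and \code{truth} (data.frame:
#'   \code{model_id}, \code{family}, \code{fnat}, \code{lrmsd},
#'   \code{class}).
#' @export
makeEnsemble <- function(native, recipe) {
  stopifnot(inherits(recipe, "ensembleRecipe"))
  a <- atoms(native)
  recRows <- which(partnerMap(native)[a$chain] == "receptor")
  ligRows <- which(partnerMap(native)[a$chain] == "ligand")
  rec <- as.matrix(a[recRows, c("x", "y", "z")])
  lig <- as.matrix(a[ligRows, c("x", "y", "z")])
  recCenter <- colMeans(rec)

  n <- recipe$nModels
  counts <- c(nearNative = round(recipe$nearNativeFraction * n),
              vapply(recipe$families, function(f) round(f$fraction * n),
                     numeric(1)))
  if (sum(counts) > n) counts[which.max(counts)] <-
      counts[which.max(counts)] - (sum(counts) - n)
  famNames <- c("nearNative",
                vapply(recipe$families, `[[`, character(1), "name"))
  assignment <- c(rep(famNames, counts),
                  rep("random", n - sum(counts)))

  identityAnchor <- poseAnchor()
  mods <- withSeed(recipe$seed, lapply(seq_len(n), function(i) {
    fam <- assignment[i]
    ligXyz <- if (fam == "nearNative") {
      poseLigand(lig, recCenter, identityAnchor,
                 recipe$nearNativeSigmaTrans, recipe$nearNativeSigmaRot)
    } else if (fam == "random") {
      # uniform pose over the receptor's lateral surface: random azimuth,
      # axial slide, ligand spin about its own axis plus a small tilt --
      # rigid-body decoys pack against the receptor like docked poses
      phi <- stats::runif(1, 0, 2 * pi)
      u <- c(cos(phi), sin(phi), 0)
      spun <- applyRigid(lig, rotationMatrix(c(0, 0, 1),
                                             stats::runif(1, 0, 2 * pi)),
                         center = colMeans(lig))
      tiltAx <- c(stats::rnorm(2), 0)
      spun <- applyRigid(spun,
                         rotationMatrix(tiltAx / sqrt(sum(tiltAx^2)),
                                        stats::rnorm(1, 0, 10 * pi / 180)),
                         center = colMeans(spun))
      slide <- recCenter + c(0, 0, stats::runif(1, -15, 15))
      placeTouching(rec, spun, slide, u, stats::runif(1, 2.6, 3.6))
    } else {
      f <- recipe$families[[match(fam, famNames) - 1L]]
      poseLigand(lig, recCenter, f$anchor, f$sigmaTrans, f$sigmaRot)
    }
    newAtoms <- a
    newAtoms[ligRows, c("x", "y", "z")] <- ligXyz
    new("StructureModel", modelId = sprintf("model_%04d", i),
        atoms = newAtoms, partnerOf = partnerMap(native))
  }))
  ensemble <- new("ModelEnsemble", models = mods, harmonized = TRUE)
  evalDf <- evaluateEnsemble(ensemble, native)
  truth <- data.frame(model_id = evalDf$model_id, family = assignment,
                      fnat = evalDf$fnat, lrmsd = evalDf$lrmsd,
                      class = evalDf$class, stringsAsFactors = FALSE)
  list(ensemble = ensemble, truth = truth)
}

#' Write a synthetic ensemble and its truth table to disk
#'
#' @param sim the list returned by [makeEnsemble()] or [t50Scenario()].
#' @param dir output directory: one PDB per model plus \code{truth.tsv}.
#' @return invisibly, \code{dir}.
#' @export
writeSimulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeEnsemble(sim$ensemble, dir)
  utils::write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' The false-consensus ("T50-like") scenario
#'
#' The worst case for pure consensus scoring: a dominant family of decoys
#' shares a false interface (about 40% of the ensemble, parked on the
#' opposite side of the receptor), flanked by two smaller false-interface
#' families, while only a small near-native family (6%) points to the true
#' interface. The remainder are uniform random poses. Pure CONSRANK is
#' dragged to the false consensus; maxclust Clust-CONSRANK can still reach
#' the near-native cluster.
#'
#' @param seed integer seed.
#' @param nModels ensemble size; default 600.
#' @return list with \code{ensemble}, \code{truth} (see [makeEnsemble()])
#'   and \code{native} (the reference [StructureModel-class]).
#' @export
t50Scenario <- function(seed, nModels = 600L) {
  spec <- complexSpec(seed = 1L)   # the complex is fixed; seed moves poses
  native <- makeNative(spec)
  recipe <- ensembleRecipe(
    nModels = nModels,
    nearNativeFraction = 0.06,
    nearNativeSigmaTrans = 0.8, nearNativeSigmaRot = 4,
    families = list(
      list(name = "falseDominant",   # a tight false consensus: its members
           # share their (wrong) interface contacts, so sub-residue jitter
           anchor = poseAnchor(aboutReceptorAngle = 180),
           fraction = 0.40, sigmaTrans = 0.4, sigmaRot = 2),
      list(name = "falseSecondary",
           anchor = poseAnchor(aboutReceptorAngle = 90),
           fraction = 0.15, sigmaTrans = 0.8, sigmaRot = 4),
      list(name = "falseTertiary",
           anchor = poseAnchor(aboutReceptorAngle = 270),
           fraction = 0.10, sigmaTrans = 0.8, sigmaRot = 4)),
    seed = seed)
  sim <- makeEnsemble(native, recipe)
  c(sim, list(native = native))
}
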