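#' @include AllClasses.R
NULL

# Residue key: "chain:resno" plus insertion code when present ("A:52B").
makeResidueKey <- function(chain, resno, insert) {
  ins <- ifelse(is.na(insert) | insert == " ", "", insert)
  paste0(chain, ":", resno, ins)
}

#' Residue keys of a model
#'
#' Returns the residue key (\code{"chain:resno[insert]"}) of every atom of a
#' [StructureModel-class], in atom order. Unique keys identify residues.
#'
#' @param model a [StructureModel-class].
#' @return character vector, one element per atom.
#' @export
residueKeys <- function(model) {
  a <- atoms(model)
  makeResidueKey(a$chain, a$resno, a$insert)
}

# Split a contact key "rkey|lkey" into its residue keys.
splitContactKey <- function(keys) {
  parts <- strsplit(keys, "|", fixed = TRUE)
  list(receptor = vapply(parts, `[[`, character(1), 1L),
       ligand = vapply(parts, `[[`, character(1), 2L))
}

# Evaluate `expr` under a fixed RNG state, restoring the caller's state.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Rotation matrix for angle (radians) about unit axis (Rodrigues).
rotationMatrix <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# Apply rotation R about `center` then translation `t` to an n x 3 matrix.
applyRigid <- function(xyz, R = diag(3), t = c(0, 0, 0),
                       center = c(0, 0, 0)) {
  sweep(sweep(xyz, 2, center) %*% t(R), 2, -(center + t))
}

# Condensed-vector index of pair (i, j), i < j, in stats::dist layout.
condensedIndex <- function(i, j, n) {
  n * (i - 1) - i * (i - 1) / 2 + j - i
}

# Expand a CondensedDistances object to a full symmetric matrix.
distanceMatrix <- function(dist) {
  stopifnot(is(dist, "CondensedDistances"))
  n <- length(dist@labels)
  d <- structure(dist@values, Size = n, Labels = dist@labels,
                 Diag = FALSE, Upper = FALSE, class = "dist")
  as.matrix(d)
}

# One-letter amino-acid code from 3-letter, X for anything unknown.
aa321 <- function(resid) {
  tab <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
           GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
           LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
           SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V",
           MSE = "M")
  out <- tab[toupper(resid)]
  out[is.na(out)] <- "X"
  unname(out)
}

# Element symbol from a PDB atom name when the element column is blank,
# e.g. " CA " -> C, "1HB " -> H.
elementFromName <- function(elety) {
  nm <- gsub("[0-9' ]", "", elety)
  substr(nm, 1, 1)
}
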