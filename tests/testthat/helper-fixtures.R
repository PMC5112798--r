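# Programmatic fixtures: tiny structures and fingerprints built in code.

# A minimal StructureModel from per-residue CA-like positions.
# residues: data.frame(chain, resno, x, y, z) with optional insert, resid,
# elety, elesy columns.
toyModel <- function(residues, modelId = "toy", partnerOf = NULL) {
  df <- data.frame(
    chain = residues$chain,
    resno = as.integer(residues$resno),
    insert = if ("insert" %in% names(residues)) residues$insert else "",
    resid = if ("resid" %in% names(residues)) residues$resid else "ALA",
    elety = if ("elety" %in% names(residues)) residues$elety else "CA",
    elesy = if ("elesy" %in% names(residues)) residues$elesy else "C",
    x = residues$x, y = residues$y, z = residues$z,
    stringsAsFactors = FALSE)
  df$isHeavy <- !(df$elesy %in% c("H", "D"))
  m <- new("StructureModel", modelId = modelId, atoms = df,
           partnerOf = if (is.null(partnerOf)) character() else partnerOf)
  if (is.null(partnerOf)) m <- assignPartners(m)
  m
}

# Random fingerprints over a small synthetic contact universe.
randomFingerprints <- function(n, universeSize = 40, lambda = 12,
                               prefix = "m") {
  universe <- paste0("A:", rep(1:8, each = 5), "|B:", rep(1:5, times = 8))
  universe <- universe[seq_len(universeSize)]
  lapply(seq_len(n), function(i) {
    k <- min(max(stats::rpois(1, lambda), 0), universeSize)
    fingerprint(sprintf("%s%03d", prefix, i), sample(universe, k))
  })
}

# Random condensed distance object (integer-valued by default, so ties are
# frequent, exercising the deterministic tie-break).
randomDistances <- function(n, integerValued = TRUE, maxValue = 12) {
  v <- if (integerValued) sample.int(maxValue, n * (n - 1) / 2, replace = TRUE)
       else stats::runif(n * (n - 1) / 2, 0.5, 20)
  new("CondensedDistances", values = as.numeric(v),
      labels = sprintf("m%03d", seq_len(n)), metric = "contact_hamming")
}

# Write a raw PDB ATOM line with fixed columns.
pdbAtomLine <- function(serial, name, resn, chain, resno, x, y, z,
                        occ = 1, b = 0, element = "C", alt = " ") {
  sprintf("ATOM  %5d %-4s%s%-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name, alt, resn, chain, resno, x, y, z, occ, b, element)
}

# rigid transform applied to a whole model (for invariance tests)
transformModel <- function(model, axis = c(1, 2, 3), angle = 0.7,
                           shift = c(5, -3, 2), id = paste0(modelId(model), "_t")) {
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
  a <- atoms(model)
  xyz <- sweep(as.matrix(a[, c("x", "y", "z")]) %*% t(R), 2, shift, "+")
  a[, c("x", "y", "z")] <- xyz
  new("StructureModel", modelId = id, atoms = a,
      partnerOf = partnerMap(model))
}

# a small simulated ensemble shared by several test files
smallScenario <- function(seed = 11, nModels = 80) {
  t50Scenario(seed = seed, nModels = nModels)
}
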