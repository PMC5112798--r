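# Independent oracle implementations used to cross-check the package.
# These deliberately share no code with the implementation under test.

# --- naive O(n^3) agglomerative clustering oracle -------------------------
# Maintains explicit member lists and recomputes every cluster-pair distance
# from the original matrix at every step. Tie-break: among minimal pairs,
# lowest (i, j) lexicographically, where i < j are the clusters' smallest
# original members. Returns the merge sequence as canonical member sets.
oracleLinkage <- function(D, method) {
  n <- nrow(D)
  cl <- lapply(seq_len(n), function(i) i)
  steps <- vector("list", n - 1L)
  for (s in seq_len(n - 1L)) {
    bestD <- Inf; bestI <- Inf; bestJ <- Inf; bestA <- 0L; bestB <- 0L
    for (a in seq_along(cl)) {
      for (b in seq_along(cl)) {
        if (a >= b) next
        sub <- D[cl[[a]], cl[[b]], drop = FALSE]
        d <- if (method == "single") min(sub) else max(sub)
        i <- min(min(cl[[a]]), min(cl[[b]]))
        j <- max(min(cl[[a]]), min(cl[[b]]))
        if (d < bestD - 1e-9 ||
            (abs(d - bestD) <= 1e-9 &&
             (i < bestI || (i == bestI && j < bestJ)))) {
          bestD <- d; bestI <- i; bestJ <- j; bestA <- a; bestB <- b
        }
      }
    }
    merged <- sort(c(cl[[bestA]], cl[[bestB]]))
    steps[[s]] <- list(members = merged, height = bestD)
    cl[[bestA]] <- merged
    cl[[bestB]] <- NULL
  }
  steps
}

# Member sets formed at each merge of a package LinkageTree, for comparison
# with the oracle's steps.
treeMergeSteps <- function(tree) {
  mg <- tree@merge
  h <- mergeHeights(tree)
  members <- vector("list", nrow(mg))
  for (k in seq_len(nrow(mg))) {
    mem <- function(x) if (x < 0) -x else members[[x]]
    members[[k]] <- sort(c(mem(mg[k, 1]), mem(mg[k, 2])))
  }
  lapply(seq_len(nrow(mg)), function(k)
    list(members = members[[k]], height = h[k]))
}

# Flat partition after the oracle's first k merges (vector of cluster ids).
oracleFlat <- function(steps, n, k) {
  lab <- seq_len(n)
  for (s in seq_len(k)) {
    m <- steps[[s]]$members
    lab[lab %in% lab[m]] <- min(lab[m])
  }
  match(lab, unique(lab))
}

# --- graph connected components at threshold t ----------------------------
componentsAtThreshold <- function(D, t) {
  n <- nrow(D)
  lab <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        if (D[i, j] <= t && lab[i] != lab[j]) {
          lab[lab == max(lab[i], lab[j])] <- min(lab[i], lab[j])
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  match(lab, unique(lab))
}

# partitions equal up to relabeling
samePartition <- function(a, b) {
  length(a) == length(b) &&
    identical(match(a, unique(a)), match(b, unique(b)))
}

# --- brute-force consensus scoring oracle ---------------------------------
# Naive frequency counting over plain character vectors + sort.
oracleConsrank <- function(contactSets) {
  allKeys <- unlist(contactSets, use.names = FALSE)
  freq <- table(allKeys) / length(contactSets)
  scores <- vapply(contactSets, function(ks) {
    if (!length(ks)) return(0)
    mean(as.numeric(freq[ks]))
  }, numeric(1))
  ord <- order(-scores, names(contactSets))
  data.frame(model_id = names(contactSets)[ord],
             score = unname(scores[ord]), stringsAsFactors = FALSE)
}

# --- independent greedy redundancy-removal oracle -------------------------
oracleRedundancy <- function(contactSets, threshold, limit = 10L) {
  rk <- oracleConsrank(contactSets)
  ids <- rk$model_id
  ham <- function(a, b) length(setdiff(a, b)) + length(setdiff(b, a))
  picked <- character(0)
  discarded <- character(0)
  for (id in ids) {
    if (id %in% discarded) next
    picked <- c(picked, id)
    if (length(picked) >= limit) break
    for (other in setdiff(ids, c(picked, discarded))) {
      if (ham(contactSets[[id]], contactSets[[other]]) <= threshold)
        discarded <- c(discarded, other)
    }
  }
  picked
}

# --- quaternion (Horn) absolute-orientation oracle ------------------------
# Optimal rotation superposing `mobile` onto `fixed` (n x 3 matrices),
# computed from the largest eigenvector of the 4x4 quaternion matrix.
hornSuperpose <- function(fixed, mobile) {
  cf <- colMeans(fixed); cm <- colMeans(mobile)
  A <- sweep(mobile, 2, cm); B <- sweep(fixed, 2, cf)
  S <- t(A) %*% B
  N <- matrix(0, 4, 4)
  N[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
  N[1, 2] <- N[2, 1] <- S[2, 3] - S[3, 2]
  N[1, 3] <- N[3, 1] <- S[3, 1] - S[1, 3]
  N[1, 4] <- N[4, 1] <- S[1, 2] - S[2, 1]
  N[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  N[2, 3] <- N[3, 2] <- S[1, 2] + S[2, 1]
  N[2, 4] <- N[4, 2] <- S[3, 1] + S[1, 3]
  N[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  N[3, 4] <- N[4, 3] <- S[2, 3] + S[3, 2]
  N[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  q <- eigen(N, symmetric = TRUE)$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    w^2 + x^2 - y^2 - z^2, 2 * (x * y - w * z),   2 * (x * z + w * y),
    2 * (x * y + w * z),   w^2 - x^2 + y^2 - z^2, 2 * (y * z - w * x),
    2 * (x * z - w * y),   2 * (y * z + w * x),   w^2 - x^2 - y^2 + z^2),
    3, 3, byrow = TRUE)
  list(apply = function(xyz) sweep(sweep(xyz, 2, cm) %*% t(R), 2, -cf))
}

# ligand RMSD computed entirely through the quaternion oracle
oracleLigandRmsd <- function(model, reference) {
  bb <- function(m, role) {
    a <- atoms(m)
    sel <- partnerMap(m)[a$chain] == role & a$elety %in% c("N", "CA", "C", "O")
    sub <- a[sel, ]
    key <- paste(sub$chain, sub$resno, sub$insert, sub$elety)
    list(key = key, xyz = as.matrix(sub[, c("x", "y", "z")]))
  }
  rm_ <- bb(model, "receptor"); rr <- bb(reference, "receptor")
  lm <- bb(model, "ligand"); lr <- bb(reference, "ligand")
  sh <- intersect(rm_$key, rr$key); sl <- intersect(lm$key, lr$key)
  fit <- hornSuperpose(rr$xyz[match(sh, rr$key), ],
                       rm_$xyz[match(sh, rm_$key), ])
  moved <- fit$apply(lm$xyz[match(sl, lm$key), ])
  sqrt(mean(rowSums((moved - lr$xyz[match(sl, lr$key), ])^2)))
}

# --- brute-force all-pairs contact detection ------------------------------
oracleContacts <- function(model, cutoff = 5.0) {
  a <- atoms(model)
  role <- partnerMap(model)[a$chain]
  rec <- a[role == "receptor" & a$isHeavy, ]
  lig <- a[role == "ligand" & a$isHeavy, ]
  out <- character(0)
  for (i in seq_len(nrow(rec))) {
    for (j in seq_len(nrow(lig))) {
      d <- sqrt((rec$x[i] - lig$x[j])^2 + (rec$y[i] - lig$y[j])^2 +
                  (rec$z[i] - lig$z[j])^2)
      if (d <= cutoff) {
        ri <- paste0(rec$chain[i], ":", rec$resno[i],
                     ifelse(rec$insert[i] == "", "", rec$insert[i]))
        lj <- paste0(lig$chain[j], ":", lig$resno[j],
                     ifelse(lig$insert[j] == "", "", lig$insert[j]))
        out <- c(out, paste0(ri, "|", lj))
      }
    }
  }
  sort(unique(out))
}
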