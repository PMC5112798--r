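#' @include AllClasses.R contacts.R
NULL

#' CONSRANK score of one model
#'
#' The consensus score of a model is the mean conservation frequency of its
#' contacts: models matching the ensemble's most conserved contacts score
#' highest. A model with no contacts scores 0 (no consensus evidence).
#'
#' @param fp a [ContactFingerprint-class].
#' @param profile the [ConservationProfile-class] of the ensemble the model
#'   belongs to.
#' @param normalize \code{"mean"} (default: mean frequency of the model's
#'   contacts) or \code{"sum"} (raw summed frequency, biased toward large
#'   interfaces).
#' @return list with \code{model_id}, \code{score} (in [0, 1] for
#'   \code{"mean"}) and \code{n_contacts}.
#' @export
scoreModel <- function(fp, profile, normalize = c("mean", "sum")) {
  normalize <- match.arg(normalize)
  keys <- contacts(fp)
  if (!length(keys))
    return(list(model_id = modelId(fp), score = 0, n_contacts = 0L))
  f <- contactFrequency(profile)
  idx <- match(keys, names(f))
  if (anyNA(idx))
    stop("fingerprint '", modelId(fp), "' has contacts outside the profile ",
         "universe (profile/ensemble mismatch): e.g. ",
         keys[which(is.na(idx))[1]], call. = FALSE)
  s <- if (normalize == "mean") mean(f[idx]) else sum(f[idx])
  list(model_id = modelId(fp), score = unname(s), n_contacts = length(keys))
}

#' CONSRANK ranking of an ensemble
#'
#' Builds the conservation profile from the given fingerprints, scores every
#' model by mean contact conservation, and sorts best-first. Ties are broken
#' lexicographically by model id, so the ranking is deterministic and
#' invariant to input order.
#'
#' @param fingerprints list of [ContactFingerprint-class] objects.
#' @param profile optionally, a precomputed [ConservationProfile-class]
#'   built from these same fingerprints.
#' @param normalize see [scoreModel()].
#' @return data.frame with columns \code{rank}, \code{model_id},
#'   \code{score}, \code{n_contacts}, ordered best first.
#' @examples
#' fps <- list(fingerprint("A", c("r1|l1", "r1|l2")),
#'             fingerprint("B", "r1|l1"),
#'             fingerprint("C", "r2|l1"))
#' rankEnsemble(fps)
#' @export
rankEnsemble <- function(fingerprints, profile = NULL,
                         normalize = c("mean", "sum")) {
  normalize <- match.arg(normalize)
  if (!length(fingerprints)) stop("empty fingerprint list", call. = FALSE)
  if (is.null(profile)) profile <- conservationProfile(fingerprints)
  rows <- lapply(fingerprints, scoreModel, profile = profile,
                 normalize = normalize)
  df <- data.frame(model_id = vapply(rows, `[[`, character(1), "model_id"),
                   score = vapply(rows, `[[`, numeric(1), "score"),
                   n_contacts = vapply(rows, `[[`, integer(1), "n_contacts"),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$score, df$model_id), , drop = FALSE]
  df <- data.frame(rank = seq_len(nrow(df)), df, row.names = NULL)
  df
}

#' Top-n model ids of a ranking
#'
#' @param ranking a ranking data.frame from [rankEnsemble()].
#' @param n number of models to keep; default 10 (the CAPRI submission
#'   limit).
#' @return character vector of the first \code{min(n, nrow)} model ids.
#' @export
topModels <- function(ranking, n = 10L) {
  stopifnot(n >= 1L)
  utils::head(ranking$model_id, n)
}

#' Write a ranking to TSV
#'
#' @param ranking data.frame from [rankEnsemble()].
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeRanking <- function(ranking, path) {
  utils::write.table(ranking, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
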