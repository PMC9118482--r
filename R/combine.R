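#' @include AllClasses.R evaluate.R
NULL

#' Fit min-max normalization for the two binding-propensity tracks
#'
#' Pools all residues of the supplied records (intended to be the training
#' split only) and records, per input track, the minimum and maximum of the
#' task's propensities. Normalization is global (fitted over the pooled
#' training residues, not per protein) so that both tracks end up on a
#' common \[0, 1\] scale.
#'
#' @param ds a [TrackDataset-class] of training records.
#' @param task `"dna"` or `"rna"`.
#' @return list with `task` and per-track elements `disorder_trained` and
#'   `structure_trained`, each `c(min, max)` with attribute `degenerate`
#'   when min equals max.
#' @export
fitNormalizer <- function(ds, task) {
  pool <- function(key) {
    v <- unlist(lapply(records(ds),
                       function(r) r@predictions[[key]]), use.names = FALSE)
    v <- v[!is.na(v)]
    if (!length(v)) stop("no residues with track ", key, " in training pool")
    out <- c(min = min(v), max = max(v))
    attr(out, "degenerate") <- out[1] == out[2]
    out
  }
  list(task = task,
       disorder_trained = pool(paste0(task, "_disorder_trained")),
       structure_trained = pool(paste0(task, "_structure_trained")))
}

#' Apply min-max normalization to a score track
#'
#' `(x - min) / (max - min)`, clipped to \[0, 1\]. Degenerate parameters
#' (constant training track) map every value to 0.5 by convention.
#'
#' @param scores numeric per-residue values.
#' @param params `c(min, max)` as one element of [fitNormalizer()] output.
#' @return normalized values in \[0, 1\] (`NA` propagates).
#' @export
applyNormalizer <- function(scores, params) {
  lo <- unname(params[1])
  hi <- unname(params[2])
  if (hi <= lo) return(ifelse(is.na(scores), NA_real_, 0.5))
  pmin(1, pmax(0, (scores - lo) / (hi - lo)))
}

#' Element-wise consensus of two normalized tracks
#'
#' @param a,b normalized per-residue tracks of equal length.
#' @param mode `"min"`, `"max"` or `"avg"` (arithmetic mean).
#' @return combined track.
#' @export
consensusCombine <- function(a, b, mode = c("min", "max", "avg")) {
  mode <- match.arg(mode)
  if (length(a) != length(b)) stop("track length mismatch")
  switch(mode, min = pmin(a, b), max = pmax(a, b), avg = (a + b) / 2)
}

## Windowed design matrix: row i holds a[i-h..i+h] then b[i-h..i+h],
## zero-padded past the termini (0 is the "no binding evidence" floor of the
## normalized scale).
.windowMatrix <- function(a, b, w) {
  stopifnot(w %% 2L == 1L)
  n <- length(a)
  h <- (w - 1L) %/% 2L
  shift <- function(x, o) {
    idx <- seq_len(n) + o
    out <- numeric(n)
    ok <- idx >= 1L & idx <= n
    out[ok] <- x[idx[ok]]
    out
  }
  cols <- c(lapply(-h:h, function(o) shift(a, o)),
            lapply(-h:h, function(o) shift(b, o)))
  do.call(cbind, cols)
}

#' Sliding-window feature vector for one residue
#'
#' Concatenates the two normalized input tracks over a window of `w`
#' residues centred on residue `i` (1-based): first the disorder-trained
#' half, then the structure-trained half, each ordered left to right.
#' Positions outside the sequence are padded with 0. The vector length is
#' exactly `2 * w`.
#'
#' @param a,b normalized per-residue tracks of equal length.
#' @param i 1-based residue index.
#' @param w odd window size.
#' @return numeric feature vector of length `2 * w`.
#' @export
windowFeatures <- function(a, b, i, w) {
  if (w %% 2L != 1L) stop("window size must be odd")
  stopifnot(length(a) == length(b), i >= 1L, i <= length(a))
  .windowMatrix(a, b, w)[i, ]
}

#' Binarize scores at a fixed false positive rate
#'
#' Chooses the smallest candidate threshold `t` (among the reference scores)
#' such that the fraction of reference negatives with score `>= t` does not
#' exceed `fprCap`, then calls positive every score `>= t`. When even the
#' largest reference score exceeds the cap, the threshold is `Inf` (nothing
#' called).
#'
#' @param scores numeric scores to binarize.
#' @param refLabels,refScores reference pool defining the negative score
#'   distribution (e.g. from [poolResidues()]).
#' @param fprCap false positive rate cap, typically 0.2 or 0.3.
#' @return list with logical `calls` and the numeric `threshold`.
#' @export
binarizeAtFpr <- function(scores, refLabels, refScores, fprCap) {
  stopifnot(length(refLabels) == length(refScores), fprCap >= 0, fprCap <= 1)
  neg <- refScores[refLabels == 0L]
  if (!length(neg)) stop("reference pool contains no negatives")
  cand <- sort(unique(refScores))
  nNeg <- length(neg)
  ## fraction of negatives at or above each candidate threshold
  fpr <- vapply(cand, function(t) sum(neg >= t) / nNeg, numeric(1))
  ok <- which(fpr <= fprCap)
  thr <- if (length(ok)) cand[ok[1]] else Inf
  list(calls = scores >= thr, threshold = thr)
}
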