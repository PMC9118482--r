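#' @include AllClasses.R
NULL

## Rank-based AUC; equals the Mann-Whitney pair statistic
## (#concordant + 0.5 #tied) / (n_pos * n_neg), with midranks handling ties.
.aucFast <- function(labels, scores) {
  pos <- labels == 1L
  nP <- sum(pos)
  nN <- sum(!pos)
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - nP * (nP + 1) / 2) / (nP * nN)
}

#' Area under the ROC curve
#'
#' Computed via midranks, which equals the Mann-Whitney pair statistic:
#' (number of positive/negative pairs where the positive outscores the
#' negative, plus half the tied pairs) divided by the number of pairs. It is
#' therefore invariant under strictly increasing transforms of the scores.
#'
#' @param labels binary vector (1 = positive, 0 = negative).
#' @param scores numeric scores, higher meaning more positive.
#' @return AUC in \[0, 1\].
#' @examples
#' aucScore(c(1, 1, 0, 0), c(0.8, 0.3, 0.6, 0.1))  # 0.75
#' @export
aucScore <- function(labels, scores) {
  stopifnot(length(labels) == length(scores))
  if (anyNA(labels) || anyNA(scores)) stop("NA in labels or scores")
  if (!any(labels == 1L) || !any(labels == 0L))
    stop("both classes must be present")
  .aucFast(labels, scores)
}

#' Step-function ROC curve
#'
#' One operating point per distinct score plus the degenerate extreme
#' (threshold above all scores), under the rule "predicted positive iff
#' score >= threshold" and no interpolation. The trapezoidal area under the
#' step curve equals [aucScore()] (ties contribute half credit through the
#' sloped tie segments).
#'
#' @inheritParams aucScore
#' @return a [RocCurve-class].
#' @export
rocCurve <- function(labels, scores) {
  stopifnot(length(labels) == length(scores))
  if (!any(labels == 1L) || !any(labels == 0L))
    stop("both classes must be present")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  l <- labels[o]
  nP <- sum(l == 1L)
  nN <- sum(l == 0L)
  idx <- cumsum(rle(s)$lengths)  # last index of each distinct score
  tpr <- cumsum(l == 1L)[idx] / nP
  fpr <- cumsum(l == 0L)[idx] / nN
  pts <- data.frame(threshold = c(Inf, s[idx]),
                    fpr = c(0, fpr), tpr = c(0, tpr))
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) +
                                utils::tail(pts$tpr, -1)) / 2)
  new("RocCurve", points = pts, auc = auc)
}

#' Sensitivity at a fixed false positive rate
#'
#' The maximal true positive rate over operating points whose FPR does not
#' exceed `cap` (step semantics, no interpolation), together with the
#' threshold that attains it. Monotone non-decreasing in `cap`.
#'
#' @param curve a [RocCurve-class].
#' @param cap FPR cap in \[0, 1\].
#' @return list with elements `tpr` and `threshold`.
#' @export
sensitivityAtFpr <- function(curve, cap) {
  stopifnot(cap >= 0, cap <= 1)
  pts <- curve@points
  ok <- pts$fpr <= cap
  best <- max(pts$tpr[ok])
  thr <- max(pts$threshold[ok & pts$tpr == best])
  list(tpr = best, threshold = thr)
}

#' Specificity at a fixed true positive rate
#'
#' The maximal specificity (1 - FPR) over operating points whose TPR is at
#' least `floor`, with the attaining threshold. Monotone non-increasing in
#' `floor`.
#'
#' @param curve a [RocCurve-class].
#' @param floor TPR floor in \[0, 1\].
#' @return list with elements `specificity` and `threshold`.
#' @export
specificityAtTpr <- function(curve, floor) {
  stopifnot(floor >= 0, floor <= 1)
  pts <- curve@points
  ok <- pts$tpr >= floor
  spec <- 1 - pts$fpr
  best <- max(spec[ok])
  thr <- max(pts$threshold[ok & spec == best])
  list(specificity = best, threshold = thr)
}

## ---- residue pooling -------------------------------------------------------

.taskTrack <- function(task) paste0(task, "_binding")

## Per-record residue labels for a task under the pooling convention:
## binding proteins contribute their labeled residues (1 = binding,
## 0 = non-binding, NA excluded); non-NA-binding proteins contribute all
## residues as negatives; other proteins contribute nothing (NULL).
.recordPoolLabels <- function(rec, task) {
  cls <- rec@bindingClass
  if (cls == .taskTrack(task)) {
    lab <- rec@labels[[.taskTrack(task)]]
    if (is.null(lab))
      stop("record ", rec@id, ": binding class without ", .taskTrack(task),
           " track")
    return(lab)
  }
  if (cls == "non_na_binding") return(rep(0L, seqLength(rec)))
  NULL
}

#' Per-record binding scores for a given score source
#'
#' Resolves a score selector to a per-residue numeric track:
#' `"disorder_trained"` and `"structure_trained"` return the raw input
#' propensity tracks; `"min"`, `"max"` and `"avg"` return the consensus of
#' the two tracks after min-max normalization (requires `norm`); `"meta"`
#' returns the stored meta track when present, otherwise predicts with
#' `model`.
#'
#' @param rec a [ProteinRecord-class].
#' @param task `"dna"` or `"rna"`.
#' @param source score selector (see Description).
#' @param norm normalization parameters from [fitNormalizer()] (consensus
#'   sources only).
#' @param model a [MetaModel-class] (meta source only, when the record has
#'   no stored meta track).
#' @return numeric per-residue score track.
#' @export
recordScores <- function(rec, task,
                         source = c("disorder_trained", "structure_trained",
                                    "min", "max", "avg", "meta"),
                         norm = NULL, model = NULL) {
  source <- match.arg(source)
  p <- rec@predictions
  dtr <- p[[paste0(task, "_disorder_trained")]]
  str <- p[[paste0(task, "_structure_trained")]]
  if (source == "disorder_trained") {
    if (is.null(dtr)) stop("record ", rec@id, ": missing disorder-trained track")
    return(dtr)
  }
  if (source == "structure_trained") {
    if (is.null(str)) stop("record ", rec@id, ": missing structure-trained track")
    return(str)
  }
  if (source == "meta") {
    mt <- p[[paste0(task, "_meta")]]
    if (!is.null(mt)) return(mt)
    if (is.null(model)) stop("meta source needs a stored meta track or a model")
    return(predictMeta(model, rec))
  }
  if (is.null(norm)) stop("consensus source '", source, "' needs norm params")
  if (is.null(dtr) || is.null(str))
    stop("record ", rec@id, ": missing input track for consensus")
  a <- applyNormalizer(dtr, norm$disorder_trained)
  b <- applyNormalizer(str, norm$structure_trained)
  consensusCombine(a, b, source)
}

#' Pool residues across proteins for evaluation
#'
#' Positives are the task-binding residues of task-binding proteins;
#' negatives are the non-binding residues of those proteins plus all
#' residues of non-nucleic-acid-binding proteins. Residues with unknown
#' binding labels are excluded; proteins of other classes contribute
#' nothing.
#'
#' @param ds a [TrackDataset-class].
#' @param task `"dna"` or `"rna"`.
#' @inheritParams recordScores
#' @return list with binary `labels` and numeric `scores`, pooled across
#'   proteins.
#' @export
poolResidues <- function(ds, task, source = "disorder_trained",
                         norm = NULL, model = NULL) {
  labs <- list()
  scs <- list()
  for (rec in records(ds)) {
    lab <- .recordPoolLabels(rec, task)
    if (is.null(lab)) next
    sc <- recordScores(rec, task, source, norm = norm, model = model)
    keep <- !is.na(lab) & !is.na(sc)
    labs[[length(labs) + 1L]] <- lab[keep]
    scs[[length(scs) + 1L]] <- sc[keep]
  }
  labels <- unlist(labs, use.names = FALSE)
  scores <- unlist(scs, use.names = FALSE)
  if (is.null(labels) || !any(labels == 1L))
    stop("no positive residues pooled for task ", task)
  if (!any(labels == 0L)) stop("no negative residues pooled for task ", task)
  list(labels = as.integer(labels), scores = as.numeric(scores))
}

.METRICS <- c("auc", "sens_fpr_0.2", "sens_fpr_0.3",
              "spec_tpr_0.4", "spec_tpr_0.5")

.metricValue <- function(labels, scores, metric) {
  if (metric == "auc") return(.aucFast(labels, scores))
  curve <- rocCurve(labels, scores)
  switch(metric,
         "sens_fpr_0.2" = sensitivityAtFpr(curve, 0.2)$tpr,
         "sens_fpr_0.3" = sensitivityAtFpr(curve, 0.3)$tpr,
         "spec_tpr_0.4" = specificityAtTpr(curve, 0.4)$specificity,
         "spec_tpr_0.5" = specificityAtTpr(curve, 0.5)$specificity,
         stop("unknown metric: ", metric))
}

#' Evaluation report for a set of score sources
#'
#' Computes the threshold-standardized metric suite (AUC, sensitivity at
#' FPR 0.2 and 0.3, specificity at TPR 0.4 and 0.5) for each requested
#' score source on the pooled residues of a dataset.
#'
#' @param ds a [TrackDataset-class].
#' @param task `"dna"` or `"rna"`.
#' @param sources character vector of score selectors (see
#'   [recordScores()]).
#' @inheritParams recordScores
#' @return data.frame with one row per source and columns `task`, `method`,
#'   `auc`, `sens_fpr_0.2`, `sens_fpr_0.3`, `spec_tpr_0.4`, `spec_tpr_0.5`,
#'   `n_pos`, `n_neg`.
#' @export
evalReport <- function(ds, task,
                       sources = c("disorder_trained", "structure_trained",
                                   "min", "max", "avg"),
                       norm = NULL, model = NULL) {
  rows <- lapply(sources, function(src) {
    pool <- poolResidues(ds, task, src, norm = norm, model = model)
    vals <- vapply(.METRICS, function(m)
      .metricValue(pool$labels, pool$scores, m), numeric(1))
    c(list(task = task, method = src), as.list(vals),
      list(n_pos = sum(pool$labels == 1L), n_neg = sum(pool$labels == 0L)))
  })
  do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
}

#' Compare two score sources by protein-level resampling
#'
#' Repeats the metric computation `nReps` times on random subsets of
#' `floor(frac * N)` proteins drawn without replacement (protein-level, to
#' respect within-protein correlation), producing paired metric values for
#' the two methods. Their differences are tested with a paired t-test when
#' the Anderson-Darling test does not reject normality at 0.05, and with
#' the Wilcoxon signed-rank test otherwise; the two-sided p-value is
#' reported. Because the resamples overlap, both branches use the
#' Nadeau-Bengio subsampling variance correction, which calibrates the test
#' against the population null (the naive resampled test would flag chance
#' dataset-level differences). A resample that leaves a single class is
#' redrawn (up to a retry cap).
#'
#' @param ds a [TrackDataset-class].
#' @param task `"dna"` or `"rna"`.
#' @param methodA,methodB score selectors (see [recordScores()]).
#' @param metric one of `"auc"`, `"sens_fpr_0.2"`, `"sens_fpr_0.3"`,
#'   `"spec_tpr_0.4"`, `"spec_tpr_0.5"`.
#' @param frac fraction of proteins per resample (default 0.5).
#' @param nReps number of resamples (default 50).
#' @param seed integer seed controlling all resampling randomness.
#' @inheritParams recordScores
#' @return a [SignificanceResult-class].
#' @export
compareMethods <- function(ds, task, methodA, methodB, metric = "auc",
                           frac = 0.5, nReps = 50L, seed = 1L,
                           norm = NULL, model = NULL) {
  stopifnot(metric %in% .METRICS, nReps >= 2L, frac > 0, frac <= 1)
  statFn <- function(recs) {
    sub <- TrackDataset(recs)
    vapply(c(methodA, methodB), function(src) {
      pool <- tryCatch(poolResidues(sub, task, src, norm = norm,
                                    model = model),
                       error = function(e) NULL)
      if (is.null(pool)) return(NA_real_)
      .metricValue(pool$labels, pool$scores, metric)
    }, numeric(1))
  }
  .pairedResampleTest(records(ds), statFn, frac = frac, nReps = nReps,
                      seed = seed, metric = metric,
                      contrast = paste(methodA, "vs", methodB))
}
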