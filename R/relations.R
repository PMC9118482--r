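#' @include AllClasses.R evaluate.R combine.R significance.R
NULL

.RELATION_PAIRS <- c("disorder_ss", "disorder_rsa", "disorder_binding",
                     "binding_rsa", "binding_ss", "ss_rsa")

#' Fraction of target residues within a group
#'
#' `|target AND group| / |group|` over pooled residue masks; residues with
#' an unknown (`NA`) value in either mask are excluded from both.
#'
#' @param targetMask,groupMask logical per-residue masks of equal length
#'   (`NA` = unknown).
#' @return fraction in \[0, 1\].
#' @export
fractionInGroup <- function(targetMask, groupMask) {
  stopifnot(length(targetMask) == length(groupMask))
  ok <- !is.na(targetMask) & !is.na(groupMask)
  grp <- ok & groupMask
  if (!sum(grp)) stop("empty group")
  sum(targetMask[grp]) / sum(grp)
}

#' Secondary-structure composition of a residue subset
#'
#' @param ss3 pooled per-residue 3-state codes (`NA` = unknown).
#' @param subsetMask logical mask selecting the subset (default: all).
#' @return named proportions `c(H, E, C)` summing to 1.
#' @export
ssComposition <- function(ss3, subsetMask = NULL) {
  if (is.null(subsetMask)) subsetMask <- rep(TRUE, length(ss3))
  stopifnot(length(ss3) == length(subsetMask))
  x <- ss3[!is.na(subsetMask) & subsetMask & !is.na(ss3)]
  if (!length(x)) stop("empty subset")
  counts <- vapply(.SS3_ALPHABET, function(s) sum(x == s), numeric(1))
  counts / sum(counts)
}

#' Five-number percentile summary
#'
#' The 5th, 25th, 50th, 75th and 95th percentiles (box-plot whiskers and
#' quartiles), computed by linear interpolation between closest ranks
#' (`stats::quantile` type 7), plus the number of values.
#'
#' @param values numeric vector (`NA` dropped).
#' @return named numeric `c(p5, p25, p50, p75, p95, n)`.
#' @export
percentileSummary <- function(values) {
  values <- values[!is.na(values)]
  if (!length(values)) stop("no values to summarize")
  q <- stats::quantile(values, c(0.05, 0.25, 0.5, 0.75, 0.95),
                       type = 7, names = FALSE)
  c(p5 = q[1], p25 = q[2], p50 = q[3], p75 = q[4], p95 = q[5],
    n = length(values))
}

## ---- pooled track extraction ----------------------------------------------

.pooledTrack <- function(recs, getter) {
  unlist(lapply(recs, getter), use.names = FALSE)
}

.disorderGetter <- function(source) {
  if (source == "experimental") {
    function(r) {
      x <- r@labels$disorder
      if (is.null(x)) rep(NA, seqLength(r)) else as.logical(x)
    }
  } else {
    function(r) {
      x <- r@predictions$disorder_prop
      if (is.null(x)) rep(NA, seqLength(r)) else x >= 0.5
    }
  }
}

.ssGetter <- function(source) {
  key <- if (source == "experimental") "ss3" else "ss3_pred"
  function(r) {
    x <- if (source == "experimental") r@labels$ss3 else
      r@predictions$ss3_pred
    if (is.null(x)) rep(NA_character_, seqLength(r)) else x
  }
}

.rsaGetter <- function(source) {
  function(r) {
    x <- if (source == "experimental") r@labels$rsa else
      r@predictions$rsa_pred
    if (is.null(x)) rep(NA_real_, seqLength(r)) else x
  }
}

## Binding masks under the pooling convention: TRUE = binding residue of a
## task-binding protein, FALSE = non-binding residue of a task-binding
## protein or any residue of a non-NA-binding protein, NA = out of scope.
## Predicted masks call scores >= a threshold standardized at fprCap on the
## full-dataset reference pool.
.bindingGetter <- function(ds, task, source, scoreSource, fprCap,
                           norm, model) {
  if (source == "experimental") {
    return(function(r) {
      lab <- .recordPoolLabels(r, task)
      if (is.null(lab)) rep(NA, seqLength(r)) else as.logical(lab)
    })
  }
  ref <- poolResidues(ds, task, scoreSource, norm = norm, model = model)
  thr <- binarizeAtFpr(numeric(0), ref$labels, ref$scores, fprCap)$threshold
  function(r) {
    lab <- .recordPoolLabels(r, task)
    if (is.null(lab)) return(rep(NA, seqLength(r)))
    sc <- recordScores(r, task, scoreSource, norm = norm, model = model)
    out <- sc >= thr
    out[is.na(lab)] <- NA
    out
  }
}

#' Relative fraction of binding residues per secondary-structure state
#'
#' Within the task-binding proteins, the fraction of residues in each
#' 3-state conformation that bind the task's nucleic acid:
#' `|binding AND state = s| / |state = s|`. A state with no residues yields
#' `NA` (undefined, never zero).
#'
#' @param ds a [TrackDataset-class].
#' @param task `"dna"` or `"rna"`.
#' @param bindingSource,ssSource `"experimental"` or `"predicted"` per axis.
#' @param scoreSource score selector for predicted binding (see
#'   [recordScores()]).
#' @param fprCap FPR cap standardizing predicted binding calls.
#' @inheritParams recordScores
#' @return named numeric `c(H, E, C)` of relative binding fractions.
#' @export
relativeBindingBySs <- function(ds, task, bindingSource = "experimental",
                                ssSource = "experimental",
                                scoreSource = "meta", fprCap = 0.2,
                                norm = NULL, model = NULL) {
  keep <- vapply(records(ds), function(r)
    r@bindingClass == .taskTrack(task), logical(1))
  sub <- ds[which(keep)]
  if (!length(sub)) stop("no ", task, "-binding proteins in dataset")
  bindG <- .bindingGetter(ds, task, bindingSource, scoreSource, fprCap,
                          norm, model)
  ssG <- .ssGetter(ssSource)
  bind <- .pooledTrack(records(sub), bindG)
  ss <- .pooledTrack(records(sub), ssG)
  vapply(.SS3_ALPHABET, function(s) {
    in_s <- !is.na(ss) & ss == s & !is.na(bind)
    if (!sum(in_s)) return(NA_real_)
    sum(bind[in_s]) / sum(in_s)
  }, numeric(1))
}

## ---- the relation suite ----------------------------------------------------

#' Cross-characteristic relation analysis
#'
#' Computes, for one pair of residue-level characteristics, per-group
#' summary statistics on the full dataset and resampled paired significance
#' tests for the group contrasts, with each axis sourced from either the
#' experimental or the predicted track. The six supported pairs are
#' `disorder_ss` (secondary-structure composition of disordered vs
#' structured residues), `disorder_rsa` (relative accessibility of
#' disordered vs structured residues), `disorder_binding` (fraction of
#' disordered residues among binding vs non-binding residues),
#' `binding_rsa` (accessibility of binding vs non-binding residues),
#' `binding_ss` (relative binding fraction per secondary-structure state
#' within binding proteins) and `ss_rsa` (accessibility by
#' secondary-structure state).
#'
#' Significance uses the same machinery as [compareMethods()]: `nReps`
#' random subsets of `frac` of the proteins, the paired per-subset group
#' statistics tested with an Anderson-Darling-gated paired t-test /
#' Wilcoxon signed-rank test at 0.05. Undefined statistics (empty groups,
#' e.g. experimental accessibility of disordered residues, which cannot be
#' measured) propagate as `NA` rather than zero; their contrasts are
#' reported untested.
#'
#' @param ds a [TrackDataset-class].
#' @param pair one of the six pair identifiers above.
#' @param sources length-2 character (`"experimental"`/`"predicted"`), one
#'   per axis in the order the pair names them.
#' @param task `"dna"` or `"rna"` for pairs involving binding.
#' @param reps number of resamples (default 100).
#' @param frac fraction of proteins per resample (default 0.2).
#' @param seed integer seed for the resampling.
#' @param scoreSource score selector used for predicted binding.
#' @param fprCap FPR cap standardizing predicted binding calls.
#' @inheritParams recordScores
#' @return a [RelationReport-class].
#' @export
relationSuite <- function(ds, pair, sources = c("experimental", "predicted"),
                          task = "dna", reps = 100L, frac = 0.2, seed = 1L,
                          scoreSource = "meta", fprCap = 0.2,
                          norm = NULL, model = NULL) {
  stopifnot(pair %in% .RELATION_PAIRS, length(sources) == 2L,
            all(sources %in% c("experimental", "predicted")))
  recs <- records(ds)

  ## group masks (logical, NA = excluded) and value extraction per pair
  if (pair %in% c("disorder_ss", "disorder_rsa")) {
    grpG <- .disorderGetter(sources[1])
    groupsOf <- function(recs) {
      g <- .pooledTrack(recs, grpG)
      list(disordered = g, structured = !g)
    }
  } else if (pair %in% c("disorder_binding", "binding_rsa")) {
    bindG <- .bindingGetter(ds, task, sources[1], scoreSource, fprCap,
                            norm, model)
    groupsOf <- function(recs) {
      g <- .pooledTrack(recs, bindG)
      list(binding = g, non_binding = !g)
    }
  } else if (pair == "ss_rsa") {
    ssG <- .ssGetter(sources[1])
    groupsOf <- function(recs) {
      ss <- .pooledTrack(recs, ssG)
      list(helix = ss == "H", strand = ss == "E", coil = ss == "C")
    }
  }

  valueOf <- switch(pair,
    disorder_ss = {
      ssG <- .ssGetter(sources[2])
      function(recs) .pooledTrack(recs, ssG)
    },
    disorder_rsa = ,
    binding_rsa = ,
    ss_rsa = {
      rsaG <- .rsaGetter(sources[2])
      function(recs) .pooledTrack(recs, rsaG)
    },
    disorder_binding = {
      disG <- .disorderGetter(sources[2])
      function(recs) .pooledTrack(recs, disG)
    },
    binding_ss = NULL)

  safe <- function(expr) tryCatch(expr, error = function(e) NA_real_)

  if (pair == "binding_ss") {
    stats <- list(relative_fraction = relativeBindingBySs(
      ds, task, bindingSource = sources[1], ssSource = sources[2],
      scoreSource = scoreSource, fprCap = fprCap, norm = norm,
      model = model))
    keep <- vapply(recs, function(r)
      r@bindingClass == .taskTrack(task), logical(1))
    bindRecs <- recs[keep]
    bindG <- .bindingGetter(ds, task, sources[1], scoreSource, fprCap,
                            norm, model)
    ssG <- .ssGetter(sources[2])
    statePair <- function(recs, s1, s2) {
      bind <- .pooledTrack(recs, bindG)
      ss <- .pooledTrack(recs, ssG)
      f <- function(s) {
        in_s <- !is.na(ss) & ss == s & !is.na(bind)
        if (!sum(in_s)) return(NA_real_)
        sum(bind[in_s]) / sum(in_s)
      }
      c(f(s1), f(s2))
    }
    contrasts <- list(coil_vs_helix = c("C", "H"),
                      helix_vs_strand = c("H", "E"),
                      coil_vs_strand = c("C", "E"))
    tests <- lapply(names(contrasts), function(nm) {
      s12 <- contrasts[[nm]]
      safeTest(.pairedResampleTest, bindRecs,
               function(rr) statePair(rr, s12[1], s12[2]),
               frac, reps, seed, "relative_binding_fraction", nm)
    })
    names(tests) <- names(contrasts)
    tests <- tests[!vapply(tests, is.null, logical(1))]
    return(new("RelationReport", pair = pair, task = task,
               sources = sources, stats = stats, tests = tests))
  }

  groups <- groupsOf(recs)
  values <- valueOf(recs)

  groupStat <- function(g, v) {
    ok <- !is.na(g) & g
    if (pair == "disorder_ss") {
      safe(ssComposition(v, ok))
    } else if (pair == "disorder_binding") {
      safe(fractionInGroup(v, ok))
    } else {
      safe(percentileSummary(v[ok]))
    }
  }
  scalarStat <- function(g, v) {
    ok <- !is.na(g) & g & !is.na(v)
    if (!sum(ok)) return(NA_real_)
    if (pair == "disorder_ss") return(mean(v[ok] == "C"))
    if (pair == "disorder_binding") return(mean(v[ok]))
    mean(v[ok])
  }

  stats <- lapply(groups, groupStat, v = values)
  metricName <- switch(pair,
                       disorder_ss = "coil_proportion",
                       disorder_binding = "disordered_fraction",
                       "mean_value")

  gn <- names(groups)
  contrastPairs <- if (length(gn) == 2L) {
    stats::setNames(list(gn), paste(gn[1], gn[2], sep = "_vs_"))
  } else {
    list(coil_vs_helix = c("coil", "helix"),
         helix_vs_strand = c("helix", "strand"),
         coil_vs_strand = c("coil", "strand"))
  }
  tests <- lapply(names(contrastPairs), function(nm) {
    gg <- contrastPairs[[nm]]
    statFn <- function(rr) {
      grp <- groupsOf(rr)
      v <- valueOf(rr)
      c(scalarStat(grp[[gg[1]]], v), scalarStat(grp[[gg[2]]], v))
    }
    safeTest(.pairedResampleTest, recs, statFn, frac, reps, seed,
             metricName, nm)
  })
  names(tests) <- names(contrastPairs)
  tests <- tests[!vapply(tests, is.null, logical(1))]
  new("RelationReport", pair = pair, task = task, sources = sources,
      stats = stats, tests = tests)
}

## run a resample test, returning NULL when the statistic is undefined on
## every subset (e.g. an empty group), so the contrast is reported untested
safeTest <- function(fn, recs, statFn, frac, reps, seed, metric, nm) {
  tryCatch(fn(recs, statFn, frac = frac, nReps = reps, seed = seed,
              metric = metric, contrast = nm),
           error = function(e) NULL)
}
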