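#' @include AllClasses.R AllGenerics.R
NULL

#' @rdname ProteinRecord
#' @export
setMethod("seqString", "ProteinRecord", function(x) x@sequence)

#' @rdname ProteinRecord
#' @export
setMethod("seqLength", "ProteinRecord", function(x) nchar(x@sequence))

#' @rdname ProteinRecord
#' @export
setMethod("trackLabels", "ProteinRecord", function(x) x@labels)

#' @rdname ProteinRecord
#' @export
setMethod("trackPredictions", "ProteinRecord", function(x) x@predictions)

#' @rdname ProteinRecord
#' @export
setReplaceMethod("trackPredictions", "ProteinRecord", function(x, value) {
  x@predictions <- value
  validObject(x)
  x
})

#' @rdname ProteinRecord
#' @export
setMethod("bindingClass", "ProteinRecord", function(x) x@bindingClass)

#' @rdname ProteinRecord
#' @export
setMethod("recordSource", "ProteinRecord", function(x) x@source)

#' @rdname ProteinRecord
#' @export
setMethod("recordSplit", "ProteinRecord", function(x) x@split)

#' @rdname ProteinRecord
#' @export
setReplaceMethod("recordSplit", "ProteinRecord", function(x, value) {
  x@split <- value
  validObject(x)
  x
})

setMethod("show", "ProteinRecord", function(object) {
  cat(sprintf("ProteinRecord %s: %d aa, class=%s, source=%s, split=%s\n",
              object@id, nchar(object@sequence), object@bindingClass,
              object@source, object@split))
  cat(sprintf("  label tracks:      %s\n",
              if (length(object@labels))
                paste(names(object@labels), collapse = ", ") else "<none>"))
  cat(sprintf("  prediction tracks: %s\n",
              if (length(object@predictions))
                paste(names(object@predictions), collapse = ", ")
              else "<none>"))
})

#' @rdname TrackDataset
#' @export
setMethod("records", "TrackDataset", function(x) x@records)

#' @rdname TrackDataset
#' @export
setMethod("recordIds", "TrackDataset",
          function(x) vapply(x@records, function(r) r@id, character(1)))

#' @rdname TrackDataset
#' @export
setMethod("length", "TrackDataset", function(x) length(x@records))

#' @rdname TrackDataset
#' @param i index vector (integer/logical) or record id(s).
#' @export
setMethod("[", "TrackDataset", function(x, i) {
  if (is.character(i)) i <- match(i, recordIds(x))
  initialize(x, records = x@records[i])
})

#' @rdname TrackDataset
#' @export
setMethod("[[", "TrackDataset", function(x, i) {
  if (is.character(i)) {
    j <- match(i, recordIds(x))
    if (is.na(j)) stop("no record with id '", i, "'")
    i <- j
  }
  x@records[[i]]
})

setMethod("show", "TrackDataset", function(object) {
  cls <- table(vapply(object@records, function(r) r@bindingClass, character(1)))
  spl <- table(vapply(object@records, function(r) r@split, character(1)))
  cat(sprintf("TrackDataset with %d record(s)\n", length(object@records)))
  if (length(cls))
    cat("  classes:", paste(sprintf("%s=%d", names(cls), cls),
                            collapse = ", "), "\n")
  if (length(spl))
    cat("  splits: ", paste(sprintf("%s=%d", names(spl), spl),
                            collapse = ", "), "\n")
  if (nzchar(object@provenance))
    cat("  provenance:", object@provenance, "\n")
})

setMethod("show", "MetaModel", function(object) {
  cat(sprintf("MetaModel (%s): window=%d, hidden=(%s), validation AUC=%.3f\n",
              object@task, object@config$window,
              paste(object@config$hidden, collapse = ","),
              object@validationAuc))
})

setMethod("show", "RocCurve", function(object) {
  cat(sprintf("RocCurve: %d operating points, AUC=%.4f\n",
              nrow(object@points), object@auc))
})

setMethod("show", "SignificanceResult", function(object) {
  cat(sprintf(
    "SignificanceResult [%s] %s: %s p=%.4g (%ssignificant at 0.05)\n",
    object@metric, object@contrast, object@chosenTest, object@pValue,
    if (isTRUE(object@significant)) "" else "not "))
  cat(sprintf("  %d resamples of %.0f%% of proteins; AD normality p=%s\n",
              object@nReps, 100 * object@frac,
              ifelse(is.na(object@normalityP), "NA",
                     sprintf("%.4g", object@normalityP))))
})

setMethod("show", "RelationReport", function(object) {
  cat(sprintf("RelationReport: %s%s, sources=(%s)\n", object@pair,
              if (nzchar(object@task)) paste0(" [", object@task, "]") else "",
              paste(object@sources, collapse = ", ")))
  cat("  statistics:", paste(names(object@stats), collapse = ", "), "\n")
  for (nm in names(object@tests)) {
    tst <- object@tests[[nm]]
    cat(sprintf("  contrast %s: p=%.4g (%s)\n", nm, tst@pValue,
                tst@chosenTest))
  }
})

#' @rdname RocCurve
#' @param x a `RocCurve`.
#' @return `rocPoints` returns the operating-point data.frame; `rocAuc` the
#'   trapezoidal area.
#' @export
rocPoints <- function(x) x@points

#' @rdname RocCurve
#' @export
rocAuc <- function(x) x@auc

#' @rdname MetaModel
#' @param x a `MetaModel`.
#' @return accessor values for the respective slots.
#' @export
modelConfig <- function(x) x@config

#' @rdname MetaModel
#' @export
modelTask <- function(x) x@task

#' @rdname MetaModel
#' @export
modelNorm <- function(x) x@norm

#' @rdname MetaModel
#' @export
validationAuc <- function(x) x@validationAuc

#' @rdname SignificanceResult
#' @param x a `SignificanceResult`.
#' @export
pValue <- function(x) x@pValue

#' @rdname SignificanceResult
#' @export
chosenTest <- function(x) x@chosenTest

#' @rdname SignificanceResult
#' @export
isSignificant <- function(x) x@significant

#' @rdname RelationReport
#' @param x a `RelationReport`.
#' @export
relationStats <- function(x) x@stats

#' @rdname RelationReport
#' @export
relationTests <- function(x) x@tests
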