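#' @import methods
NULL

## Track name registry. Label tracks hold experimental annotations, prediction
## tracks hold per-residue predictor outputs. Names double as the row keys of
## the track_tsv on-disk format.
.LABEL_TRACKS <- c("disorder", "ss8", "ss3", "asa", "rsa",
                   "dna_binding", "rna_binding")
.PRED_TRACKS <- c("disorder_prop", "ss3_pred", "rsa_pred",
                  "dna_disorder_trained", "rna_disorder_trained",
                  "dna_structure_trained", "rna_structure_trained",
                  "dna_meta", "rna_meta")
.CHAR_TRACKS <- c("ss8", "ss3", "ss3_pred")

.SOURCES <- c("pdb_annotated", "disprot_annotated", "synthetic", "unknown")
.BINDING_CLASSES <- c("dna_binding", "rna_binding", "non_na_binding",
                      "unlabeled")
.SPLITS <- c("train", "validation", "test", "none")

.SS8_ALPHABET <- c("H", "G", "I", "E", "B", "T", "S", "-")
.SS3_ALPHABET <- c("H", "E", "C")

#' ProteinRecord: one protein's sequence with aligned residue-level tracks
#'
#' Container for a single protein: its amino-acid sequence, experimental
#' label tracks (intrinsic disorder, 8- and 3-state secondary structure,
#' absolute and relative solvent accessibility, DNA-/RNA-binding flags) and
#' predicted tracks (disorder propensity, 3-state secondary structure,
#' relative accessibility, and DNA-/RNA-binding propensities from a
#' disorder-trained and a structure-trained predictor, plus optional
#' meta-predictor outputs).
#'
#' Ternary label tracks (disorder, binding) are integer vectors with values
#' 1 (positive), 0 (negative) and `NA` (unknown). Secondary-structure tracks
#' are character vectors over their alphabet with `NA` for unknown. Numeric
#' tracks use `NA` for missing residues; an entirely absent track is simply
#' not stored. Structural validity (slot types) is enforced at construction;
#' the full scientific invariant set is checked by [validateRecord()], which
#' reports violations instead of throwing.
#'
#' @slot id accession string, unique within a [TrackDataset].
#' @slot sequence amino-acid sequence (one-letter codes), non-empty.
#' @slot source one of `"pdb_annotated"`, `"disprot_annotated"`,
#'   `"synthetic"`, `"unknown"`.
#' @slot bindingClass one of `"dna_binding"`, `"rna_binding"`,
#'   `"non_na_binding"`, `"unlabeled"`.
#' @slot labels named list of experimental tracks (see Details).
#' @slot predictions named list of predicted tracks.
#' @slot split one of `"train"`, `"validation"`, `"test"`, `"none"`.
#' @seealso [validateRecord()], [TrackDataset]
#' @export
setClass("ProteinRecord",
         representation(id = "character",
                        sequence = "character",
                        source = "character",
                        bindingClass = "character",
                        labels = "list",
                        predictions = "list",
                        split = "character"))

setValidity("ProteinRecord", function(object) {
  msg <- character(0)
  if (length(object@id) != 1L || !nzchar(object@id))
    msg <- c(msg, "id must be a single non-empty string")
  if (length(object@sequence) != 1L || !nzchar(object@sequence))
    msg <- c(msg, "sequence must be a single non-empty string")
  if (length(object@source) != 1L || !(object@source %in% .SOURCES))
    msg <- c(msg, sprintf("source must be one of %s",
                          paste(.SOURCES, collapse = ", ")))
  if (length(object@bindingClass) != 1L ||
      !(object@bindingClass %in% .BINDING_CLASSES))
    msg <- c(msg, sprintf("bindingClass must be one of %s",
                          paste(.BINDING_CLASSES, collapse = ", ")))
  if (length(object@split) != 1L || !(object@split %in% .SPLITS))
    msg <- c(msg, sprintf("split must be one of %s",
                          paste(.SPLITS, collapse = ", ")))
  bad <- setdiff(names(object@labels), .LABEL_TRACKS)
  if (length(bad))
    msg <- c(msg, sprintf("unknown label track(s): %s",
                          paste(bad, collapse = ", ")))
  bad <- setdiff(names(object@predictions), .PRED_TRACKS)
  if (length(bad))
    msg <- c(msg, sprintf("unknown prediction track(s): %s",
                          paste(bad, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Construct a ProteinRecord
#'
#' @param id accession string.
#' @param sequence amino-acid sequence string.
#' @param source provenance tag; see [ProteinRecord-class].
#' @param bindingClass protein-level binding class.
#' @param labels named list of experimental tracks.
#' @param predictions named list of predicted tracks.
#' @param split dataset split assignment.
#' @return a [ProteinRecord-class] object.
#' @examples
#' rec <- ProteinRecord("P1", "MKLV",
#'                      labels = list(disorder = c(0L, 0L, 1L, 1L)))
#' seqLength(rec)
#' @export
ProteinRecord <- function(id, sequence, source = "synthetic",
                          bindingClass = "unlabeled",
                          labels = list(), predictions = list(),
                          split = "none") {
  new("ProteinRecord", id = as.character(id), sequence = as.character(sequence),
      source = source, bindingClass = bindingClass,
      labels = labels, predictions = predictions, split = split)
}

#' TrackDataset: an ordered collection of ProteinRecord objects
#'
#' Ids are unique; records keep their insertion order. Subset with `[`
#' (returns a `TrackDataset`) or extract one record with `[[` by integer
#' index or by id.
#'
#' @slot records list of [ProteinRecord-class] objects.
#' @slot provenance free-text metadata about the dataset's origin.
#' @export
setClass("TrackDataset",
         representation(records = "list", provenance = "character"))

setValidity("TrackDataset", function(object) {
  if (!all(vapply(object@records, is, logical(1), "ProteinRecord")))
    return("all records must be ProteinRecord objects")
  ids <- vapply(object@records, function(r) r@id, character(1))
  if (anyDuplicated(ids))
    return(sprintf("duplicate record id(s): %s",
                   paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  if (length(object@provenance) != 1L)
    return("provenance must be a single string")
  TRUE
})

#' Construct a TrackDataset
#'
#' @param records list of [ProteinRecord-class] objects.
#' @param provenance free-text provenance string.
#' @return a [TrackDataset-class] object.
#' @export
TrackDataset <- function(records = list(), provenance = "") {
  new("TrackDataset", records = unname(records), provenance = provenance)
}

#' MetaModel: a windowed feed-forward meta-predictor for one binding task
#'
#' A small fully connected network that maps a sliding window of two
#' normalized binding-propensity tracks (disorder-trained and
#' structure-trained) to the binding propensity of the central residue.
#' Input width is `2 * window`; hidden layers use ReLU, the single output
#' unit a sigmoid. The fitted min-max normalization parameters travel with
#' the model so that prediction is self-contained.
#'
#' @slot task `"dna"` or `"rna"`.
#' @slot config list: `window` (odd), `hidden` (integer widths), `seed`,
#'   and training hyperparameters (`epochs`, `batch`, `lr`, `patience`).
#' @slot weights list with elements `W` (list of weight matrices) and
#'   `b` (list of bias vectors).
#' @slot norm normalization parameters from [fitNormalizer()].
#' @slot validationAuc AUC attained on the validation split during selection.
#' @seealso [trainMeta()], [predictMeta()]
#' @export
setClass("MetaModel",
         representation(task = "character", config = "list",
                        weights = "list", norm = "list",
                        validationAuc = "numeric"))

#' RocCurve: step-function ROC operating points and area
#'
#' Operating points are (threshold, FPR, TPR) triples, one per distinct
#' score plus the degenerate extremes; the prediction rule is
#' "positive iff score >= threshold", with no interpolation.
#'
#' @slot points data.frame with columns `threshold`, `fpr`, `tpr`, ordered
#'   by decreasing threshold (so FPR and TPR are non-decreasing).
#' @slot auc trapezoidal area under the step curve.
#' @seealso [rocCurve()], [aucScore()]
#' @export
setClass("RocCurve",
         representation(points = "data.frame", auc = "numeric"))

#' SignificanceResult: a resampled paired comparison of two methods/groups
#'
#' Holds the per-resample paired metric values, the Anderson-Darling
#' normality decision on their differences, the test that decision selected
#' (paired t-test if normal at 0.05, Wilcoxon signed-rank otherwise) and the
#' two-sided p-value. Because resampled subsets are drawn from one shared
#' dataset, both test branches apply the Nadeau-Bengio subsampling variance
#' correction (see the methods vignette); all-zero differences yield p = 1
#' by convention (the signed-rank statistic is undefined; "no evidence of
#' difference" is the only safe report).
#'
#' @slot metric name of the compared metric or statistic.
#' @slot contrast label of the compared pair (e.g. `"avg vs meta"`).
#' @slot frac fraction of proteins drawn per resample.
#' @slot nReps number of resamples.
#' @slot valuesA,valuesB per-resample paired metric values.
#' @slot normalityP Anderson-Darling p-value on the paired differences
#'   (`NA` when the test is degenerate).
#' @slot chosenTest `"t_test"` or `"wilcoxon_signed_rank"`.
#' @slot pValue two-sided p-value.
#' @slot significant logical, `pValue < 0.05`.
#' @seealso [compareMethods()], [relationSuite()]
#' @export
setClass("SignificanceResult",
         representation(metric = "character", contrast = "character",
                        frac = "numeric", nReps = "integer",
                        valuesA = "numeric", valuesB = "numeric",
                        normalityP = "numeric", chosenTest = "character",
                        pValue = "numeric", significant = "logical"))

#' RelationReport: cross-characteristic relation summary for one pair
#'
#' Result of [relationSuite()] for one characteristic pair (for example
#' disorder x secondary structure): per-group summary statistics computed on
#' the full dataset plus resampled paired significance tests for each
#' contrast.
#'
#' @slot pair characteristic pair identifier.
#' @slot task `"dna"`, `"rna"`, or `""` when the pair does not involve
#'   binding.
#' @slot sources length-2 character, `"experimental"` or `"predicted"`, one
#'   per axis of the pair.
#' @slot stats named list of per-group statistics (fractions, compositions,
#'   or percentile summaries).
#' @slot tests named list of [SignificanceResult-class] objects, one per
#'   contrast.
#' @export
setClass("RelationReport",
         representation(pair = "character", task = "character",
                        sources = "character", stats = "list",
                        tests = "list"))
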