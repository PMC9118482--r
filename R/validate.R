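#' @include AllClasses.R
NULL

#' Validate a ProteinRecord against the residue-track invariants
#'
#' Checks every scientific invariant of the record: all present tracks have
#' the sequence length; relative accessibility lies in \[0, 1\] and
#' propensities in \[0, 1\] wherever present; ternary tracks only hold
#' 0/1/NA; secondary-structure tracks stay on their alphabet; residues
#' marked disordered carry no experimental secondary structure or solvent
#' accessibility (disordered regions have no measurable structure); and the
#' protein-level binding class is consistent with the residue labels
#' (a DNA-binding protein has at least one DNA-binding residue, a
#' non-nucleic-acid-binding protein has none for either task).
#'
#' Validation never throws: it returns a character vector of violation
#' descriptions, empty when the record is fully consistent. Residue indices
#' in the descriptions are 1-based.
#'
#' @param rec a [ProteinRecord-class].
#' @return character vector of violations; `character(0)` if none.
#' @examples
#' rec <- ProteinRecord("P1", "MKLV",
#'                      labels = list(rsa = c(0.1, 1.3, NA, 0.4)))
#' validateRecord(rec)
#' @export
validateRecord <- function(rec) {
  stopifnot(is(rec, "ProteinRecord"))
  v <- character(0)
  n <- nchar(rec@sequence)
  tracks <- c(rec@labels, rec@predictions)

  for (nm in names(tracks)) {
    if (length(tracks[[nm]]) != n)
      v <- c(v, sprintf("track %s has length %d but sequence has %d residues",
                        nm, length(tracks[[nm]]), n))
  }
  ok_len <- function(nm) !is.null(tracks[[nm]]) && length(tracks[[nm]]) == n

  rng_check <- function(nm, lo, hi) {
    x <- tracks[[nm]]
    bad <- which(!is.na(x) & (x < lo | x > hi))
    sprintf("track %s value %s at residue %d outside [%g, %g]",
            nm, format(x[bad]), bad, lo, hi)
  }
  for (nm in intersect(c("rsa", "rsa_pred", "disorder_prop",
                         "dna_disorder_trained", "rna_disorder_trained",
                         "dna_structure_trained", "rna_structure_trained",
                         "dna_meta", "rna_meta"), names(tracks)))
    if (ok_len(nm)) v <- c(v, rng_check(nm, 0, 1))
  if (ok_len("asa")) {
    bad <- which(!is.na(tracks$asa) & tracks$asa < 0)
    v <- c(v, sprintf("track asa negative value at residue %d", bad))
  }

  tern_check <- function(nm) {
    x <- tracks[[nm]]
    bad <- which(!is.na(x) & !(x %in% c(0L, 1L)))
    sprintf("track %s non-ternary value at residue %d", nm, bad)
  }
  for (nm in intersect(c("disorder", "dna_binding", "rna_binding"),
                       names(tracks)))
    if (ok_len(nm)) v <- c(v, tern_check(nm))

  alpha_check <- function(nm, alphabet) {
    x <- tracks[[nm]]
    bad <- which(!is.na(x) & !(x %in% alphabet))
    sprintf("track %s unknown state '%s' at residue %d", nm, x[bad], bad)
  }
  if (ok_len("ss8")) v <- c(v, alpha_check("ss8", .SS8_ALPHABET))
  for (nm in intersect(c("ss3", "ss3_pred"), names(tracks)))
    if (ok_len(nm)) v <- c(v, alpha_check(nm, .SS3_ALPHABET))

  ## disordered residues have no measurable structure
  if (ok_len("disorder")) {
    dis <- which(!is.na(tracks$disorder) & tracks$disorder == 1L)
    for (nm in intersect(c("ss8", "ss3", "asa", "rsa"), names(tracks))) {
      if (!ok_len(nm)) next
      bad <- dis[!is.na(tracks[[nm]][dis])]
      v <- c(v, sprintf(
        "track %s has a value at disordered residue %d", nm, bad))
    }
  }

  n_bind <- function(nm) {
    if (!ok_len(nm)) return(0L)
    sum(tracks[[nm]] == 1L, na.rm = TRUE)
  }
  if (rec@bindingClass == "dna_binding" && n_bind("dna_binding") == 0L)
    v <- c(v, "bindingClass dna_binding but no residue with dna_binding=1")
  if (rec@bindingClass == "rna_binding" && n_bind("rna_binding") == 0L)
    v <- c(v, "bindingClass rna_binding but no residue with rna_binding=1")
  if (rec@bindingClass == "non_na_binding" &&
      (n_bind("dna_binding") > 0L || n_bind("rna_binding") > 0L))
    v <- c(v, "bindingClass non_na_binding but binding-labeled residue present")

  v
}

#' Validate every record of a dataset
#'
#' @param ds a [TrackDataset-class].
#' @return named list of violation vectors, one element per offending record
#'   (empty list when the dataset is fully valid).
#' @export
validateDataset <- function(ds) {
  out <- lapply(records(ds), validateRecord)
  names(out) <- recordIds(ds)
  out[lengths(out) > 0L]
}
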