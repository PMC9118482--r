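#' @include AllClasses.R validate.R
NULL

.TSV_HEADER <- "# nucmeta track_tsv v1"
.TERNARY_TRACKS <- c("disorder", "dna_binding", "rna_binding")
.NUMERIC_TRACKS <- c("asa", "rsa", "rsa_pred", "disorder_prop",
                     "dna_disorder_trained", "rna_disorder_trained",
                     "dna_structure_trained", "rna_structure_trained",
                     "dna_meta", "rna_meta")
.SS_TRACKS <- c("ss8", "ss3", "ss3_pred")

.fmtTrack <- function(nm, x) {
  if (nm %in% .NUMERIC_TRACKS) {
    out <- sprintf("%.3f", x)
  } else if (nm %in% .TERNARY_TRACKS) {
    out <- as.character(as.integer(x))
  } else {
    out <- as.character(x)
  }
  out[is.na(x)] <- "NA"
  out
}

.parseTrack <- function(nm, fields, lineno) {
  vals <- fields
  vals[vals == "NA"] <- NA
  if (nm %in% .NUMERIC_TRACKS) {
    out <- suppressWarnings(as.numeric(vals))
    if (any(is.na(out) & !is.na(vals)))
      stop(sprintf("line %d: non-numeric value in track %s", lineno, nm))
    return(out)
  }
  if (nm %in% .TERNARY_TRACKS) {
    bad <- !is.na(vals) & !(vals %in% c("0", "1"))
    if (any(bad))
      stop(sprintf("line %d: invalid ternary code '%s' in track %s",
                   lineno, vals[which(bad)[1]], nm))
    return(as.integer(vals))
  }
  if (nm %in% .SS_TRACKS) {
    alpha <- if (nm == "ss8") .SS8_ALPHABET else .SS3_ALPHABET
    bad <- !is.na(vals) & !(vals %in% alpha)
    if (any(bad))
      stop(sprintf("line %d: unknown state code '%s' in track %s",
                   lineno, vals[which(bad)[1]], nm))
    return(as.character(vals))
  }
  stop(sprintf("line %d: unknown track name '%s'", lineno, nm))
}

#' Write a dataset of residue-level tracks
#'
#' `track_tsv` is a greppable one-file-per-dataset dialect: a format header
#' line, then one block per protein starting with
#' `>id<TAB>binding_class<TAB>source<TAB>split`, followed by one line per
#' present track (`track_name<TAB>v1<TAB>v2...`). Missing values use the
#' sentinel `NA`; ternary labels are encoded 1/0/NA; numeric tracks are
#' written with exactly 3 decimals, making output byte-deterministic for a
#' fixed dataset. `caid` writes the per-residue
#' index/residue/propensity/binary layout used for disorder predictions.
#'
#' @param ds a [TrackDataset-class].
#' @param path output file path.
#' @param format `"track_tsv"` or `"caid"`.
#' @return invisibly, `path`.
#' @seealso [readDataset()]
#' @export
writeDataset <- function(ds, path, format = c("track_tsv", "caid")) {
  format <- match.arg(format)
  stopifnot(is(ds, "TrackDataset"))
  bad <- validateDataset(ds)
  if (length(bad))
    stop("invalid record(s): ", paste(names(bad), collapse = ", "),
         " -- first violation: ", bad[[1]][1])
  lines <- character(0)
  if (format == "track_tsv") {
    lines <- .TSV_HEADER
    for (rec in records(ds)) {
      lines <- c(lines, paste(paste0(">", rec@id), rec@bindingClass,
                              rec@source, rec@split, sep = "\t"))
      lines <- c(lines, paste0("sequence\t",
                               paste(strsplit(rec@sequence, "")[[1]],
                                     collapse = "\t")))
      tracks <- c(rec@labels[intersect(.LABEL_TRACKS, names(rec@labels))],
                  rec@predictions[intersect(.PRED_TRACKS,
                                            names(rec@predictions))])
      for (nm in names(tracks))
        lines <- c(lines, paste(c(nm, .fmtTrack(nm, tracks[[nm]])),
                                collapse = "\t"))
    }
  } else {
    for (rec in records(ds)) {
      prop <- rec@predictions$disorder_prop
      lab <- rec@labels$disorder
      if (is.null(prop))
        stop("record ", rec@id, ": caid format requires disorder_prop")
      aa <- strsplit(rec@sequence, "")[[1]]
      lines <- c(lines, paste0(">", rec@id),
                 paste(seq_along(aa), aa, .fmtTrack("disorder_prop", prop),
                       if (is.null(lab)) "NA" else
                         .fmtTrack("disorder", lab),
                       sep = "\t"))
    }
  }
  con <- file(path, open = "wb")  # fixed newline convention across platforms
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Read a dataset of residue-level tracks
#'
#' Parses the formats written by [writeDataset()]. Every record is checked
#' against the full invariant set on read: a track whose length differs from
#' the sequence length raises a malformed-record error naming the id, and an
#' unknown state code raises a parse error naming the line number. Tracks
#' absent from the file are represented as absent, never zero-filled.
#'
#' @param path input file path.
#' @param format `"track_tsv"` or `"caid"`.
#' @param provenance provenance string stored on the returned dataset.
#' @return a [TrackDataset-class].
#' @export
readDataset <- function(path, format = c("track_tsv", "caid"),
                        provenance = path) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  recs <- list()
  if (format == "track_tsv") {
    i <- 1L
    if (length(lines) && startsWith(lines[1], "#")) i <- 2L
    cur <- NULL
    flush <- function(cur) {
      if (is.null(cur)) return(NULL)
      if (is.null(cur$sequence))
        stop("record ", cur$id, ": missing sequence line")
      rec <- ProteinRecord(cur$id, cur$sequence, source = cur$source,
                           bindingClass = cur$class, labels = cur$labels,
                           predictions = cur$preds, split = cur$split)
      viol <- validateRecord(rec)
      if (length(viol))
        stop("malformed record '", cur$id, "': ", viol[1])
      rec
    }
    while (i <= length(lines)) {
      ln <- lines[i]
      if (!nzchar(ln)) { i <- i + 1L; next }
      f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
      if (startsWith(f[1], ">")) {
        if (length(f) != 4L)
          stop(sprintf("line %d: record header needs 4 fields", i))
        recs <- c(recs, flush(cur))
        cur <- list(id = substring(f[1], 2), class = f[2], source = f[3],
                    split = f[4], sequence = NULL,
                    labels = list(), preds = list())
      } else if (is.null(cur)) {
        stop(sprintf("line %d: track line before any record header", i))
      } else if (f[1] == "sequence") {
        cur$sequence <- paste(f[-1], collapse = "")
      } else {
        nm <- f[1]
        vals <- .parseTrack(nm, f[-1], i)
        if (nm %in% .LABEL_TRACKS) cur$labels[[nm]] <- vals
        else cur$preds[[nm]] <- vals
      }
      i <- i + 1L
    }
    recs <- c(recs, flush(cur))
  } else {
    hdr <- which(startsWith(lines, ">"))
    if (!length(hdr)) stop("no record headers found in caid file")
    bounds <- c(hdr, length(lines) + 1L)
    for (k in seq_along(hdr)) {
      id <- substring(lines[hdr[k]], 2)
      body <- lines[seq.int(hdr[k] + 1L, bounds[k + 1L] - 1L)]
      body <- body[nzchar(body)]
      if (!length(body)) stop("record ", id, ": empty caid block")
      f <- strsplit(body, "\t", fixed = TRUE)
      if (any(lengths(f) < 3L))
        stop(sprintf("line %d: caid rows need index/residue/propensity",
                     hdr[k] + which(lengths(f) < 3L)[1]))
      aa <- vapply(f, `[`, character(1), 2)
      prop <- .parseTrack("disorder_prop",
                          vapply(f, `[`, character(1), 3), hdr[k] + 1L)
      lab <- if (all(lengths(f) >= 4L))
        .parseTrack("disorder", vapply(f, `[`, character(1), 4),
                    hdr[k] + 1L)
      labels <- if (!is.null(lab) && !all(is.na(lab)))
        list(disorder = lab) else list()
      rec <- ProteinRecord(id, paste(aa, collapse = ""), source = "unknown",
                           labels = labels,
                           predictions = list(disorder_prop = prop))
      viol <- validateRecord(rec)
      if (length(viol)) stop("malformed record '", id, "': ", viol[1])
      recs <- c(recs, rec)
    }
  }
  TrackDataset(recs, provenance = provenance)
}

#' Read protein sequences from a FASTA file
#'
#' Minimal FASTA reader returning a dataset of sequence-only records (no
#' tracks), e.g. as input to a prediction pipeline.
#'
#' @param path FASTA file path.
#' @return a [TrackDataset-class] with sequence-only records.
#' @export
readFasta <- function(path) {
  lines <- readLines(path)
  hdr <- which(startsWith(lines, ">"))
  if (!length(hdr)) stop("no FASTA headers in ", path)
  bounds <- c(hdr, length(lines) + 1L)
  recs <- lapply(seq_along(hdr), function(k) {
    id <- sub("\\s.*$", "", substring(lines[hdr[k]], 2))
    seq <- paste(lines[seq.int(hdr[k] + 1L, bounds[k + 1L] - 1L)],
                 collapse = "")
    ProteinRecord(id, gsub("\\s", "", seq), source = "unknown")
  })
  TrackDataset(recs, provenance = path)
}
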