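#' @include AllClasses.R
NULL

## includes C -> C so that 3-state strings (the output alphabet) pass through
.SS8_TO_SS3 <- c(H = "H", G = "H", E = "E", B = "E",
                 I = "C", T = "C", S = "C", "-" = "C", C = "C")

#' Collapse 8-state secondary structure to 3 states
#'
#' DSSP-style 8-state codes are reduced to helix/strand/coil: H and G become
#' helix (H), E and B become strand (E), and the remaining states (I, T, S
#' and `-`) become coil (C). `NA` entries (unknown residues) pass through
#' unchanged. Codes already in \{H, E, C\} map to themselves, so the collapse
#' is idempotent.
#'
#' @param ss8 a single string over the 8-state alphabet, or a character
#'   vector of per-residue codes (possibly with `NA`).
#' @return same shape as the input, over \{H, E, C\}.
#' @examples
#' ss8ToSs3("HGEBTSI-")  # "HHEECCCC"
#' @export
ss8ToSs3 <- function(ss8) {
  if (length(ss8) == 1L && !is.na(ss8)) {
    codes <- strsplit(ss8, "")[[1]]
    bad <- which(!(codes %in% names(.SS8_TO_SS3)))
    if (length(bad))
      stop(sprintf("unknown secondary-structure code '%s' at position %d",
                   codes[bad[1]], bad[1]))
    return(paste(.SS8_TO_SS3[codes], collapse = ""))
  }
  out <- rep(NA_character_, length(ss8))
  known <- !is.na(ss8)
  bad <- which(known & !(ss8 %in% names(.SS8_TO_SS3)))
  if (length(bad))
    stop(sprintf("unknown secondary-structure code '%s' at position %d",
                 ss8[bad[1]], bad[1]))
  out[known] <- unname(.SS8_TO_SS3[ss8[known]])
  out
}

#' Default maximum solvent accessibility table
#'
#' Residue-specific maximum accessible surface areas (in square Angstrom)
#' used to normalize absolute solvent accessibility to relative solvent
#' accessibility. The bundled values are the theoretical maxima of Tien et
#' al. (2013, PLoS ONE 8:e80635), shipped as data under
#' `inst/extdata/max_asa.tsv`; any table covering the 20 standard residues
#' with positive values can be supplied instead.
#'
#' @param path optional path to an alternative two-column TSV
#'   (residue, max_asa).
#' @return named numeric vector, one entry per amino-acid letter.
#' @export
defaultMaxAsaTable <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "max_asa.tsv", package = "nucmeta",
                        mustWork = TRUE)
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  out <- stats::setNames(as.numeric(tab$max_asa), tab$residue)
  stopifnot(all(out > 0), length(out) >= 20L)
  out
}

#' Relative solvent accessibility
#'
#' Normalizes absolute solvent accessibility by a residue-specific maximum
#' and clips at 1 (observed values can exceed the tabulated maxima). `NA`
#' accessibilities propagate as `NA`.
#'
#' @param asa absolute solvent accessibility in square Angstrom (vectorized).
#' @param residue amino-acid letter(s), recycled against `asa`.
#' @param table named numeric maximum-ASA table, e.g.
#'   [defaultMaxAsaTable()].
#' @return relative accessibility in \[0, 1\].
#' @examples
#' tab <- c(G = 104, W = 285)
#' relativeAccessibility(c(52, 300), c("G", "W"), tab)
#' @export
relativeAccessibility <- function(asa, residue, table) {
  if (length(residue) == 1L) residue <- rep(residue, length(asa))
  stopifnot(length(residue) == length(asa))
  miss <- setdiff(unique(residue[!is.na(asa)]), names(table))
  if (length(miss))
    stop("residue(s) absent from max-ASA table: ",
         paste(miss, collapse = ", "))
  if (any(asa < 0, na.rm = TRUE)) stop("negative absolute accessibility")
  pmin(1, asa / unname(table[residue]))
}

#' Remove protein fragments by description token
#'
#' Drops entries whose description contains the token "Fragment"
#' (case-sensitive, whether bare or parenthesized), preserving the order of
#' the remaining entries. This mirrors the curation rule that excludes
#' UniProt fragment sequences from a proteome collection.
#'
#' @param entries data.frame with columns `id`, `description`, `sequence`.
#' @return the retained rows of `entries`.
#' @export
filterFragments <- function(entries) {
  stopifnot(all(c("id", "description", "sequence") %in% names(entries)))
  keep <- !grepl("Fragment", entries$description, fixed = TRUE)
  entries[keep, , drop = FALSE]
}

#' Position-wise selection of covering PDB chains
#'
#' Assigns to each position of a protein sequence the chain that should
#' provide its structural annotation: short chains (length below `minLen`,
#' i.e. 30 or fewer residues by default) are discarded; among the remaining
#' chains covering a position, the longest wins; length ties are broken by
#' the best (numerically smallest) resolution, with chains lacking a
#' resolution losing all resolution tie-breaks; remaining ties fall back to
#' lexicographic (pdb_id, chain_id). Assignment is per position, so
#' different portions of the sequence may come from different chains.
#'
#' @param chains data.frame with columns `pdb_id`, `chain_id`, `start`,
#'   `end` (half-open 0-based coverage interval on the protein sequence)
#'   and `resolution` (Angstrom, `NA` allowed).
#' @param seqLen protein sequence length.
#' @param minLen minimum chain length retained (default 31, excluding
#'   chains of 30 or fewer residues).
#' @return character vector of length `seqLen`: `"<pdb_id>_<chain_id>"` per
#'   covered position, `NA` where no retained chain covers the position.
#' @examples
#' ch <- data.frame(pdb_id = c("1AAA", "1BBB"), chain_id = c("A", "B"),
#'                  start = c(0, 0), end = c(120, 150),
#'                  resolution = c(2.0, 2.5))
#' selectCoveringChains(ch, 200)[11]  # "1BBB_B": longer chain wins
#' @export
selectCoveringChains <- function(chains, seqLen, minLen = 31L) {
  stopifnot(all(c("pdb_id", "chain_id", "start", "end", "resolution") %in%
                  names(chains)))
  if (nrow(chains)) {
    if (any(chains$start >= chains$end))
      stop("chain coverage interval with start >= end")
    if (any(chains$start < 0 | chains$end > seqLen))
      stop("chain coverage interval outside [0, seqLen)")
  }
  len <- chains$end - chains$start
  chains <- chains[len >= minLen, , drop = FALSE]
  out <- rep(NA_character_, seqLen)
  if (!nrow(chains)) return(out)
  len <- chains$end - chains$start
  res <- ifelse(is.na(chains$resolution), Inf, chains$resolution)
  ## global priority order implements the per-position rule: the first
  ## covering chain in this order is the winner at every position it covers
  ord <- order(-len, res, chains$pdb_id, chains$chain_id)
  for (k in rev(ord)) {
    idx <- seq.int(chains$start[k] + 1L, chains$end[k])
    out[idx] <- paste(chains$pdb_id[k], chains$chain_id[k], sep = "_")
  }
  out
}

#' Disorder labels from unresolved residues
#'
#' Missing-density convention for PDB-derived disorder: residues present in
#' SEQRES but absent from the resolved coordinates are labeled disordered;
#' resolved residues are labeled structured.
#'
#' @param resolvedMask logical vector, `TRUE` where the residue is resolved.
#' @return integer ternary disorder track (1 = disordered, 0 = structured).
#' @export
disorderFromUnresolved <- function(resolvedMask) {
  stopifnot(is.logical(resolvedMask))
  as.integer(!resolvedMask)
}
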