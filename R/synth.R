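#' @include AllClasses.R annotate.R validate.R
NULL

.AA20 <- c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I",
           "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Configuration for the synthetic residue-track generator
#'
#' Defines the statistical structure of generated datasets: a mix of
#' DNA-binding, RNA-binding and non-nucleic-acid-binding proteins; segmental
#' disorder regions; segmental binding sites placed at a higher prevalence
#' inside disordered regions than inside structured ones; coil-enriched
#' secondary structure inside disordered regions; solvent accessibility
#' elevated for coil, binding and disordered residues; and two noisy
#' binding-propensity tracks, one detecting the disorder-region binding
#' segments (disorder-trained role) and one the structured-region segments
#' (structure-trained role), with `overlapKappa` mixing the two
#' (the probability that a segment is detectable by both roles).
#'
#' Default prevalences follow curated human-proteome benchmarks: about 7%
#' of residues bind in structure-annotated binding proteins and about 20%
#' in disorder-annotated ones; structured-region secondary-structure
#' proportions (H, E, C) default to (0.38, 0.21, 0.41) and disordered-region
#' predicted proportions to (0.26, 0.08, 0.66). Secondary structure of
#' binding residues is drawn from `ssPropsBinding`, which encodes the strand
#' depletion of nucleic-acid-binding sites.
#'
#' @param nProteins number of proteins to generate.
#' @param lengthRange integer `c(min, max)` protein length.
#' @param classProbs probabilities `c(dna, rna, non_na)`, summing to 1.
#' @param bindingPrevalenceStructured fraction of structured-region residues
#'   that bind, within binding proteins.
#' @param bindingPrevalenceDisordered fraction of disordered-region residues
#'   that bind, within binding proteins.
#' @param disorderContent stationary fraction of disordered residues.
#' @param meanDisorderSegment mean disordered-segment length (residues).
#' @param overlapKappa probability a binding segment is detectable by both
#'   predictor roles (0 = fully complementary, 1 = fully redundant).
#' @param signalMu mean propensity lift on detectable residues.
#' @param noiseSigma Gaussian s.d. of propensity noise.
#' @param baseProp baseline propensity level of the binding tracks.
#' @param segmentLength integer `c(min, max)` binding-segment length.
#' @param ssPropsStructured (H, E, C) proportions for structured
#'   non-binding residues.
#' @param ssPropsBinding (H, E, C) proportions for structured binding
#'   residues (strand-depleted).
#' @param ssPropsDisordered (H, E, C) proportions of predicted secondary
#'   structure inside disordered regions (coil-biased).
#' @param rsaParams list: per-state mean RSA (`meanH`, `meanE`, `meanC`),
#'   additive `bindingLift`, Beta `concentration`, and
#'   `disorderedPredMean` for predicted RSA inside disordered regions.
#' @param predictionNoise list: `ssFlip` (probability a predicted SS state
#'   is flipped), `rsaSd` (s.d. of predicted-RSA noise), `disorderPropSd`
#'   plus `disorderPropMeanDis`/`disorderPropMeanStr` (predicted disorder
#'   propensity distribution by true state).
#' @param testFraction fraction of proteins held out as the test pool; the
#'   remainder is split 70/30 into train/validation.
#' @param seed integer seed; [generateDataset()] is fully reproducible
#'   from it.
#' @return a validated `SynthConfig` list.
#' @export
synthConfig <- function(nProteins = 300L,
                        lengthRange = c(80L, 300L),
                        classProbs = c(dna = 0.3, rna = 0.3, non_na = 0.4),
                        bindingPrevalenceStructured = 0.07,
                        bindingPrevalenceDisordered = 0.20,
                        disorderContent = 0.20,
                        meanDisorderSegment = 30,
                        overlapKappa = 0.25,
                        signalMu = 0.4,
                        noiseSigma = 0.1,
                        baseProp = 0.2,
                        segmentLength = c(3L, 15L),
                        ssPropsStructured = c(H = 0.38, E = 0.21, C = 0.41),
                        ssPropsBinding = c(H = 0.40, E = 0.07, C = 0.53),
                        ssPropsDisordered = c(H = 0.26, E = 0.08, C = 0.66),
                        rsaParams = list(meanH = 0.30, meanE = 0.22,
                                         meanC = 0.45, bindingLift = 0.15,
                                         concentration = 8,
                                         disorderedPredMean = 0.65),
                        predictionNoise = list(ssFlip = 0.15, rsaSd = 0.10,
                                               disorderPropSd = 0.15,
                                               disorderPropMeanDis = 0.70,
                                               disorderPropMeanStr = 0.25),
                        testFraction = 0.5,
                        seed = 1L) {
  cfg <- list(nProteins = as.integer(nProteins),
              lengthRange = as.integer(lengthRange),
              classProbs = classProbs,
              bindingPrevalenceStructured = bindingPrevalenceStructured,
              bindingPrevalenceDisordered = bindingPrevalenceDisordered,
              disorderContent = disorderContent,
              meanDisorderSegment = meanDisorderSegment,
              overlapKappa = overlapKappa, signalMu = signalMu,
              noiseSigma = noiseSigma, baseProp = baseProp,
              segmentLength = as.integer(segmentLength),
              ssPropsStructured = ssPropsStructured,
              ssPropsBinding = ssPropsBinding,
              ssPropsDisordered = ssPropsDisordered,
              rsaParams = rsaParams, predictionNoise = predictionNoise,
              testFraction = testFraction, seed = as.integer(seed))
  probs <- c(cfg$classProbs, cfg$bindingPrevalenceStructured,
             cfg$bindingPrevalenceDisordered, cfg$disorderContent,
             cfg$overlapKappa, cfg$testFraction,
             cfg$ssPropsStructured, cfg$ssPropsBinding, cfg$ssPropsDisordered)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (abs(sum(cfg$classProbs) - 1) > 1e-9) stop("classProbs must sum to 1")
  if (cfg$lengthRange[1] < cfg$segmentLength[2] ||
      cfg$lengthRange[1] > cfg$lengthRange[2])
    stop("invalid lengthRange")
  if (cfg$nProteins < 1L) stop("nProteins must be positive")
  structure(cfg, class = c("SynthConfig", "list"))
}

## Two-state Markov chain with stationary disorder fraction `content` and
## mean disordered-segment length `meanLen`; returns logical disorder mask.
.disorderMask <- function(L, content, meanLen) {
  if (content <= 0) return(rep(FALSE, L))
  exitP <- 1 / meanLen
  enterP <- exitP * content / (1 - content)
  state <- stats::runif(1) < content
  out <- logical(L)
  for (i in seq_len(L)) {
    out[i] <- state
    state <- if (state) stats::runif(1) >= exitP else stats::runif(1) < enterP
  }
  out
}

## Place contiguous binding segments inside the positions `region` (indices)
## until `target` residues are marked; segments are confined to runs of the
## region and truncated so the target is hit exactly.
.placeSegments <- function(L, region, target, segLen) {
  mask <- logical(L)
  segs <- list()
  if (target <= 0L || !length(region))
    return(list(mask = mask, segs = segs))
  target <- min(target, length(region))
  runs <- split(region, cumsum(c(1L, diff(region) != 1L)))
  guard <- 0L
  while (sum(mask) < target && guard < 10000L) {
    guard <- guard + 1L
    run <- runs[[sample.int(length(runs), 1L,
                            prob = lengths(runs))]]
    len <- sample(seq.int(segLen[1], segLen[2]), 1L)
    start <- sample(seq_along(run), 1L)
    idx <- run[seq.int(start, min(start + len - 1L, length(run)))]
    idx <- idx[!mask[idx]]
    need <- target - sum(mask)
    if (length(idx) > need) idx <- idx[seq_len(need)]
    if (!length(idx)) next
    mask[idx] <- TRUE
    segs[[length(segs) + 1L]] <- idx
  }
  list(mask = mask, segs = segs)
}

.rbetaMean <- function(n, mean, conc) {
  mean <- pmin(0.95, pmax(0.05, mean))
  stats::rbeta(n, mean * conc, (1 - mean) * conc)
}

.clip01 <- function(x) pmin(1, pmax(0, x))

## ss3 -> representative ss8 code (exercises the 8->3 collapse downstream)
.expandSs8 <- function(ss3) {
  vapply(ss3, function(s) {
    if (is.na(s)) return(NA_character_)
    switch(s,
           H = sample(c("H", "G"), 1L, prob = c(0.8, 0.2)),
           E = sample(c("E", "B"), 1L, prob = c(0.9, 0.1)),
           C = sample(c("T", "S", "-", "I"), 1L,
                      prob = c(0.35, 0.25, 0.35, 0.05)))
  }, character(1), USE.NAMES = FALSE)
}

#' Generate one synthetic protein record
#'
#' Draws a protein from the generative model of [synthConfig()] using the
#' current RNG state (seed it with `set.seed` or let [generateDataset()]
#' manage seeding). The returned record passes [validateRecord()]:
#' disordered residues carry no experimental secondary structure or
#' accessibility, binding classes have at least one binding residue, and
#' non-nucleic-acid-binding proteins have none.
#'
#' @param cfg a [synthConfig()] object.
#' @param id record id.
#' @param class optionally force the binding class instead of drawing it
#'   from `classProbs`.
#' @return a [ProteinRecord-class].
#' @export
generateProtein <- function(cfg, id = "SYN0001", class = NULL) {
  stopifnot(inherits(cfg, "SynthConfig"))
  if (is.null(class))
    class <- sample(c("dna_binding", "rna_binding", "non_na_binding"), 1L,
                    prob = cfg$classProbs)
  L <- sample(seq.int(cfg$lengthRange[1], cfg$lengthRange[2]), 1L)
  seq <- paste(sample(.AA20, L, replace = TRUE), collapse = "")
  aa <- strsplit(seq, "")[[1]]

  dis <- .disorderMask(L, cfg$disorderContent, cfg$meanDisorderSegment)
  struct <- which(!dis)
  disIdx <- which(dis)

  ## --- binding segments (one task per binding class) ---
  bind <- logical(L)
  detD <- logical(L)  # detectable by the disorder-trained role
  detS <- logical(L)  # detectable by the structure-trained role
  if (class != "non_na_binding") {
    tS <- round(cfg$bindingPrevalenceStructured * length(struct))
    tD <- round(cfg$bindingPrevalenceDisordered * length(disIdx))
    if (tS + tD == 0L) tS <- 1L  # binding class must have >= 1 binding residue
    pS <- .placeSegments(L, struct, tS, cfg$segmentLength)
    pD <- .placeSegments(L, disIdx, tD, cfg$segmentLength)
    bind <- pS$mask | pD$mask
    detS <- pS$mask
    detD <- pD$mask
    ## kappa: whole segments become detectable by both roles
    for (idx in pS$segs)
      if (stats::runif(1) < cfg$overlapKappa) detD[idx] <- TRUE
    for (idx in pD$segs)
      if (stats::runif(1) < cfg$overlapKappa) detS[idx] <- TRUE
  }

  ## --- experimental secondary structure (structured residues only) ---
  ss3 <- rep(NA_character_, L)
  nb <- struct[!bind[struct]]
  bb <- struct[bind[struct]]
  if (length(nb))
    ss3[nb] <- sample(names(cfg$ssPropsStructured), length(nb),
                      replace = TRUE, prob = cfg$ssPropsStructured)
  if (length(bb))
    ss3[bb] <- sample(names(cfg$ssPropsBinding), length(bb),
                      replace = TRUE, prob = cfg$ssPropsBinding)
  ss8 <- .expandSs8(ss3)

  ## --- solvent accessibility (structured residues only) ---
  rp <- cfg$rsaParams
  rsa <- rep(NA_real_, L)
  if (length(struct)) {
    means <- c(H = rp$meanH, E = rp$meanE, C = rp$meanC)[ss3[struct]]
    means <- means + rp$bindingLift * bind[struct]
    rsa[struct] <- .rbetaMean(length(struct), means, rp$concentration)
  }
  maxAsa <- defaultMaxAsaTable()
  asa <- round(rsa * unname(maxAsa[aa]), 3)
  rsa <- round(rsa, 3)

  ## --- predicted tracks ---
  pn <- cfg$predictionNoise
  ss3Pred <- character(L)
  if (length(struct)) {
    ss3Pred[struct] <- ss3[struct]
    flip <- struct[stats::runif(length(struct)) < pn$ssFlip]
    if (length(flip))
      ss3Pred[flip] <- vapply(ss3Pred[flip], function(s)
        sample(setdiff(.SS3_ALPHABET, s), 1L), character(1))
  }
  if (length(disIdx))
    ss3Pred[disIdx] <- sample(names(cfg$ssPropsDisordered), length(disIdx),
                              replace = TRUE, prob = cfg$ssPropsDisordered)

  rsaPred <- rep(NA_real_, L)
  if (length(struct))
    rsaPred[struct] <- .clip01(rsa[struct] +
                                 stats::rnorm(length(struct), 0, pn$rsaSd))
  if (length(disIdx))
    rsaPred[disIdx] <- .rbetaMean(length(disIdx), rp$disorderedPredMean,
                                  rp$concentration)
  rsaPred <- round(rsaPred, 3)

  disProp <- .clip01(stats::rnorm(
    L, ifelse(dis, pn$disorderPropMeanDis, pn$disorderPropMeanStr),
    pn$disorderPropSd))
  disProp <- round(disProp, 3)

  propTrack <- function(ind) {
    round(.clip01(cfg$baseProp + cfg$signalMu * ind +
                    stats::rnorm(L, 0, cfg$noiseSigma)), 3)
  }
  task <- switch(class, dna_binding = "dna", rna_binding = "rna", NA)
  zero <- logical(L)
  dnaD <- propTrack(if (identical(task, "dna")) detD else zero)
  dnaS <- propTrack(if (identical(task, "dna")) detS else zero)
  rnaD <- propTrack(if (identical(task, "rna")) detD else zero)
  rnaS <- propTrack(if (identical(task, "rna")) detS else zero)

  labels <- list(disorder = as.integer(dis), ss8 = ss8, ss3 = ss3,
                 asa = asa, rsa = rsa,
                 dna_binding = as.integer(bind & identical(task, "dna")),
                 rna_binding = as.integer(bind & identical(task, "rna")))
  preds <- list(disorder_prop = disProp, ss3_pred = ss3Pred,
                rsa_pred = rsaPred,
                dna_disorder_trained = dnaD, rna_disorder_trained = rnaD,
                dna_structure_trained = dnaS, rna_structure_trained = rnaS)
  ProteinRecord(id, seq, source = "synthetic", bindingClass = class,
                labels = labels, predictions = preds)
}

#' Generate a seeded synthetic dataset with train/validation/test splits
#'
#' Produces `cfg$nProteins` records under the generative model of
#' [synthConfig()], holds out `cfg$testFraction` of the proteins as a test
#' pool and splits the remainder 70/30 into train/validation (protein-level,
#' unstratified). Fully reproducible from `cfg$seed`.
#'
#' @param cfg a [synthConfig()] object.
#' @return a [TrackDataset-class] with split assignments.
#' @export
generateDataset <- function(cfg) {
  stopifnot(inherits(cfg, "SynthConfig"))
  n <- cfg$nProteins
  if (n < 10L && all(cfg$classProbs > 0))
    stop("need at least 10 proteins when all three classes are requested")
  withr::with_seed(cfg$seed, {
    recs <- lapply(seq_len(n), function(i)
      generateProtein(cfg, id = sprintf("SYN%04d", i)))
    splits <- rep("train", n)
    testIdx <- sample.int(n, round(cfg$testFraction * n))
    rest <- setdiff(seq_len(n), testIdx)
    valIdx <- sample(rest, round(0.3 * length(rest)))
    splits[testIdx] <- "test"
    splits[valIdx] <- "validation"
    recs <- Map(function(r, s) { r@split <- s; r }, recs, splits)
  })
  TrackDataset(recs, provenance = sprintf(
    "synthetic: n=%d, kappa=%.2f, sigma=%.2f, seed=%d",
    n, cfg$overlapKappa, cfg$noiseSigma, cfg$seed))
}

#' Subset a dataset by split assignment
#'
#' @param ds a [TrackDataset-class].
#' @param split one of `"train"`, `"validation"`, `"test"`, `"none"`.
#' @return a [TrackDataset-class] with the matching records.
#' @export
splitRecords <- function(ds, split) {
  keep <- vapply(records(ds), function(r) r@split == split, logical(1))
  ds[which(keep)]
}
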