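# Fixture builders shared across the suite. Everything is generated in code;
# no fixture files.

# A small fully structured DNA-binding record with consistent tracks.
makeBindingRecord <- function(id = "P1", n = 12L, nBind = 3L,
                              class = "dna_binding") {
  task <- if (class == "rna_binding") "rna" else "dna"
  bind <- integer(n)
  if (class != "non_na_binding") bind[seq_len(nBind)] <- 1L
  ss3 <- rep(c("H", "E", "C"), length.out = n)
  labels <- list(disorder = integer(n),
                 ss3 = ss3,
                 rsa = round(seq(0.1, 0.9, length.out = n), 3))
  labels[[paste0(task, "_binding")]] <- bind
  if (class == "non_na_binding") {
    labels$dna_binding <- integer(n)
    labels$rna_binding <- integer(n)
  }
  preds <- list(
    disorder_prop = round(seq(0.05, 0.6, length.out = n), 3),
    ss3_pred = ss3,
    rsa_pred = round(seq(0.1, 0.9, length.out = n), 3),
    dna_disorder_trained = round(0.2 + 0.6 * (bind * (task == "dna")), 3),
    dna_structure_trained = round(0.25 + 0.5 * (bind * (task == "dna")), 3),
    rna_disorder_trained = round(0.2 + 0.6 * (bind * (task == "rna")), 3),
    rna_structure_trained = round(0.25 + 0.5 * (bind * (task == "rna")), 3))
  ProteinRecord(id, paste(rep("ACDEFGHIKLMNPQRSTVWY", 5), collapse = "") |>
                  substr(1, n),
                source = "synthetic", bindingClass = class,
                labels = labels, predictions = preds)
}

makeSmallDataset <- function() {
  TrackDataset(list(
    makeBindingRecord("D1", 12, 3, "dna_binding"),
    makeBindingRecord("D2", 10, 2, "dna_binding"),
    makeBindingRecord("N1", 8, 0, "non_na_binding"),
    makeBindingRecord("N2", 9, 0, "non_na_binding")))
}

# Brute-force pair-counting AUC oracle (independent of the rank-based path).
aucBrute <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  s <- 0
  for (p in pos) s <- s + sum(p > neg) + 0.5 * sum(p == neg)
  s / (length(pos) * length(neg))
}

# Exhaustive threshold-enumeration oracles for the operating-point metrics.
sensOracle <- function(labels, scores, cap) {
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  best <- 0
  for (t in thr) {
    fpr <- mean(scores[labels == 0] >= t)
    if (fpr <= cap) best <- max(best, mean(scores[labels == 1] >= t))
  }
  best
}
specOracle <- function(labels, scores, floor) {
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  best <- 0
  for (t in thr) {
    tpr <- mean(scores[labels == 1] >= t)
    if (tpr >= floor) best <- max(best, 1 - mean(scores[labels == 0] >= t))
  }
  best
}
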