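# Independent oracles and fixture builders shared across the suite.

# Exhaustive cutoff search: tries every distinct observed value as a cutoff
# and scores it by direct comparison; ties broken toward the smallest value.
oracleCutoff <- function(values, labels, direction) {
  cand <- sort(unique(values))
  best <- list(cutoff = NA_real_, accuracy = -1)
  for (c in cand) {
    pred <- if (direction == "oncogene") as.integer(values >= c)
            else as.integer(values <= c)
    acc <- mean(pred == labels)
    if (acc > best$accuracy) best <- list(cutoff = c, accuracy = acc)
  }
  best
}

# Exhaustive pairwise Mann-Whitney AUC, ties counted one half.
oracleAuc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

panelDirections <- c(FGFR1 = "suppressor", MYPT1 = "oncogene",
                     LDHB = "oncogene")

# Tiny StainingExperiment from a markers-by-cases matrix.
makeSE <- function(mat, batch = rep("TMA1", ncol(mat)), normalized = FALSE,
                   clinical = NULL) {
  if (is.null(rownames(mat))) rownames(mat) <- paste0("M", seq_len(nrow(mat)))
  if (is.null(colnames(mat))) colnames(mat) <- paste0("P", seq_len(ncol(mat)))
  StainingExperiment(mat, batch = batch, clinical = clinical,
                     normalized = normalized)
}

# A separable toy panel: marker rows carry opposite-side class means with no
# overlap, so any sensible fit reaches training accuracy 1.
separableConfig <- function(nAgg = 10, nInd = 15, seed = 11,
                            nBatches = 1, batchShiftSd = 0,
                            batchScaleRange = c(1, 1)) {
  cohortConfig(
    nAggressive = nAgg, nIndolent = nInd,
    markers = markerPanel(names(panelDirections),
                          unname(panelDirections),
                          trueCutoff = c(150, 120, 135),
                          classSeparation = 30, noiseSd = 0),
    nBatches = nBatches, batchShiftSd = batchShiftSd,
    batchScaleRange = batchScaleRange, seed = seed)
}
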