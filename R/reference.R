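#' Published reference performance tables
#'
#' Detection-performance and confusion-count tables reported for the
#' ten-subject prefrontal single-channel auditory ERP-BCI study whose
#' paradigm and defaults this package models. `performance` holds one row
#' per subject x analysis x command count with the number of correct
#' decisions (`correct`) out of all decisions (`total`) — the exact
#' fractions fixed by the design (15/60/90/60 decisions offline for
#' 5/4/3/2 commands, 6 in the first online session, 24 in the second) —
#' plus the printed accuracy percentage and ITR. Two cells are flagged:
#' their printed ITR (1.30) disagrees with the ITR formula at 100%
#' accuracy and 2 commands (1.33), an apparent typo. `confusion` holds the
#' aggregated true-by-predicted decision counts of the offline and two
#' online analyses in long format.
#'
#' Analyses: `offline_candidates` (ordinary LOTOCV, training restricted to
#' candidate-target trials), `offline_all` (non-candidate trials included
#' in training), `online1`, `online2`.
#'
#' @return list of two data.frames, `performance` and `confusion`.
#' @export
referenceBenchmarks <- function() {
  dir <- system.file("extdata", "reference", package = "erpbci")
  perf <- utils::read.csv(file.path(dir, "detection_performance.csv"))
  perf$flagged <- as.logical(perf$flagged)
  conf <- utils::read.csv(file.path(dir, "confusion_counts.csv"))
  list(performance = perf, confusion = conf)
}

#' Reference confusion matrix of one analysis
#'
#' Convenience reshaping of the long-format confusion counts into the
#' square matrix [confusionFromCounts()] expects.
#'
#' @param analysis one of "offline", "online1", "online2".
#' @return integer matrix, true labels in rows.
#' @export
referenceConfusionMatrix <- function(analysis = c("offline", "online1", "online2")) {
  analysis <- match.arg(analysis)
  conf <- referenceBenchmarks()$confusion
  conf <- conf[conf$analysis == analysis, ]
  labs <- sort(unique(conf$true))
  m <- matrix(0L, length(labs), length(labs), dimnames = list(labs, labs))
  for (i in seq_len(nrow(conf)))
    m[as.character(conf$true[i]), as.character(conf$predicted[i])] <-
      conf$count[i]
  m
}
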