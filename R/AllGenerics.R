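#' @import methods
NULL

#' Sound labels of the five-command auditory oddball paradigm
#'
#' Integer codes and azimuths of the five natural-sound stimuli used by the
#' paradigm: 1 = duck (0 deg, left), 2 = singing bird (45 deg, center-left),
#' 3 = frog (90 deg, center), 4 = seagull (135 deg, center-right),
#' 5 = dove (180 deg, right). The label/azimuth mapping is a bijection.
#'
#' @format `soundLabels()` returns a named integer vector; `soundAzimuths()`
#'   a named numeric vector of azimuths in degrees, named by label code.
#' @export
soundLabels <- function() {
  c(duck = 1L, bird = 2L, frog = 3L, seagull = 4L, dove = 5L)
}

#' @rdname soundLabels
#' @export
soundAzimuths <- function() {
  c(`1` = 0, `2` = 45, `3` = 90, `4` = 135, `5` = 180)
}

#' @title Accessor generics
#' @description Slot accessors for the package's S4 classes. `samples()`
#'   returns raw signal in microvolts, `sampleRate()` the sampling rate in
#'   Hz, `scheduleEvents()` the event table of a stimulus schedule,
#'   `epochMatrix()`/`featureMatrix()` the epoch-by-time and
#'   epoch-by-feature matrices of an [EpochSet], `epochLabels()` and
#'   `epochTargets()` their per-epoch sound labels and target flags,
#'   `targetLabel()` the attended sound of a schedule or trial,
#'   `selectedFeatures()` the feature indices retained by a fitted
#'   [SWLDAModel], and `trials()` the per-trial [EpochSet] list of an
#'   [ERPDataset].
#' @param x object
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("samples", function(x) standardGeneric("samples"))

#' @rdname accessors
#' @export
setGeneric("sampleRate", function(x) standardGeneric("sampleRate"))

#' @rdname accessors
#' @export
setGeneric("scheduleEvents", function(x) standardGeneric("scheduleEvents"))

#' @rdname accessors
#' @export
setGeneric("targetLabel", function(x) standardGeneric("targetLabel"))

#' @rdname accessors
#' @export
setGeneric("epochMatrix", function(x) standardGeneric("epochMatrix"))

#' @rdname accessors
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))

#' @rdname accessors
#' @export
setGeneric("epochLabels", function(x) standardGeneric("epochLabels"))

#' @rdname accessors
#' @export
setGeneric("epochTargets", function(x) standardGeneric("epochTargets"))

#' @rdname accessors
#' @export
setGeneric("selectedFeatures", function(x) standardGeneric("selectedFeatures"))

#' @rdname accessors
#' @export
setGeneric("trials", function(x) standardGeneric("trials"))
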