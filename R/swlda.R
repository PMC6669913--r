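#' Least-squares coefficient p-values
#'
#' Ordinary least squares of `y` on `X` (no implicit intercept; include a
#' column of ones if wanted) via Cholesky factorization of the Gram
#' matrix, returning coefficients and two-sided t-test p-values. This is
#' the primitive both stepwise directions use.
#'
#' @param X numeric design matrix (n x p).
#' @param y numeric response.
#' @return list with `coef`, `se`, `p` (length p) and `df`.
#' @export
olsCoefPValues <- function(X, y) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (n <= p) stop("rank deficiency: need more observations than coefficients")
  fit <- gramOls(crossprod(X), crossprod(X, y), sum(y^2), n,
                 seq_len(p))
  if (is.null(fit)) stop("rank-deficient design matrix")
  fit
}

## Subset OLS from sufficient statistics: G = X'X, cy = X'y, yty = y'y.
## Returns NULL when the subset is numerically rank-deficient
## (condition > condLimit on the Cholesky factor).
gramOls <- function(G, cy, yty, n, cols, condLimit = 1e10) {
  Gs <- G[cols, cols, drop = FALSE]
  R <- tryCatch(chol(Gs), error = function(e) NULL)
  if (is.null(R)) return(NULL)
  d <- diag(R)
  if (min(d) <= 0 || (max(d) / min(d))^2 > condLimit) return(NULL)
  b <- backsolve(R, forwardsolve(t(R), cy[cols]))
  rss <- max(yty - sum(b * cy[cols]), 0)
  df <- n - length(cols)
  if (df <= 0) return(NULL)
  sigma2 <- rss / df
  XtXinv <- chol2inv(R)
  se <- sqrt(pmax(diag(XtXinv), 0) * sigma2)
  tt <- ifelse(se > 0, b / se, Inf)
  list(coef = as.numeric(b), se = se, p = 2 * stats::pt(-abs(tt), df),
       df = df)
}

#' Fit a stepwise linear discriminant (SWLDA)
#'
#' Classic stepwise regression of class-coded labels (targets +1,
#' non-targets -1) on the feature columns. Forward step: among unselected
#' features, compute each candidate's coefficient p-value in the
#' least-squares fit on (intercept + selected + candidate) and add the
#' minimum-p candidate if its p < `pEnter` (0.10). Backward step: after
#' any addition, refit on the selected set and repeatedly remove the
#' feature with the largest p > `pRemove` (0.15). Iterate until no change
#' or the caps are hit; final weights are the least-squares coefficients
#' on the retained set. The intercept is always included and never subject
#' to stepping. Candidates whose addition makes the design numerically
#' rank-deficient (condition > 1e10) are skipped; p-value ties resolve to
#' the lower feature index.
#'
#' @param X numeric feature matrix, one row per epoch (n x 16 at defaults).
#' @param y class labels: logical, 0/1, or +/-1; TRUE/1 = target.
#' @param pEnter forward entry threshold, default 0.10.
#' @param pRemove backward removal threshold, default 0.15; must be >=
#'   pEnter.
#' @param maxFeatures cap on retained features, default ncol(X).
#' @param maxIterations safety cap on forward/backward rounds.
#' @return [SWLDAModel]. A model that selects no feature is returned with
#'   a warning (its score is the constant intercept).
#' @seealso [swldaScore()], [decideTarget()]
#' @export
swldaFit <- function(X, y, pEnter = 0.10, pRemove = 0.15,
                     maxFeatures = ncol(X), maxIterations = 100L) {
  X <- as.matrix(X)
  n <- nrow(X); nf <- ncol(X)
  stopifnot(0 < pEnter, pEnter <= pRemove, pRemove < 1)
  yy <- if (is.logical(y)) ifelse(y, 1, -1)
        else if (all(y %in% c(0, 1))) ifelse(y == 1, 1, -1)
        else as.numeric(y)
  if (length(yy) != n) stop("length(y) must equal nrow(X)")
  if (length(unique(sign(yy))) < 2)
    stop("both classes must be present in the training labels")
  if (n <= 2) stop("too few observations")
  Xd <- cbind(1, X)                       # column 1 = intercept
  model <- swldaFitCore(crossprod(Xd), as.numeric(crossprod(Xd, yy)),
                        sum(yy^2), n, nf, pEnter, pRemove, maxFeatures,
                        maxIterations)
  if (length(model@selected) == 0)
    warning("no feature met the entry criterion; intercept-only model")
  model@trainingMeta <- list(n = n, nTarget = sum(yy > 0),
                             nNonTarget = sum(yy < 0), nFeatures = nf)
  model
}

## Stepwise core on sufficient statistics (G = [1 X]'[1 X], cy = [1 X]'y,
## yty = y'y). Gram matrices are additive over epoch blocks, which the
## cross-validation loops exploit.
swldaFitCore <- function(G, cy, yty, n, nf, pEnter = 0.10, pRemove = 0.15,
                         maxFeatures = nf, maxIterations = 100L) {
  selected <- integer(0)
  for (iter in seq_len(maxIterations)) {
    changed <- FALSE
    ## forward
    if (length(selected) < maxFeatures) {
      bestP <- Inf; bestJ <- NA_integer_
      for (j in setdiff(seq_len(nf), selected)) {
        fit <- gramOls(G, cy, yty, n, c(1L, selected + 1L, j + 1L))
        if (is.null(fit)) next                    # collinear: skip
        pj <- fit$p[length(fit$p)]
        if (pj < bestP - 1e-15) { bestP <- pj; bestJ <- j }
      }
      if (!is.na(bestJ) && bestP < pEnter) {
        selected <- c(selected, bestJ)
        changed <- TRUE
      }
    }
    ## backward (runs to completion after each forward decision)
    repeat {
      if (length(selected) == 0) break
      fit <- gramOls(G, cy, yty, n, c(1L, selected + 1L))
      if (is.null(fit)) stop("selected set became rank-deficient")
      pv <- fit$p[-1]
      worst <- which.max(pv)
      if (pv[worst] > pRemove) {
        selected <- selected[-worst]
        changed <- TRUE
      } else break
    }
    if (!changed) break
  }
  cfg <- list(pEnter = pEnter, pRemove = pRemove,
              maxFeatures = maxFeatures, maxIterations = maxIterations)
  if (length(selected) == 0)
    return(new("SWLDAModel", selected = integer(0), weights = numeric(0),
               intercept = cy[1] / n, config = cfg,
               trainingMeta = list(n = n)))
  final <- gramOls(G, cy, yty, n, c(1L, selected + 1L))
  new("SWLDAModel",
      selected = as.integer(selected),
      weights = final$coef[-1],
      intercept = final$coef[1],
      config = cfg, trainingMeta = list(n = n))
}

#' Score feature vectors with a fitted SWLDA model
#'
#' Linear discriminant score `intercept + x[selected] %*% weights`; larger
#' scores are more target-like. Accepts a single vector or a matrix (one
#' row per waveform).
#'
#' @param model [SWLDAModel].
#' @param x numeric vector or matrix of feature values.
#' @return numeric score(s).
#' @export
swldaScore <- function(model, x) {
  stopifnot(is(model, "SWLDAModel"))
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  if (length(model@selected) == 0)
    return(rep(model@intercept, nrow(x)))
  as.numeric(model@intercept +
             x[, model@selected, drop = FALSE] %*% model@weights)
}

#' Decide the target sound from per-label scores
#'
#' The label with the highest score is the decision; if that label is not
#' an eligible output command, the decision falls through to the
#' next-highest score until an eligible label is reached (the rule that
#' always excludes sounds 2 and 4 online). Score ties resolve to the lower
#' label number.
#'
#' @param scores numeric vector of discriminant scores; names or positions
#'   are the sound labels (1..5 by default).
#' @param candidates integer labels eligible as output (2 to 5 of them).
#' @return the predicted label (integer).
#' @export
decideTarget <- function(scores, candidates = seq_along(scores)) {
  labels <- if (!is.null(names(scores))) as.integer(names(scores))
            else seq_along(scores)
  candidates <- as.integer(candidates)
  if (!any(labels %in% candidates))
    stop("no candidate label among the scored labels")
  ord <- order(-scores, labels)    # ties: lower label first
  for (i in ord) if (labels[i] %in% candidates) return(labels[i])
}

#' Serialize / restore an SWLDA model as JSON
#'
#' @param model [SWLDAModel].
#' @param path JSON file path.
#' @return `writeSwldaModel` the path invisibly; `readSwldaModel` an
#'   [SWLDAModel].
#' @export
writeSwldaModel <- function(model, path) {
  stopifnot(is(model, "SWLDAModel"))
  obj <- list(selected = model@selected, weights = model@weights,
              intercept = model@intercept, config = model@config,
              training_meta = model@trainingMeta)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeSwldaModel
#' @export
readSwldaModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("SWLDAModel", selected = as.integer(obj$selected),
      weights = as.numeric(obj$weights),
      intercept = as.numeric(obj$intercept),
      config = as.list(obj$config),
      trainingMeta = as.list(obj$training_meta))
}
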