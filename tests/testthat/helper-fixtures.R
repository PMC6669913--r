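# Shared fixtures, built in code at test time.

# A deterministic schedule whose target always occupies the same slot, so
# consecutive target onsets are >= 1.5 s apart and target epochs carry no
# bleed from neighbouring target responses.
fixedSlotSchedule <- function(targetLabel = 1L, nSequences = 10L,
                              slot = 3L, soa = 0.3) {
  labels <- integer(0)
  others <- setdiff(1:5, targetLabel)
  for (i in seq_len(nSequences)) {
    perm <- integer(5)
    perm[slot] <- targetLabel
    perm[-slot] <- sample(others)
    labels <- c(labels, perm)
  }
  ev <- data.frame(onset_s = (seq_along(labels) - 1) * soa,
                   label = labels, is_target = labels == targetLabel)
  new("StimulusSchedule", events = ev, soa = soa,
      nSequences = as.integer(nSequences),
      targetLabel = as.integer(targetLabel))
}

# A small, quick noiseless subject (reduced sequence count) for structural
# and ceiling checks where the full 30-sequence design is not needed.
quickSubject <- function(seed, noiseSd = 0, nSequences = 10L,
                         jitterCv = 0, template = NULL) {
  simulateSubject(seed, template = template,
                  noise = noiseModel(sd = noiseSd),
                  nSequences = nSequences, epochJitterCv = jitterCv)
}

# Independent normal-equations OLS oracle: coefficient p-values via
# explicit solve() and the t distribution.
naiveOlsPValues <- function(X, y) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  XtXinv <- solve(t(X) %*% X)
  beta <- XtXinv %*% t(X) %*% y
  res <- y - X %*% beta
  sigma2 <- sum(res^2) / (n - p)
  se <- sqrt(diag(XtXinv) * sigma2)
  tval <- beta / se
  list(coef = as.numeric(beta),
       p = as.numeric(2 * pt(-abs(tval), n - p)))
}

# Independent reimplementation of the stepwise selection loop on top of
# the naive OLS oracle (no code shared with swldaFit).
naiveStepwise <- function(X, y, pEnter = 0.10, pRemove = 0.15) {
  X <- as.matrix(X)
  yy <- ifelse(as.logical(y), 1, -1)
  sel <- integer(0)
  repeat {
    changed <- FALSE
    cand <- setdiff(seq_len(ncol(X)), sel)
    if (length(cand)) {
      ps <- sapply(cand, function(j) {
        Xj <- cbind(1, X[, sel, drop = FALSE], X[, j])
        if (qr(Xj)$rank < ncol(Xj)) return(Inf)
        fit <- naiveOlsPValues(Xj, yy)
        fit$p[length(fit$p)]
      })
      if (min(ps) < pEnter) {
        sel <- c(sel, cand[which.min(ps)])
        changed <- TRUE
      }
    }
    repeat {
      if (!length(sel)) break
      fit <- naiveOlsPValues(cbind(1, X[, sel, drop = FALSE]), yy)
      pv <- fit$p[-1]
      w <- which.max(pv)
      if (pv[w] > pRemove) { sel <- sel[-w]; changed <- TRUE } else break
    }
    if (!changed) break
  }
  fit <- if (length(sel))
    naiveOlsPValues(cbind(1, X[, sel, drop = FALSE]), yy) else NULL
  list(selected = sel,
       weights = if (length(sel)) fit$coef[-1] else numeric(0),
       intercept = if (length(sel)) fit$coef[1] else mean(yy))
}

# Independent ITR reimplementation (plain transcription of the formula).
naiveItr <- function(N, P, T = 45) {
  b <- log2(N)
  if (P < 1) b <- b + P * log2(P) + (1 - P) * log2((1 - P) / (N - 1))
  b * 60 / T
}
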