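#' @include substitution_model.R
NULL

## ---- ancestral posteriors ---------------------------------------------------

#' Posterior distribution of the ancestral nucleotide at one position
#'
#' Bayes inversion of the star-phylogeny model: the posterior of ancestral
#' nucleotide r given the observed (human, mouse, dog) triple is
#' proportional to p(r) p(h|r) p(m|r) p(d|r). The normalizer — the marginal
#' probability of the observed triple under the model — is returned as
#' attribute \code{"normalizer"}; across positions these normalizers (and
#' the per-position posteriors) multiply into the full-site ancestral
#' probability, see \code{\link{ancestralSiteProbability}}.
#'
#' @param model a \linkS4class{PositionModel}
#' @param h,m,d single nucleotides (A/C/G/T) observed in human, mouse, dog
#' @return numeric(4) posterior over A,C,G,T with attribute
#'   \code{normalizer}
#' @export
ancestralPosterior <- function(model, h, m, d) {
  ih <- .nucIndex(h); im <- .nucIndex(m); id <- .nucIndex(d)
  if (anyNA(c(ih, im, id)))
    stop("h, m, d must each be one of A, C, G, T")
  w <- model@ancestral * model@matrices$human[, ih] *
    model@matrices$mouse[, im] * model@matrices$dog[, id]
  z <- sum(w)
  if (z <= 0)
    stop("observed triple (", h, ",", m, ",", d,
         ") has zero probability under the model")
  out <- w / z
  names(out) <- NUC
  attr(out, "normalizer") <- z
  out
}

#' Probability of a full ancestral site given the descendant triple
#'
#' Product over analysis-window positions of the per-position ancestral
#' posteriors (positions are assumed independent in the ancestor).
#'
#' @param models named list of \linkS4class{PositionModel}s keyed by
#'   position label
#' @param r,h,m,d character vectors of nucleotides at those positions for
#'   the ancestor and the three descendants (parallel to \code{models})
#' @return the probability p(R | H, M, D)
#' @export
ancestralSiteProbability <- function(models, r, h, m, d) {
  stopifnot(length(r) == length(models), length(h) == length(models),
            length(m) == length(models), length(d) == length(models))
  p <- 1
  for (i in seq_along(models)) {
    post <- ancestralPosterior(models[[i]], h[i], m[i], d[i])
    p <- p * post[.nucIndex(r[i])]
  }
  unname(p)
}

## ---- PWM --------------------------------------------------------------------

#' Build a position weight matrix over the analysis window
#'
#' With \code{source = "descendants_pooled"} (the default), foreground
#' probabilities are pseudocounted nucleotide frequencies over the pooled
#' human + mouse + dog sequences of all supplied datasets. With
#' \code{source = "ancestral"}, they come from the fitted ancestral vectors
#' p(Z) of \code{models}, mixed with the same pseudocount against the
#' effective site count.
#'
#' @param datasets a \linkS4class{SpliceSiteSet} or list of them (pooled).
#' @param source "descendants_pooled" or "ancestral".
#' @param pseudocount added per nucleotide per position (default 0.5).
#' @param logBase base for strengths (default 2, bits).
#' @param positions window labels; default = the scheme's analysis window.
#' @param models for \code{source = "ancestral"}: named list of
#'   \linkS4class{PositionFit}/\linkS4class{PositionModel} keyed by label.
#' @return a \linkS4class{SitePWM}
#' @export
buildPWM <- function(datasets, source = c("descendants_pooled", "ancestral"),
                     pseudocount = 0.5, logBase = 2, positions = NULL,
                     models = NULL) {
  source <- match.arg(source)
  if (is(datasets, "SpliceSiteSet")) datasets <- list(datasets)
  if (length(datasets) == 0L || all(vapply(datasets, length, 1L) == 0L))
    stop("empty input")
  sch <- positionScheme(ssType(datasets[[1]]))
  if (is.null(positions)) positions <- sch@window
  if (source == "descendants_pooled") {
    counts <- matrix(0, 4L, length(positions),
                     dimnames = list(NUC, positions))
    for (ds in datasets) for (g in c("human", "mouse", "dog")) {
      pm <- positionMatrix(ds, g, positions)
      for (j in seq_along(positions)) {
        i <- .nucIndex(pm[, j])
        counts[, j] <- counts[, j] + tabulate(i[!is.na(i)], 4L)
      }
    }
    if (any(colSums(counts) == 0))
      stop("position(s) with zero usable sequences: ",
           paste(positions[colSums(counts) == 0], collapse = ", "))
    probs <- sweep(counts + pseudocount, 2L,
                   colSums(counts) + 4 * pseudocount, "/")
  } else {
    if (is.null(models))
      stop("source = 'ancestral' requires fitted models")
    nEff <- sum(vapply(datasets, length, 1L))
    probs <- vapply(positions, function(lab) {
      m <- models[[lab]]
      if (is.null(m)) stop("no model supplied for position ", lab)
      pZ <- ancestralVector(m)
      (pZ * nEff + pseudocount) / (nEff + 4 * pseudocount)
    }, numeric(4))
    rownames(probs) <- NUC
  }
  new("SitePWM", probs = probs, pseudocount = pseudocount,
      logBase = logBase, source = source)
}

#' @rdname SitePWM-class
#' @export
setMethod("pwmProbs", "SitePWM", function(x) x@probs)

#' @describeIn SitePWM-class per-position strengths W = log(pF/0.25) as a
#'   4 x L matrix
#' @export
setMethod("strengthMatrix", "SitePWM", function(x) {
  log(x@probs / 0.25) / log(x@logBase)
})

setMethod("show", "SitePWM", function(object) {
  cat(sprintf("SitePWM over %d positions (source: %s, pseudocount %g, log base %g)\n",
              ncol(object@probs), object@source, object@pseudocount,
              object@logBase))
  cat("  consensus:",
      paste(NUC[apply(object@probs, 2L, which.max)], collapse = ""), "\n")
})

#' Strength of a nucleotide at a position
#'
#' W = log(pF(nucleotide, position) / 0.25) in the PWM's log base. Positive
#' strengths mark consensus-like nucleotides, 0 is background.
#'
#' @param pwm a \linkS4class{SitePWM}
#' @param position a window position label
#' @param nucleotide one of A, C, G, T (vectorized)
#' @return numeric strength(s)
#' @export
positionStrength <- function(pwm, position, nucleotide) {
  W <- strengthMatrix(pwm)
  if (!position %in% colnames(W))
    stop("position ", position, " not covered by this PWM")
  unname(W[.nucIndex(nucleotide), position])
}

#' Average strength of a position under a nucleotide distribution
#'
#' W-hat = sum_a freqs(a) W(a, i).
#'
#' @param freqs numeric(4) nucleotide distribution (A,C,G,T), on the simplex
#' @param pwm a \linkS4class{SitePWM}
#' @param position a window position label
#' @return the average strength
#' @export
averageStrength <- function(freqs, pwm, position) {
  if (!.isSimplex(freqs, tol = 1e-6))
    stop("freqs must be a probability 4-vector")
  W <- strengthMatrix(pwm)
  sum(freqs * W[, position])
}

#' Expected ancestral strength given a descendant triple
#'
#' W-bar = sum_r W(r, i) p(r | h, m, d), the posterior-weighted strength of
#' the reconstructed ancestral nucleotide.
#'
#' @inheritParams ancestralPosterior
#' @param pwm a \linkS4class{SitePWM}
#' @param position a window position label
#' @return the expected ancestral strength
#' @export
expectedAncestralStrength <- function(model, pwm, position, h, m, d) {
  post <- ancestralPosterior(model, h, m, d)
  W <- strengthMatrix(pwm)
  sum(W[, position] * post)
}

## ---- strength changes and omega --------------------------------------------

## empirical per-branch nucleotide frequencies at a position (N skipped)
.empiricalFreqs <- function(x, genome, position) {
  i <- .nucIndex(positionMatrix(x, genome, position)[, 1])
  cnt <- tabulate(i[!is.na(i)], 4L)
  if (sum(cnt) == 0L)
    stop("no usable nucleotides at position ", position, " in ", genome)
  cnt / sum(cnt)
}

.strengthChangeCore <- function(ancVec, obsFreq, neutral, pwm, position,
                                branch) {
  expFreq <- as.vector(ancVec %*% neutral@matrices[[branch]])
  wAnc <- averageStrength(ancVec, pwm, position)
  wObs <- averageStrength(obsFreq, pwm, position)
  wExp <- averageStrength(expFreq, pwm, position)
  dWO <- wObs - wAnc
  dWE <- wExp - wAnc
  defined <- abs(dWE) >= 1e-9
  omega <- if (defined) (dWE - dWO) / dWE else NA_real_
  list(wAncestor = wAnc, wObserved = wObs, wExpected = wExp,
       dWO = dWO, dWE = dWE, omega = omega, omegaDefined = defined)
}

#' Observed and neutrally expected strength change at one position
#'
#' Ancestor nucleotide frequencies are the fitted ancestral vector p(Z);
#' observed descendant frequencies are the empirical per-branch frequencies
#' in the dataset; expected descendant frequencies apply the neutral matrix
#' to the ancestor vector. The relative strength change is
#' omega = (dWE - dWO) / dWE: 1 when the position's strength is preserved,
#' 0 when it evolves neutrally, > 1 when it strengthens. When |dWE| is below
#' 1e-9 omega is undefined and reported as NA with
#' \code{omegaDefined = FALSE}.
#'
#' @param x the \linkS4class{SpliceSiteSet} the models were fitted on
#' @param fitted \linkS4class{PositionFit} or \linkS4class{PositionModel}
#'   for this position
#' @param neutral neutral-control \linkS4class{PositionModel}
#' @param pwm a \linkS4class{SitePWM}
#' @param position a window position label
#' @param branch "human", "mouse" or "dog"
#' @return one-row data.frame with columns position, branch, wAncestor,
#'   wObserved, wExpected, dWO, dWE, omega, omegaDefined (p-value columns
#'   are filled by \code{\link{strengthChangeTable}})
#' @export
strengthChange <- function(x, fitted, neutral, pwm, position,
                           branch = c("human", "mouse", "dog")) {
  branch <- match.arg(branch)
  ancVec <- ancestralVector(fitted)
  obsFreq <- .empiricalFreqs(x, branch, position)
  core <- .strengthChangeCore(ancVec, obsFreq, neutral, pwm, position,
                              branch)
  data.frame(position = position, branch = branch,
             wAncestor = core$wAncestor, wObserved = core$wObserved,
             wExpected = core$wExpected, dWO = core$dWO, dWE = core$dWE,
             omega = core$omega, omegaDefined = core$omegaDefined,
             omegaLo = NA_real_, omegaHi = NA_real_,
             pChange = NA_real_, pOmega = NA_real_,
             stringsAsFactors = FALSE)
}

## Precompute per-site nucleotide indices (n x L, NA outside ACGT) and
## triple codes for a set of position labels, so bootstrap resamples reduce
## to tabulate() calls instead of re-parsing sequence strings.
.posNucIndices <- function(x, labels) {
  out <- lapply(c(human = "human", mouse = "mouse", dog = "dog"),
                function(g) {
    M <- positionMatrix(x, g, labels)
    matrix(.nucIndex(M), nrow(M), ncol(M), dimnames = dimnames(M))
  })
  codes <- out$human + 4L * (out$mouse - 1L) + 16L * (out$dog - 1L)
  c(out, list(codes = codes))
}

.freqFromCodes <- function(codesCol, idx = NULL) {
  v <- if (is.null(idx)) codesCol else codesCol[idx]
  v <- v[!is.na(v)]
  q <- array(tabulate(v, 64L) / length(v), dim = c(4L, 4L, 4L))
  attr(q, "n") <- length(v)
  q
}

## Fit all positions needed for a strength-change table: the window itself
## plus every control position, on the right dataset (donor companion for
## acceptor intronic controls).
.fitPositionsFor <- function(x, positions, donorCompanion, restarts, seed) {
  sch <- positionScheme(ssType(x))
  ctrl <- lapply(positions, controlPositionsFor, ssType = ssType(x))
  names(ctrl) <- positions
  selfLabels <- unique(c(positions,
    unlist(ctrl[vapply(ctrl, attr, "", "dataset") == "self"])))
  donorLabels <- unique(unlist(ctrl[vapply(ctrl, attr, "",
                                           "dataset") == "donor"]))
  fitAt <- function(ds, labels) {
    fits <- lapply(seq_along(labels), function(k) {
      fitPositionModel(countTriples(ds, labels[k]), restarts = restarts,
                       seed = .childSeed(seed, 37L + k),
                       position = labels[k])
    })
    names(fits) <- labels
    fits
  }
  selfFits <- fitAt(x, selfLabels)
  donorFits <- if (length(donorLabels)) {
    if (is.null(donorCompanion))
      stop("acceptor intronic controls need the companion donor dataset ",
           "(donorCompanion argument)")
    fitAt(donorCompanion, donorLabels)
  } else list()
  list(self = selfFits, donor = donorFits, control = ctrl)
}

.neutralFor <- function(fits, position) {
  ctrl <- fits$control[[position]]
  pool <- if (attr(ctrl, "dataset") == "donor") fits$donor else fits$self
  neutralModel(pool[ctrl])
}

#' Strength-change and omega table for all window positions and branches
#'
#' Runs the full per-position analysis: least-squares model fits for every
#' analysis-window and control position, neutral-control pooling, observed
#' and expected strength changes and omega, with bootstrap p-values from
#' resampling site triples (whole sites move together across positions and
#' branches; model fits are re-estimated on each resample by a warm-started
#' descent from the full-data solution).
#'
#' \code{pChange} tests dWO = dWE (equivalently omega = 0, neutral
#' evolution); \code{pOmega} tests omega = 1 (strength preservation). Both
#' are two-sided sign-counting bootstrap p-values floored at 1/nTrials.
#'
#' @param x a \linkS4class{SpliceSiteSet}
#' @param pwm a \linkS4class{SitePWM} covering the window
#' @param positions window labels (default: the scheme's analysis window)
#' @param branches which branches to report
#' @param donorCompanion donor \linkS4class{SpliceSiteSet} of the same
#'   splicing type; required for acceptor intronic positions, whose neutral
#'   control lives in the donor intron
#' @param nTrials bootstrap trials (default 1500)
#' @param restarts random restarts for the full-data fits
#' @param seed master seed
#' @return data.frame, one row per position x branch (see
#'   \code{\link{strengthChange}}), with bootstrap percentile 95\% CI
#'   columns for omega (\code{omegaLo}, \code{omegaHi}); fitted models are
#'   in attribute \code{"fits"}, neutral models in \code{"neutrals"}
#' @export
strengthChangeTable <- function(x, pwm, positions = NULL,
                                branches = c("human", "mouse", "dog"),
                                donorCompanion = NULL, nTrials = 1500L,
                                restarts = 10L, seed = 1L) {
  sch <- positionScheme(ssType(x))
  if (is.null(positions)) positions <- sch@window
  fits <- .fitPositionsFor(x, positions, donorCompanion, restarts, seed)
  neutrals <- lapply(positions, function(p) .neutralFor(fits, p))
  names(neutrals) <- positions

  pointRows <- list()
  for (p in positions) for (b in branches)
    pointRows[[paste(p, b)]] <-
      strengthChange(x, fits$self[[p]], neutrals[[p]], pwm, p, b)
  tab <- do.call(rbind, pointRows)
  rownames(tab) <- NULL

  if (nTrials > 0L) {
    allSelf <- names(fits$self)
    allDonor <- names(fits$donor)
    nSelf <- length(x)
    nDonor <- if (length(allDonor)) length(donorCompanion) else 0L
    idxSelf <- .posNucIndices(x, allSelf)
    idxDonor <- if (nDonor) .posNucIndices(donorCompanion, allDonor)
    stats <- array(NA_real_,
                   c(nTrials, length(positions), length(branches), 2L),
                   dimnames = list(NULL, positions, branches,
                                   c("diff", "omega")))
    for (t in seq_len(nTrials)) {
      set.seed(.childSeed(seed, 100000L + t))
      idx <- sort(sample.int(nSelf, nSelf, replace = TRUE))
      bsSelf <- lapply(fits$self, function(f) {
        .refitFrom(f@model, .freqFromCodes(idxSelf$codes[, f@position],
                                           idx))
      })
      bsDonor <- list()
      if (nDonor) {
        idxD <- sort(sample.int(nDonor, nDonor, replace = TRUE))
        bsDonor <- lapply(fits$donor, function(f) {
          .refitFrom(f@model, .freqFromCodes(idxDonor$codes[, f@position],
                                             idxD))
        })
      }
      bsFits <- list(self = bsSelf, donor = bsDonor,
                     control = fits$control)
      for (pi in seq_along(positions)) {
        p <- positions[pi]
        neu <- .neutralFor(bsFits, p)
        anc <- ancestralVector(bsSelf[[p]])
        for (bi in seq_along(branches)) {
          b <- branches[bi]
          iv <- idxSelf[[b]][idx, p]
          cnt <- tabulate(iv[!is.na(iv)], 4L)
          obs <- cnt / sum(cnt)
          core <- .strengthChangeCore(anc, obs, neu, pwm, p, b)
          stats[t, pi, bi, "diff"] <- core$dWO - core$dWE
          stats[t, pi, bi, "omega"] <-
            if (core$omegaDefined) core$omega else NA_real_
        }
      }
    }
    for (r in seq_len(nrow(tab))) {
      p <- tab$position[r]; b <- tab$branch[r]
      tab$pChange[r] <- .signCountP(stats[, p, b, "diff"], 0)
      om <- stats[, p, b, "omega"]
      om <- om[!is.na(om)]
      if (length(om)) {
        tab$pOmega[r] <- .signCountP(om, 1)
        ci <- unname(stats::quantile(om, c(0.025, 0.975), type = 7))
        tab$omegaLo[r] <- ci[1]
        tab$omegaHi[r] <- ci[2]
      }
    }
  }
  attr(tab, "fits") <- fits$self
  attr(tab, "neutrals") <- neutrals
  tab
}
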