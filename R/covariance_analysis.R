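#' @include evolution_sim.R
NULL

#' Per-site strength vectors
#'
#' One vector of per-position strengths per site, for one descendant genome:
#' element i is W(nucleotide at position i, i) under the PWM. Positions with
#' a non-ACGT character yield NA and are handled pairwise downstream.
#'
#' @param x a \linkS4class{SpliceSiteSet}
#' @param pwm a \linkS4class{SitePWM} covering the window
#' @param genome "human", "mouse" or "dog"
#' @param positions window labels (default: the PWM's columns)
#' @return numeric matrix, sites x positions (rownames = site ids)
#' @export
strengthVectors <- function(x, pwm, genome = c("human", "mouse", "dog"),
                            positions = NULL) {
  genome <- match.arg(genome)
  W <- strengthMatrix(pwm)
  if (is.null(positions)) positions <- colnames(W)
  if (!all(positions %in% colnames(W)))
    stop("PWM does not cover all requested positions")
  pm <- positionMatrix(x, genome, positions)
  V <- matrix(NA_real_, nrow(pm), length(positions),
              dimnames = list(rownames(pm), positions))
  for (j in seq_along(positions)) {
    i <- .nucIndex(pm[, j])
    V[!is.na(i), j] <- W[i[!is.na(i)], positions[j]]
  }
  V
}

.pairwiseCov <- function(V) {
  C <- suppressWarnings(stats::cov(V, use = "pairwise.complete.obs"))
  ## cells with fewer than 2 complete pairs come back NA already; force
  ## exact symmetry against floating-point asymmetries
  (C + t(C)) / 2
}

#' Covariance matrix of strength vectors, with bootstrap significance
#'
#' Sample covariance (denominator n-1, pairwise-complete over missing
#' entries) of the per-position strength vectors, plus per-cell two-sided
#' bootstrap p-values that the covariance differs from zero, from
#' resampling sites with replacement. P-values are raw (no multiple-testing
#' correction), mirroring how such matrices are usually reported.
#'
#' @param vectors sites x positions strength matrix from
#'   \code{\link{strengthVectors}}
#' @param nTrials bootstrap trials (default 1500); 0 skips the p-values
#' @param seed master seed
#' @param genome label stored in the result
#' @return a \linkS4class{CovarianceResult}
#' @export
covarianceMatrix <- function(vectors, nTrials = 1500L, seed = 1L,
                             genome = NA_character_) {
  if (nrow(vectors) < 2L)
    stop("need at least 2 strength vectors")
  if (!is.null(rownames(vectors)))
    vectors <- vectors[order(rownames(vectors)), , drop = FALSE]
  C <- .pairwiseCov(vectors)
  L <- ncol(vectors)
  P <- matrix(NA_real_, L, L, dimnames = dimnames(C))
  if (nTrials > 0L) {
    n <- nrow(vectors)
    reps <- array(NA_real_, c(nTrials, L, L))
    for (t in seq_len(nTrials)) {
      set.seed(.childSeed(seed, t))
      idx <- sort(sample.int(n, n, replace = TRUE))
      reps[t, , ] <- .pairwiseCov(vectors[idx, , drop = FALSE])
    }
    for (a in seq_len(L)) for (b in seq_len(L)) {
      r <- reps[, a, b]
      r <- r[!is.na(r)]
      if (length(r)) P[a, b] <- .signCountP(r, 0)
    }
  }
  new("CovarianceResult", cov = C, pValues = P,
      n = nrow(vectors), genome = genome)
}

setMethod("show", "CovarianceResult", function(object) {
  cat(sprintf("CovarianceResult: %d x %d positions, n = %d sites%s\n",
              nrow(object@cov), ncol(object@cov), object@n,
              if (is.na(object@genome)) "" else
                paste0(" (", object@genome, ")")))
  print(signif(object@cov, 3))
})

#' Cellwise difference of two covariance matrices
#'
#' @param real,simulated \linkS4class{CovarianceResult}s or plain matrices
#'   over the same window
#' @return matrix of real - simulated
#' @export
covarianceDifference <- function(real, simulated) {
  A <- if (is(real, "CovarianceResult")) real@cov else real
  B <- if (is(simulated, "CovarianceResult")) simulated@cov else simulated
  if (!identical(dim(A), dim(B)) ||
      !identical(colnames(A), colnames(B)))
    stop("covariance matrices are over different windows")
  A - B
}

#' Real-vs-simulated covariance comparison under the independence null
#'
#' Compares the strength covariance matrix of real sites in one genome with
#' the covariance expected if positions had evolved independently. The
#' point estimate subtracts the mean covariance over \code{nSim} independent
#' re-simulations of the full dataset (\code{\link{simulateDataset}}).
#' Significance is assessed by a paired bootstrap: each trial resamples site
#' triples, computes the real covariance on the resample, regenerates one
#' simulated dataset for the resampled sites under the null, and records the
#' cellwise difference; p-values count the sign of the trial differences
#' against zero.
#'
#' @param x a \linkS4class{SpliceSiteSet}
#' @param models named list of per-position models (see
#'   \code{\link{simulateDataset}})
#' @param pwm a \linkS4class{SitePWM}
#' @param genome which descendant genome to compare
#' @param positions window labels (default: the PWM's columns)
#' @param nTrials bootstrap trials (default 1500)
#' @param nSim full-data simulations behind the point estimate (default 20)
#' @param seed master seed
#' @return list with elements \code{difference} (real - simulated matrix),
#'   \code{pValues}, \code{real}, \code{simulated} (mean simulated
#'   covariance), \code{n}, \code{nTrials}
#' @export
compareCovariances <- function(x, models, pwm,
                               genome = c("human", "mouse", "dog"),
                               positions = NULL, nTrials = 1500L,
                               nSim = 20L, seed = 1L) {
  genome <- match.arg(genome)
  if (is.null(positions)) positions <- colnames(strengthMatrix(pwm))
  Vreal <- strengthVectors(x, pwm, genome, positions)
  Creal <- .pairwiseCov(Vreal)
  simCov <- 0
  for (s in seq_len(nSim)) {
    sim <- simulateDataset(x, models, positions,
                           seed = .childSeed(seed, 5000L + s))
    simCov <- simCov + .pairwiseCov(strengthVectors(sim, pwm, genome,
                                                    positions))
  }
  Csim <- simCov / nSim
  L <- length(positions)
  P <- matrix(NA_real_, L, L, dimnames = dimnames(Creal))
  if (nTrials > 0L) {
    n <- length(x)
    reps <- array(NA_real_, c(nTrials, L, L))
    for (t in seq_len(nTrials)) {
      set.seed(.childSeed(seed, 900000L + t))
      idx <- sort(sample.int(n, n, replace = TRUE))
      bs <- x[idx]
      ## resampling duplicates ids; reassign unique ids for the container
      bs@id <- sprintf("bs%d", seq_along(idx))
      Vb <- strengthVectors(bs, pwm, genome, positions)
      simB <- simulateDataset(bs, models, positions,
                              seed = .childSeed(seed, 910000L + t))
      Vs <- strengthVectors(simB, pwm, genome, positions)
      reps[t, , ] <- .pairwiseCov(Vb) - .pairwiseCov(Vs)
    }
    for (a in seq_len(L)) for (b in seq_len(L)) {
      r <- reps[, a, b]
      r <- r[!is.na(r)]
      if (length(r)) P[a, b] <- .signCountP(r, 0)
    }
  }
  list(difference = Creal - Csim, pValues = P, real = Creal,
       simulated = Csim, n = length(x), nTrials = nTrials)
}

#' Write a covariance result as TSV (plus a companion p-value TSV)
#'
#' @param covResult a \linkS4class{CovarianceResult}
#' @param path output TSV path; p-values go to \code{<path>.pvalues.tsv}
#' @return \code{path}, invisibly
#' @export
writeCovarianceTSV <- function(covResult, path) {
  utils::write.table(covResult@cov, path, sep = "\t", quote = FALSE,
                     col.names = NA)
  utils::write.table(covResult@pValues, paste0(path, ".pvalues.tsv"),
                     sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}
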