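#' @include covariance_analysis.R
NULL

.DINUCS <- as.vector(outer(NUC, NUC, paste0))  # AA, CA, ... column-major
.DINUCS <- sort(.DINUCS)

## region matrix: sites x region positions, validated to be consecutive
.regionMatrix <- function(x, genome, region) {
  sch <- positionScheme(ssType(x))
  off <- offsetOf(sch, region)
  if (length(region) < 2L)
    stop("region must span at least 2 positions")
  if (any(diff(off) != 1L))
    stop("region positions must be consecutive in the site window")
  positionMatrix(x, genome, region)
}

.pairCounts <- function(M) {
  cnt <- matrix(0, 4L, 4L, dimnames = list(from = NUC, to = NUC))
  for (j in seq_len(ncol(M) - 1L)) {
    a <- .nucIndex(M[, j]); b <- .nucIndex(M[, j + 1L])
    ok <- !is.na(a) & !is.na(b)
    if (any(ok))
      cnt <- cnt + matrix(tabulate(a[ok] + 4L * (b[ok] - 1L), 16L), 4L, 4L)
  }
  cnt
}

.monoCounts <- function(M) {
  i <- .nucIndex(as.vector(M))
  tabulate(i[!is.na(i)], 4L)
}

.obsExpRatios <- function(M) {
  pc <- .pairCounts(M)
  obs <- pc / sum(pc)
  mono <- .monoCounts(M)
  p <- mono / sum(mono)
  expd <- p %o% p
  ratio <- obs / expd
  ratio[expd == 0] <- NaN
  list(obs = obs, expd = expd, ratio = ratio, pairCounts = pc)
}

#' Observed/expected dinucleotide ratios in a sequence region
#'
#' Counts every adjacent (overlapping) nucleotide pair within the region,
#' pooled over sites, and compares the observed pair frequencies with the
#' expectation under independence — the product of the region's pooled
#' mononucleotide frequencies. Ratios near 1 indicate no dinucleotide
#' preference; the acceptor PPT shows strong AG depletion (the AG exclusion
#' zone) and the genome-wide CpG depletion shows up as a low CG ratio.
#'
#' When a comparison region is supplied, per-dinucleotide bootstrap
#' p-values for the difference of the two ratios are added (sites of each
#' dataset resampled independently when the comparison lives in another
#' dataset, jointly otherwise).
#'
#' @param x a \linkS4class{SpliceSiteSet}
#' @param region consecutive position labels (e.g. \code{paste0("-", 12:7)}
#'   for the PPT)
#' @param genome which genome's sequences to use (default "human")
#' @param comparison optional list with elements \code{x} (a
#'   SpliceSiteSet; defaults to the same dataset), \code{region} and
#'   optionally \code{genome} — the control region (e.g. the companion
#'   donor's intron +7..+12)
#' @param nTrials bootstrap trials for the comparison p-values
#' @param seed master seed
#' @return data.frame with one row per dinucleotide: observed count,
#'   observed and expected frequency, ratio, and (with a comparison)
#'   comparison ratio and p-value; rows ordered by ratio
#' @export
dinucleotideObsExp <- function(x, region, genome = "human",
                               comparison = NULL, nTrials = 1500L,
                               seed = 1L) {
  M <- .regionMatrix(x, genome, region)
  r <- .obsExpRatios(M)
  ## flatten a 4x4 (from, to) matrix into alphabetical dinucleotide order
  flat <- function(A) {
    v <- as.vector(A)                     # column-major: "from" fastest
    names(v) <- as.vector(outer(NUC, NUC, function(a, b) paste0(a, b)))
    v[.DINUCS]
  }
  tab <- data.frame(dinucleotide = .DINUCS,
                    observedCount = unname(flat(r$pairCounts)),
                    observedFreq = unname(flat(r$obs)),
                    expectedFreq = unname(flat(r$expd)),
                    ratio = unname(flat(r$ratio)),
                    stringsAsFactors = FALSE)
  if (!is.null(comparison)) {
    cx <- if (is.null(comparison$x)) x else comparison$x
    cg <- if (is.null(comparison$genome)) genome else comparison$genome
    cM <- .regionMatrix(cx, cg, comparison$region)
    cr <- .obsExpRatios(cM)
    tab$comparisonRatio <- unname(flat(cr$ratio))
    same <- identical(siteIds(cx), siteIds(x))
    nA <- nrow(M); nB <- nrow(cM)
    reps <- matrix(NA_real_, nTrials, 16L)
    for (t in seq_len(nTrials)) {
      set.seed(.childSeed(seed, t))
      ia <- sort(sample.int(nA, nA, replace = TRUE))
      ib <- if (same) ia else sort(sample.int(nB, nB, replace = TRUE))
      ra <- .obsExpRatios(M[ia, , drop = FALSE])$ratio
      rb <- .obsExpRatios(cM[ib, , drop = FALSE])$ratio
      reps[t, ] <- flat(ra) - flat(rb)
    }
    tab$pValue <- vapply(seq_len(16L), function(k) {
      r <- reps[, k]
      r <- r[is.finite(r)]
      if (length(r) < 0.9 * nTrials) NA_real_ else .signCountP(r, 0)
    }, numeric(1))
  }
  tab[order(tab$ratio), , drop = FALSE]
}

#' Fit a first-order Markov model to a sequence region
#'
#' Initial probabilities are the nucleotide frequencies at the region's
#' first position; transition probabilities are conditional adjacent-pair
#' frequencies pooled over the region. Conditioning nucleotides never
#' observed get a uniform row and are flagged.
#'
#' @inheritParams dinucleotideObsExp
#' @return a \linkS4class{MarkovRegionModel}
#' @export
fitMarkovRegion <- function(x, region, genome = "human") {
  M <- .regionMatrix(x, genome, region)
  if (nrow(M) == 0L) stop("no sequences cover the region")
  i1 <- .nucIndex(M[, 1])
  init <- tabulate(i1[!is.na(i1)], 4L)
  init <- init / sum(init)
  pc <- .pairCounts(M)
  rs <- rowSums(pc)
  flagged <- rs == 0
  Tm <- matrix(0.25, 4L, 4L, dimnames = list(from = NUC, to = NUC))
  Tm[!flagged, ] <- pc[!flagged, , drop = FALSE] / rs[!flagged]
  new("MarkovRegionModel", initial = init, transition = Tm,
      region = region, flagged = flagged)
}

setMethod("show", "MarkovRegionModel", function(object) {
  cat(sprintf("MarkovRegionModel over %s..%s\n", object@region[1],
              object@region[length(object@region)]))
  cat("  initial:", paste(sprintf("%s:%.2f", NUC, object@initial),
                          collapse = " "), "\n")
  if (any(object@flagged))
    cat("  uniform fallback rows:",
        paste(NUC[object@flagged], collapse = ","), "\n")
})

#' Replace a region with first-order Markov samples
#'
#' Generates artificial sites that keep everything outside the region
#' verbatim but replace the region (in the chosen genome's sequences) with
#' independent samples from the fitted Markov chain. This preserves
#' adjacent-pair (dinucleotide) structure while destroying dependencies at
#' distances of two or more.
#'
#' @inheritParams dinucleotideObsExp
#' @param model a \linkS4class{MarkovRegionModel} fitted on the same region
#' @param seed master seed
#' @return a \linkS4class{SpliceSiteSet} with the genome's region replaced
#' @export
generateArtificialPPT <- function(x, region, model, genome = "human",
                                  seed = 1L) {
  sch <- positionScheme(ssType(x))
  off <- offsetOf(sch, region) + 1L
  mats <- list(human = .charMatrix(siteSeqs(x, "human")),
               mouse = .charMatrix(siteSeqs(x, "mouse")),
               dog = .charMatrix(siteSeqs(x, "dog")))
  n <- length(x)
  set.seed(.childSeed(seed, 1L))
  cur <- .drawNuc(matrix(model@initial, n, 4L, byrow = TRUE),
                  stats::runif(n))
  mats[[genome]][, off[1]] <- NUC[cur]
  for (j in seq_along(off)[-1]) {
    prob <- model@transition[cur, , drop = FALSE]
    cur <- .drawNuc(prob, stats::runif(n))
    mats[[genome]][, off[j]] <- NUC[cur]
  }
  collapse <- function(M) apply(M, 1L, paste, collapse = "")
  SpliceSiteSet(siteIds(x), collapse(mats$human), collapse(mats$mouse),
                collapse(mats$dog), ssType(x), splicingType(x),
                ageKs = siteAges(x), meta = x@meta,
                provenance = c(x@provenance,
                               list(artificialRegion = region,
                                    artificialGenome = genome,
                                    artificialSeed = as.integer(seed))))
}

#' Run-length histogram of a tandem dinucleotide repeat
#'
#' Counts maximal tandem repeats (XY)_n of the given dinucleotide in each
#' sequence and pools the counts per repeat length n >= 1.
#'
#' @param seqs character vector (or DNAStringSet) of sequences
#' @param dinucleotide a 2-letter string such as "TC"
#' @return named integer vector: counts of maximal runs per length n
#' @export
runLengthCounts <- function(seqs, dinucleotide) {
  stopifnot(nchar(dinucleotide) == 2L)
  seqs <- as.character(seqs)
  pat <- paste0("(", dinucleotide, ")+")
  hist <- integer(0)
  for (s in seqs) {
    m <- gregexpr(pat, s)[[1]]
    if (m[1] == -1L) next
    lens <- attr(m, "match.length") %/% 2L
    for (l in lens) {
      if (l > length(hist)) hist <- c(hist, integer(l - length(hist)))
      hist[l] <- hist[l] + 1L
    }
  }
  if (length(hist)) names(hist) <- seq_along(hist)
  hist
}
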