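#' @include ancestral_strength.R
NULL

## Conditional distribution of the re-simulated descendant nucleotide given
## the observed triple, for all 64 triples at once:
##   p(x* | h,m,d) = sum_r p(x*|r) p(r | h,m,d)
## Rows are indexed by triple code h + 4(m-1) + 16(d-1), columns by x*.
.condDrawTable <- function(model, branch) {
  P <- model@matrices[[branch]]
  out <- matrix(NA_real_, 64L, 4L, dimnames = list(NULL, NUC))
  for (d in 1:4) for (m in 1:4) for (h in 1:4) {
    w <- model@ancestral * model@matrices$human[, h] *
      model@matrices$mouse[, m] * model@matrices$dog[, d]
    z <- sum(w)
    code <- h + 4L * (m - 1L) + 16L * (d - 1L)
    out[code, ] <- if (z > 0) as.vector((w / z) %*% P) else NA_real_
  }
  out
}

#' Simulate one descendant nucleotide under position-independent evolution
#'
#' Draws a re-simulated descendant nucleotide from its conditional
#' distribution given the observed (human, mouse, dog) triple: the ancestral
#' posterior is mixed through the branch's own substitution matrix. Draws
#' use inverse-CDF sampling in A,C,G,T order on the session RNG.
#'
#' @param model a \linkS4class{PositionModel}
#' @param branch "human", "mouse" or "dog"
#' @param h,m,d the observed triple (single nucleotides)
#' @param n number of draws
#' @return character vector of \code{n} simulated nucleotides
#' @export
simulateDescendantNt <- function(model, branch, h, m, d, n = 1L) {
  branch <- match.arg(branch, c("human", "mouse", "dog"))
  post <- ancestralPosterior(model, h, m, d)
  prob <- as.vector(post %*% model@matrices[[branch]])
  NUC[.drawNuc(matrix(prob, n, 4L, byrow = TRUE), stats::runif(n))]
}

#' Simulate a dataset under independent evolution of positions
#'
#' For every site and every analysis-window position, all three descendant
#' nucleotides are re-simulated independently from their conditional
#' distributions given the site's real triple (the three branches share the
#' ancestral posterior but are drawn independently). Invariant dinucleotides
#' and flanking positions are copied unchanged, as are positions where the
#' real triple contains a non-ACGT character.
#'
#' @param x a \linkS4class{SpliceSiteSet}
#' @param models named list of \linkS4class{PositionFit} or
#'   \linkS4class{PositionModel}, keyed by position label; must cover every
#'   position in \code{positions}
#' @param positions labels to re-simulate (default: the analysis window)
#' @param seed master seed; output is reproducible given it
#' @return a \linkS4class{SpliceSiteSet} of simulated triples (same ids and
#'   metadata; provenance records the simulation)
#' @export
simulateDataset <- function(x, models, positions = NULL, seed = 1L) {
  sch <- positionScheme(ssType(x))
  if (is.null(positions)) positions <- sch@window
  missing <- setdiff(positions, names(models))
  if (length(missing))
    stop("no model supplied for window position(s): ",
         paste(missing, collapse = ", "))
  models <- lapply(models, function(m) if (is(m, "PositionFit")) m@model
                   else m)
  mats <- list(human = .charMatrix(siteSeqs(x, "human")),
               mouse = .charMatrix(siteSeqs(x, "mouse")),
               dog = .charMatrix(siteSeqs(x, "dog")))
  n <- length(x)
  for (k in seq_along(positions)) {
    lab <- positions[k]
    off <- offsetOf(sch, lab) + 1L
    h <- .nucIndex(mats$human[, off])
    m <- .nucIndex(mats$mouse[, off])
    d <- .nucIndex(mats$dog[, off])
    ok <- !is.na(h) & !is.na(m) & !is.na(d)
    if (!any(ok)) next
    code <- h[ok] + 4L * (m[ok] - 1L) + 16L * (d[ok] - 1L)
    for (b in c("human", "mouse", "dog")) {
      tab <- .condDrawTable(models[[lab]], b)
      prob <- tab[code, , drop = FALSE]
      bad <- is.na(prob[, 1])
      set.seed(.childSeed(seed, 1000L * k + match(b, c("human", "mouse",
                                                       "dog"))))
      u <- stats::runif(sum(ok))
      draw <- NUC[.drawNuc(prob, u)]
      draw[bad] <- mats[[b]][which(ok)[bad], off]
      mats[[b]][ok, off] <- draw
    }
  }
  collapse <- function(M) apply(M, 1L, paste, collapse = "")
  out <- SpliceSiteSet(siteIds(x), collapse(mats$human),
                       collapse(mats$mouse), collapse(mats$dog),
                       ssType(x), splicingType(x), ageKs = siteAges(x),
                       meta = x@meta,
                       provenance = c(x@provenance,
                                      list(simulated = TRUE,
                                           simSeed = as.integer(seed))))
  out
}
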