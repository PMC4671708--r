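#' @include ppt_dinucleotide.R
NULL

## ---- building blocks --------------------------------------------------------

#' Simple substitution matrix with a common conservation probability
#'
#' Each nucleotide stays with probability \code{stay}; the remaining mass is
#' distributed over the other three nucleotides proportionally to
#' \code{bias} (default uniform). With a consensus-shaped \code{bias} this
#' mimics selection pulling substitutions toward the consensus.
#'
#' @param stay probability of no change per branch
#' @param bias numeric(4) attraction weights (A,C,G,T)
#' @return 4x4 row-stochastic matrix
#' @export
substitutionMatrix <- function(stay = 0.93, bias = rep(1, 4)) {
  P <- matrix(0, 4L, 4L, dimnames = list(ancestor = NUC, descendant = NUC))
  for (r in 1:4) {
    w <- bias
    w[r] <- 0
    P[r, ] <- (1 - stay) * w / sum(w)
    P[r, r] <- stay
  }
  P
}

#' Neutral flank substitution matrix for a given background composition
#'
#' The matrix used to evolve flanking (non-window) positions in the
#' synthetic generator: each nucleotide is conserved with probability
#' \code{stay}, and substitutions land on the other nucleotides
#' proportionally to the background composition implied by \code{gc}. This
#' is also the ground-truth neutral matrix for omega-recovery checks:
#' window positions evolved with this same matrix evolve neutrally by
#' construction.
#'
#' @param gc background GC content
#' @param stay per-branch conservation probability
#' @return 4x4 row-stochastic matrix
#' @export
neutralFlankMatrix <- function(gc = 0.42, stay = 0.75) {
  bg <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  substitutionMatrix(stay, bias = bg)
}

#' Consensus-peaked ancestral probability vector
#'
#' @param consensus the consensus nucleotide
#' @param weight probability mass on the consensus nucleotide
#' @return numeric(4) on the simplex
#' @export
consensusAncestral <- function(consensus, weight = 0.7) {
  p <- rep((1 - weight) / 3, 4L)
  p[.nucIndex(consensus)] <- weight
  names(p) <- NUC
  p
}

#' Construct a GeneratorSpec
#'
#' @param ssType "donor" or "acceptor"
#' @param n number of sites
#' @param models named list of \linkS4class{PositionModel}, one per window
#'   position to generate; remaining window positions fall back to the
#'   flank background
#' @param coupling empty list for independent positions, or
#'   \code{list(weights = , ancestral = )} where \code{ancestral} is a list
#'   (one element per class) of named lists of ancestral 4-vectors
#'   overriding the models' p(Z) at selected positions
#' @param pptModel optional \linkS4class{MarkovRegionModel} for the
#'   acceptor PPT (region positions override model-based generation)
#' @param ageMeanlog,ageSdlog lognormal age (K_s) parameters; the defaults
#'   put roughly 45\% of sites below the 1 K_s young/old threshold
#' @param gc flank background GC content (default 0.42, intron-like)
#' @param flankStay flank conservation probability per branch (default
#'   0.75; flanks evolve on the star tree via
#'   \code{\link{neutralFlankMatrix}})
#' @param splicingType "constitutive" or "cassette"
#' @param seed master seed
#' @return a \linkS4class{GeneratorSpec}
#' @export
generatorSpec <- function(ssType, n, models, coupling = list(),
                          pptModel = NULL, ageMeanlog = 0.1,
                          ageSdlog = 0.75, gc = 0.42, flankStay = 0.75,
                          splicingType = "constitutive", seed = 1L) {
  new("GeneratorSpec", ssType = ssType, splicingType = splicingType,
      n = as.integer(n), models = models, coupling = coupling,
      pptModel = pptModel, ageMeanlog = ageMeanlog, ageSdlog = ageSdlog,
      gc = gc, flankStay = flankStay, seed = as.integer(seed))
}

setMethod("show", "GeneratorSpec", function(object) {
  cat(sprintf("GeneratorSpec: %d synthetic %s %s sites, %d modelled positions\n",
              object@n, object@splicingType, object@ssType,
              length(object@models)))
  if (length(object@coupling))
    cat(sprintf("  ancestor-class coupling with %d classes\n",
                length(object@coupling$weights)))
  if (!is.null(object@pptModel))
    cat("  dinucleotide-biased PPT region\n")
})

#' Default generator: consensus-shaped donor or acceptor sites
#'
#' Builds a \linkS4class{GeneratorSpec} whose per-position models emulate
#' mammalian splice sites: consensus-peaked ancestral vectors (donor
#' MAG|GTRAGT, acceptor pyrimidine tract + NCAG|G), branch conservation
#' around 0.93 per position, and substitutions biased toward the consensus.
#' With \code{coupled = TRUE}, sites are drawn from a two-class ancestor
#' mixture — "strong exon / weak intron" vs "weak exon / strong intron" —
#' the minimal mechanism producing the negative exon-intron strength
#' covariance reported for real donor sites; in addition, substitutions at
#' intronic positions are coupled to the exonic -2 ancestor (drifting when
#' the exon is consensus, frozen otherwise), planting epistasis in the
#' substitution process itself that the real-vs-simulated covariance
#' comparison is designed to detect (ancestor-level covariance alone is
#' retained by the conditioned simulation and is invisible to it).
#'
#' @param ssType "donor" or "acceptor"
#' @param n number of sites
#' @param coupled plant the two-class exon/intron coupling (default FALSE)
#' @param pptBias for acceptors: generate the PPT (-12..-7) from a
#'   first-order Markov chain with AG-avoiding, pyrimidine-rich transitions
#' @param seed master seed
#' @return a \linkS4class{GeneratorSpec}
#' @export
defaultGeneratorSpec <- function(ssType = c("donor", "acceptor"), n = 4000L,
                                 coupled = FALSE, pptBias = FALSE,
                                 seed = 1L) {
  ssType <- match.arg(ssType)
  sch <- positionScheme(ssType)
  if (ssType == "donor") {
    cons <- c("-3" = "A", "-2" = "A", "-1" = "G", "+3" = "A", "+4" = "A",
              "+5" = "G", "+6" = "T")
    wt <- c("-3" = 0.40, "-2" = 0.62, "-1" = 0.78, "+3" = 0.55,
            "+4" = 0.70, "+5" = 0.80, "+6" = 0.50)
  } else {
    labs <- sch@window
    cons <- setNames(rep("T", length(labs)), labs)
    cons[c("-5", "-3")] <- "C"
    cons[c("+1")] <- "G"
    cons[c("+2", "+3")] <- "A"
    cons["-4"] <- "T"
    wt <- setNames(rep(0.45, length(labs)), labs)
    wt[paste0("-", 12:7)] <- 0.55
    wt["-3"] <- 0.70
    wt["-4"] <- 0.30
    wt["+1"] <- 0.50
  }
  models <- lapply(names(cons), function(lab) {
    anc <- consensusAncestral(cons[[lab]], wt[[lab]])
    P <- substitutionMatrix(0.93, bias = 0.5 + 3 * anc)
    PositionModel(anc, P, P, P)
  })
  names(models) <- names(cons)
  coupling <- list()
  if (coupled) {
    if (ssType != "donor")
      stop("the built-in coupling classes are defined for donor sites")
    exon <- c("-3", "-2", "-1"); intron <- c("+3", "+4", "+5", "+6")
    mk <- function(strongLabs, weakLabs) {
      ov <- list()
      for (lab in strongLabs)
        ov[[lab]] <- consensusAncestral(cons[[lab]],
                                        min(wt[[lab]] + 0.22, 0.95))
      for (lab in weakLabs)
        ov[[lab]] <- consensusAncestral(cons[[lab]],
                                        max(wt[[lab]] - 0.22, 0.1))
      ov
    }
    coupling <- list(weights = c(0.5, 0.5),
                     ancestral = list(mk(exon, intron), mk(intron, exon)),
                     ## epistasis in substitutions: when the exonic -2
                     ## ancestor is consensus (A), the intronic positions
                     ## drift (weakening); otherwise they are frozen
                     substitution = list(
                       driver = "-2", consensus = "A", targets = intron,
                       matrixIfConsensus = substitutionMatrix(0.78),
                       matrixOtherwise = diag(4)))
  }
  pptModel <- NULL
  if (pptBias) {
    if (ssType != "acceptor")
      stop("pptBias applies to acceptor sites")
    ## pyrimidine-rich chain avoiding A->G steps (AG exclusion) and
    ## depleting CG; C and T alternate more than they repeat
    Tm <- rbind(A = c(0.28, 0.22, 0.02, 0.48),
                C = c(0.06, 0.22, 0.04, 0.68),
                G = c(0.10, 0.25, 0.10, 0.55),
                T = c(0.10, 0.38, 0.12, 0.40))
    colnames(Tm) <- NUC
    pptModel <- new("MarkovRegionModel",
                    initial = c(0.10, 0.30, 0.08, 0.52),
                    transition = Tm, region = paste0("-", 12:7),
                    flagged = rep(FALSE, 4))
  }
  generatorSpec(ssType, n, models, coupling = coupling,
                pptModel = pptModel, seed = seed)
}

## ---- generation -------------------------------------------------------------

#' Generate synthetic orthologous site triples with known ground truth
#'
#' Per site: draw an ancestor class (if the spec couples positions), draw
#' the ancestral nucleotide at every modelled window position from the
#' (class-conditional) ancestral vector, evolve each branch independently
#' through its substitution matrix, insert the invariant GT/AG dinucleotide,
#' fill all remaining offsets i.i.d. from the flank background, and attach
#' lognormal ages. If the spec carries a PPT Markov model, the PPT region of
#' each genome is generated from that chain instead (independently per
#' genome).
#'
#' @param spec a \linkS4class{GeneratorSpec}
#' @param seed optional override of the spec's master seed
#' @return a \linkS4class{SpliceSiteSet}
#' @export
generateTriples <- function(spec, seed = NULL) {
  if (is.null(seed)) seed <- spec@seed
  sch <- positionScheme(spec@ssType)
  n <- spec@n
  ## flanks: ancestor i.i.d. from the background, then each branch evolves
  ## through the neutral flank matrix on the star tree
  pBg <- c((1 - spec@gc) / 2, spec@gc / 2, spec@gc / 2, (1 - spec@gc) / 2)
  Pflank <- neutralFlankMatrix(spec@gc, spec@flankStay)
  genomes <- c("human", "mouse", "dog")
  set.seed(.childSeed(seed, 11L))
  flankAnc <- .drawNuc(matrix(pBg, n * 30L, 4L, byrow = TRUE),
                       stats::runif(n * 30L))
  mats <- list()
  for (g in genomes) {
    set.seed(.childSeed(seed, 14L + match(g, genomes)))
    drawn <- .drawNuc(Pflank[flankAnc, , drop = FALSE],
                      stats::runif(n * 30L))
    mats[[g]] <- matrix(NUC[drawn], n, 30L)
  }
  ## invariant dinucleotide
  invOff <- offsetOf(sch, sch@invariant) + 1L
  di <- strsplit(sch@canonical, "")[[1]]
  for (g in genomes) {
    mats[[g]][, invOff[1]] <- di[1]
    mats[[g]][, invOff[2]] <- di[2]
  }
  ## ancestor classes (coupling of consensus adherence across positions)
  cls <- rep(1L, n)
  if (!is.null(spec@coupling$weights)) {
    set.seed(.childSeed(seed, 12L))
    cls <- .drawNuc(matrix(c(spec@coupling$weights,
                             rep(0, 4 - length(spec@coupling$weights))),
                           n, 4L, byrow = TRUE), stats::runif(n))
  }
  ## phase 1: draw all ancestral nucleotides (class-conditional if coupled)
  labs <- names(spec@models)
  anc <- matrix(NA_integer_, n, length(labs), dimnames = list(NULL, labs))
  for (k in seq_along(labs)) {
    lab <- labs[k]
    pz <- matrix(spec@models[[lab]]@ancestral, n, 4L, byrow = TRUE)
    if (!is.null(spec@coupling$ancestral)) {
      for (cl in seq_along(spec@coupling$ancestral)) {
        ov <- spec@coupling$ancestral[[cl]][[lab]]
        if (!is.null(ov))
          pz[cls == cl, ] <- matrix(ov, sum(cls == cl), 4L, byrow = TRUE)
      }
    }
    set.seed(.childSeed(seed, 100L + k))
    anc[, k] <- .drawNuc(pz, stats::runif(n))
  }
  ## phase 2: evolve each branch; the substitution-coupling knob switches a
  ## target position's matrix on the ancestor state of the driver position
  ## (epistasis in substitutions, not just in the ancestor)
  subc <- spec@coupling$substitution
  for (k in seq_along(labs)) {
    lab <- labs[k]
    m <- spec@models[[lab]]
    off <- offsetOf(sch, lab) + 1L
    for (g in genomes) {
      rows <- m@matrices[[g]][anc[, k], , drop = FALSE]
      if (!is.null(subc) && lab %in% subc$targets) {
        cond <- anc[, subc$driver] == .nucIndex(subc$consensus)
        rows[cond, ] <- subc$matrixIfConsensus[anc[cond, k], ,
                                               drop = FALSE]
        rows[!cond, ] <- subc$matrixOtherwise[anc[!cond, k], ,
                                              drop = FALSE]
      }
      set.seed(.childSeed(seed, 200L + 10L * k + match(g, genomes)))
      mats[[g]][, off] <- NUC[.drawNuc(rows, stats::runif(n))]
    }
  }
  ## dinucleotide-biased PPT overrides
  if (!is.null(spec@pptModel)) {
    off <- offsetOf(sch, spec@pptModel@region) + 1L
    for (g in genomes) {
      set.seed(.childSeed(seed, 300L + match(g, genomes)))
      cur <- .drawNuc(matrix(spec@pptModel@initial, n, 4L, byrow = TRUE),
                      stats::runif(n))
      mats[[g]][, off[1]] <- NUC[cur]
      for (j in seq_along(off)[-1]) {
        cur <- .drawNuc(spec@pptModel@transition[cur, , drop = FALSE],
                        stats::runif(n))
        mats[[g]][, off[j]] <- NUC[cur]
      }
    }
  }
  set.seed(.childSeed(seed, 13L))
  ages <- stats::rlnorm(n, spec@ageMeanlog, spec@ageSdlog)
  collapse <- function(M) apply(M, 1L, paste, collapse = "")
  out <- SpliceSiteSet(sprintf("syn%05d", seq_len(n)),
                       collapse(mats$human), collapse(mats$mouse),
                       collapse(mats$dog), spec@ssType, spec@splicingType,
                       ageKs = ages,
                       provenance = list(generator = "spliceCoev",
                                         seed = as.integer(seed),
                                         coupled = length(spec@coupling) > 0))
  attr(out, "ancestorClass") <- cls
  attr(out, "ancestralDraws") <- {
    colnames(anc) <- labs
    matrix(NUC[anc], n, length(labs), dimnames = list(siteIds(out), labs))
  }
  out
}

## ---- worked fixture ---------------------------------------------------------

#' A small deterministic dataset with brute-force expected results
#'
#' Returns a fixed 12-site donor dataset (hand-written sequences) together
#' with an expected-results bundle computed inside this function by naive,
#' loop-based arithmetic: the (-2)-position triple tally, the pooled
#' descendant PWM with pseudocount 0.5, the per-position strength table,
#' human strength vectors and their covariance. The bundle is an
#' independent oracle for the vectorized implementations.
#'
#' @return list with elements \code{dataset} (a
#'   \linkS4class{SpliceSiteSet}) and \code{expected} (list of
#'   brute-force-computed values)
#' @export
generateWorkedFixture <- function() {
  ## exon offsets 1-10 (-10..-1), GT at 11-12, intron +3..+20 at 13-30
  ex <- c("CCAAGCCAAG", "CCAAGCCCAG", "CCAAGCCGAG", "CCAAGCCAAG",
          "CCAAGCCACG", "CCAAGCCAAG", "CCAAGCCTAG", "CCAAGCCAAG",
          "CCAAGCCAAG", "CCAAGCCAAG", "CCAAGCCAGG", "CCAAGCCAAG")
  intr <- c("AAGTACGTACGTACGTAC", "AAGTACGTACGTACGTAC",
            "GAGTACGTACGTACGTAC", "AAGAACGTACGTACGTAC",
            "ACGTACGTACGTACGTAC", "AAGTACGTACGTACGTAC",
            "AATTACGTACGTACGTAC", "GAGTACGTACGTACGTAC",
            "AAGTTCGTACGTACGTAC", "CAGTACGTACGTACGTAC",
            "AAGTACGTACGTACGTAC", "AAGCACGTACGTACGTAC")
  hum <- paste0(ex, "GT", intr)
  mm <- hum
  substr(mm[2], 8, 8) <- "A"    # -3: C -> A
  substr(mm[4], 15, 15) <- "T"  # +5: A -> T
  substr(mm[6], 9, 9) <- "C"    # -2: A -> C
  substr(mm[9], 13, 13) <- "G"  # +3: A -> G
  dg <- hum
  substr(dg[3], 9, 9) <- "G"    # -2: A -> G
  substr(dg[7], 8, 8) <- "G"    # -3: T -> G
  substr(dg[11], 14, 14) <- "G" # +4: A -> G
  ds <- SpliceSiteSet(sprintf("fx%02d", 1:12), hum, mm, dg, "donor",
                      ageKs = rep(c(0.4, 1.6), 6),
                      provenance = list(fixture = TRUE))
  sch <- positionScheme("donor")
  win <- sch@window
  ## --- brute-force expected values (naive loops, no package fast paths) ---
  seqs <- list(human = hum, mouse = mm, dog = dg)
  offs <- vapply(win, function(l) offsetOf(sch, l) + 1L, 1L)
  ## triple tally at -2
  o2 <- offsetOf(sch, "-2") + 1L
  tally <- array(0, c(4, 4, 4), dimnames = list(NUC, NUC, NUC))
  for (i in 1:12) {
    a <- substr(hum[i], o2, o2); b <- substr(mm[i], o2, o2)
    cc <- substr(dg[i], o2, o2)
    tally[a, b, cc] <- tally[a, b, cc] + 1
  }
  tripleFreq <- tally / 12
  ## pooled PWM, pseudocount 0.5
  pwmExp <- matrix(NA_real_, 4, length(win), dimnames = list(NUC, win))
  for (j in seq_along(win)) {
    cnt <- c(A = 0, C = 0, G = 0, T = 0)
    for (g in names(seqs)) for (i in 1:12) {
      nt <- substr(seqs[[g]][i], offs[j], offs[j])
      cnt[nt] <- cnt[nt] + 1
    }
    pwmExp[, j] <- (cnt + 0.5) / (sum(cnt) + 2)
  }
  strengthExp <- log2(pwmExp / 0.25)
  ## human strength vectors + covariance, by hand
  V <- matrix(NA_real_, 12, length(win), dimnames = list(NULL, win))
  for (i in 1:12) for (j in seq_along(win))
    V[i, j] <- strengthExp[substr(hum[i], offs[j], offs[j]), j]
  covExp <- matrix(NA_real_, length(win), length(win),
                   dimnames = list(win, win))
  for (a in seq_along(win)) for (b in seq_along(win)) {
    xa <- V[, a] - mean(V[, a]); xb <- V[, b] - mean(V[, b])
    covExp[a, b] <- sum(xa * xb) / 11
  }
  list(dataset = ds,
       expected = list(tripleFreqMinus2 = tripleFreq,
                       pwm = pwmExp, strengths = strengthExp,
                       humanVectors = V, humanCov = covExp))
}
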