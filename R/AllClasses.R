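#' @include utils.R
#' @import methods
#' @importFrom Biostrings DNAStringSet
#' @importFrom S4Vectors DataFrame
NULL

#' PositionScheme: biological position labels for a 30-nt splice-site window
#'
#' Maps biological position labels (strings such as \code{"-2"}, \code{"+5"})
#' onto 0-based string offsets of the 30-nt site window, and records which
#' labels form the default analysis window and which are the invariant
#' canonical dinucleotide.
#'
#' Donor sites are laid out exon-first: offsets 0--9 are exonic positions
#' -10..-1, offsets 10--11 are the invariant GT (+1, +2), offsets 12--29 are
#' intronic +3..+20. Acceptor sites are laid out intron-first: offsets 0--17
#' are intronic -20..-3, offsets 18--19 are the invariant AG (-2, -1), and
#' offsets 20--29 are exonic +1..+10.
#'
#' @slot ssType \code{"donor"} or \code{"acceptor"}.
#' @slot labels character(30), biological label at each string offset.
#' @slot window ordered labels of the default analysis window (invariant
#'   positions never appear here).
#' @slot invariant labels of the canonical dinucleotide positions.
#' @slot canonical the invariant dinucleotide itself ("GT" or "AG").
#' @exportClass PositionScheme
setClass("PositionScheme",
  representation(ssType = "character", labels = "character",
                 window = "character", invariant = "character",
                 canonical = "character"),
  validity = function(object) {
    msg <- NULL
    if (length(object@labels) != 30L)
      msg <- c(msg, "labels must have length 30")
    if (!object@ssType %in% c("donor", "acceptor"))
      msg <- c(msg, "ssType must be 'donor' or 'acceptor'")
    if (any(object@window %in% object@invariant))
      msg <- c(msg, "invariant positions cannot be in the analysis window")
    if (anyDuplicated(object@labels))
      msg <- c(msg, "duplicate position labels")
    if (is.null(msg)) TRUE else msg
  })

#' SpliceSiteSet: orthologous splice-site triples from three genomes
#'
#' The central data container: a set of orthologous splice sites, each
#' represented by three aligned 30-nt windows (10 exonic nt, the canonical
#' GT/AG dinucleotide, 18 intronic nt) from the human, mouse and dog genomes,
#' together with the splicing-type label and the site age in units of
#' synonymous-substitution distance (K_s).
#'
#' @slot id character vector of unique site identifiers.
#' @slot ssType \code{"donor"} or \code{"acceptor"} (homogeneous per set).
#' @slot splicingType \code{"constitutive"} or \code{"cassette"}.
#' @slot ageKs numeric site ages (K_s), NA when unknown.
#' @slot human,mouse,dog \code{DNAStringSet}s of width 30, parallel to
#'   \code{id}.
#' @slot meta \code{DataFrame} of pass-through metadata (chromosome, strand,
#'   coordinate), parallel to \code{id}.
#' @slot exclusions data.frame of records rejected at load time (id, reason).
#' @slot provenance list describing where the data came from.
#' @exportClass SpliceSiteSet
setClass("SpliceSiteSet",
  representation(id = "character", ssType = "character",
                 splicingType = "character", ageKs = "numeric",
                 human = "DNAStringSet", mouse = "DNAStringSet",
                 dog = "DNAStringSet", meta = "DataFrame",
                 exclusions = "data.frame", provenance = "list"),
  validity = function(object) {
    msg <- NULL
    n <- length(object@id)
    if (length(object@human) != n || length(object@mouse) != n ||
        length(object@dog) != n || length(object@ageKs) != n)
      msg <- c(msg, "id, ageKs and the three sequence sets must be parallel")
    if (anyDuplicated(object@id))
      msg <- c(msg, "duplicate site ids")
    if (!object@ssType %in% c("donor", "acceptor"))
      msg <- c(msg, "ssType must be 'donor' or 'acceptor'")
    if (n > 0L) {
      ws <- c(Biostrings::width(object@human), Biostrings::width(object@mouse),
              Biostrings::width(object@dog))
      if (any(ws != 30L))
        msg <- c(msg, "all sequences must be 30 nt")
      sch <- positionScheme(object@ssType)
      off <- match(sch@invariant, sch@labels)
      for (g in c("human", "mouse", "dog")) {
        di <- paste0(substr(as.character(slot(object, g)), off[1], off[1]),
                     substr(as.character(slot(object, g)), off[2], off[2]))
        if (any(di != sch@canonical))
          msg <- c(msg, sprintf("non-canonical %s dinucleotide in %s",
                                sch@canonical, g))
      }
    }
    if (is.null(msg)) TRUE else msg
  })

#' PositionModel: star-phylogeny substitution model for one site position
#'
#' An ancestral nucleotide probability vector p(Z) and three branch-specific
#' 4x4 substitution matrices (human, mouse, dog). Matrix rows are indexed by
#' the ancestral nucleotide Z and columns by the descendant nucleotide X, so
#' entry (Z, X) is p(X|Z); every row is a probability distribution.
#'
#' @slot ancestral numeric(4), p(Z) in A,C,G,T order.
#' @slot matrices named list of three 4x4 row-stochastic matrices
#'   (\code{human}, \code{mouse}, \code{dog}).
#' @exportClass PositionModel
setClass("PositionModel",
  representation(ancestral = "numeric", matrices = "list"),
  validity = function(object) {
    msg <- NULL
    if (length(object@ancestral) != 4L || !.isSimplex(object@ancestral))
      msg <- c(msg, "ancestral must be a probability 4-vector")
    if (!identical(sort(names(object@matrices)), c("dog", "human", "mouse")))
      msg <- c(msg, "matrices must be named human, mouse, dog")
    for (nm in names(object@matrices)) {
      P <- object@matrices[[nm]]
      if (!is.matrix(P) || !identical(dim(P), c(4L, 4L)))
        msg <- c(msg, sprintf("%s matrix must be 4x4", nm))
      else if (any(P < -1e-9) || any(P > 1 + 1e-9) ||
               any(abs(rowSums(P) - 1) > 1e-9))
        msg <- c(msg, sprintf("%s matrix rows must be stochastic", nm))
    }
    if (is.null(msg)) TRUE else msg
  })

#' PositionFit: result of least-squares estimation of a PositionModel
#'
#' @slot model the fitted \linkS4class{PositionModel}.
#' @slot objective the attained sum of squared residuals over the 64 triple
#'   probabilities.
#' @slot restartObjectives numeric, the objective reached by each random
#'   restart.
#' @slot identifiable logical(4); FALSE for matrix rows whose ancestral
#'   probability mass is below 1e-3 (their entries are essentially
#'   unconstrained by the data).
#' @slot position the position label the model was fitted for.
#' @slot n effective number of sites behind the triple frequency table.
#' @slot seed master seed of the restart schedule.
#' @exportClass PositionFit
setClass("PositionFit",
  representation(model = "PositionModel", objective = "numeric",
                 restartObjectives = "numeric", identifiable = "logical",
                 position = "character", n = "numeric", seed = "integer"),
  validity = function(object) {
    msg <- NULL
    if (object@objective < 0)
      msg <- c(msg, "objective must be nonnegative")
    if (length(object@restartObjectives) &&
        object@objective > min(object@restartObjectives) + 1e-12)
      msg <- c(msg, "objective must attain the minimum over restarts")
    if (is.null(msg)) TRUE else msg
  })

#' SitePWM: position weight matrix over the analysis window
#'
#' Foreground nucleotide probabilities per window position against a fixed
#' uniform background of 0.25. The strength of nucleotide a at position i is
#' W = log(pF(a,i) / 0.25) in the stored log base.
#'
#' @slot probs 4 x L matrix of foreground probabilities, rows A,C,G,T,
#'   columns named by position label; each column sums to 1.
#' @slot pseudocount pseudocount added per nucleotide when counting.
#' @slot logBase base of the strength logarithm (default 2, i.e. bits).
#' @slot source \code{"descendants_pooled"} or \code{"ancestral"}.
#' @exportClass SitePWM
setClass("SitePWM",
  representation(probs = "matrix", pseudocount = "numeric",
                 logBase = "numeric", source = "character"),
  validity = function(object) {
    msg <- NULL
    if (nrow(object@probs) != 4L)
      msg <- c(msg, "probs must have 4 rows (A,C,G,T)")
    if (any(object@probs < 0))
      msg <- c(msg, "foreground probabilities must be nonnegative")
    if (object@pseudocount > 0 && any(object@probs == 0))
      msg <- c(msg, "pseudocounted probabilities must be positive")
    if (any(abs(colSums(object@probs) - 1) > 1e-9))
      msg <- c(msg, "each position's probabilities must sum to 1")
    if (object@logBase <= 0 || object@logBase == 1)
      msg <- c(msg, "logBase must be positive and != 1")
    if (is.null(msg)) TRUE else msg
  })

#' BootstrapResult: point estimate with percentile CI and sign-counting p
#'
#' @slot estimate statistic on the full sample.
#' @slot ci numeric(2) percentile 95\% confidence interval.
#' @slot pValue two-sided p-value against \code{nullValue}, floored at
#'   1/nTrials.
#' @slot nullValue the null value tested.
#' @slot nTrials number of completed bootstrap trials.
#' @slot nDropped trials dropped because the statistic failed.
#' @slot seed master seed.
#' @slot replicates the bootstrap replicate values (kept for diagnostics).
#' @exportClass BootstrapResult
setClass("BootstrapResult",
  representation(estimate = "numeric", ci = "numeric", pValue = "numeric",
                 nullValue = "numeric", nTrials = "integer",
                 nDropped = "integer", seed = "integer",
                 replicates = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (length(object@ci) != 2L)
      msg <- c(msg, "ci must have length 2")
    if (object@pValue <= 0 || object@pValue > 1)
      msg <- c(msg, "pValue must lie in (0, 1]")
    if (is.null(msg)) TRUE else msg
  })

#' CovarianceResult: position-by-position covariance of strength vectors
#'
#' @slot cov L x L symmetric covariance matrix (pairwise-complete, n-1
#'   denominator), dimnames = position labels.
#' @slot pValues L x L matrix of bootstrap p-values that each covariance
#'   differs from zero (raw, no multiple-testing correction).
#' @slot n number of sites.
#' @slot genome which descendant genome the strength vectors came from.
#' @exportClass CovarianceResult
setClass("CovarianceResult",
  representation(cov = "matrix", pValues = "matrix", n = "integer",
                 genome = "character"),
  validity = function(object) {
    msg <- NULL
    if (!isTRUE(all.equal(object@cov, t(object@cov), tolerance = 1e-8,
                          check.attributes = FALSE)))
      msg <- c(msg, "covariance matrix must be symmetric")
    d <- diag(object@cov)
    if (any(d[!is.na(d)] < -1e-12))
      msg <- c(msg, "variances must be nonnegative")
    if (is.null(msg)) TRUE else msg
  })

#' MarkovRegionModel: first-order Markov chain over a sequence region
#'
#' @slot initial numeric(4) initial nucleotide probabilities.
#' @slot transition 4x4 row-stochastic transition matrix (rows: preceding
#'   nucleotide).
#' @slot region character labels of the region positions, in order.
#' @slot flagged logical(4); TRUE for rows that had zero conditioning counts
#'   and fell back to uniform.
#' @exportClass MarkovRegionModel
setClass("MarkovRegionModel",
  representation(initial = "numeric", transition = "matrix",
                 region = "character", flagged = "logical"),
  validity = function(object) {
    msg <- NULL
    if (!.isSimplex(object@initial))
      msg <- c(msg, "initial must be on the simplex")
    if (any(abs(rowSums(object@transition) - 1) > 1e-9))
      msg <- c(msg, "transition rows must be stochastic")
    if (is.null(msg)) TRUE else msg
  })

#' GeneratorSpec: ground-truth description for synthetic site triples
#'
#' Defines the generative process for a synthetic \linkS4class{SpliceSiteSet}:
#' one \linkS4class{PositionModel} per analysis-window position (ancestral
#' vector + three branch matrices), an optional ancestor-class mixture that
#' couples consensus adherence across positions, an optional first-order
#' Markov model for the polypyrimidine tract of acceptor sites, an age
#' distribution, and flank background composition.
#'
#' @slot ssType,splicingType site type labels.
#' @slot n number of sites to generate.
#' @slot models named list of PositionModel, one per window label.
#' @slot coupling list with elements \code{weights} (class probabilities) and
#'   \code{ancestral} (per class: named list of ancestral 4-vectors
#'   overriding the models' p(Z)); empty list = independent positions.
#' @slot pptModel a \linkS4class{MarkovRegionModel} for the acceptor PPT
#'   region, or NULL.
#' @slot ageMeanlog,ageSdlog parameters of the lognormal K_s age
#'   distribution.
#' @slot gc flank background GC content.
#' @slot flankStay per-branch conservation probability of flank positions;
#'   flanks evolve on the same star tree (ancestor i.i.d. from the
#'   background, each branch substituting with the neutral flank matrix) so
#'   that neutral-control estimation sees phylogenetically correlated
#'   triples, as it does on real data.
#' @slot seed master seed.
#' @exportClass GeneratorSpec
setClass("GeneratorSpec",
  representation(ssType = "character", splicingType = "character",
                 n = "integer", models = "list", coupling = "list",
                 pptModel = "ANY", ageMeanlog = "numeric",
                 ageSdlog = "numeric", gc = "numeric",
                 flankStay = "numeric", seed = "integer"),
  validity = function(object) {
    msg <- NULL
    if (object@n < 0L) msg <- c(msg, "n must be nonnegative")
    if (!all(vapply(object@models, is, logical(1), "PositionModel")))
      msg <- c(msg, "models must all be PositionModel objects")
    if (!is.null(object@coupling$weights) &&
        !.isSimplex(object@coupling$weights, tol = 1e-6))
      msg <- c(msg, "coupling class weights must be on the simplex")
    sub <- object@coupling$substitution
    if (!is.null(sub)) {
      need <- c("driver", "consensus", "targets", "matrixIfConsensus",
                "matrixOtherwise")
      if (!all(need %in% names(sub)))
        msg <- c(msg, paste("substitution coupling needs fields:",
                            paste(need, collapse = ", ")))
    }
    if (object@gc <= 0 || object@gc >= 1)
      msg <- c(msg, "gc must be in (0, 1)")
    if (is.null(msg)) TRUE else msg
  })
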