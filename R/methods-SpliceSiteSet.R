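#' @include AllGenerics.R
NULL

## ---- constructor -----------------------------------------------------------

#' Construct a SpliceSiteSet
#'
#' Low-level constructor; most users get a \linkS4class{SpliceSiteSet} from
#' \code{\link{readSpliceSites}} or \code{\link{generateTriples}}.
#'
#' @param id character vector of unique ids.
#' @param human,mouse,dog character vectors (or DNAStringSets) of 30-nt
#'   windows, parallel to \code{id}.
#' @param ssType "donor" or "acceptor".
#' @param splicingType "constitutive" or "cassette".
#' @param ageKs numeric ages in K_s units (NA allowed).
#' @param meta optional DataFrame of pass-through metadata.
#' @param exclusions data.frame of records rejected upstream.
#' @param provenance free-form list.
#' @return a \linkS4class{SpliceSiteSet}
#' @export
SpliceSiteSet <- function(id, human, mouse, dog, ssType,
                          splicingType = "constitutive",
                          ageKs = rep(NA_real_, length(id)),
                          meta = S4Vectors::DataFrame(),
                          exclusions = data.frame(id = character(0),
                                                  reason = character(0)),
                          provenance = list()) {
  if (nrow(meta) == 0L && length(id) > 0L)
    meta <- S4Vectors::DataFrame(matrix(nrow = length(id), ncol = 0L))
  new("SpliceSiteSet", id = as.character(id),
      human = Biostrings::DNAStringSet(human),
      mouse = Biostrings::DNAStringSet(mouse),
      dog = Biostrings::DNAStringSet(dog),
      ssType = ssType, splicingType = splicingType,
      ageKs = as.numeric(ageKs), meta = meta,
      exclusions = exclusions, provenance = provenance)
}

## ---- accessors -------------------------------------------------------------

#' @rdname SpliceSiteSet-class
#' @export
setMethod("siteIds", "SpliceSiteSet", function(x) x@id)

#' @rdname SpliceSiteSet-class
#' @export
setMethod("siteAges", "SpliceSiteSet", function(x) x@ageKs)

#' @rdname SpliceSiteSet-class
#' @export
setMethod("ssType", "SpliceSiteSet", function(x) x@ssType)

#' @rdname SpliceSiteSet-class
#' @export
setMethod("splicingType", "SpliceSiteSet", function(x) x@splicingType)

#' @rdname SpliceSiteSet-class
#' @export
setMethod("siteSeqs", "SpliceSiteSet", function(x, genome) {
  genome <- match.arg(genome, c("human", "mouse", "dog"))
  slot(x, genome)
})

#' @rdname SpliceSiteSet-class
#' @export
setMethod("exclusions", "SpliceSiteSet", function(x) x@exclusions)

#' @describeIn SpliceSiteSet-class number of site triples
#' @export
setMethod("length", "SpliceSiteSet", function(x) length(x@id))

#' @describeIn SpliceSiteSet-class subset by index, logical mask or id
#' @param i index vector
#' @param j,...,drop ignored
#' @export
setMethod("[", "SpliceSiteSet", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, x@id)
  ## resampling with replacement may select a site twice; keep ids unique
  initialize(x, id = make.unique(x@id[i]), human = x@human[i],
             mouse = x@mouse[i],
             dog = x@dog[i], ageKs = x@ageKs[i],
             meta = x@meta[i, , drop = FALSE])
})

setMethod("show", "SpliceSiteSet", function(object) {
  cat(sprintf("SpliceSiteSet of %d %s %s site triples (human/mouse/dog)\n",
              length(object), object@splicingType, object@ssType))
  aged <- sum(!is.na(object@ageKs))
  cat(sprintf("  aged records: %d; excluded at load: %d\n",
              aged, nrow(object@exclusions)))
  if (length(object) > 0L) {
    k <- min(length(object), 2L)
    for (i in seq_len(k))
      cat(sprintf("  %s  H:%s\n", object@id[i],
                  as.character(object@human[i])))
    if (length(object) > k) cat("  ...\n")
  }
})

## ---- sequence matrix views -------------------------------------------------

#' Nucleotide matrix of one genome at selected positions
#'
#' @param x a SpliceSiteSet
#' @param genome "human", "mouse" or "dog"
#' @param positions position labels (default: full analysis window)
#' @return character matrix, sites x positions, with position labels as
#'   column names; entries outside A,C,G,T are returned as-is.
#' @export
positionMatrix <- function(x, genome, positions = NULL) {
  sch <- positionScheme(ssType(x))
  if (is.null(positions)) positions <- sch@window
  off <- offsetOf(sch, positions) + 1L
  if (length(x) == 0L)
    return(matrix(character(0), 0L, length(positions),
                  dimnames = list(NULL, positions)))
  cm <- .charMatrix(siteSeqs(x, genome))
  m <- cm[, off, drop = FALSE]
  dimnames(m) <- list(siteIds(x), positions)
  m
}
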