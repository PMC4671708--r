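#' @include AllClasses.R
NULL

#' @rdname SpliceSiteSet-class
#' @param x a SpliceSiteSet
#' @export
setGeneric("siteIds", function(x) standardGeneric("siteIds"))

#' @rdname SpliceSiteSet-class
#' @export
setGeneric("siteAges", function(x) standardGeneric("siteAges"))

#' @rdname SpliceSiteSet-class
#' @export
setGeneric("ssType", function(x) standardGeneric("ssType"))

#' @rdname SpliceSiteSet-class
#' @export
setGeneric("splicingType", function(x) standardGeneric("splicingType"))

#' @rdname SpliceSiteSet-class
#' @param genome one of "human", "mouse", "dog"
#' @export
setGeneric("siteSeqs", function(x, genome) standardGeneric("siteSeqs"))

#' @rdname SpliceSiteSet-class
#' @export
setGeneric("exclusions", function(x) standardGeneric("exclusions"))

#' @rdname PositionModel-class
#' @param x a PositionModel or PositionFit
#' @export
setGeneric("ancestralVector", function(x) standardGeneric("ancestralVector"))

#' @rdname PositionModel-class
#' @param branch one of "human", "mouse", "dog"
#' @export
setGeneric("branchMatrix", function(x, branch) standardGeneric("branchMatrix"))

#' @rdname SitePWM-class
#' @param x a SitePWM
#' @export
setGeneric("pwmProbs", function(x) standardGeneric("pwmProbs"))

#' @rdname SitePWM-class
#' @export
setGeneric("strengthMatrix", function(x) standardGeneric("strengthMatrix"))
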