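#' @include methods-SpliceSiteSet.R
NULL

## ---- position schemes ------------------------------------------------------

#' Position scheme for donor or acceptor sites
#'
#' @param ssType "donor" or "acceptor"
#' @return a \linkS4class{PositionScheme}
#' @examples
#' sch <- positionScheme("donor")
#' offsetOf(sch, c("-1", "+3"))
#' @export
positionScheme <- function(ssType = c("donor", "acceptor")) {
  ssType <- match.arg(ssType)
  if (ssType == "donor") {
    labels <- c(paste0("-", 10:1), paste0("+", 1:20))
    new("PositionScheme", ssType = "donor", labels = labels,
        window = c("-3", "-2", "-1", "+3", "+4", "+5", "+6"),
        invariant = c("+1", "+2"), canonical = "GT")
  } else {
    labels <- c(paste0("-", 20:1), paste0("+", 1:10))
    new("PositionScheme", ssType = "acceptor", labels = labels,
        window = c(paste0("-", 20:3), "+1", "+2", "+3"),
        invariant = c("-2", "-1"), canonical = "AG")
  }
}

setMethod("show", "PositionScheme", function(object) {
  cat(sprintf("PositionScheme (%s): invariant %s at offsets %s\n",
              object@ssType, object@canonical,
              paste(offsetOf(object, object@invariant), collapse = ",")))
  cat(sprintf("  analysis window: %s\n",
              paste(object@window, collapse = " ")))
})

#' Map position labels to 0-based string offsets
#'
#' @param scheme a \linkS4class{PositionScheme}
#' @param label character vector of position labels (e.g. "-2", "+5")
#' @return integer vector of 0-based offsets into the 30-nt window
#' @export
offsetOf <- function(scheme, label) {
  i <- match(label, scheme@labels)
  if (anyNA(i))
    stop("unknown position label(s): ",
         paste(label[is.na(i)], collapse = ", "))
  i - 1L
}

## ---- reading and writing ---------------------------------------------------

.REQUIRED_COLS <- c("id", "hg19_chr_num", "hg19_chr_chain", "hg19_coord",
                    "age", "human_seq", "mouse_seq", "dog_seq")

.openSiteTable <- function(path, member = NULL) {
  if (grepl("\\.zip$", path, ignore.case = TRUE)) {
    if (is.null(member)) {
      listed <- utils::unzip(path, list = TRUE)$Name
      listed <- listed[!grepl("/$", listed)]
      if (length(listed) != 1L)
        stop("ZIP contains ", length(listed),
             " files; pass `member` to pick one")
      member <- listed
    }
    unz(path, member)
  } else {
    path   # read.delim opens and closes plain paths itself
  }
}

## Orientation auto-detection: the published tables do not document whether
## the exon precedes the intron within the 30-nt string, so we look for the
## canonical dinucleotide at the two offsets the two orientations imply and
## take the majority vote over human sequences.
.detectOrientation <- function(seqs, scheme) {
  std <- offsetOf(scheme, scheme@invariant) + 1L
  alt <- if (scheme@ssType == "donor") c(19L, 20L) else c(11L, 12L)
  di <- function(off) {
    paste0(substr(seqs, off[1], off[1]), substr(seqs, off[2], off[2]))
  }
  nStd <- sum(di(std) == scheme@canonical)
  nAlt <- sum(di(alt) == scheme@canonical)
  if (nAlt > nStd) "flipped" else "standard"
}

.flipLayout <- function(seqs, ssType) {
  ## flipped donor: 18 intronic + GT + 10 exonic -> exon-first standard
  ## flipped acceptor: 10 exonic + AG + 18 intronic -> intron-first standard
  if (ssType == "donor")
    paste0(substr(seqs, 21, 30), substr(seqs, 19, 20), substr(seqs, 1, 18))
  else
    paste0(substr(seqs, 13, 30), substr(seqs, 11, 12), substr(seqs, 1, 10))
}

#' Read a splice-site triple table
#'
#' Reads a tab-separated site table (one header row; columns \code{id},
#' \code{hg19_chr_num}, \code{hg19_chr_chain}, \code{hg19_coord}, \code{age},
#' \code{human_seq}, \code{mouse_seq}, \code{dog_seq}; order taken from the
#' header) or a single-file ZIP container of one. Records whose three
#' sequences are not 30 nt long, contain characters outside A,C,G,T,N, or
#' lack the canonical GT (donor) / AG (acceptor) dinucleotide in any of the
#' three species are excluded; exclusion counts and reasons are kept in the
#' returned object. The orientation of the sequence string (whether the
#' exonic part comes first) is auto-detected from the location of the
#' canonical dinucleotide and recorded in the provenance.
#'
#' @param path TSV file (or .zip containing one).
#' @param ssType "donor" or "acceptor".
#' @param splicingType "constitutive" or "cassette".
#' @param member file name inside a ZIP container, if ambiguous.
#' @return a \linkS4class{SpliceSiteSet}
#' @export
readSpliceSites <- function(path, ssType = c("donor", "acceptor"),
                            splicingType = c("constitutive", "cassette"),
                            member = NULL) {
  ssType <- match.arg(ssType)
  splicingType <- match.arg(splicingType)
  con <- .openSiteTable(path, member)
  tab <- utils::read.delim(con, header = TRUE, sep = "\t",
                           colClasses = "character",
                           stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(.REQUIRED_COLS, colnames(tab))
  if (length(missing))
    stop("site table is missing required column(s): ",
         paste(missing, collapse = ", "))
  sch <- positionScheme(ssType)
  prov <- list(path = path, ssType = ssType, splicingType = splicingType,
               nRows = nrow(tab))
  if (nrow(tab) == 0L) {
    return(SpliceSiteSet(character(0), character(0), character(0),
                         character(0), ssType, splicingType,
                         provenance = prov))
  }
  seqCols <- c("human_seq", "mouse_seq", "dog_seq")
  for (sc in seqCols) tab[[sc]] <- toupper(tab[[sc]])

  orientation <- .detectOrientation(tab$human_seq[nchar(tab$human_seq) == 30],
                                    sch)
  if (orientation == "flipped")
    for (sc in seqCols) tab[[sc]] <- .flipLayout(tab[[sc]], ssType)
  prov$orientation <- orientation

  off <- offsetOf(sch, sch@invariant) + 1L
  reason <- rep(NA_character_, nrow(tab))
  for (sc in seqCols) {
    s <- tab[[sc]]
    bad <- nchar(s) != 30L
    reason[bad & is.na(reason)] <- paste0(sc, ": not 30 nt")
    bad <- !bad & grepl("[^ACGTN]", s)
    reason[bad & is.na(reason)] <- paste0(sc, ": non-ACGTN character")
    di <- paste0(substr(s, off[1], off[1]), substr(s, off[2], off[2]))
    bad <- is.na(reason) & di != sch@canonical
    reason[bad] <- paste0(sc, ": non-canonical ", sch@canonical)
  }
  dup <- duplicated(tab$id)
  reason[dup & is.na(reason)] <- "duplicate id"
  keep <- is.na(reason)
  excl <- data.frame(id = tab$id[!keep], reason = reason[!keep],
                     stringsAsFactors = FALSE)
  tab <- tab[keep, , drop = FALSE]
  prov$nExcluded <- nrow(excl)

  SpliceSiteSet(tab$id, tab$human_seq, tab$mouse_seq, tab$dog_seq,
                ssType, splicingType,
                ageKs = suppressWarnings(as.numeric(tab$age)),
                meta = S4Vectors::DataFrame(
                  hg19_chr_num = tab$hg19_chr_num,
                  hg19_chr_chain = tab$hg19_chr_chain,
                  hg19_coord = tab$hg19_coord),
                exclusions = excl, provenance = prov)
}

#' Write a SpliceSiteSet back to the TSV dialect it is read from
#'
#' Also writes a JSON provenance sidecar at \code{<path>.provenance.json}.
#'
#' @param x a SpliceSiteSet
#' @param path output TSV path
#' @return \code{path}, invisibly
#' @export
writeSpliceSites <- function(x, path) {
  m <- x@meta
  getcol <- function(nm) {
    if (nm %in% colnames(m)) as.character(m[[nm]]) else
      rep(NA_character_, length(x))
  }
  out <- data.frame(id = siteIds(x),
                    hg19_chr_num = getcol("hg19_chr_num"),
                    hg19_chr_chain = getcol("hg19_chr_chain"),
                    hg19_coord = getcol("hg19_coord"),
                    age = siteAges(x),
                    human_seq = as.character(siteSeqs(x, "human")),
                    mouse_seq = as.character(siteSeqs(x, "mouse")),
                    dog_seq = as.character(siteSeqs(x, "dog")),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  prov <- c(x@provenance, list(ssType = ssType(x),
                               splicingType = splicingType(x),
                               n = length(x)))
  jsonlite::write_json(prov, paste0(path, ".provenance.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

## ---- young / old split -----------------------------------------------------

#' Split a site set into young and old strata by age
#'
#' Sites younger than \code{thresholdKs} synonymous-substitution units are
#' "young"; sites at or above the threshold are "old" (the boundary value is
#' assigned to the old stratum). Records with missing age are excluded from
#' both strata and counted.
#'
#' @param x a SpliceSiteSet
#' @param thresholdKs age threshold in K_s units (default 1)
#' @return list with elements \code{young}, \code{old} (SpliceSiteSets) and
#'   \code{nMissingAge}
#' @export
splitByAge <- function(x, thresholdKs = 1.0) {
  age <- siteAges(x)
  if (any(age < 0, na.rm = TRUE))
    stop("negative site ages are invalid")
  aged <- !is.na(age)
  young <- x[which(aged & age < thresholdKs)]
  old <- x[which(aged & age >= thresholdKs)]
  young@provenance <- c(young@provenance, list(stratum = "young"))
  old@provenance <- c(old@provenance, list(stratum = "old"))
  list(young = young, old = old, nMissingAge = sum(!aged))
}
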