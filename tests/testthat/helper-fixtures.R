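# Shared helpers: tiny deterministic datasets, random-but-seeded models,
# and TSV writers in the site-table dialect.

NUC4 <- c("A", "C", "G", "T")

# assemble a donor 30-mer from its exonic (10 nt) and intronic (18 nt) parts
## intron chosen without GT at the offsets the alternative (flipped)
## layout would place the canonical dinucleotide, so tiny all-identical
## fixtures do not confuse the orientation vote
donorSeq <- function(exon = "CCCCCCCAAG", intron = "AAGAAACCCTTTCCCAAA") {
  stopifnot(nchar(exon) == 10, nchar(intron) == 18)
  paste0(exon, "GT", intron)
}

acceptorSeq <- function(intron = "TTTTTTTTTTTTTTTCTC",
                        exon = "GCCGCCGCCG") {
  stopifnot(nchar(intron) == 18, nchar(exon) == 10)
  paste0(intron, "AG", exon)
}

# a donor set whose three species differ at chosen positions only
tinyDonorSet <- function(n = 4, ages = rep(0.5, n)) {
  SpliceSiteSet(sprintf("s%02d", seq_len(n)),
                human = rep(donorSeq(), n),
                mouse = rep(donorSeq(), n),
                dog = rep(donorSeq(), n),
                ssType = "donor", ageKs = ages)
}

# replace the nucleotide at a biological position for selected sites
setNt <- function(x, genome, label, i, nt) {
  sch <- positionScheme(ssType(x))
  off <- offsetOf(sch, label) + 1L
  s <- as.character(siteSeqs(x, genome))
  substr(s[i], off, off) <- nt
  slot(x, genome) <- Biostrings::DNAStringSet(s)
  x
}

# seeded random valid PositionModel (rows strictly positive)
randomModel <- function(seed) {
  set.seed(seed)
  rsimplex <- function() {
    g <- rexp(4) + 0.05
    g / sum(g)
  }
  rmat <- function() t(vapply(1:4, function(i) rsimplex(), numeric(4)))
  PositionModel(rsimplex(), rmat(), rmat(), rmat())
}

# write a SpliceSiteSet-shaped TSV by hand (no package writer involved)
writeSiteTSV <- function(path, id, human, mouse, dog,
                         age = rep(0.5, length(id))) {
  df <- data.frame(id = id, hg19_chr_num = "1", hg19_chr_chain = "+",
                   hg19_coord = seq_along(id), age = age,
                   human_seq = human, mouse_seq = mouse, dog_seq = dog)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# brute-force triple tally oracle (naive loop over sites)
oracleTripleFreq <- function(x, label) {
  sch <- positionScheme(ssType(x))
  off <- offsetOf(sch, label) + 1L
  h <- substr(as.character(siteSeqs(x, "human")), off, off)
  m <- substr(as.character(siteSeqs(x, "mouse")), off, off)
  d <- substr(as.character(siteSeqs(x, "dog")), off, off)
  tal <- array(0, c(4, 4, 4), dimnames = list(NUC4, NUC4, NUC4))
  n <- 0
  for (i in seq_along(h)) {
    if (all(c(h[i], m[i], d[i]) %in% NUC4)) {
      tal[h[i], m[i], d[i]] <- tal[h[i], m[i], d[i]] + 1
      n <- n + 1
    }
  }
  tal / n
}
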