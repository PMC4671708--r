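## Internal helpers shared across modules.
##
## Nucleotide order is fixed package-wide as A, C, G, T; every 4-vector and
## every 4x4 matrix row/column follows this order, and all categorical draws
## use inverse-CDF sampling on it so runs are reproducible across platforms.

NUC <- c("A", "C", "G", "T")

.nucIndex <- function(x) {
  i <- match(x, NUC)
  i
}

## Row-wise softmax; rows of `logits` map onto the probability simplex.
.softmaxRows <- function(logits) {
  m <- apply(logits, 1L, max)
  e <- exp(logits - m)
  e / rowSums(e)
}

.softmaxVec <- function(logits) {
  e <- exp(logits - max(logits))
  e / sum(e)
}

## Inverse-CDF draw of nucleotide indices: one draw per row of `prob`
## (n x 4, rows on the simplex), driven by uniforms `u`.
.drawNuc <- function(prob, u) {
  c1 <- prob[, 1L]
  c2 <- c1 + prob[, 2L]
  c3 <- c2 + prob[, 3L]
  1L + (u > c1) + (u > c2) + (u > c3)
}

.isSimplex <- function(p, tol = 1e-9) {
  all(p >= -tol) && abs(sum(p) - 1) < tol
}

## Deterministic child seeds below 2^31, derived from a master seed.
.childSeed <- function(seed, k) {
  ## double arithmetic is exact here and avoids 32-bit overflow
  as.integer((as.numeric(seed) + 1000003 * as.numeric(k)) %% 2147483647)
}

.charMatrix <- function(x) {
  ## DNAStringSet or character vector of equal-width strings -> n x width
  ## character matrix
  s <- as.character(x)
  if (length(s) == 0L) {
    return(matrix(character(0), nrow = 0L, ncol = 0L))
  }
  w <- unique(nchar(s))
  stopifnot(length(w) == 1L)
  matrix(unlist(strsplit(s, "", fixed = TRUE), use.names = FALSE),
         nrow = length(s), ncol = w, byrow = TRUE)
}
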