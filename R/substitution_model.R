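#' @include sites_io.R
NULL

## ---- PositionModel construction & accessors --------------------------------

#' Construct a PositionModel
#'
#' @param ancestral numeric(4) ancestral nucleotide probabilities (A,C,G,T).
#' @param human,mouse,dog 4x4 row-stochastic branch substitution matrices,
#'   rows = ancestral nucleotide, columns = descendant nucleotide.
#' @return a \linkS4class{PositionModel}
#' @examples
#' m <- PositionModel(rep(0.25, 4), diag(4), diag(4), diag(4))
#' branchMatrix(m, "human")
#' @export
PositionModel <- function(ancestral, human, mouse, dog) {
  nm <- list(A = NUC, B = NUC)
  fix <- function(P) {
    P <- as.matrix(P)
    dimnames(P) <- list(ancestor = NUC, descendant = NUC)
    P
  }
  ancestral <- as.numeric(ancestral)
  names(ancestral) <- NUC
  new("PositionModel", ancestral = ancestral,
      matrices = list(human = fix(human), mouse = fix(mouse),
                      dog = fix(dog)))
}

#' @rdname PositionModel-class
#' @export
setMethod("ancestralVector", "PositionModel", function(x) x@ancestral)

#' @rdname PositionModel-class
#' @export
setMethod("branchMatrix", "PositionModel", function(x, branch) {
  x@matrices[[match.arg(branch, c("human", "mouse", "dog"))]]
})

#' @rdname PositionModel-class
#' @export
setMethod("ancestralVector", "PositionFit", function(x) x@model@ancestral)

#' @rdname PositionModel-class
#' @export
setMethod("branchMatrix", "PositionFit", function(x, branch) {
  branchMatrix(x@model, branch)
})

setMethod("show", "PositionModel", function(object) {
  cat("PositionModel  p(Z) =",
      paste(sprintf("%s:%.3f", NUC, object@ancestral), collapse = " "), "\n")
  cat("  branch matrices: human, mouse, dog (rows = ancestor)\n")
})

setMethod("show", "PositionFit", function(object) {
  cat(sprintf("PositionFit at position %s (n = %g)\n",
              object@position, object@n))
  cat(sprintf("  objective %.3g over %d restarts (best %d identical)\n",
              object@objective, length(object@restartObjectives),
              sum(object@restartObjectives - object@objective < 1e-8)))
  if (!all(object@identifiable))
    cat("  unidentifiable rows:",
        paste(NUC[!object@identifiable], collapse = ","), "\n")
  show(object@model)
})

## ---- triple frequency tables -----------------------------------------------

#' Observed triple frequencies at one site position
#'
#' Tallies the (human, mouse, dog) nucleotide triple at the given position
#' over all sites, skipping sites with a non-ACGT character at that position
#' in any genome, and normalizes to frequencies.
#'
#' @param x a \linkS4class{SpliceSiteSet}
#' @param position a position label
#' @return a 4x4x4 numeric array \code{q[h, m, d]} summing to 1, with
#'   attribute \code{n} = number of sites used
#' @export
countTriples <- function(x, position) {
  h <- .nucIndex(positionMatrix(x, "human", position)[, 1])
  m <- .nucIndex(positionMatrix(x, "mouse", position)[, 1])
  d <- .nucIndex(positionMatrix(x, "dog", position)[, 1])
  ok <- !is.na(h) & !is.na(m) & !is.na(d)
  n <- sum(ok)
  if (n == 0L)
    stop("no usable (ACGT) triples at position ", position)
  idx <- h[ok] + 4L * (m[ok] - 1L) + 16L * (d[ok] - 1L)
  q <- array(tabulate(idx, 64L) / n, dim = c(4L, 4L, 4L),
             dimnames = list(human = NUC, mouse = NUC, dog = NUC))
  attr(q, "n") <- n
  q
}

#' Model-implied triple probabilities
#'
#' Computes p(h,m,d) = sum_r p(r) p(h|r) p(m|r) p(d|r) for all 64 triples.
#'
#' @param model a \linkS4class{PositionModel}
#' @return a 4x4x4 array summing to 1
#' @export
forwardTripleProbs <- function(model) {
  pZ <- model@ancestral
  A <- model@matrices$human; B <- model@matrices$mouse
  C <- model@matrices$dog
  E <- array(0, dim = c(4L, 4L, 4L),
             dimnames = list(human = NUC, mouse = NUC, dog = NUC))
  for (r in 1:4)
    E <- E + pZ[r] * (A[r, ] %o% B[r, ] %o% C[r, ])
  E
}

## ---- least-squares fit ------------------------------------------------------

## Parameter layout (52 logits): 4 for p(Z), then 16 each for the human,
## mouse and dog matrices (row-major). Rows and the ancestral vector are
## mapped to the simplex by softmax, which keeps the quasi-Newton search
## unconstrained while every iterate satisfies the stochasticity constraints.
.unpackTheta <- function(theta) {
  pZ <- .softmaxVec(theta[1:4])
  mats <- lapply(0:2, function(k) {
    .softmaxRows(matrix(theta[5:20 + 16L * k], 4L, 4L, byrow = TRUE))
  })
  list(pZ = pZ, A = mats[[1]], B = mats[[2]], C = mats[[3]])
}

.lsObjective <- function(theta, Q) {
  u <- .unpackTheta(theta)
  E <- array(0, dim = c(4L, 4L, 4L))
  for (r in 1:4)
    E <- E + u$pZ[r] * (u$A[r, ] %o% u$B[r, ] %o% u$C[r, ])
  sum((E - Q)^2)
}

.lsGradient <- function(theta, Q) {
  u <- .unpackTheta(theta)
  pZ <- u$pZ; A <- u$A; B <- u$B; C <- u$C
  E <- array(0, dim = c(4L, 4L, 4L))
  for (r in 1:4)
    E <- E + pZ[r] * (A[r, ] %o% B[r, ] %o% C[r, ])
  e <- 2 * (E - Q)
  ## residual contractions against pairs of branch rows
  eX <- matrix(e, 4L)                       # x by (y,z), y fastest
  eY <- matrix(aperm(e, c(2, 1, 3)), 4L)    # y by (x,z), x fastest
  eZ <- matrix(aperm(e, c(3, 1, 2)), 4L)    # z by (x,y), x fastest
  BC <- t(vapply(1:4, function(r) as.vector(B[r, ] %o% C[r, ]),
                 numeric(16)))
  AC <- t(vapply(1:4, function(r) as.vector(A[r, ] %o% C[r, ]),
                 numeric(16)))
  AB <- t(vapply(1:4, function(r) as.vector(A[r, ] %o% B[r, ]),
                 numeric(16)))
  M1 <- eX %*% t(BC)                        # [x, r]
  M2 <- eY %*% t(AC)                        # [y, r]
  M3 <- eZ %*% t(AB)                        # [z, r]
  dA <- t(M1) * pZ
  dB <- t(M2) * pZ
  dC <- t(M3) * pZ
  dpZ <- rowSums(t(M1) * A)
  ## chain through softmax: dlogit = p * (g - sum(p * g))
  chainVec <- function(p, g) p * (g - sum(p * g))
  chainRows <- function(P, G) {
    t(vapply(1:4, function(r) chainVec(P[r, ], G[r, ]), numeric(4)))
  }
  c(chainVec(pZ, dpZ),
    as.vector(t(chainRows(A, dA))),
    as.vector(t(chainRows(B, dB))),
    as.vector(t(chainRows(C, dC))))
}

.randomSimplexLogits <- function(k) {
  g <- stats::rexp(k)
  log(g / sum(g))
}

.modelToTheta <- function(model, eps = 1e-12) {
  rows <- function(P) as.vector(t(log(pmax(P, eps))))
  c(log(pmax(model@ancestral, eps)),
    rows(model@matrices$human), rows(model@matrices$mouse),
    rows(model@matrices$dog))
}

.thetaToModel <- function(theta) {
  u <- .unpackTheta(theta)
  PositionModel(u$pZ, u$A, u$B, u$C)
}

## The objective is exactly invariant under a joint relabelling of the
## ancestral states (permuting p(Z) together with the rows of all three
## matrices), so every fit has 24 equivalent global minima. We anchor the
## labelling biologically: the ancestor of a nucleotide is the state that
## is predominantly conserved, i.e. we pick the permutation maximizing the
## summed diagonal of the three matrices.
.PERMS4 <- {
  p <- list()
  for (a in 1:4) for (b in setdiff(1:4, a)) for (cc in setdiff(1:4, c(a, b)))
    p[[length(p) + 1L]] <- c(a, b, cc, setdiff(1:4, c(a, b, cc)))
  p
}

.canonicalizeModel <- function(model) {
  score <- vapply(.PERMS4, function(pm) {
    sum(vapply(model@matrices,
               function(P) sum(P[cbind(pm, 1:4)]), numeric(1)))
  }, numeric(1))
  pm <- .PERMS4[[which.max(score)]]
  if (identical(pm, 1:4)) return(model)
  PositionModel(model@ancestral[pm],
                model@matrices$human[pm, , drop = FALSE],
                model@matrices$mouse[pm, , drop = FALSE],
                model@matrices$dog[pm, , drop = FALSE])
}

#' Fit a per-position substitution model by constrained least squares
#'
#' Minimizes the sum of squared differences between the 64 model-implied
#' triple probabilities (\code{\link{forwardTripleProbs}}) and the observed
#' triple frequencies, over the 39-dimensional space of one ancestral
#' probability vector and three row-stochastic branch matrices. The search
#' runs from \code{restarts} random starting points (uniform on each
#' simplex, seeds derived deterministically from \code{seed}) and keeps the
#' lowest local minimum. Matrix rows whose fitted ancestral mass falls below
#' 1e-3 carry essentially no gradient and are flagged unidentifiable.
#'
#' The objective is exactly invariant to a joint relabelling of the
#' ancestral states, so each fit has 24 equivalent minima; the returned
#' model is anchored to the biologically meaningful labelling in which
#' ancestral states are predominantly conserved (the permutation maximizing
#' the summed diagonals of the three branch matrices).
#'
#' @param freqs 4x4x4 observed triple frequency array from
#'   \code{\link{countTriples}} (or any nonnegative array summing to 1).
#' @param restarts number of random restarts (default 10).
#' @param seed master seed; the fit is deterministic given it.
#' @param position label stored in the result, for bookkeeping.
#' @param maxit maximum BFGS iterations per restart.
#' @return a \linkS4class{PositionFit}
#' @export
fitPositionModel <- function(freqs, restarts = 10L, seed = 1L,
                             position = NA_character_, maxit = 1000L) {
  Q <- array(as.numeric(freqs), dim = c(4L, 4L, 4L))
  if (any(Q < 0) || abs(sum(Q) - 1) > 1e-6)
    stop("freqs must be a nonnegative array summing to 1")
  n <- attr(freqs, "n")
  fits <- vector("list", restarts + 1L)
  objs <- rep(NA_real_, restarts + 1L)
  errs <- character(0)
  ## two stages: cheap descent from each start, then one tightly converged
  ## polish of the best local minimum. Start 1 is deterministic and
  ## data-informed (ancestral vector = mean descendant marginal,
  ## near-identity matrices) — highly conserved positions put the optimum
  ## near the boundary of the simplex, where random starts often stall in
  ## local minima; the remaining starts are uniform on each simplex.
  margInit <- {
    pH <- apply(Q, 1L, sum); pM <- apply(Q, 2L, sum)
    pD <- apply(Q, 3L, sum)
    p0 <- pmax((pH + pM + pD) / 3, 1e-6)
    nearI <- log(diag(4) * 0.88 + 0.04)
    c(log(p0 / sum(p0)), rep(as.vector(t(nearI)), 3L))
  }
  for (k in seq_len(restarts + 1L)) {
    init <- if (k == 1L) margInit else {
      set.seed(.childSeed(seed, k - 1L))
      c(.randomSimplexLogits(4),
        unlist(lapply(1:12, function(i) .randomSimplexLogits(4))))
    }
    res <- tryCatch(
      stats::optim(init, cpp_ls_obj, cpp_ls_grad, Q = as.numeric(Q),
                   method = "BFGS",
                   control = list(maxit = 400L, reltol = 1e-10)),
      error = function(e) e)
    if (inherits(res, "error")) {
      errs <- c(errs, conditionMessage(res))
      next
    }
    fits[[k]] <- res
    objs[k] <- res$value
  }
  if (all(is.na(objs)))
    stop("optimizer failed in all ", restarts, " restarts: ",
         paste(unique(errs), collapse = "; "))
  best <- fits[[which.min(objs)]]
  polished <- stats::optim(best$par, cpp_ls_obj, cpp_ls_grad,
                           Q = as.numeric(Q), method = "BFGS",
                           control = list(maxit = maxit, reltol = 1e-15))
  if (polished$value <= best$value) best <- polished
  model <- .canonicalizeModel(.thetaToModel(best$par))
  objs[which.min(objs)] <- best$value
  new("PositionFit", model = model, objective = best$value,
      restartObjectives = objs[!is.na(objs)],
      identifiable = model@ancestral >= 1e-3,
      position = as.character(position),
      n = if (is.null(n)) NA_real_ else as.numeric(n),
      seed = as.integer(seed))
}

## Warm refit from an existing solution: used by the bootstrap machinery,
## where the resampled frequency table is a small perturbation of the
## original and a single descent from the point estimate suffices.
.refitFrom <- function(model, Q, maxit = 60L) {
  theta <- .modelToTheta(model)
  res <- stats::optim(theta, cpp_ls_obj, cpp_ls_grad, Q = as.numeric(Q),
                      method = "BFGS",
                      control = list(maxit = maxit, reltol = 1e-9))
  .thetaToModel(res$par)
}

## ---- parsimony alternative --------------------------------------------------

#' Parsimony-based substitution model
#'
#' For each site, the ancestral nucleotide is taken as the majority
#' nucleotide among (human, mouse, dog); when all three differ, the site
#' contributes 1/3 of a count to each of the three equally parsimonious
#' ancestors. Ancestor-to-descendant counts are accumulated per branch and
#' row-normalized; ancestral probabilities are the ancestor-count
#' frequencies. Ancestor rows never observed fall back to the identity row
#' (the nucleotide is kept), keeping the matrices stochastic.
#'
#' @param x a \linkS4class{SpliceSiteSet}
#' @param position a position label
#' @return a \linkS4class{PositionModel}
#' @export
fitParsimony <- function(x, position) {
  if (length(x) == 0L)
    stop("empty dataset")
  q <- countTriples(x, position)
  n <- attr(q, "n")
  counts <- q * n
  ancCount <- numeric(4L)
  trans <- list(human = matrix(0, 4, 4), mouse = matrix(0, 4, 4),
                dog = matrix(0, 4, 4))
  for (h in 1:4) for (m in 1:4) for (d in 1:4) {
    cnt <- counts[h, m, d]
    if (cnt == 0) next
    trip <- c(h, m, d)
    tab <- tabulate(trip, 4L)
    if (max(tab) >= 2L) {
      anc <- list(which.max(tab))
      w <- cnt
    } else {
      anc <- as.list(trip)
      w <- cnt / 3
    }
    for (a in anc) {
      ancCount[a] <- ancCount[a] + w
      trans$human[a, h] <- trans$human[a, h] + w
      trans$mouse[a, m] <- trans$mouse[a, m] + w
      trans$dog[a, d] <- trans$dog[a, d] + w
    }
  }
  norm <- function(M) {
    rs <- rowSums(M)
    for (r in 1:4) {
      if (rs[r] > 0) M[r, ] <- M[r, ] / rs[r]
      else M[r, r] <- 1
    }
    M
  }
  PositionModel(ancCount / sum(ancCount),
                norm(trans$human), norm(trans$mouse), norm(trans$dog))
}

## ---- neutral controls -------------------------------------------------------

#' Control positions used to build the neutral expectation
#'
#' Donor intronic positions (+3..+6) are controlled by the adjacent intronic
#' region +7..+12; donor exonic positions -1/-2/-3 by the frame-matched
#' exonic pairs {-4,-7}/{-5,-8}/{-6,-9}; acceptor exonic +1/+2/+3 by
#' {+4,+7}/{+5,+8}/{+6,+9}. Acceptor intronic positions (the PPT has no
#' clean flanking neutral region) use the donor intronic control region
#' +7..+12, taken from the companion donor dataset of the same splicing
#' type; the attribute \code{"dataset"} of the return value says which
#' dataset the control positions refer to ("self" or "donor").
#'
#' @param ssType "donor" or "acceptor"
#' @param position a position label in the analysis window
#' @return character vector of control position labels, with attribute
#'   \code{dataset}
#' @export
controlPositionsFor <- function(ssType = c("donor", "acceptor"), position) {
  ssType <- match.arg(ssType)
  sch <- positionScheme(ssType)
  if (position %in% sch@invariant)
    stop("invariant position ", position, " has no neutral control")
  if (!position %in% sch@labels)
    stop("unknown position label: ", position)
  donorIntron <- paste0("+", 7:12)
  res <- if (ssType == "donor") {
    switch(position,
           "-1" = c("-4", "-7"), "-2" = c("-5", "-8"), "-3" = c("-6", "-9"),
           "+3" = , "+4" = , "+5" = , "+6" = donorIntron,
           stop("position ", position,
                " is outside the donor analysis window"))
  } else {
    switch(position,
           "+1" = c("+4", "+7"), "+2" = c("+5", "+8"), "+3" = c("+6", "+9"),
           {
             if (!grepl("^-", position))
               stop("position ", position,
                    " is outside the acceptor analysis window")
             structure(donorIntron, fromDonor = TRUE)
           })
  }
  attr(res, "dataset") <-
    if (isTRUE(attr(res, "fromDonor"))) "donor" else "self"
  attr(res, "fromDonor") <- NULL
  res
}

#' Pool control-position models into a neutral expectation
#'
#' For each branch, joint ancestor-descendant probability matrices
#' J(z,x) = p(z) p(x|z) are summed over the control positions and
#' row-normalized, giving the expected (neutral) matrix P_E; the neutral
#' ancestral vector is the normalized sum of the control ancestral vectors.
#'
#' @param models list of \linkS4class{PositionModel} (or
#'   \linkS4class{PositionFit}) objects fitted at the control positions
#' @return a \linkS4class{PositionModel}
#' @export
neutralModel <- function(models) {
  if (length(models) == 0L)
    stop("at least one control-position model is required")
  models <- lapply(models, function(m) {
    if (is(m, "PositionFit")) m@model else m
  })
  anc <- Reduce(`+`, lapply(models, slot, "ancestral"))
  mats <- lapply(c(human = "human", mouse = "mouse", dog = "dog"),
                 function(b) {
    J <- Reduce(`+`, lapply(models, function(m) {
      m@ancestral * m@matrices[[b]]   # multiplies rows by p(z)
    }))
    rs <- rowSums(J)
    if (any(rs <= 0))
      stop("degenerate neutral control: zero mass for ancestor ",
           paste(NUC[rs <= 0], collapse = ","), " in branch ", b)
    J / rs
  })
  PositionModel(anc / sum(anc), mats$human, mats$mouse, mats$dog)
}

## ---- serialization ----------------------------------------------------------

#' Serialize fitted models to JSON
#'
#' @param fits named list of PositionFit objects (names = position labels)
#' @param path output JSON path
#' @return \code{path}, invisibly
#' @export
writeModelsJSON <- function(fits, path) {
  out <- lapply(fits, function(f) {
    m <- if (is(f, "PositionFit")) f@model else f
    list(position = if (is(f, "PositionFit")) f@position else NA,
         ancestral = as.numeric(m@ancestral),
         human = m@matrices$human, mouse = m@matrices$mouse,
         dog = m@matrices$dog,
         objective = if (is(f, "PositionFit")) f@objective else NA,
         seed = if (is(f, "PositionFit")) f@seed else NA)
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}
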