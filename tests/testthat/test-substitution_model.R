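test_that("triple frequencies match a brute-force tally", {
  ds <- tinyDonorSet(2)
  ds <- setNt(ds, "dog", "-2", 2, "C")    # triples: (A,A,A), (A,A,C)
  q <- countTriples(ds, "-2")
  expect_equal(attr(q, "n"), 2L)
  expect_equal(q["A", "A", "A"], 0.5)
  expect_equal(q["A", "A", "C"], 0.5)
  expect_equal(sum(q), 1)

  # 10 fixed triples vs the naive loop oracle; N at the position is skipped
  set.seed(31)
  ds10 <- tinyDonorSet(10)
  for (i in 1:10) {
    ds10 <- setNt(ds10, "human", "+4", i, sample(NUC4, 1))
    ds10 <- setNt(ds10, "mouse", "+4", i, sample(NUC4, 1))
    ds10 <- setNt(ds10, "dog", "+4", i, sample(NUC4, 1))
  }
  ds10 <- setNt(ds10, "human", "+4", 3, "N")
  q10 <- countTriples(ds10, "+4")
  expect_equal(attr(q10, "n"), 9L)
  expect_equal(unname(unclass(q10)), unname(oracleTripleFreq(ds10, "+4")),
               ignore_attr = TRUE)
  expect_error(countTriples(tinyDonorSet(0), "-2"), "no usable")
})

test_that("forward triple probabilities agree with the four-term sum", {
  ident <- PositionModel(c(1, 0, 0, 0), diag(4), diag(4), diag(4))
  E <- forwardTripleProbs(ident)
  expect_equal(E["A", "A", "A"], 1)
  expect_equal(sum(E), 1)
  unif <- PositionModel(rep(0.25, 4), matrix(0.25, 4, 4),
                        matrix(0.25, 4, 4), matrix(0.25, 4, 4))
  expect_equal(as.vector(forwardTripleProbs(unif)), rep(1 / 64, 64))

  m <- randomModel(7)
  E <- forwardTripleProbs(m)
  # independent term-by-term oracle
  for (h in 1:4) for (mm in 1:4) for (d in 1:4) {
    s <- 0
    for (r in 1:4)
      s <- s + m@ancestral[r] * m@matrices$human[r, h] *
        m@matrices$mouse[r, mm] * m@matrices$dog[r, d]
    expect_equal(E[h, mm, d], s, tolerance = 1e-12, ignore_attr = TRUE)
  }
  expect_equal(sum(E), 1, tolerance = 1e-12)
})

test_that("compiled objective and gradient match the R reference", {
  set.seed(12)
  for (rep in 1:5) {
    th <- rnorm(52)
    Q <- forwardTripleProbs(randomModel(rep))
    Qv <- as.numeric(Q)
    Qa <- array(Qv, c(4, 4, 4))
    expect_equal(spliceCoev:::cpp_ls_obj(th, Qv),
                 spliceCoev:::.lsObjective(th, Qa), tolerance = 1e-12)
    expect_equal(as.numeric(spliceCoev:::cpp_ls_grad(th, Qv)),
                 spliceCoev:::.lsGradient(th, Qa), tolerance = 1e-12)
  }
})

test_that("fit recovers a known model from its exact triple probabilities", {
  truth <- PositionModel(c(0.7, 0.1, 0.1, 0.1),
                         substitutionMatrix(0.9),
                         substitutionMatrix(0.88),
                         substitutionMatrix(0.92))
  E <- forwardTripleProbs(truth)
  fit <- fitPositionModel(E, restarts = 10, seed = 21)
  expect_lt(fit@objective, 1e-10)
  expect_equal(ancestralVector(fit), ancestralVector(truth),
               tolerance = 1e-3)
  for (b in c("human", "mouse", "dog"))
    expect_equal(branchMatrix(fit, b), branchMatrix(truth, b),
                 tolerance = 1e-3)
})

test_that("degenerate all-A data give a point-mass fit with flags", {
  q <- array(0, c(4, 4, 4))
  q[1, 1, 1] <- 1
  fit <- fitPositionModel(q, seed = 5)
  expect_lt(fit@objective, 1e-12)
  expect_equal(unname(ancestralVector(fit)[1]), 1, tolerance = 1e-5)
  for (b in c("human", "mouse", "dog"))
    expect_equal(unname(branchMatrix(fit, b)[1, ]), c(1, 0, 0, 0),
                 tolerance = 1e-5)
  expect_equal(unname(fit@identifiable), c(TRUE, FALSE, FALSE, FALSE))
})

test_that("fitting is deterministic given the seed", {
  ds <- generateTriples(defaultGeneratorSpec("donor", n = 400, seed = 3))
  q <- countTriples(ds, "+5")
  f1 <- fitPositionModel(q, seed = 17)
  f2 <- fitPositionModel(q, seed = 17)
  expect_identical(f1@model@ancestral, f2@model@ancestral)
  expect_identical(f1@model@matrices, f2@model@matrices)
  expect_identical(f1@objective, f2@objective)
})

test_that("fitted models remain row-stochastic and on the simplex", {
  ds <- generateTriples(defaultGeneratorSpec("donor", n = 600, seed = 9))
  for (p in c("-2", "+5")) {
    fit <- fitPositionModel(countTriples(ds, p), seed = 2)
    expect_equal(sum(ancestralVector(fit)), 1, tolerance = 1e-9)
    for (b in c("human", "mouse", "dog"))
      expect_equal(rowSums(branchMatrix(fit, b)), rep(1, 4),
                   tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("parsimony majority rule, ties, and PB-vs-LB diagonal property", {
  ds <- tinyDonorSet(1)
  ds <- setNt(ds, "dog", "-2", 1, "C")   # (A, A, C): ancestor A
  pb <- fitParsimony(ds, "-2")
  expect_equal(unname(ancestralVector(pb)), c(1, 0, 0, 0))
  expect_equal(pb@matrices$dog["A", "C"], 1)
  expect_equal(pb@matrices$human["A", "A"], 1)
  expect_equal(pb@matrices$mouse["A", "A"], 1)

  dsG <- tinyDonorSet(3)
  for (g in c("human", "mouse", "dog")) for (i in 1:3)
    dsG <- setNt(dsG, g, "-2", i, "G")
  pbG <- fitParsimony(dsG, "-2")
  expect_equal(unname(ancestralVector(pbG)), c(0, 0, 1, 0))
  expect_equal(pbG@matrices$human["G", "G"], 1)

  # all-distinct triple: 1/3 weight to each candidate ancestor
  dsT <- tinyDonorSet(1)
  dsT <- setNt(dsT, "mouse", "-2", 1, "C")
  dsT <- setNt(dsT, "dog", "-2", 1, "G")  # (A, C, G)
  pbT <- fitParsimony(dsT, "-2")
  expect_equal(unname(ancestralVector(pbT)), c(1, 1, 1, 0) / 3)

  # strict majorities: PB conserves at least as much as LB on the diagonal
  ds2 <- generateTriples(defaultGeneratorSpec("donor", n = 2000, seed = 8))
  lb <- fitPositionModel(countTriples(ds2, "-2"), seed = 4)
  pb2 <- fitParsimony(ds2, "-2")
  idf <- lb@identifiable
  for (b in c("human", "mouse", "dog"))
    expect_true(all(diag(branchMatrix(pb2, b))[idf] >=
                      diag(branchMatrix(lb, b))[idf] - 0.02))
  expect_error(fitParsimony(tinyDonorSet(0), "-2"), "empty")
})

test_that("control positions follow the frame and region rules", {
  expect_equal(as.vector(controlPositionsFor("donor", "+5")),
               paste0("+", 7:12))
  expect_equal(as.vector(controlPositionsFor("donor", "-1")), c("-4", "-7"))
  expect_equal(as.vector(controlPositionsFor("donor", "-2")), c("-5", "-8"))
  expect_equal(as.vector(controlPositionsFor("donor", "-3")), c("-6", "-9"))
  expect_equal(as.vector(controlPositionsFor("acceptor", "+2")),
               c("+5", "+8"))
  expect_equal(attr(controlPositionsFor("acceptor", "+2"), "dataset"),
               "self")
  ppt <- controlPositionsFor("acceptor", "-9")
  expect_equal(as.vector(ppt), paste0("+", 7:12))
  expect_equal(attr(ppt, "dataset"), "donor")
  expect_error(controlPositionsFor("donor", "+1"), "invariant")
  expect_error(controlPositionsFor("acceptor", "-1"), "invariant")
})

test_that("neutral pooling sums joint matrices then row-normalizes", {
  m1 <- randomModel(41)
  expect_equal(neutralModel(list(m1))@matrices, m1@matrices,
               tolerance = 1e-12)
  expect_equal(neutralModel(list(m1, m1))@ancestral, m1@ancestral,
               tolerance = 1e-12)
  m2 <- randomModel(42)
  pooled <- neutralModel(list(m1, m2))
  # direct arithmetic oracle
  for (b in c("human", "mouse", "dog")) {
    J <- m1@ancestral * m1@matrices[[b]] + m2@ancestral * m2@matrices[[b]]
    expect_equal(pooled@matrices[[b]], J / rowSums(J), tolerance = 1e-12)
    expect_equal(rowSums(pooled@matrices[[b]]), rep(1, 4),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
  expect_equal(pooled@ancestral,
               (m1@ancestral + m2@ancestral) / 2, tolerance = 1e-12)
  expect_error(neutralModel(list()), "at least one")
})
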