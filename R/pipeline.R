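#' @include synthetic_data.R
NULL

## tiny rolling hash of a string, for stamping outputs with a config digest
.configHash <- function(s) {
  h <- 5381
  for (b in utf8ToInt(s))
    h <- (h * 31 + b) %% 2147483647
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}

.stage <- function(name, verbose, expr) {
  t0 <- Sys.time()
  if (verbose) message(sprintf("[%s] starting", name))
  res <- tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
  if (verbose)
    message(sprintf("[%s] done in %.1fs", name,
                    as.numeric(Sys.time() - t0, units = "secs")))
  res
}

#' Run the full splice-site evolution pipeline
#'
#' Orchestrates: data loading (or synthetic generation) -> per-position
#' least-squares model fits -> neutral controls -> PWM -> strength-change /
#' omega table -> strength covariance matrices per genome -> simulation
#' under position-independent evolution and covariance comparison -> (for
#' acceptors) PPT dinucleotide report. All tables are written as TSV into
#' \code{outdir}, with a JSON provenance record carrying the seeds and a
#' hash of the configuration; rerunning with the same config and seed
#' reproduces every number.
#'
#' @param config a named list, or path to a YAML file with the same
#'   structure. Recognised fields: \code{input} (path to a site TSV),
#'   \code{ssType}, \code{splicingType}, \code{donorCompanion} (path,
#'   needed for acceptor runs), \code{synthetic} (list passed to
#'   \code{\link{defaultGeneratorSpec}}, used when no \code{input}),
#'   \code{outdir}, \code{positions}, \code{pseudocount} (0.5),
#'   \code{logBase} (2), \code{restarts} (10), \code{trials} (1500),
#'   \code{nSim} (20), \code{seed} (1), \code{genomes}, \code{parsimony}
#'   (also fit the parsimony models), \code{ppt} (run the PPT dinucleotide
#'   stage), \code{verbose}.
#' @return invisibly, a list with all in-memory results (dataset, fits,
#'   pwm, strength table, covariances, comparison, ppt table, output paths)
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(
    list(input = NULL, ssType = "donor", splicingType = "constitutive",
         donorCompanion = NULL, synthetic = list(), outdir = "spliceCoev_out",
         positions = NULL, pseudocount = 0.5, logBase = 2, restarts = 10L,
         trials = 1500L, nSim = 20L, seed = 1L,
         genomes = c("human", "mouse", "dog"), parsimony = FALSE,
         ppt = NULL, verbose = TRUE),
    config)
  v <- isTRUE(cfg$verbose)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  emit <- function(obj, name) {
    p <- file.path(cfg$outdir, name)
    utils::write.table(obj, p, sep = "\t", quote = FALSE, row.names = FALSE)
    outputs[[length(outputs) + 1L]] <<- p
    p
  }

  ds <- .stage("load", v, {
    if (!is.null(cfg$input)) {
      readSpliceSites(cfg$input, cfg$ssType, cfg$splicingType)
    } else {
      spec <- do.call(defaultGeneratorSpec,
                      utils::modifyList(list(ssType = cfg$ssType,
                                             seed = cfg$seed),
                                        cfg$synthetic))
      generateTriples(spec)
    }
  })
  if (v) message(sprintf("  %d sites loaded, %d excluded", length(ds),
                         nrow(exclusions(ds))))
  companion <- NULL
  if (!is.null(cfg$donorCompanion))
    companion <- .stage("load-companion", v, {
      readSpliceSites(cfg$donorCompanion, "donor", cfg$splicingType)
    })
  sch <- positionScheme(ssType(ds))
  positions <- if (is.null(cfg$positions)) sch@window else cfg$positions

  pwm <- .stage("pwm", v, {
    buildPWM(ds, pseudocount = cfg$pseudocount, logBase = cfg$logBase,
             positions = positions)
  })
  emit(data.frame(position = colnames(pwmProbs(pwm)),
                  t(pwmProbs(pwm)), check.names = FALSE), "pwm.tsv")

  changes <- .stage("strength-changes", v, {
    strengthChangeTable(ds, pwm, positions = positions,
                        branches = cfg$genomes,
                        donorCompanion = companion,
                        nTrials = cfg$trials, restarts = cfg$restarts,
                        seed = cfg$seed)
  })
  emit(changes, "strength_changes.tsv")
  fits <- attr(changes, "fits")
  writeModelsJSON(fits, file.path(cfg$outdir, "models.json"))

  if (isTRUE(cfg$parsimony)) {
    .stage("parsimony", v, {
      pb <- lapply(positions, function(p) fitParsimony(ds, p))
      names(pb) <- positions
      writeModelsJSON(pb, file.path(cfg$outdir, "models_parsimony.json"))
    })
  }

  covs <- .stage("covariance", v, {
    lapply(stats::setNames(cfg$genomes, cfg$genomes), function(g) {
      cm <- covarianceMatrix(strengthVectors(ds, pwm, g, positions),
                             nTrials = cfg$trials, seed = cfg$seed,
                             genome = g)
      writeCovarianceTSV(cm, file.path(cfg$outdir,
                                       sprintf("covariance_%s.tsv", g)))
      cm
    })
  })

  cmp <- .stage("simulate-null", v, {
    compareCovariances(ds, fits, pwm, genome = cfg$genomes[1],
                       positions = positions, nTrials = cfg$trials,
                       nSim = cfg$nSim, seed = cfg$seed)
  })
  utils::write.table(cmp$difference,
                     file.path(cfg$outdir, "covariance_real_minus_sim.tsv"),
                     sep = "\t", quote = FALSE, col.names = NA)
  utils::write.table(cmp$pValues,
                     file.path(cfg$outdir,
                               "covariance_real_minus_sim.pvalues.tsv"),
                     sep = "\t", quote = FALSE, col.names = NA)

  pptTab <- NULL
  doPpt <- if (is.null(cfg$ppt)) ssType(ds) == "acceptor" else
    isTRUE(cfg$ppt)
  if (doPpt) {
    pptTab <- .stage("ppt", v, {
      region <- paste0("-", 12:7)
      comparison <- if (!is.null(companion))
        list(x = companion, region = paste0("+", 7:12)) else NULL
      dinucleotideObsExp(ds, region, genome = cfg$genomes[1],
                         comparison = comparison, nTrials = cfg$trials,
                         seed = cfg$seed)
    })
    emit(pptTab, "ppt_dinucleotides.tsv")
  }

  prov <- list(package = "spliceCoev",
               version = as.character(utils::packageVersion("spliceCoev")),
               seed = cfg$seed,
               configHash = .configHash(jsonlite::toJSON(cfg[order(names(cfg))],
                                                    auto_unbox = TRUE,
                                                    null = "null",
                                                    force = TRUE)),
               nSites = length(ds), positions = positions)
  jsonlite::write_json(prov, file.path(cfg$outdir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(dataset = ds, pwm = pwm, changes = changes, fits = fits,
                 covariances = covs, comparison = cmp, ppt = pptTab,
                 outdir = cfg$outdir))
}
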