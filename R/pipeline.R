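# End-to-end orchestration and the on-disk session container.

# Stage seeds derive from the top-level seed by fixed small offsets so
# every source of randomness is reproducible from one integer.
.stageSeed <- function(seed, stage) {
  offs <- c(simulate = 1L, preprocess = 2L, qc = 3L, features = 4L,
            fit = 5L, report = 6L)
  as.integer(seed) * 10L + offs[[stage]]
}

#' Write a paired session to a container directory
#'
#' Self-describing hierarchical layout: \code{meta.json} holds the
#' schema version, per-group sampling rates, alignment, condition
#' labels, electrode tables and array dimensions; each group
#' (\code{eeg/}, \code{intracranial/}) stores its (electrode, trial,
#' time) array as little-endian float64 in \code{signal.bin}.
#'
#' @param session list with \code{eeg} and \code{wideband}
#'   \linkS4class{TrialSet}s.
#' @param path directory to create/overwrite.
#' @return \code{path}, invisibly.
#' @export
writeContainer <- function(session, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  groups <- list(eeg = session$eeg, intracranial = session$wideband)
  meta <- list(schema_version = "1.0", groups = list())
  for (g in names(groups)) {
    ts <- groups[[g]]
    gdir <- file.path(path, g)
    dir.create(gdir, showWarnings = FALSE)
    con <- file(file.path(gdir, "signal.bin"), "wb")
    writeBin(as.vector(ts@signal), con, size = 8L, endian = "little")
    close(con)
    meta$groups[[g]] <- list(
      dim = dim(ts@signal),
      fs = samplingRate(ts),
      alignment_ms = stimulusOnset(ts),
      condition = trialConditions(ts),
      electrodes = electrodeInfo(ts))
  }
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}

#' Read a paired session from a container directory
#'
#' @param path container directory written by
#'   \code{\link{writeContainer}}.
#' @return List with \code{eeg} and \code{wideband}
#'   \linkS4class{TrialSet}s.
#' @export
readContainer <- function(path) {
  metaPath <- file.path(path, "meta.json")
  if (!file.exists(metaPath)) stop("no meta.json under ", path)
  meta <- jsonlite::read_json(metaPath, simplifyVector = TRUE)
  if (!identical(meta$schema_version, "1.0"))
    stop("unknown container schema version: ", meta$schema_version)
  readGroup <- function(g) {
    gm <- meta$groups[[g]]
    if (is.null(gm)) stop("container group missing: ", g)
    for (fld in c("dim", "fs", "alignment_ms", "condition", "electrodes"))
      if (is.null(gm[[fld]]))
        stop("container metadata missing '", fld, "' for group ", g)
    d <- as.integer(gm$dim)
    con <- file(file.path(path, g, "signal.bin"), "rb")
    v <- readBin(con, "double", n = prod(d), size = 8L,
                 endian = "little")
    close(con)
    if (length(v) != prod(d))
      stop("signal array shape mismatch for group ", g)
    ei <- as.data.frame(gm$electrodes)
    if (!"depth" %in% names(ei)) ei$depth <- NA
    ei$depth[vapply(ei$depth, is.null, logical(1))] <- NA
    ei$depth <- as.character(ei$depth)
    TrialSet(array(v, dim = d), fs = as.numeric(gm$fs),
             alignment = as.numeric(gm$alignment_ms),
             condition = as.numeric(gm$condition), electrodeInfo = ei)
  }
  list(eeg = readGroup("eeg"), wideband = readGroup("intracranial"))
}

# Hash of a configuration for provenance (text serialization -> md5).
.configHash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(utils::capture.output(utils::str(config, digits.d = 15)),
             tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full analysis pipeline
#'
#' Stages, in dependency order: \emph{simulate} (or read a container),
#' \emph{preprocess} (MUAe extraction, EEG band decomposition),
#' \emph{qc} (SSVEP SNR electrode selection; LFP- and EEG-based
#' artifact-trial exclusion), \emph{features} (per-band analytic
#' amplitude/phase over the analysis window), \emph{fit} (nested-CV
#' LASSO per EEG electrode x intracranial electrode x condition), and
#' \emph{report}. Intermediate artifacts are persisted under
#' \code{outdir} (when given) so downstream stages can be rerun without
#' touching upstream files.
#'
#' @param config a \linkS4class{RunConfig}.
#' @param outdir optional directory for stage artifacts and report
#'   tables.
#' @param stages stages to run (prefix of the full list; earlier
#'   results are loaded from \code{outdir} when skipped).
#' @return The report: list with \code{correlations}, \code{snr},
#'   \code{qc}, \code{pac}, \code{metrics}, \code{coefficients} tables
#'   and \code{provenance}.
#' @export
runPipeline <- function(config, outdir = NULL,
                        stages = c("simulate", "preprocess", "qc",
                                   "features", "fit", "report")) {
  validObject(config)
  all_stages <- c("simulate", "preprocess", "qc", "features", "fit",
                  "report")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  persist <- !is.null(outdir)
  if (persist) dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  art <- function(name) file.path(outdir, paste0(name, ".rds"))
  loadArt <- function(name) {
    if (!persist || !file.exists(art(name)))
      stop("missing upstream artifact for requested stage: ", name)
    readRDS(art(name))
  }
  saveArt <- function(obj, name) {
    if (persist) saveRDS(obj, art(name))
    obj
  }

  window <- config@analysisWindowMs
  bands <- config@bands

  # -- simulate / load ------------------------------------------------
  if ("simulate" %in% stages) {
    if (nzchar(config@inputPath)) {
      data <- list(sessions = list(readContainer(config@inputPath)),
                   truth = NULL)
    } else {
      sim <- config@simulation
      sim@seed <- .stageSeed(config@seed, "simulate")
      data <- generateDataset(sim)
    }
    saveArt(data, "simulate")
  } else data <- loadArt("simulate")

  nSess <- length(data$sessions)

  # -- preprocess -----------------------------------------------------
  if ("preprocess" %in% stages) {
    pre <- lapply(seq_len(nSess), function(s) {
      sess <- data$sessions[[s]]
      list(muae = extractMuaeTrials(sess$wideband,
                                    fsOut = samplingRate(sess$eeg)),
           lfp = deriveLfp(sess$wideband,
                           fsOut = samplingRate(sess$eeg)),
           eeg = sess$eeg)
    })
    saveArt(pre, "preprocess")
  } else pre <- loadArt("preprocess")

  # -- qc -------------------------------------------------------------
  if ("qc" %in% stages) {
    qc <- lapply(seq_len(nSess), function(s) {
      eeg <- pre[[s]]$eeg
      snr <- snrTable(eeg, session = s)
      kept <- selectEegElectrodes(snr, config@snrThreshold)[[1L]]
      lfpMask <- flagArtifactTrialsLfp(pre[[s]]$lfp,
                                       zThreshold = config@zThreshold,
                                       magnitudeUv = config@lfpMagnitudeUv)
      eegMask <- flagArtifactTrialsEeg(eeg,
                                       zThreshold = config@zThreshold,
                                       magnitudeUv = config@eegMagnitudeUv,
                                       durationMs = config@eegDurationMs)
      mask <- combineArtifactMasks(lfpMask, eegMask)
      list(snr = snr, retainedEeg = kept, mask = mask)
    })
    saveArt(qc, "qc")
  } else qc <- loadArt("qc")

  # -- features -------------------------------------------------------
  if ("features" %in% stages) {
    feats <- lapply(seq_len(nSess), function(s) {
      eeg <- pre[[s]]$eeg
      muae <- pre[[s]]$muae
      keepTrials <- which(!qc[[s]]$mask$excluded)
      eegKept <- eeg[keepTrials]
      muaeKept <- muae[keepTrials]
      keptNames <- qc[[s]]$retainedEeg
      eIdx <- match(keptNames, electrodeInfo(eeg)$name)
      conds <- sort(unique(trialConditions(eegKept)))
      perE <- lapply(eIdx, function(e) {
        perC <- lapply(conds, function(cc) {
          lapply(stats::setNames(config@granularity,
                                 config@granularity), function(g)
            computeBandFeatures(eegKept, electrode = e, condition = cc,
                                bands = bands, windowMs = window,
                                granularity = g))
        })
        stats::setNames(perC, as.character(conds))
      })
      list(features = stats::setNames(perE, keptNames),
           eegKept = eegKept, muaeKept = muaeKept, conds = conds)
    })
    saveArt(feats, "features")
  } else feats <- loadArt("features")

  # -- fit ------------------------------------------------------------
  if ("fit" %in% stages) {
    fits <- lapply(seq_len(nSess), function(s) {
      fs <- feats[[s]]
      muae <- fs$muaeKept
      icNames <- electrodeInfo(muae)$name
      out <- list()
      for (eegName in names(fs$features)) {
        for (cc in fs$conds) {
          for (g in config@granularity) {
            fe <- fs$features[[eegName]][[as.character(cc)]][[g]]
            for (ic in seq_along(icNames)) {
              y <- .muaeResponse(muae, ic, cc, g, window)
              spec <- config@model
              spec@includeStimulusPhase <- FALSE
              X <- buildDesignMatrix(fe, spec)
              fit <- fitLassoNestedCv(X, y, spec)
              key <- list(session = s, eeg = eegName,
                          electrode = icNames[ic], condition = cc,
                          granularity = g, variant = "base")
              out[[length(out) + 1L]] <- c(key, list(fit = fit))
              if (config@fitStimulusPhaseModel && cc > 0) {
                spec2 <- spec
                spec2@includeStimulusPhase <- TRUE
                X2 <- buildDesignMatrix(fe, spec2, fStim = cc)
                fit2 <- fitLassoNestedCv(X2, y, spec2)
                key$variant <- "stimulus_phase"
                out[[length(out) + 1L]] <- c(key, list(fit = fit2))
              }
            }
          }
        }
      }
      out
    })
    saveArt(fits, "fit")
  } else fits <- loadArt("fit")

  # -- report ---------------------------------------------------------
  metrics <- do.call(rbind, lapply(seq_along(fits), function(s)
    do.call(rbind, lapply(fits[[s]], function(r)
      data.frame(session = r$session, eeg = r$eeg,
                 electrode = r$electrode, condition = r$condition,
                 granularity = r$granularity, variant = r$variant,
                 meanR = r$fit@meanR, adjustedR2 = r$fit@adjustedR2,
                 nRetained = sum(rowSums(
                   r$fit@foldCoefficients != 0) > 0))))))
  if (is.null(metrics))  # every EEG electrode failed the SNR rule
    metrics <- data.frame(session = integer(0), eeg = character(0),
                          electrode = character(0),
                          condition = numeric(0),
                          granularity = character(0),
                          variant = character(0), meanR = numeric(0),
                          adjustedR2 = numeric(0),
                          nRetained = integer(0))

  correlations <- do.call(rbind, lapply(seq_len(nSess), function(s) {
    eeg <- feats[[s]]$eegKept
    muae <- feats[[s]]$muaeKept
    do.call(rbind, lapply(feats[[s]]$conds, function(cc) {
      eAvg <- trialAverage(eeg, cc)
      mAvg <- trialAverage(muae, cc)
      idxE <- .windowIndex(window, stimulusOnset(eeg),
                           samplingRate(eeg), ncol(eAvg))
      idxM <- .windowIndex(window, stimulusOnset(muae),
                           samplingRate(muae), ncol(mAvg))
      grid <- expand.grid(eeg = seq_len(nrow(eAvg)),
                          electrode = seq_len(nrow(mAvg)))
      grid$session <- s; grid$condition <- cc
      grid$r <- vapply(seq_len(nrow(grid)), function(i) {
        x <- filterBand(eAvg[grid$eeg[i], ], samplingRate(eeg))[idxE]
        correlateSeries(x, mAvg[grid$electrode[i], idxM])
      }, numeric(1))
      grid
    }))
  }))

  qcSummary <- do.call(rbind, lapply(seq_len(nSess), function(s)
    data.frame(session = s,
               retainedEeg = length(qc[[s]]$retainedEeg),
               totalTrials = nrow(qc[[s]]$mask),
               excludedTrials = sum(qc[[s]]$mask$excluded))))

  snrAll <- do.call(rbind, lapply(qc, `[[`, "snr"))

  report <- list(
    metrics = metrics,
    correlations = correlations,
    snr = snrAll,
    qc = qcSummary,
    fits = fits,
    truth = data$truth,
    provenance = list(configHash = .configHash(config),
                      seed = config@seed,
                      package = as.character(
                        utils::packageVersion("eegMUAe"))))
  if (persist) {
    utils::write.csv(metrics, file.path(outdir, "metrics.csv"),
                     row.names = FALSE)
    utils::write.csv(snrAll, file.path(outdir, "snr.csv"),
                     row.names = FALSE)
    utils::write.csv(qcSummary, file.path(outdir, "qc_summary.csv"),
                     row.names = FALSE)
    saveRDS(report, art("report"))
  }
  report
}

# Held-out MUAe response aligned with the feature rows.
.muaeResponse <- function(muae, electrode, condition, granularity,
                          windowMs) {
  idx <- .windowIndex(windowMs, stimulusOnset(muae),
                      samplingRate(muae), nTimepoints(muae))
  sel <- which(trialConditions(muae) == condition)
  if (granularity == "trial-averaged") {
    avg <- trialAverage(muae, condition)
    avg[electrode, idx]
  } else {
    as.vector(t(muae@signal[electrode, sel, idx]))
  }
}
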