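#' Pipeline configuration
#'
#' Bundles stage toggles and the per-stage configurations for
#' \code{\link{runPipeline}}.
#'
#' @param cohort a \code{\link{cohortConfig}}.
#' @param thresholds a \code{\link{qcThresholds}}.
#' @param segmentation \code{"baseline"} (classical segmenter) or
#'   \code{"truth"} (ground-truth mask passthrough).
#' @param gwas list: \code{enabled}, \code{nVariants},
#'   \code{ldBlockSize}, \code{withinBlockR}, \code{pThreshold}.
#' @param mr list: \code{enabled}, \code{simConfig} (an
#'   \code{\link{mrSimConfig}}; defaults to a 60-instrument simulation with
#'   a causal effect of log 1.5).
#' @param seed master seed for stages not covered by the cohort seed.
#' @return list of class \code{"pipelineConfig"}.
#' @export
pipelineConfig <- function(cohort = cohortConfig(20, nFrames = 10),
                           thresholds = qcThresholds(),
                           segmentation = c("baseline", "truth"),
                           gwas = list(enabled = TRUE, nVariants = 200L,
                                       ldBlockSize = 10L, withinBlockR = 0.2,
                                       pThreshold = 1e-5),
                           mr = list(enabled = TRUE, simConfig = NULL),
                           seed = 1L) {
  segmentation <- match.arg(segmentation)
  if (is.null(mr$simConfig))
    mr$simConfig <- mrSimConfig(60, theta = log(1.5), seed = seed)
  structure(list(cohort = cohort, thresholds = thresholds,
                 segmentation = segmentation, gwas = gwas, mr = mr,
                 seed = as.integer(seed)),
            class = "pipelineConfig")
}

#' Run the full pipeline: simulate, segment, extract, QC, phenotype,
#' associate, clump, MR
#'
#' Stages run in order; a stage failure is recorded in \code{errors} and
#' downstream stages are skipped with a reason. The flow report counts, per
#' trait, the participants each exclusion reason removed and the number
#' retained (included + excluded-distinct = cohort size). Results are
#' deterministic for a fixed configuration.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @param outputDir optional directory; when given, tables are written
#'   tab-delimited and the flow report as JSON.
#' @return list: \code{covariates}, \code{features} (per participant),
#'   \code{qcReports}, \code{flowReport}, \code{phenotypes},
#'   \code{gwas} (association tables, leads and loci per trait),
#'   \code{lambda}, \code{mr} (analysis + report), \code{errors},
#'   \code{skipped}.
#' @export
runPipeline <- function(config, outputDir = NULL) {
  stopifnot(inherits(config, "pipelineConfig"))
  errors <- list(); skipped <- character()
  out <- list()

  cohort <- generateCohort(config$cohort)
  out$covariates <- cohort$covariates

  # segment + extract + QC + phenotypes per participant
  feats <- list(); reports <- list(); phen <- list()
  for (id in names(cohort$studies)) {
    st <- cohort$studies[[id]]
    masks <- if (config$segmentation == "truth")
      groundTruth(st)$masks else NULL
    fe <- extractStudyFeatures(st, masks = masks,
                               cropSize = config$thresholds$cropSize)
    rep <- participantQC(fe, covariates(st), config$thresholds)
    cv <- covariates(st)
    bsa <- computeBSA(cv$height, cv$weight)
    retained <- fe[rep$retainedFrames, , drop = FALSE]
    ph <- deriveAAoPhenotypes(retained, cv$sbp, cv$dbp, bsa)
    ph$id <- id
    # QC inclusion flags mask the per-trait values
    if (!rep$includedFor[["AAomax"]]) ph$aaoMaxCm2 <- ph$aaoMaxIdx <- NA_real_
    if (!rep$includedFor[["AAomin"]]) ph$aaoMinCm2 <- ph$aaoMinIdx <- NA_real_
    if (!rep$includedFor[["AAodist"]]) ph$distensibility <- NA_real_
    feats[[id]] <- fe; reports[[id]] <- rep; phen[[id]] <- ph
  }
  out$features <- feats
  out$qcReports <- reports
  excl <- cohortExclusionTable(reports)
  out$flowReport <- list(nCohort = excl$nCohort,
                         included = as.list(excl$included),
                         exclusions = excl$counts)
  out$phenotypes <- do.call(rbind, phen)
  rownames(out$phenotypes) <- NULL

  # association scan + clumping + loci
  if (isTRUE(config$gwas$enabled)) {
    tryCatch({
      g <- generateGenotypes(n = config$cohort$nParticipants,
                             m = config$gwas$nVariants,
                             ldBlockSize = config$gwas$ldBlockSize,
                             withinBlockR = config$gwas$withinBlockR,
                             seed = config$seed + 1L)
      r2 <- ldMatrix(g$dosages)
      covM <- cbind(age = out$covariates$age,
                    sex = as.numeric(out$covariates$sex == "M"))
      traits <- c(AAomax = "aaoMaxIdx", AAomin = "aaoMinIdx",
                  AAodist = "distensibility")
      gw <- list()
      for (tr in names(traits)) {
        y <- out$phenotypes[[traits[[tr]]]]
        okN <- sum(!is.na(y))
        if (okN < ncol(covM) + 3L || length(unique(y[!is.na(y)])) < 3L) {
          skipped <- c(skipped, paste0("gwas_", tr, ": too few phenotyped participants"))
          next
        }
        yInt <- inverseNormalTransform(y)
        assoc <- associateAll(g$dosages, yInt, covM, variants = g$variants)
        leads <- greedyClump(assoc, r2, pThreshold = config$gwas$pThreshold)
        gw[[tr]] <- list(associations = assoc, leads = leads,
                         lambda = genomicLambda(assoc$p))
      }
      if (length(gw)) {
        out$gwas <- gw
        out$loci <- defineLoci(lapply(gw, `[[`, "leads"))
        out$lambda <- vapply(gw, `[[`, numeric(1), "lambda")
      }
    }, error = function(e) errors[["gwas"]] <<- conditionMessage(e))
  }

  # two-sample MR on simulated summary statistics
  if (isTRUE(config$mr$enabled)) {
    if (!is.null(errors[["gwas"]])) {
      skipped <- c(skipped, "mr: upstream gwas stage failed")
    } else tryCatch({
      ss <- generateMRSummaryStats(config$mr$simConfig)
      hset <- harmonizeInstruments(filterVariants(ss$exposure),
                                   filterVariants(ss$outcome),
                                   exposureName = "AAo trait",
                                   outcomeName = "outcome")
      an <- mrAnalyze(hset, seed = config$seed)
      out$mr <- list(analysis = an,
                     report = mrReport(list("AAo trait|outcome" = an)))
    }, error = function(e) errors[["mr"]] <<- conditionMessage(e))
  }

  out$errors <- errors
  out$skipped <- skipped

  if (!is.null(outputDir)) {
    dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(out$covariates, file.path(outputDir, "covariates.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(out$phenotypes, file.path(outputDir, "phenotypes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    allFeat <- do.call(rbind, lapply(names(feats), function(id)
      cbind(participant = id, feats[[id]])))
    utils::write.table(allFeat, file.path(outputDir, "frame_features.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(out$flowReport, file.path(outputDir, "flow_report.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    if (!is.null(excl$counts))
      utils::write.table(excl$counts, file.path(outputDir, "exclusions.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(out$mr))
      utils::write.table(out$mr$report, file.path(outputDir, "mr_report.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}
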