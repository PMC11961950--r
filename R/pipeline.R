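#' Pipeline configuration
#'
#' Assembles all stage configurations for \code{\link{runPipeline}}.  A
#' single master seed deterministically derives every stage's sub-seed
#' (cohort, split, network, GA), so identical configurations reproduce all
#' outputs bit-identically.  A YAML file with any subset of the fields
#' \code{cohort}, \code{preprocess}, \code{welch}, \code{bpnn}, \code{ga},
#' \code{split}, \code{trainFrac}, \code{models}, \code{seed} overrides the
#' defaults.
#'
#' @param file Optional YAML configuration file.
#' @param seed Master seed (overrides the file's).
#' @param ... Named overrides: \code{cohort}, \code{preprocess},
#'   \code{welch}, \code{bpnn}, \code{ga} take the corresponding
#'   constructor's arguments as lists; \code{split}, \code{trainFrac},
#'   \code{models} are passed through.
#' @return List of class \code{"PipelineConfig"}.
#' @export
pipelineConfig <- function(file = NULL, seed = 1L, ...) {
  over <- list(...)
  if (!is.null(file)) {
    yml <- yaml::read_yaml(file)
    over <- utils::modifyList(yml, over)
    if (!is.null(yml$seed) && missing(seed)) seed <- yml$seed
  }
  build <- function(ctor, args) do.call(ctor, as.list(args %||% list()))
  cfg <- list(
    seed = as.integer(seed),
    cohort = build(cohortSpec, utils::modifyList(
      list(seed = deriveSeed(seed, 10)), as.list(over$cohort %||% list()))),
    preprocess = build(preprocessConfig, over$preprocess),
    welch = build(welchConfig, over$welch),
    bpnn = build(bpnnConfig, utils::modifyList(
      list(seed = deriveSeed(seed, 20)), as.list(over$bpnn %||% list()))),
    ga = build(gaConfig, utils::modifyList(
      list(seed = deriveSeed(seed, 30)), as.list(over$ga %||% list()))),
    split = over$split %||% "holdout",
    trainFrac = over$trainFrac %||% 0.7,
    models = over$models %||% .MODEL_ROSTER)
  structure(cfg, class = "PipelineConfig")
}

#' Run the full analysis pipeline
#'
#' Executes every stage in order -- simulate (baseline + post-intervention
#' recordings), preprocess, extract region features, compare the model
#' roster across regions, compute the per-state asymmetry table and its
#' Spearman correlation with stress level, and score the music
#' interventions with the best-region model -- writing every intermediate
#' artifact (manifest, features.tsv, model comparison, asymmetry tables,
#' regulation scores) plus a run-summary JSON to \code{outputDir}.
#' Recordings are generated and preprocessed one at a time, so memory use
#' is bounded by a single recording.
#'
#' @param cfg A \code{\link{pipelineConfig}}.
#' @param outputDir Output directory for artifacts (created if needed);
#'   \code{NULL} skips all file output.
#' @param interventions Generate and score post-intervention recordings?
#' @param verbose Log stage progress to stderr?
#' @return List of class \code{"PipelineResult"}: \code{features},
#'   \code{comparison}, \code{asymmetry}, \code{regulation} (or NULL),
#'   \code{summary}.
#' @export
runPipeline <- function(cfg = pipelineConfig(), outputDir = NULL,
                        interventions = TRUE, verbose = interactive()) {
  t0 <- Sys.time()
  log <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      .stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }

  spec <- cfg$cohort
  plan <- stage("simulate", cohortPlan(spec, interventions))
  log("simulate: %d recordings planned", nrow(plan))

  # streaming generate -> preprocess -> features/AI, one recording at a time
  regions <- regionMap(spec@channels)
  featRows <- vector("list", nrow(plan))
  aiRows <- numeric(nrow(plan))
  rejected <- integer(nrow(plan))
  for (i in seq_len(nrow(plan))) {
    rec <- stage("simulate", generateRecording(
      spec, plan$label[i], plan$condition[i], subjectId = plan$subject_id[i],
      seed = plan$seed[i], intensity = plan$intensity[i]))
    es <- stage("preprocess", preprocessRecording(rec, cfg$preprocess))
    rejected[i] <- rejectedCount(es)
    featRows[[i]] <- stage("features", extractRegionFeatures(es, regions, cfg$welch))
    # asymmetry on the filtered, re-referenced recording
    filt <- rereference(bandpassFilter(rec, cfg$preprocess), cfg$preprocess)
    aiRows[i] <- stage("asymmetry", asymmetryIndex(filt, cfg = cfg$welch))
  }
  features <- do.call(rbind, featRows)
  log("features: %d rows (%d epochs rejected)", nrow(features), sum(rejected))

  comparison <- stage("classify", compareModelsByRegion(
    features, models = cfg$models, split = cfg$split,
    trainFrac = cfg$trainFrac, seed = deriveSeed(cfg$seed, 40),
    bpCfg = cfg$bpnn, gaCfg = cfg$ga))
  log("classify: best %s on %s (accuracy %.3f)",
      comparison$best$model, comparison$best$region, comparison$best$accuracy)

  # per-state asymmetry table + Spearman correlation, from the stored AI
  base <- plan$condition == "baseline"
  aiTab <- do.call(rbind, lapply(.STATE_NAMES, function(s) {
    v <- aiRows[base & plan$label == s]
    if (!length(v)) return(NULL)
    data.frame(state = s, level = stressLevel(s), n = length(v),
               mean_ai = mean(v), sd_ai = stats::sd(v), stringsAsFactors = FALSE)
  }))
  sr <- spearmanRho(aiTab$level, aiTab$mean_ai)
  asym <- structure(list(table = aiTab, rho = sr$rho, p = sr$p,
                         pMethod = sr$method,
                         perRecording = data.frame(
                           subject_id = plan$subject_id, state = plan$label,
                           condition = plan$condition, ai = aiRows,
                           stringsAsFactors = FALSE)),
                    class = "AsymmetryResult")
  log("asymmetry: rho = %.3f (p = %.4g, %s)", sr$rho, sr$p, sr$method)

  regulation <- NULL
  if (interventions && any(!base)) {
    regulation <- stage("regulation", {
      bestRegion <- comparison$best$region
      ftBase <- features[features$condition == "baseline" &
                           features$region == bestRegion, ]
      model <- trainGaBpnn(as.matrix(ftBase[, .FEATURE_NAMES]), ftBase$label,
                           cfg$bpnn, cfg$ga)
      # predicted levels straight from the feature table (identical to the
      # per-recording extraction above)
      predLv <- function(rows) .predictLevel(model, as.matrix(rows[, .FEATURE_NAMES]))
      ftAll <- features[features$region == bestRegion, ]
      lvl <- stats::setNames(predLv(ftAll), paste(ftAll$subject_id, ftAll$condition))
      post <- plan[!base, ]
      preL <- unname(lvl[paste(post$subject_id, "baseline")])
      postL <- unname(lvl[paste(post$subject_id, post$condition)])
      outcomes <- data.frame(
        subject_id = post$subject_id, music_type = post$condition,
        pre_state = post$label,
        pre_level_pred = preL, objective_score = postL,
        percent_reduction = 100 * (preL - postL) / preL,
        post_ai = aiRows[!base], stringsAsFactors = FALSE)
      cells <- unique(outcomes[, c("music_type", "pre_state")])
      summ <- do.call(rbind, lapply(seq_len(nrow(cells)), function(j) {
        sel <- outcomes$music_type == cells$music_type[j] &
          outcomes$pre_state == cells$pre_state[j]
        data.frame(music_type = cells$music_type[j],
                   pre_state = cells$pre_state[j], n = sum(sel),
                   mean_pre_level = mean(outcomes$pre_level_pred[sel]),
                   mean_post_level = mean(outcomes$objective_score[sel]),
                   percent_reduction = mean(outcomes$percent_reduction[sel]),
                   mean_post_ai = mean(outcomes$post_ai[sel]),
                   stringsAsFactors = FALSE)
      }))
      ranking <- lapply(split(summ, summ$pre_state), function(d)
        d$music_type[order(-d$percent_reduction, d$mean_post_level)])
      structure(list(outcomes = outcomes, summary = summ, ranking = ranking,
                     model = model),
                class = "RegulationResult")
    })
    log("regulation: %d post-intervention recordings scored", sum(!base))
  }

  summary <- list(
    seed = cfg$seed,
    stageSeeds = list(cohort = spec@seed, split = deriveSeed(cfg$seed, 40),
                      bpnn = cfg$bpnn$seed, ga = cfg$ga$seed),
    nRecordings = nrow(plan), nRejectedEpochs = sum(rejected),
    best = comparison$best,
    asymmetry = list(rho = sr$rho, p = sr$p, method = sr$method),
    elapsedSec = as.numeric(difftime(Sys.time(), t0, units = "secs")))

  if (!is.null(outputDir)) {
    dir.create(outputDir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(plan, file.path(outputDir, "manifest.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    writeFeatureTable(features, file.path(outputDir, "features.tsv"))
    utils::write.table(comparison$summary,
                       file.path(outputDir, "model_comparison.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    bestRep <- comparison$reports[[paste(comparison$best$model,
                                         comparison$best$region, sep = ".")]]
    utils::write.csv(confusionMatrix(bestRep),
                     file.path(outputDir, "best_confusion.csv"))
    utils::write.table(aiTab, file.path(outputDir, "asymmetry_by_state.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    jsonlite::write_json(list(rho = sr$rho, p = sr$p, method = sr$method),
                         file.path(outputDir, "asymmetry_correlation.json"),
                         auto_unbox = TRUE, digits = NA)
    if (!is.null(regulation)) {
      utils::write.table(regulation$summary,
                         file.path(outputDir, "regulation.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
    jsonlite::write_json(summary, file.path(outputDir, "run_summary.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }

  structure(list(features = features, comparison = comparison,
                 asymmetry = asym, regulation = regulation, plan = plan,
                 summary = summary),
            class = "PipelineResult")
}

#' @export
print.PipelineResult <- function(x, ...) {
  cat(sprintf("Pipeline run (seed %d): %d recordings, best %s on %s (acc %.3f), AI rho %.3f\n",
              x$summary$seed, x$summary$nRecordings, x$summary$best$model,
              x$summary$best$region, x$summary$best$accuracy,
              x$summary$asymmetry$rho))
  invisible(x)
}
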