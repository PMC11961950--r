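#' Frontal-pole alpha asymmetry index
#'
#' The EEG asymmetry index by the power-subtraction method: alpha-band
#' power (a squared-amplitude quantity, via Welch PSD and trapezoidal band
#' integration) of Fp1 minus that of Fp2.  Positive values indicate
#' left-dominant alpha; increasingly negative values accompany rising
#' stress.  A log-ratio variant (log P(Fp1) - log P(Fp2)) is available.
#'
#' @param rec An \linkS4class{EEGRecording} containing Fp1 and Fp2.
#' @param alphaBand Alpha band in Hz (default 8-13).
#' @param cfg A \code{\link{welchConfig}}.
#' @param method "subtraction" (default) or "log_ratio".
#' @return Scalar asymmetry value (uV^2 for "subtraction").
#' @export
asymmetryIndex <- function(rec, alphaBand = c(8, 13), cfg = welchConfig(),
                           method = c("subtraction", "log_ratio")) {
  stopifnot(is(rec, "EEGRecording"))
  method <- match.arg(method)
  lc <- tolower(channelNames(rec))
  i1 <- match("fp1", lc); i2 <- match("fp2", lc)
  if (is.na(i1) || is.na(i2)) .stopf("recording lacks Fp1/Fp2 channels")
  fs <- samplingRate(rec)
  p1 <- {w <- welchPsd(eegData(rec)[i1, ], fs, cfg); bandPower(w$freq, w$psd, alphaBand)}
  p2 <- {w <- welchPsd(eegData(rec)[i2, ], fs, cfg); bandPower(w$freq, w$psd, alphaBand)}
  if (method == "log_ratio") log(p1) - log(p2) else p1 - p2
}

#' Spearman rank correlation with exact permutation p-value
#'
#' Spearman's rho between an ordinal level sequence and a value sequence:
#' both are converted to mid-ranks (ties averaged) and the Pearson
#' correlation of the ranks is returned, which reduces to the classical
#' rank-difference formula when there are no ties.  For n <= 8 the
#' two-tailed p-value is exact, by enumeration of all n! rank
#' permutations of one margin; for larger n the t approximation with
#' n - 2 degrees of freedom is used.
#'
#' @param levels Ordinal sequence (length >= 3).
#' @param values Numeric sequence, same length.
#' @return List: \code{rho}, \code{p} (two-tailed), \code{method} ("exact"
#'   or "t-approximation"), \code{n}.  Constant input yields \code{rho =
#'   NA} (undefined correlation).
#' @examples
#' spearmanRho(1:5, c(0.1340, -0.2367, -1.9866, -2.9117, -5.0518))
#' @export
spearmanRho <- function(levels, values) {
  n <- length(levels)
  if (length(values) != n) .stopf("levels and values must align")
  if (n < 3) .stopf("need at least 3 observations")
  if (any(!is.finite(levels)) || any(!is.finite(values)))
    .stopf("non-finite input")
  rl <- rank(levels); rv <- rank(values)
  if (stats::sd(rl) == 0 || stats::sd(rv) == 0)
    return(list(rho = NA_real_, p = NA_real_, method = "undefined", n = n))
  rho <- .rankRho(rl, rv)
  if (n <= 8) {
    perms <- .permutations(n)
    # rho for every permutation of the value ranks against fixed level ranks
    rhos <- apply(perms, 1, function(p) .rankRho(rl, rv[p]))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
    method <- "exact"
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    method <- "t-approximation"
  }
  list(rho = rho, p = p, method = method, n = n)
}

# rho from mid-ranks: the classical rank-difference formula when both
# margins are tie-free (exact, gives +-1 without rounding), the Pearson
# correlation of the ranks otherwise
.rankRho <- function(rl, rv) {
  n <- length(rl)
  if (length(unique(rl)) == n && length(unique(rv)) == n)
    1 - 6 * sum((rl - rv)^2) / (n * (n^2 - 1))
  else
    stats::cor(rl, rv)
}

# all permutations of 1..n, one per row (n! rows); n <= 8 keeps this small
.permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, ifelse(sub >= k, sub + 1L, sub))
  }))
}

#' Per-state asymmetry and its correlation with stress level
#'
#' Computes the asymmetry index of every recording, averages it per stress
#' state, and correlates the state means with the ordinal stress levels via
#' \code{\link{spearmanRho}}.
#'
#' @param recs List of \linkS4class{EEGRecording} objects (baseline
#'   recordings; other conditions are ignored).
#' @param alphaBand,cfg,method Passed to \code{\link{asymmetryIndex}}.
#' @return List of class \code{"AsymmetryResult"}: \code{table} (data.frame
#'   state, level, n, mean_ai, sd_ai), \code{rho}, \code{p},
#'   \code{pMethod}, and \code{perRecording}.
#' @export
asymmetryByState <- function(recs, alphaBand = c(8, 13), cfg = welchConfig(),
                             method = "subtraction") {
  stopifnot(length(recs) > 0)
  keep <- vapply(recs, function(r) condition(r) %in% c("baseline", "none"), TRUE)
  recs <- recs[keep]
  if (!length(recs)) .stopf("no baseline recordings supplied")
  ai <- vapply(recs, asymmetryIndex, numeric(1),
               alphaBand = alphaBand, cfg = cfg, method = method)
  lab <- vapply(recs, stressLabel, "")
  states <- .STATE_NAMES[.STATE_NAMES %in% lab]
  tab <- do.call(rbind, lapply(states, function(s) {
    v <- ai[lab == s]
    data.frame(state = s, level = stressLevel(s), n = length(v),
               mean_ai = mean(v), sd_ai = stats::sd(v),
               stringsAsFactors = FALSE)
  }))
  rownames(tab) <- NULL
  sr <- if (nrow(tab) >= 3) spearmanRho(tab$level, tab$mean_ai)
        else list(rho = NA_real_, p = NA_real_, method = "undefined", n = nrow(tab))
  structure(list(table = tab, rho = sr$rho, p = sr$p, pMethod = sr$method,
                 perRecording = data.frame(subject_id = vapply(recs, subjectId, ""),
                                           state = lab, ai = ai,
                                           stringsAsFactors = FALSE)),
            class = "AsymmetryResult")
}

#' @export
print.AsymmetryResult <- function(x, ...) {
  cat("Per-state Fp1-Fp2 alpha asymmetry:\n")
  print(x$table, row.names = FALSE)
  cat(sprintf("Spearman rho(level, mean AI) = %.4f, two-tailed p = %.4g (%s)\n",
              x$rho, x$p, x$pMethod))
  invisible(x)
}

#' Score music-intervention effects
#'
#' Feeds post-intervention feature vectors into a pre-trained stress
#' classifier to obtain objective post-regulation stress scores, computes
#' post-intervention asymmetry, and summarizes the stress reduction per
#' music type and pre-intervention state: each subject's
#' \code{percent_reduction} is 100 x (predicted pre level - predicted post
#' level) / predicted pre level, paired within subject; the cell summary
#' averages the subjects' reductions.  Music types are ranked per state by
#' that mean reduction.  For network classifiers the predicted level is the
#' probability-weighted expected level (continuous in [1,5]), which avoids
#' the discretization noise of argmax class labels; for other models the
#' predicted class's level is used.
#'
#' @param pre,post Lists of \linkS4class{EEGRecording}, paired by subject
#'   id (every post subject must appear in pre).
#' @param model A trained classifier as returned by \code{\link{trainBpnn}}
#'   / \code{\link{trainGaBpnn}}, or any object with a \code{predict}
#'   method returning state names.
#' @param regions Region map; the model is fed the region named by
#'   \code{modelRegion}.
#' @param modelRegion Region whose features the model expects (default Fp).
#' @param cfg Welch configuration for feature extraction.
#' @param preCfg Preprocessing applied before feature extraction; must
#'   match what the classifier was trained on (default: the standard
#'   chain).  \code{NULL} extracts features from the raw recordings.
#' @param subjective Optional named vector of subjective post ratings by
#'   subject id.
#' @return List of class \code{"RegulationResult"}: \code{outcomes} (one
#'   row per post recording), \code{summary} (per music x state cell),
#'   \code{ranking} (music types ranked per state).
#' @export
scoreRegulation <- function(pre, post, model, regions = NULL,
                            modelRegion = "Fp", cfg = welchConfig(),
                            preCfg = preprocessConfig(), subjective = NULL) {
  preIds <- vapply(pre, subjectId, "")
  postIds <- vapply(post, subjectId, "")
  if (!all(postIds %in% preIds))
    .stopf("unpaired post-intervention subject(s): %s",
           paste(setdiff(postIds, preIds), collapse = ", "))
  featOf <- function(rec) {
    es <- if (is.null(preCfg)) segmentEpochs(rec, preprocessConfig(
      epochLength = ncol(eegData(rec)) / samplingRate(rec)))
      else preprocessRecording(rec, preCfg)
    rg <- if (is.null(regions)) regionMap(channelNames(rec)) else regions
    ft <- extractRegionFeatures(es, rg[modelRegion], cfg)
    as.matrix(ft[, .FEATURE_NAMES])
  }
  predLevel <- function(recs) {
    X <- do.call(rbind, lapply(recs, featOf))
    .predictLevel(model, X)
  }
  preLv <- predLevel(pre)
  names(preLv) <- preIds
  postLv <- predLevel(post)
  postAi <- vapply(post, asymmetryIndex, numeric(1), cfg = cfg)
  outcomes <- data.frame(
    subject_id = postIds,
    music_type = vapply(post, condition, ""),
    pre_state = vapply(post, stressLabel, ""),
    pre_level_pred = preLv[postIds],
    objective_score = postLv,
    percent_reduction = 100 * (preLv[postIds] - postLv) / preLv[postIds],
    post_ai = postAi,
    subjective_score = if (is.null(subjective)) NA_real_
                       else unname(subjective[postIds]),
    stringsAsFactors = FALSE, row.names = NULL)
  cells <- unique(outcomes[, c("music_type", "pre_state")])
  summary <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    sel <- outcomes$music_type == cells$music_type[i] &
      outcomes$pre_state == cells$pre_state[i]
    data.frame(music_type = cells$music_type[i], pre_state = cells$pre_state[i],
               n = sum(sel),
               mean_pre_level = mean(outcomes$pre_level_pred[sel]),
               mean_post_level = mean(outcomes$objective_score[sel]),
               percent_reduction = mean(outcomes$percent_reduction[sel]),
               mean_post_ai = mean(outcomes$post_ai[sel]),
               stringsAsFactors = FALSE)
  }))
  ranking <- lapply(split(summary, summary$pre_state), function(d)
    d$music_type[order(-d$percent_reduction, d$mean_post_level)])
  structure(list(outcomes = outcomes, summary = summary, ranking = ranking),
            class = "RegulationResult")
}

#' @export
print.RegulationResult <- function(x, ...) {
  cat("Music-intervention regulation summary:\n")
  print(x$summary, row.names = FALSE)
  for (s in names(x$ranking))
    cat(sprintf("  %s: %s\n", s, paste(x$ranking[[s]], collapse = " > ")))
  invisible(x)
}
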