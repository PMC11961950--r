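#' Construct a synthetic-cohort specification
#'
#' Builds a \linkS4class{CohortSpec} describing a labelled synthetic EEG
#' cohort.  The defaults emulate the study conditions the analysis assumes:
#' 120 baseline recordings (60 calm, 12 almost-no-stress, 16 each
#' slight/moderate/severe), 30 s per recording at 500 Hz over the 31-channel
#' 10-10 montage, band-structured oscillatory EEG whose Fp1-Fp2 alpha-power
#' difference is calibrated per state to reference asymmetry magnitudes
#' (0.1340, -0.2367, -1.9866, -2.9117, -5.0518 uV^2 for calm through
#' severe), plus optional post-intervention recordings whose stress
#' intensity -- and with it the asymmetry -- is pulled back toward calm by a
#' per-music-type fraction (gentle > joyful > exhilarating ~ sorrowful).
#'
#' @param nPerState Named integer vector of recordings per stress state.
#' @param duration Recording length in seconds.
#' @param fs Sampling rate in Hz.
#' @param channels Ordered channel names; must contain Fp1 and Fp2.
#' @param seed Integer master seed for the cohort.
#' @param asymmetryTargets Named numeric, target Fp1-Fp2 alpha-power
#'   difference (uV^2) per state, strictly decreasing with stress level.
#' @param bandPowers Baseline oscillation power (uV^2) per EEG band.
#' @param noiseSd Total additive noise SD in uV.
#' @param noiseCommon Fraction of the noise variance shared scalp-wide.
#' @param artifactRate Blink artifacts per minute on frontal channels
#'   (default 0: the baseline cohort is artifact-free; blink injection is a
#'   knob used to exercise the rejection stage).
#' @param regionalEffect Fraction of the stress band-modulation applied
#'   outside the frontal pole.
#' @param alphaSuppression,betaEnhancement Relative alpha decrease / beta
#'   increase at full stress (level 5) on frontal-pole channels.
#' @param subjectSd Log-scale SD of the per-subject global power factor
#'   (a subject trait, constant across a subject's recordings).
#' @param interventionPull Named fractions in [0,1] per music type.
#' @return A validated \linkS4class{CohortSpec}.
#' @examples
#' spec <- cohortSpec(nPerState = c(calm = 2, almost_no_stress = 2,
#'                                  slight = 2, moderate = 2, severe = 2),
#'                    duration = 5)
#' spec
#' @export
cohortSpec <- function(nPerState = c(calm = 60L, almost_no_stress = 12L,
                                     slight = 16L, moderate = 16L, severe = 16L),
                       duration = 30, fs = 500, channels = .CHANNELS_31,
                       seed = 1L,
                       asymmetryTargets = c(calm = 0.1340,
                                            almost_no_stress = -0.2367,
                                            slight = -1.9866,
                                            moderate = -2.9117,
                                            severe = -5.0518),
                       bandPowers = c(delta = 20, theta = 10, alpha = 5, beta = 4),
                       noiseSd = 2, noiseCommon = 0.95, artifactRate = 0,
                       regionalEffect = 0.25, alphaSuppression = 0.3,
                       betaEnhancement = 2.0, subjectSd = 0.05,
                       interventionPull = c(joyful = 0.65, sorrowful = 0.30,
                                            exhilarating = 0.35, gentle = 0.80)) {
  new("CohortSpec",
      nPerState = as.integer(nPerState[.STATE_NAMES]) |>
        stats::setNames(.STATE_NAMES),
      duration = duration, fs = fs, channels = channels,
      seed = as.integer(seed),
      asymmetryTargets = asymmetryTargets, bandPowers = bandPowers,
      noiseSd = noiseSd, noiseCommon = noiseCommon,
      artifactRate = artifactRate, regionalEffect = regionalEffect,
      alphaSuppression = alphaSuppression, betaEnhancement = betaEnhancement,
      subjectSd = subjectSd, interventionPull = interventionPull)
}

# One band-limited oscillation: a sinusoid whose instantaneous frequency is
# slowly modulated inside its band.  Consumes the current RNG stream.
.fmSine <- function(n, fs, f0, halfBw, amp, jitFrac = 0.15) {
  fm <- stats::runif(1, 0.05, 0.3)                 # modulation rate, Hz
  a <- stats::runif(1, 0, jitFrac) * halfBw        # modulation depth, Hz
  ph <- stats::runif(1, 0, 2 * pi)
  t <- (seq_len(n) - 1) / fs
  f <- f0 + a * sin(2 * pi * fm * t + stats::runif(1, 0, 2 * pi))
  amp * sin(2 * pi * cumsum(f) / fs + ph)
}

# band synthesis parameters: center frequency and jitter half-width
.BAND_CENTERS <- c(delta = 2.5, theta = 6, alpha = 10.5, beta = 20)
.BAND_HALFBW <- c(delta = 1.5, theta = 2, alpha = 2.5, beta = 8)

# Linear interpolation of the per-state asymmetry target at a (possibly
# fractional) stress intensity, used for post-intervention recordings.
.targetAt <- function(spec, intensity) {
  stats::approx(x = 1:5, y = spec@asymmetryTargets[.STATE_NAMES],
                xout = intensity, rule = 2)$y
}

.fpChannels <- function(channels) {
  channels[tolower(channels) %in% c("fp1", "fp2", "af3", "af4")]
}

# stable small hash of a subject id, for per-subject random traits
.stringHash <- function(id) {
  h <- 0
  for (k in utf8ToInt(id)) h <- (h * 31 + k) %% 1048573
  h
}

# the per-recording global power factor is a subject trait: identical for
# every recording of one subject within a cohort (pre- and
# post-intervention), so paired comparisons cancel it
.subjectFactor <- function(spec, subjectId) {
  u <- withSeed(deriveSeed(spec@seed, 9, .stringHash(subjectId)),
                stats::runif(1))
  exp(stats::qnorm(u) * spec@subjectSd)
}

#' Generate one synthetic EEG recording
#'
#' Synthesizes a multi-channel recording as a sum of band-limited
#' oscillations (delta 1-4, theta 4-8, alpha 8-13, beta 13-30 Hz) plus
#' Gaussian broadband noise (largely shared across channels, emulating the
#' strong inter-electrode correlation of scalp EEG) and optional blink
#' transients on frontal channels.  The Fp1/Fp2 alpha amplitudes are set so
#' the expected alpha-power difference equals the spec's target for the
#' recording's stress state; under a music condition the effective stress
#' intensity is pulled toward calm by the spec's per-music-type fraction.
#' Stress also modulates alpha (down) and beta (up) power, at full strength
#' on frontal-pole channels and at \code{regionalEffect} strength elsewhere.
#'
#' @param spec A \linkS4class{CohortSpec}.
#' @param label Stress-state name.
#' @param condition Intervention condition (default "baseline").
#' @param subjectId Identifier stored in the recording.
#' @param seed Integer seed for this recording's random draws (defaults to
#'   the spec's master seed).
#' @param intensity Optional fractional stress intensity in [1,5] overriding
#'   the label/condition-derived value (used for post-intervention
#'   recordings).
#' @return An \linkS4class{EEGRecording}.
#' @examples
#' spec <- cohortSpec(duration = 2, channels = c("Fp1", "Fp2"))
#' rec <- generateRecording(spec, "calm", seed = 7)
#' rec
#' @export
generateRecording <- function(spec, label, condition = "baseline",
                              subjectId = "S000", seed = spec@seed,
                              intensity = NULL) {
  validObject(spec)
  if (!label %in% .STATE_NAMES) .stopf("unknown stress state: %s", label)
  if (!condition %in% .CONDITIONS) .stopf("unknown condition: %s", condition)
  lv <- stressLevel(label)
  if (is.null(intensity)) {
    intensity <- if (condition %in% .MUSIC_TYPES)
      lv - spec@interventionPull[[condition]] * (lv - 1) else lv
  }
  if (!is.finite(intensity) || intensity < 1 || intensity > 5)
    .stopf("stress intensity must lie in [1,5]")

  n <- round(spec@duration * spec@fs)
  fs <- spec@fs
  chans <- spec@channels
  nch <- length(chans)
  lc <- tolower(chans)
  iFp1 <- match("fp1", lc); iFp2 <- match("fp2", lc)
  fpSet <- tolower(.fpChannels(chans))
  g <- (intensity - 1) / 4
  d <- .targetAt(spec, intensity)

  powFac <- .subjectFactor(spec, subjectId)
  withSeed(seed, {

    # band power multipliers at frontal pole; elsewhere scaled by regionalEffect
    stateMult <- function(band, w) {
      m <- switch(band, alpha = 1 - spec@alphaSuppression * g,
                  beta = 1 + spec@betaEnhancement * g, 1)
      1 + w * (m - 1)
    }

    common <- stats::rnorm(n, 0, spec@noiseSd * sqrt(spec@noiseCommon))
    indSd <- spec@noiseSd * sqrt(1 - spec@noiseCommon)

    # the Fp1/Fp2 pair shares its oscillatory waveforms (homologous frontal
    # sites are strongly correlated); asymmetry enters only through the
    # alpha amplitudes
    pairWave <- lapply(names(.BANDS), function(b)
      .fmSine(n, fs, .BAND_CENTERS[[b]], .BAND_HALFBW[[b]], 1))
    names(pairWave) <- names(.BANDS)

    dat <- matrix(0, nch, n, dimnames = list(chans, NULL))
    for (i in seq_len(nch)) {
      w <- if (lc[i] %in% fpSet) 1 else spec@regionalEffect
      x <- numeric(n)
      for (b in names(.BANDS)) {
        P <- spec@bandPowers[[b]] * stateMult(b, w) * powFac
        if (i == iFp1 || i == iFp2) {
          if (b == "alpha") {
            P <- spec@bandPowers[["alpha"]] * stateMult("alpha", 1) * powFac +
              (if (i == iFp1) d / 2 else -d / 2)
            if (P < 0) .stopf("alpha base power too low for asymmetry target %.3f", d)
          }
          x <- x + sqrt(2 * P) * pairWave[[b]]
        } else {
          x <- x + .fmSine(n, fs, .BAND_CENTERS[[b]], .BAND_HALFBW[[b]], sqrt(2 * P))
        }
      }
      dat[i, ] <- x + common + stats::rnorm(n, 0, indSd)
    }

    if (spec@artifactRate > 0) {
      nBlink <- stats::rpois(1, spec@artifactRate * spec@duration / 60)
      if (nBlink > 0) {
        blinkLen <- round(0.3 * fs)
        shape <- 100 * sin(pi * seq_len(blinkLen) / blinkLen)  # 300 ms, 100 uV
        rows <- which(lc %in% fpSet)
        starts <- sample.int(max(1L, n - blinkLen), nBlink, replace = TRUE)
        for (s in starts) {
          idx <- s:(s + blinkLen - 1L)
          dat[rows, idx] <- sweep(dat[rows, idx, drop = FALSE], 2, shape, "+")
        }
      }
    }

    new("EEGRecording", data = dat, fs = fs, channelNames = chans,
        label = label, condition = condition, subjectId = subjectId)
  })
}

#' Plan the recordings of a cohort
#'
#' Enumerates the recordings \code{\link{generateCohort}} will produce, with
#' their subject ids, labels, conditions, stress intensities and derived
#' per-recording seeds.  Baseline recordings come first (states in level
#' order); when \code{interventions} is \code{TRUE}, every subject at level
#' slight or above additionally receives one post-intervention recording,
#' with the four music types assigned cyclically within each state.
#'
#' @inheritParams generateRecording
#' @param interventions Include post-intervention recordings?
#' @return data.frame with columns subject_id, label, condition, intensity,
#'   seed.
#' @export
cohortPlan <- function(spec, interventions = FALSE) {
  validObject(spec)
  lab <- rep(.STATE_NAMES, times = spec@nPerState[.STATE_NAMES])
  ids <- sprintf("S%03d", seq_along(lab))
  plan <- data.frame(subject_id = ids, label = lab, condition = "baseline",
                     intensity = stressLevel(lab), stringsAsFactors = FALSE)
  if (interventions) {
    post <- do.call(rbind, lapply(c("slight", "moderate", "severe"), function(st) {
      i <- which(lab == st)
      if (!length(i)) return(NULL)
      mt <- .MUSIC_TYPES[(seq_along(i) - 1L) %% 4L + 1L]
      data.frame(subject_id = ids[i], label = st, condition = mt,
                 intensity = stressLevel(st) -
                   spec@interventionPull[mt] * (stressLevel(st) - 1),
                 stringsAsFactors = FALSE)
    }))
    plan <- rbind(plan, post)
  }
  plan$seed <- vapply(seq_len(nrow(plan)),
                      function(i) deriveSeed(spec@seed, 1, i), numeric(1))
  rownames(plan) <- NULL
  plan
}

#' Generate a labelled synthetic EEG cohort
#'
#' Produces the full cohort described by a \linkS4class{CohortSpec}: exactly
#' \code{sum(nPerState)} baseline recordings with the configured label
#' counts and, when \code{interventions = TRUE}, one post-intervention
#' recording per subject at stress level slight or above (music types
#' cycled within state).  Identical specs yield bit-identical cohorts.
#'
#' @inheritParams cohortPlan
#' @return List of \linkS4class{EEGRecording} objects.
#' @examples
#' spec <- cohortSpec(nPerState = c(calm = 1, almost_no_stress = 1, slight = 1,
#'                                  moderate = 1, severe = 1),
#'                    duration = 2, channels = c("Fp1", "Fp2"))
#' cohort <- generateCohort(spec)
#' table(vapply(cohort, stressLabel, ""))
#' @export
generateCohort <- function(spec, interventions = FALSE) {
  plan <- cohortPlan(spec, interventions)
  lapply(seq_len(nrow(plan)), function(i)
    generateRecording(spec, plan$label[i], plan$condition[i],
                      subjectId = plan$subject_id[i], seed = plan$seed[i],
                      intensity = plan$intensity[i]))
}
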