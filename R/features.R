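#' Time-domain moment features
#'
#' The four time-domain features of a signal, all with population (divisor
#' n) moments: the mean; the variance (second central moment); skewness
#' k3 / k2^(3/2) with k3 the third and k2 the second central moment; and
#' excess kurtosis m4 / m2^2 - 3, which is 0 for a Gaussian.  For a
#' constant signal (k2 = 0) skewness and kurtosis are undefined and
#' returned as \code{NA}.
#'
#' @param x Numeric signal of length >= 4 with finite samples.
#' @return Named numeric: mean, variance, skewness, kurtosis.
#' @examples
#' timeDomainFeatures(c(1, 2, 3, 4, 5))          # skewness 0
#' timeDomainFeatures(rep(c(-1, 1), 10))          # kurtosis -2
#' @export
timeDomainFeatures <- function(x) {
  if (length(x) < 4) .stopf("signal must have length >= 4")
  if (!all(is.finite(x))) .stopf("signal contains non-finite samples")
  m <- mean(x)
  d <- x - m
  k2 <- mean(d^2)
  if (k2 == 0) {
    sk <- NA_real_; ku <- NA_real_
  } else {
    sk <- mean(d^3) / k2^1.5
    ku <- mean(d^4) / k2^2 - 3
  }
  c(mean = m, variance = k2, skewness = sk, kurtosis = ku)
}

#' Scalp region map
#'
#' Groups the 31 10-10 channels into the five scalp regions used by the
#' classifier comparison: Fp (frontal pole), F (frontal, incl.
#' fronto-central), C (central), P (parietal, incl. centro-parietal) and O
#' (occipital, incl. parieto-occipital).  Regions are disjoint and jointly
#' cover the full montage.
#'
#' @param channels Channel names to partition (default the canonical 31).
#' @return Named list region -> character vector of channel names.
#' @export
regionMap <- function(channels = .CHANNELS_31) {
  grp <- list(
    Fp = c("Fp1", "Fp2", "AF3", "AF4"),
    F  = c("F7", "F3", "Fz", "F4", "F8", "FC5", "FC1", "FC2", "FC6"),
    C  = c("C5", "C3", "Cz", "C4", "C6"),
    P  = c("CP5", "CP1", "CP2", "CP6", "P7", "P3", "Pz", "P4", "P8"),
    O  = c("PO3", "PO4", "O1", "O2"))
  out <- lapply(grp, function(g) channels[tolower(channels) %in% tolower(g)])
  out <- out[vapply(out, length, 0L) > 0]
  covered <- tolower(unlist(out))
  missing <- channels[!tolower(channels) %in% covered]
  if (length(missing))
    .stopf("channels not covered by any region: %s", paste(missing, collapse = ", "))
  out
}

.FEATURE_NAMES <- c("mean", "variance", "skewness", "kurtosis", "psd_power")

# all five features for one channel's samples in one epoch
.channelFeatures <- function(x, fs, cfg) {
  td <- timeDomainFeatures(x)
  w <- welchPsd(x, fs, cfg)
  bp <- bandPower(w$freq, w$psd, cfg$band) / diff(cfg$band)  # mean PSD in band
  c(td, psd_power = bp)
}

#' Region-averaged feature table
#'
#' Computes the five features (mean, variance, skewness, kurtosis, mean PSD
#' in the configured band) for every channel of every epoch, then averages
#' across the channels of each region and across each recording's epochs,
#' yielding exactly one 5-dimensional feature vector per recording per
#' region -- the input contract of the 5-input classifiers.
#'
#' @param es An \linkS4class{EpochSet}.
#' @param regions Region map as from \code{\link{regionMap}}.
#' @param cfg A \code{\link{welchConfig}}.
#' @return data.frame with columns subject_id, region, label, condition and
#'   the five feature columns; one row per recording x region.
#' @export
extractRegionFeatures <- function(es, regions = regionMap(channelNames(es)),
                                  cfg = welchConfig()) {
  stopifnot(is(es, "EpochSet"))
  if (!length(epochs(es))) .stopf("empty epoch set")
  chl <- tolower(channelNames(es))
  rows <- lapply(regions, function(g) {
    i <- match(tolower(g), chl)
    if (anyNA(i))
      .stopf("region channel(s) missing from epochs: %s",
             paste(g[is.na(i)], collapse = ", "))
    i
  })
  fs <- samplingRate(es)
  # per-epoch, per-region mean feature vector
  perEpoch <- lapply(epochs(es), function(ep) {
    feats <- t(apply(ep, 1, .channelFeatures, fs = fs, cfg = cfg))
    vapply(rows, function(i) colMeans(feats[i, , drop = FALSE]),
           numeric(length(.FEATURE_NAMES)))
  })
  key <- paste(epochSubjects(es), epochConditions(es), sep = "\r")
  uk <- unique(key)
  out <- do.call(rbind, lapply(uk, function(k) {
    sel <- which(key == k)
    m <- Reduce(`+`, perEpoch[sel]) / length(sel)  # average over epochs
    data.frame(subject_id = epochSubjects(es)[sel[1]],
               region = names(regions),
               label = epochLabels(es)[sel[1]],
               condition = epochConditions(es)[sel[1]],
               t(m), stringsAsFactors = FALSE, row.names = NULL)
  }))
  names(out)[5:9] <- .FEATURE_NAMES
  rownames(out) <- NULL
  out
}
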