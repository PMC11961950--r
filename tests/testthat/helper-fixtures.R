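# Shared fixtures: small montages and cohort specs keep unit tests fast;
# acceptance tests use the default-scale spec.

fpMontage <- c("Fp1", "Fp2", "AF3", "AF4")

fullMontage <- c("Fp1", "Fp2", "AF3", "AF4", "F7", "F3", "Fz", "F4", "F8",
                 "FC5", "FC1", "FC2", "FC6", "C5", "C3", "Cz", "C4", "C6",
                 "CP5", "CP1", "CP2", "CP6", "P7", "P3", "Pz", "P4", "P8",
                 "PO3", "PO4", "O1", "O2")

smallSpec <- function(n = 1L, duration = 5, channels = fpMontage, ...) {
  cohortSpec(nPerState = c(calm = n, almost_no_stress = n, slight = n,
                           moderate = n, severe = n),
             duration = duration, channels = channels, ...)
}

# recording wrapper around an arbitrary channel x sample matrix
recFromMatrix <- function(m, fs = 500, channels = paste0("ch", seq_len(nrow(m))),
                          label = "calm", condition = "baseline", id = "T1") {
  new("EEGRecording", data = m, fs = fs, channelNames = channels,
      label = label, condition = condition, subjectId = id)
}

# short Welch config suitable for 5 s fixtures
shortWelch <- function(M = 500, ...) welchConfig(segmentLength = M, ...)

# deterministic separable 2-cluster feature set for classifier sanity fits
twoClusterFeatures <- function(n = 30, seed = 42) {
  withr::local_seed(seed)
  x <- rbind(matrix(rnorm(n * 5, 0, 0.3), n, 5),
             matrix(rnorm(n * 5, 2, 0.3), n, 5))
  colnames(x) <- c("mean", "variance", "skewness", "kurtosis", "psd_power")
  list(x = x, y = rep(c("calm", "severe"), each = n))
}
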