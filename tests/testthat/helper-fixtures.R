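# Shared fixture builders; everything is generated in code.

identityDesign <- function(n = 24, labels = masticationNodeLabels()[seq_len(n)]) {
  S <- diag(n)
  dimnames(S) <- list(labels, labels)
  S
}

# Small deterministic series with named nodes.
makeSeries <- function(data, tr = 2) {
  ROITimeSeries(data, nodeLabels = paste0("n", seq_len(ncol(data))),
                samplingInterval = tr)
}

# Connectivity matrices for all subjects of a cohort, computed on the
# band-limited component (the quantity the planted couplings refer to).
cohortConnectivity <- function(cohort, lowHz = 0.01, highHz = 0.08) {
  lapply(cohort$series, function(s)
    computeConnectivity(bandpassFilter(s, lowHz, highHz), clip = TRUE))
}
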