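# Planted-signal cohort used for parameter-recovery checks: equal ROI base
# means (so regional GMV carries no linear component of the planted signal),
# heterogeneous ROI sigmas, 10 disjoint planted edges with alternating-sign
# weights, planted-model R^2 = 0.7.
recoverySpec <- function(seed, nParticipants = 60) {
  cohortSpec(nParticipants = nParticipants, nRois = 20, nVoxels = 500,
             roiMeanBase = 0.55,
             roiSigmaBase = seq(0.08, 0.16, length.out = 20),
             subjectSd = 0.05,
             plantedEdges = cbind(seq(1, 19, 2), seq(2, 20, 2)),
             plantedWeights = rep_len(c(1, -1), 10),
             plantedR2 = 0.7, seed = seed)
}

# Pure-noise cohort: zero planted weights, thresholds are rescaled noise.
nullSpec <- function(seed, nParticipants = 40, nRois = 10) {
  cohortSpec(nParticipants = nParticipants, nRois = nRois, nVoxels = 150,
             roiMeanBase = 0.55,
             roiSigmaBase = seq(0.09, 0.14, length.out = nRois),
             subjectSd = 0.04,
             plantedEdges = cbind(1, 2), plantedWeights = 0,
             plantedR2 = NA, noiseSd = c(1, 1), seed = seed)
}

# Small cohort for smoke tests.
tinyCohort <- function(seed = 1, nParticipants = 20, nRois = 6,
                       nVoxels = 60) {
  generateCohort(cohortSpec(nParticipants = nParticipants, nRois = nRois,
                            nVoxels = nVoxels, seed = seed))
}
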