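# Shared synthetic cohorts, generated once per test run.
.cohortCache <- new.env(parent = emptyenv())

cachedCohort <- function(key, config) {
  if (is.null(.cohortCache[[key]]))
    .cohortCache[[key]] <- generateCohort(config)
  .cohortCache[[key]]
}

# the default study conditions: 40/40/40 samples, 300 genes, 50 miRNAs,
# 12 pathways with 3 planted (log2 shift 2), 2 planted regulators
defaultCohort <- function() cachedCohort("default", syntheticConfig())

# tiny labeled matrix for direct unit tests
tinyExpression <- function(values, basal, normal) {
  labels <- setNames(rep(c("basal", "normal"), c(length(basal),
                                                 length(normal))),
                     c(basal, normal))
  LabeledExpression(values, labels)
}
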