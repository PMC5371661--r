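# Shared study-scale synthetic cohort for the headline-replication tests.
# Runs the full pipeline once per test session (a 12-participant,
# 30 + 30-scene cohort; the generator's scientific defaults for trial
# structure and gaze statistics are unchanged) and caches the result.

.cohort_cache <- new.env(parent = emptyenv())

headline_results <- function() {
  if (is.null(.cohort_cache$res)) {
    coh <- generate_cohort(cohort_config(n_participants = 12, n_social = 30,
                                         n_nonsocial = 30, seed = 1))
    .cohort_cache$res <- suppressWarnings(
      analyze_cohort(coh, models = c("3a", "4", "6"))
    )
  }
  .cohort_cache$res
}
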