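# The desk-scale experiment is expensive (nine scenarios x three repeats of
# an 800-year individual-based run), so it is computed once per test session
# and shared by the dynamical-phenomena tests.

.desk_cache <- new.env(parent = emptyenv())

desk_experiment <- function() {
  if (is.null(.desk_cache$ex)) {
    .desk_cache$ex <- run_experiment(desk_plan(master_seed = 1),
                                     desk_scale = FALSE)
  }
  .desk_cache$ex
}

# one repeat's records for a scenario of the cached experiment
desk_records <- function(scenario, post_peak = "continued", rep = NULL) {
  rec <- dplyr::filter(desk_experiment()$records,
                       scenario == !!scenario, post_peak == !!post_peak)
  if (!is.null(rep)) rec <- dplyr::filter(rec, `repeat` == rep)
  rec
}
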