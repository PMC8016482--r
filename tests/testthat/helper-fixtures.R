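# shared fixtures, built in code
fixture_design <- build_design(42L)
fixture_params <- activation_params(0.5, 0.2, 0.1)

# a single randomized generalization run used by several model tests
fixture_run <- generate_randomized_generalization_runs(fixture_design, 7L,
                                                       n_runs = 1L)[[1L]]

make_trial <- function(design, context, category,
                       phase = "generalization_blocked") {
  data.frame(phase = phase, context = context, category = category,
             latent_state = taskstates:::context_ls(design, context),
             stringsAsFactors = FALSE)
}
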