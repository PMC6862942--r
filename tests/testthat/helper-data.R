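# Small synthetic recall tables shared across test files. All fixtures are
# generated in code from the package's own generator, at sizes chosen to
# keep individual tests fast.
tiny_recalls <- function(n = 400, days = 1, seed = 1, ...) {
  generate_recalls(generator_spec(n_persons = n, days_per_person = days,
                                  seed = seed, ...))
}

# Covariate formula mirroring the analysis model: continuous age, group
# indicators, weekend indicator as the temporal covariate.
full_formula <- intake ~ age + group + weekend
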