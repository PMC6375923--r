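# shared fixture loaders for the test-suite

published_effects <- function() {
  utils::read.csv(system.file("extdata", "ffd_effects.csv",
                              package = "phenoval"))
}

effects_for <- function(response) {
  df <- published_effects()
  effect_table(stats::setNames(df[[response]], df$effect), response)
}

published_models <- function() {
  df <- utils::read.csv(system.file("extdata", "quadratic_models.csv",
                                    package = "phenoval"))
  models <- lapply(seq_len(nrow(df)), function(i)
    quadratic_model(df$intercept[i], c(df$x1[i], df$x2[i]),
                    c(df$x1_sq[i], df$x2_sq[i]), df$x1_x2[i]))
  names(models) <- df$response
  models
}

recovery_fixture <- function() {
  utils::read.csv(system.file("extdata", "recovery_levels.csv",
                              package = "phenoval"))
}
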