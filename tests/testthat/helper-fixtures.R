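# Shared fixtures, memoised so expensive fits are computed once per test run.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures, inherits = FALSE)) {
    assign(name, force(expr), envir = .fixtures)
  }
  get(name, envir = .fixtures, inherits = FALSE)
}

default_cfg <- function() fixture("cfg", meno_config(seed = 42))

# stage-1 model at the generating parameters (no estimation noise)
true_amh_fit <- function() fixture("af_true", {
  cal <- default_cfg()$calibration
  amh_fit_from_params(cal$coefs, cal$scale1, cal$shape_a, cal$shape_b)
})

true_model <- function() fixture("model_true", as_meno_model(default_cfg()))

sim_amh <- function() fixture("amh", simulate_amh_cohort(default_cfg()))

sim_meno <- function() fixture("meno", simulate_menopause_cohort(default_cfg()))

fitted_amh <- function() fixture("af_fit", fit_amh(sim_amh()))

fitted_threshold <- function() {
  fixture("tf_fit", fit_threshold(sim_meno(), fitted_amh()))
}

with_seed <- function(seed, code) menothresh:::with_preserved_seed(seed, code)

mu_at <- function(coefs, age) {
  coefs[[1]] + coefs[[2]] * age + coefs[[3]] * age^2
}
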