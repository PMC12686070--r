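# Model experiments are deterministic but not free; compute each gradient set
# once per test session and reuse across files.
.curve_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .curve_cache))
    assign(key, force(expr), envir = .curve_cache)
  get(key, envir = .curve_cache)
}

exp1_curves <- function() {
  cached("exp1", lapply(build_experiment1(), run_gradient))
}

exp1_estimates <- function() {
  cached("exp1_est", lapply(exp1_curves(), detect_ter))
}

exp2_curves <- function() {
  cached("exp2",
         lapply(build_experiment2(), function(s) suppressWarnings(run_gradient(s))))
}

exp2_estimates <- function() {
  cached("exp2_est", lapply(exp2_curves(), detect_ter))
}
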