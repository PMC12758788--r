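# Shared fixtures. The trained model is expensive, so it is built once per
# test run and cached in this environment.

.fixtures <- new.env(parent = emptyenv())

small_spec <- function(seed = 7, ...) {
  args <- utils::modifyList(
    list(n_ref = 500, n_query = 500, n_features = 80, K = 4,
         separation = 12, shift_strength = 0.2, dropout_rate = 0.3,
         seed = seed),
    list(...))
  do.call(synthetic_spec, args)
}

prepared_domains <- function(spec) {
  sim <- generate_paired_domains(spec)
  prep <- intersect_features(sim$ref, sim$query)
  list(ref = log_normalize(prep$ref), query = log_normalize(prep$query),
       query_labels = sim$query_labels, spec = spec)
}

small_config <- function(...) {
  args <- utils::modifyList(
    list(alpha = 1.2, beta = 0.05, gamma = 0.01, tau = 0.8,
         batch_size = 200L, max_iterations = 200L, hidden_dims = 64L,
         learning_rate = 0.01, warmup = 80L, seed = 5),
    list(...))
  do.call(scenario_config, args)
}

# one trained model on a moderately shifted 4-type problem, reused by the
# prediction / interpretation / evaluation tests
trained_fixture <- function() {
  if (is.null(.fixtures$trained)) {
    dat <- prepared_domains(small_spec())
    fit <- fit_annotator(dat$ref, dat$query, small_config())
    .fixtures$trained <- list(fit = fit, dat = dat)
  }
  .fixtures$trained
}

random_model <- function(p = 10, K = 3, hidden = 8, m = 6, e_dim = 4,
                         seed = 1) {
  init_model(model_config(p, K, hidden_dims = hidden, m = m, e_dim = e_dim),
             seed = seed)
}
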