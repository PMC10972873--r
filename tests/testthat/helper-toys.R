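# Hand-built toy networks and small fixtures shared across tests.

# two neurons feeding each other with weight +1: state (1,0) cycles with period 2
toy_mutual <- function(weight = 1) {
  reservoir_from_edges(
    2, data.frame(target = c(1L, 2L), source = c(2L, 1L), weight = weight)
  )
}

# planted separable readout fixture: one column carries round(target)
separable_fixture <- function(n = 300, p = 10, seed = 1) {
  set.seed(seed)
  x <- matrix(rbinom(n * p, 1, 0.5), n, p)
  target <- ifelse(x[, 3] == 1, 0.9, 0.1)
  n_train <- (2 * n) %/% 3
  list(x = x, target = target, train = seq_len(n_train), test = (n_train + 1):n)
}

# quick config for orchestrator tests: small everything
tiny_sweep_config <- function(...) {
  sweep_config(
    n = 120, k = 3, sigma_star = c(-2, 2), r_dynamics = 4, r_task = 2,
    steps = 240, t0 = 120, deltas = -2, taus = numeric(),
    task_length = 260, washout = 20,
    train = train_config(epochs = 150),
    base_seed = 7, ...
  )
}
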