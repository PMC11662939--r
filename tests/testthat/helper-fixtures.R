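# shared fixtures, built once per test run

map_nts5 <- function(...) substrate_map(label = list(strand = "NTS", end = "5p"), ...)
map_nts3 <- function(...) substrate_map(label = list(strand = "NTS", end = "3p"), ...)
map_ts5 <- function(...) substrate_map(label = list(strand = "TS", end = "5p"), ...)
map_ts3 <- function(...) substrate_map(label = list(strand = "TS", end = "3p"), ...)

# a minimal two-state scheme A -> B at rate k (for closed-form oracles)
two_state_scheme <- function(k = 1) {
  Q <- matrix(c(-k, k, 0, 0), 2, 2, byrow = TRUE,
              dimnames = list(c("A", "B"), c("A", "B")))
  st <- data.frame(name = c("A", "B"))
  rownames(st) <- st$name
  list(Q = Q, states = st)
}

# mechanistic initialisation used for HaMMy-style fits of the fixture data
fret_init <- function() {
  list(mu = c(0.02, 0.30, 0.55, 0.90), sigma = rep(0.06, 4),
       A = matrix(0.02 / 3, 4, 4) + diag(rep(0.98 - 0.02 / 3, 4)),
       pi = c(0.97, 0.01, 0.01, 0.01))
}

# cached heavy fixtures
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# a processed wild-type ensemble at 10 mM Mg (selected fret_traces)
wt_ensemble <- function(n = 60, seed = 3) {
  cached(sprintf("wt_%d_%d", n, seed), {
    traces <- simulate_fret_experiment(fret_scheme(), n = n, seed = seed)
    fts <- lapply(traces, fret_trace, bkg_D = 100, bkg_A = 100,
                  leakage = 0.07)
    select_trajectories(fts)$kept
  })
}

# shared HMM fit + idealizations of the wt ensemble
wt_fit <- function(n = 60, seed = 3) {
  cached(sprintf("wtfit_%d_%d", n, seed), {
    kept <- wt_ensemble(n, seed)
    model <- suppressWarnings(
      fit_hmm(kept, K = 4, init = fret_init(), seed = 1, n_restarts = 2,
              max_iter = 300))
    classes <- classify_states(model)
    ideal <- lapply(kept, function(tr) viterbi_path(model, tr))
    list(kept = kept, model = model, classes = classes, ideal = ideal)
  })
}

# random sequence fixture for the unzipping module
random_sequence <- function(n = 300, seed = 42) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
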