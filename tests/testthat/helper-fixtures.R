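# Shared fixtures, memoized so expensive steady runs are computed once per
# test session and reused across files.

.ct_cache <- new.env(parent = emptyenv())

ct_memo <- function(key, expr) {
  if (!exists(key, .ct_cache)) assign(key, force(expr), .ct_cache)
  get(key, .ct_cache)
}

ct_model <- function() ct_memo("model", build_body())
ct_winter <- function() ct_memo("winter", clothing_ensemble("winter"))
ct_summer <- function() ct_memo("summer", clothing_ensemble("summer"))

# converged steady state, winter ensemble at 0 C / 85% RH
ct_steady0 <- function() ct_memo("steady0", {
  simulate_body(ct_model(), ct_winter(), environment_spec(0, 0.85))
})

# six-temperature winter sweep used by resistance/monotonicity checks
ct_sweep <- function() ct_memo("sweep", {
  ambient_sweep(ct_model(), ct_winter(), c(0, 3, 5, 8, 12, 14), RH = 0.85)
})

# steady run of the indoor validation scenario (18 C, short sleeves)
ct_indoor18 <- function() ct_memo("indoor18", {
  simulate_body(ct_model(), ct_summer(), environment_spec(18, 0.5))
})

# a thermoneutral body: set points 37 C everywhere, zero basal metabolism
ct_neutral_body <- function() ct_memo("neutral_body", {
  seg <- ct_model()$segments
  seg[, c("Q0_core", "Q0_eq", "Q0_skin")] <- 0
  seg[, c("Tset_core", "Tset_eq", "Tset_skin")] <- 37
  build_body(list(body = seg))
})
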