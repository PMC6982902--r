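# Shared fixtures, built once per test run and memoized. All synthetic data
# comes from the package's own virtual learner under fixed seeds.

.fx <- new.env(parent = emptyenv())

fx_memo <- function(key, builder) {
  if (is.null(.fx[[key]])) .fx[[key]] <- builder()
  .fx[[key]]
}

fx_roles <- function() {
  list("1" = c("class", "shape"), "2" = c("class", "shape"), "3" = "time")
}

# preprocessed multi-signal from a virtual-learner run
fx_msig <- function(mode = "alpha", seed = 1, duration = 10, noise = 0.4,
                    jitter = TRUE, wobble = 5) {
  cfg <- learner_config(class_mode = mode, duration = duration,
                        noise_density = noise,
                        amplitude_jitter = if (jitter) 0.05 else 0,
                        phase_jitter = if (jitter) 0.02 else 0,
                        wobble_deg = wobble, seed = seed)
  st <- synth_stream(make_trajectory(cfg), cfg)
  select_signals(st, default_selection(), period_w = 200)
}

# two-class pattern bank built from one training recording per class
fx_bank <- function() {
  fx_memo("bank", function() {
    pattern_bank(list(
      build_pattern_md(fx_msig("alpha", seed = 300, duration = 12),
                       roles = fx_roles(), label = "Calpha", w = 200),
      build_pattern_md(fx_msig("beta", seed = 301, duration = 12),
                       roles = fx_roles(), label = "Cbeta", w = 200)))
  })
}

# a clean one-period sine pattern and a three-period signal built from it
fx_sine_pattern <- function(w = 200) {
  pattern1d(sin(2 * pi * (0:(w - 1)) / w), index = 1, roles = "time")
}

expect_circ_close <- function(b, expect, w, tol) {
  d <- (b - expect) %% w
  expect_lte(min(d, w - d), tol)
}
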