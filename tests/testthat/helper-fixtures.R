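# Shared fixtures, built once per test run and memoized.
.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) {
    assign(key, force(expr), envir = .fixtures)
  }
  get(key, envir = .fixtures)
}

# Ground-truth three-mode prior: weights 0.5 / 0.3 / 0.2 on three
# integer-ratio categories.
three_mode_prior <- function(sd = 0.02) {
  o22 <- omega22()
  anchors <- o22[match(c("1:1:2", "1:2:2", "3:3:2"), o22$ratio), ]
  mixture_prior(anchors, weights = c(0.5, 0.3, 0.2), sd = sd)
}

# Moderate simulated dataset with a peaked prior (posterior-mean observer).
peaked_dataset <- function() {
  memo("peaked_dataset", {
    simulate_dataset(observer_params(prior = three_mode_prior()),
                     n_trials = 150, seed = 4101)
  })
}

# Large posterior-sampling dataset used for recovery and reliability.
recovery_dataset <- function() {
  memo("recovery_dataset", {
    simulate_dataset(observer_params(prior = three_mode_prior(),
                                     posterior = "sample"),
                     n_trials = 400, seed = 4202)
  })
}

# Flat-prior dataset (unbiased echo observer).
uniform_dataset <- function() {
  memo("uniform_dataset", {
    simulate_dataset(observer_params(prior = NULL, sigma_s = 0),
                     n_trials = 150, seed = 4303)
  })
}

coarse_grid <- function() memo("coarse_grid", triangle_grid(bin = 0.02))
fine_grid <- function() memo("fine_grid", triangle_grid(bin = 0.006))

# Small well-separated anchor set for mixture tests.
separated_anchors <- function() {
  o22 <- omega22()
  an <- o22[match(c("1:1:1", "1:1:3", "3:1:1"), o22$ratio), ]
  class(an) <- c("ratio_set", "data.frame")
  an
}
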