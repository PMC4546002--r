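# Shared fixtures: all test data is generated in code.

default_bend <- function() bend_geometry()

# 48 m mid-lane path radius bend matching the studied ramps
paper_speed <- 42 / 3.6  # m/s

noiseless_params <- function(strategy = "waypoint", ...) {
  strategy_params(strategy, noise_sd = 0, vibration_sd = 0,
                  dropout_prob = 0, ...)
}

noiseless_trial <- function(strategy = "waypoint", seed = 7,
                            condition = if (strategy == "waypoint") "normal" else "tp",
                            ...) {
  simulate_trial(default_bend(), noiseless_params(strategy, ...),
                 speed = paper_speed, seed = seed, condition = condition)
}

# Exhaustive minimum of the penalised piecewise-linear cost, by unpruned
# recursive enumeration of every admissible composition of 1..n into
# contiguous segments. Independent of the dynamic program: segment SSEs come
# from lm residuals.
brute_force_partition_cost <- function(t, gh, gv, penalty, min_len = 2) {
  n <- length(t)
  seg_sse <- function(i, j) {
    idx <- i:j
    tc <- t[idx] - mean(t[idx])
    r <- function(y) {
      f <- stats::lm.fit(cbind(1, tc), y[idx])
      sum(f$residuals^2)
    }
    r(gh) + r(gv)
  }
  best <- Inf
  recurse <- function(start, acc) {
    for (end in (start + min_len - 1L):n) {
      if (end > n) break
      cost <- acc + seg_sse(start, end) + penalty
      if (end == n) {
        if (cost < best) best <<- cost
      } else if (n - end >= min_len) {
        recurse(end + 1L, cost)
      }
    }
  }
  recurse(1L, 0)
  best
}
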