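# shared fixtures: small cohorts and a cheap fitted model, built once per run

consts_default <- age_reference_constants()

# modest-variability population used where full Table-style IIV would make
# tiny test cohorts too wild to be informative
test_population <- function(omega_scale = 1) {
  pop <- default_population_parameters()
  pop$omega <- pop$omega * omega_scale
  pop
}

small_cohort <- function(n = 20, seed = 101, pop = test_population(),
                         effects = list()) {
  simulate_cohort(pop, effects = effects,
                  spec = cohort_spec(n_subjects = n, seed = seed))
}

# fixed-step classical RK4 on the model right-hand side, written
# independently of the production solver (used as integration oracle)
rk4_cd4 <- function(params, age0, times, h = 0.05,
                    consts = consts_default) {
  m <- grouping_multiplier(consts)
  rhs <- function(t, x) {
    tau <- age0 + t
    N <- consts$n_total_asymptote +
      consts$n_total_amplitude * exp(-consts$n_total_rate * tau)
    Nn <- consts$n_naive_asymptote +
      consts$n_naive_amplitude * exp(-consts$n_naive_rate * tau)
    y <- consts$ki67_at_birth * exp(-consts$ki67_decay_rate * tau)
    num <- 1 - exp(-2 * t / params[["lambda_h"]])
    z <- params[["lambda_r"]] * (1 - t / params[["lambda_h"]])
    delta <- if (z > 700) num * exp(-z) else num / (1 + exp(z))
    lam <- params[["lambda0"]] * m * y * Nn * delta
    r <- x / N
    lam - params[["d0"]] * y * exp(params[["cd"]] * (r - 1)) * x +
      params[["p0"]] * y * exp(params[["cp"]] * (1 - r)) * x
  }
  out <- numeric(length(times))
  x <- params[["x0"]]
  t <- 0
  for (i in seq_along(times)) {
    while (t < times[i] - 1e-12) {
      hh <- min(h, times[i] - t)
      k1 <- rhs(t, x)
      k2 <- rhs(t + hh / 2, x + hh / 2 * k1)
      k3 <- rhs(t + hh / 2, x + hh / 2 * k2)
      k4 <- rhs(t + hh, x + hh * k3)
      x <- x + hh / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      t <- t + hh
    }
    out[i] <- x
  }
  out
}
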