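# shared fixtures, computed lazily and memoised across test files

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, force(expr), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# the standard single-field seizure (uniform epileptogenic field, default
# stimulation protocol), reused by several test files
default_seizure <- function() memo("default_seizure", {
  simulate_field(field_params(), duration = 2500)
})

# two-field seizure with long-range coupling; field 2 is less excitable and
# transitions later
two_field_seizure <- function(gamma_het = 0.3, u0_2 = -1.9, noise = 0,
                              seed = NULL, duration = 3000, N = 128) {
  p <- field_params(N = N, noise_sigma2 = noise)
  L <- p$L
  conn <- connectivity_spec(2, het = list(
    het_connection(1, L / 2, 2, L / 2, gamma_het),
    het_connection(2, L / 2, 1, L / 2, gamma_het)))
  simulate_field(p, conn, duration = duration, seed = seed,
                 u0_fields = list(-1.8, u0_2))
}

# reference RK4 step built on the R-level rhs (independent of the compiled
# integrator)
rk4_step_r <- function(state, params, dt, conn = NULL) {
  add <- function(a, b, h) Map(function(x, y) x + h * y, a, b)
  k1 <- field_rhs(state, params, conn)
  k2 <- field_rhs(add(state, k1, dt / 2), params, conn)
  k3 <- field_rhs(add(state, k2, dt / 2), params, conn)
  k4 <- field_rhs(add(state, k3, dt), params, conn)
  Map(function(s0, a, b, c, d) s0 + dt / 6 * (a + 2 * b + 2 * c + d),
      state, k1, k2, k3, k4)
}

uniform_state <- function(vals, N) {
  lapply(as.list(vals), rep, N)
}

skl_available <- function() {
  memo("skl_available", {
    code <- "import sklearn"
    identical(suppressWarnings(
      system2("python", c("-c", shQuote(code)), stdout = FALSE,
              stderr = FALSE)), 0L)
  })
}
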