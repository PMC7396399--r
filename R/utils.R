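# Internal helpers.

# run code under a fixed RNG seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(seed)
  force(code)
}

# lognormal draw with natural-scale mean m and coefficient of variation cv
rlnorm_cv <- function(n, m, cv) {
  if (cv <= 0) return(rep(m, n))
  sdlog <- sqrt(log(1 + cv^2))
  m * exp(stats::rnorm(n, -sdlog^2 / 2, sdlog))
}
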