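# Seeding helpers: all randomness in the package flows through these.

# Evaluate `expr` under `set.seed(seed)` without disturbing the caller's RNG
# state. `seed = NULL` evaluates as-is.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
    get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
        rm(".Random.seed", envir = .GlobalEnv)
    } else assign(".Random.seed", old, envir = .GlobalEnv)
  })
  set.seed(seed)
  expr
}

#' Derive a stage-keyed sub-seed from a master seed
#'
#' Stable string hash of \code{(master_seed, keys...)} into \code{[0, 2^31)},
#' so that adding an outcome or stage to a pipeline run never perturbs the
#' sub-seed (hence the results) of any other stage.
#'
#' @param master_seed integer master seed.
#' @param ... further keys (stage name, outcome, group, ...), coerced to
#'   character.
#' @return a single integer seed.
#' @export
sub_seed <- function(master_seed, ...) {
  key <- paste(c(as.character(master_seed), vapply(list(...), as.character,
                                                   character(1))),
               collapse = "/")
  h <- 17
  for (b in utf8ToInt(key)) h <- (h * 31 + b) %% 2147483629
  as.integer(h)
}

# variance of a normal(mu, sd) truncated to [a, b]
.trunc_norm_var <- function(mu, sd, a, b) {
  al <- (a - mu) / sd; be <- (b - mu) / sd
  Z <- stats::pnorm(be) - stats::pnorm(al)
  t1 <- (al * stats::dnorm(al) - be * stats::dnorm(be)) / Z
  t2 <- (stats::dnorm(al) - stats::dnorm(be)) / Z
  sd^2 * (1 + t1 - t2^2)
}

# truncated-normal sampling by resampling (no boundary atoms)
.rtruncnorm <- function(n, mu, sd, a, b) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(2 * (n - length(out)) + 10, mu, sd)
    out <- c(out, x[x >= a & x <= b])
  }
  out[seq_len(n)]
}

# standardized right-skewed noise: lognormal shifted/scaled to mean 0, sd 1
.rskew <- function(n, sdlog = 0.8) {
  m <- exp(sdlog^2 / 2)
  s <- sqrt((exp(sdlog^2) - 1) * exp(sdlog^2))
  (stats::rlnorm(n, 0, sdlog) - m) / s
}
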