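# Internal helpers shared across modules.

nad_extdata <- function(file) {
  path <- system.file("extdata", file, package = "nadpbpk")
  if (!nzchar(path)) {
    stop("packaged data file not found: ", file, call. = FALSE)
  }
  path
}

read_extdata_csv <- function(file) {
  utils::read.csv(nad_extdata(file), stringsAsFactors = FALSE)
}

#' @noRd
nad_stop <- function(..., class = "nadpbpk_error") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Truncated standard normal draws (truncation at +/- k SD, by resampling).
rnorm_trunc <- function(n, k = 3) {
  z <- stats::rnorm(n)
  bad <- abs(z) > k
  while (any(bad)) {
    z[bad] <- stats::rnorm(sum(bad))
    bad <- abs(z) > k
  }
  z
}

# Log-normal multiplicative factors with coefficient of variation `cv`,
# unit median, truncated at +/- 3 SD on the log scale.
lognormal_factors <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  exp(rnorm_trunc(n, 3) * sdlog)
}

trapz <- function(x, y) {
  n <- length(x)
  if (n < 2) return(0)
  sum((y[-1] + y[-n]) / 2 * diff(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
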