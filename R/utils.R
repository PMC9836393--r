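#' @importFrom rlang abort warn .data
#' @importFrom stats dnorm median qt quantile rnorm runif sd var cor fft t.test p.adjust setNames
#' @importFrom utils head tail
NULL

# Derive a reproducible child seed from a master seed and a stream index.
# Kept below 2^31 - 1 so it is always a valid integer seed.
derive_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 48271 + stream * 1299709) %% 2147483399) + 1L
}

# Run code with a local RNG state seeded from `seed`; never touches the
# caller's global stream.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# half-up rounding used wherever onsets are mapped to samples
round_half_up <- function(x) floor(x + 0.5)

`%||%` <- function(a, b) if (is.null(a)) b else a
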