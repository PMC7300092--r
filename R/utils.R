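#' @keywords internal
"_PACKAGE"

# Numerical helpers shared across the package.

.relu <- function(x) {
  x[x < 0] <- 0
  x
}

.sigmoid <- function(x) 1 / (1 + exp(-x))

# Row-broadcast addition of a bias vector.
.add_bias <- function(A, b) sweep(A, 2L, b, "+")

.assert <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}

# All stochastic entry points funnel through here so the caller's RNG state
# is never disturbed and a fixed seed gives bit-identical results.
.with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

.msg <- function(..., verbose = TRUE) {
  if (isTRUE(verbose)) message(...)
}
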