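# Internal helpers: FFT layout, seeds, classed errors.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
abort_droiq <- function(message, class) {
  stop(structure(
    class = c(class, "droiq_error", "error", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

# Swap quadrants so the DC-centered layout maps to the FFT origin layout and
# back. For even N the shift is its own inverse.
#' @noRd
fftshift2 <- function(m) {
  n <- dim(m)
  if (n[1] %% 2L != 0L || n[2] %% 2L != 0L)
    abort_droiq("fftshift2 requires even dimensions", "droiq_invalid_input")
  m[c((n[1] / 2 + 1):n[1], 1:(n[1] / 2)),
    c((n[2] / 2 + 1):n[2], 1:(n[2] / 2)), drop = FALSE]
}

# Deterministic substream seeds: every realization / calibration draw is
# reproducible in isolation from one master seed. Kept below 2^31 - 1.
#' @noRd
derive_seed <- function(master, stream, index = 0L) {
  m <- 2147483629
  (((as.double(master) %% m) * 48271 + stream * 1299709 + index * 7919) %% m)
}

#' @noRd
is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
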