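# shared internal helpers

# round half away from zero (base round() is half-to-even, which makes
# 8-bit conversions platform-dependent at *.5 boundaries)
round_half_up <- function(x) {
  floor(x + 0.5)
}

clip <- function(x, lo, hi) {
  pmin(pmax(x, lo), hi)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == trunc(x)
}

is_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
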