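`%||%` <- function(a, b) if (is.null(a)) b else a

# locale-independent lexicographic sort, used everywhere an output gene or
# dataset list must be deterministic across platforms
sort_c <- function(x) sort(x, method = "radix")

# half-up rounding (round() is banker's rounding, which would turn 4.5 into 4)
round_half_up <- function(x, digits = 0) {
  f <- 10^digits
  floor(x * f + 0.5) / f
}
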