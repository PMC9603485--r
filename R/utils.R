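# Internal helpers shared across modules.

# Round half away from zero, matching the "15.7%" style of reported
# percentages (base R round() is banker's rounding).
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Population standard deviation (the module is the full population of its
# nodes, so no n-1 correction).
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

# Deterministic per-stage child seed derived from the run seed, so stages
# are independently rerunnable. Kept below 2^31 - 1.
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647L)
}
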