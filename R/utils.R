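# Largest-remainder (Hamilton) integer allocation: returns non-negative
# integers summing exactly to `total`, proportional to `weights`.
largest_remainder <- function(weights, total) {
  stopifnot(total >= 0, all(weights >= 0), sum(weights) > 0)
  q <- weights / sum(weights) * total
  base <- floor(q)
  rem <- total - sum(base)
  if (rem > 0) {
    # deterministic tie-break: larger fraction first, then earlier index
    ord <- order(-(q - base), seq_along(q))
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  as.integer(base)
}

# Round half up to `digits` decimals (the rounding Table-style percentages use;
# base round() is banker's rounding).
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

# Derive independent sub-seeds from one master seed so pipeline stages can be
# regenerated in isolation. Documented splitting scheme: the master seed seeds
# R's RNG once and the sub-seeds are drawn from it.
split_seed <- function(seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  # headroom below 2^31 so callers may add small offsets and stay integral
  sample.int(2^30, n)
}
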