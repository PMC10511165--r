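# Shared fixtures: compact single-lead configurations.

noiseFree <- list(wanderAmp = 0, broadbandSd = 0, powerlineAmp = 0)

# Quiet single-lead record for fiducial tests.
quietConfig <- function(..., leads = "II", duration = 60, seed = 1L,
                        noise = noiseFree) {
  synthConfig(leads = leads, duration = duration, seed = seed,
              noise = noise, ...)
}

# Independent brute-force STV oracle: a literal loop over the formula,
# dropping pairs that bridge an invalid beat.
bruteStv <- function(qt, valid = rep(TRUE, length(qt)),
                     denominator = "beats") {
  s <- 0; npairs <- 0
  for (i in seq_len(length(qt) - 1)) {
    if (valid[i] && valid[i + 1]) {
      s <- s + abs(qt[i + 1] - qt[i])
      npairs <- npairs + 1
    }
  }
  n <- if (denominator == "beats") sum(valid) else npairs
  s / (n * sqrt(2))
}
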