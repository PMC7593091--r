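# trapezoidal rule; x need not be increasing (signed integral)
trapz <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)]) / 2)

geoMean <- function(x) exp(mean(log(x)))

# derive a reproducible child seed (kept below 2^31)
childSeed <- function(seed, i) as.integer((as.numeric(seed) * 104729 + i * 7919) %% 2147483647)
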