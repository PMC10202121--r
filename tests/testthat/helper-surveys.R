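# shared fixtures: small synthetic surveys with known confounding structure

psc_survey <- function(n = 500, seed = 101, ...) {
  generate_survey(survey_config(n = n, group = "PSC", seed = seed, ...))
}

# independent type-7 percentile oracle: sort and linearly interpolate
decile_oracle <- function(x, p = 0.10) {
  x <- sort(x[!is.na(x)])
  h <- (length(x) - 1) * p
  lo <- floor(h) + 1
  x[lo] + (h - floor(h)) * (x[min(lo + 1, length(x))] - x[lo])
}
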