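# build an angle series tibble from vectors (test convenience)
angle_series <- function(t, trunk, thigh = 0, source = "ground-truth") {
  tibble::tibble(
    t = t,
    theta_trunk_deg = rep_len(trunk, length(t)),
    theta_thigh_deg = rep_len(thigh, length(t)),
    source = source,
    valid = TRUE
  )
}

# textbook Pearson correlation written out longhand (independent oracle)
pearson_oracle <- function(a, b) {
  am <- a - sum(a) / length(a)
  bm <- b - sum(b) / length(b)
  sum(am * bm) / sqrt(sum(am^2) * sum(bm^2))
}

# Fisher z-average via the log form of atanh (independent oracle)
fisher_oracle <- function(rs) {
  z <- 0.5 * log((1 + rs) / (1 - rs))
  zb <- sum(z) / length(z)
  (exp(2 * zb) - 1) / (exp(2 * zb) + 1)
}
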