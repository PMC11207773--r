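# shared fixture builders; everything is generated in code at test time

# random but valid IBI series (ms), length n, around 800 ms
random_ibi <- function(n, sd = 40, mean = 800) {
  ibi_series(pmax(stats::rnorm(n, mean, sd), 350))
}

# small norm table with one decade bin and one all-ages pooled fallback
toy_norm_table <- function() {
  norm_table(data.frame(
    stratum_age_lo = c(30, 30, 20),
    stratum_age_hi = c(40, 40, 70),
    sex = c("female", "pooled", "pooled"),
    index_name = "sdnn_ms",
    mean = c(45, 44, 40),
    sd = c(15, 14, 16),
    n = c(20, 40, 300)))
}

# indices list carrying a single SDNN value
sdnn_only <- function(x) list(sdnn_ms = x)
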