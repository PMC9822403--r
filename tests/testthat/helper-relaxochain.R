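# shared fixtures built in code

table1 <- oil_table("table1")

# three perfectly collinear synthetic oils: CL = 50 * (R2/eta)
collinear_records <- data.frame(
  name = c("a", "b", "c"),
  chain_length = c(5, 10, 15),
  r2_over_eta = c(0.1, 0.2, 0.3),
  state = "liquid"
)

# a quick, small IR-CPMG acquisition for inversion tests: 300 echoes at
# 1 ms spacing extends the CPMG window to 300 ms at a fraction of the cost
fast_meta <- acquisition_defaults(echo_time_ms = 1, n_echoes = 300)

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected) / abs(expected)), tol)
}
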