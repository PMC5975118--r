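#!/usr/bin/env Rscript

# How far back does the synapse "remember" its stimulation history?
# Two measures of the dependence of the response on preceding ISIs, at 5 Hz
# (theta) and 50 Hz (gamma), control vs muscarine:
#   sum mode   — histogram MI between the stochastic response and the sum of
#                the k preceding ISIs, k = 1..8;
#   tuple mode — KSG k-nearest-neighbor MI between the deterministic
#                response and the ordered n-tuple of preceding ISIs, n = 1..6.
#
# Writes: results/history_mi_sum.csv, results/history_mi_tuple.csv

suppressPackageStartupMessages(library(fdsynapse))
dir.create("results", showWarnings = FALSE)
seed <- 20260922L
n <- 2^14
model <- response_model()

conditions <- list(control = fd_params("control"),
                   muscarine = fd_params("muscarine", delta = 1))

sum_rows <- list(); tup_rows <- list()
for (f in c(5, 50)) {
  for (cond in names(conditions)) {
    p <- conditions[[cond]]
    sum_rows[[paste(cond, f)]] <-
      as.data.frame(run_history_mi(p, f, "sum", max_depth = 8, model = model,
                                   n = n, seed = seed))
    tup_rows[[paste(cond, f)]] <-
      as.data.frame(run_history_mi(p, f, "tuple", max_depth = 6, n = n,
                                   seed = seed))
  }
}
sum_mi <- do.call(rbind, sum_rows)
tup_mi <- do.call(rbind, tup_rows)
write.csv(sum_mi, "results/history_mi_sum.csv", row.names = FALSE)
write.csv(tup_mi, "results/history_mi_tuple.csv", row.names = FALSE)

for (f in c(5, 50)) {
  s <- subset(sum_mi, frequency_hz == f)
  t <- subset(tup_mi, frequency_hz == f)
  ctrl_s <- s$mi_bits[s$condition == "control"]
  musc_s <- s$mi_bits[s$condition == "muscarine"]
  ctrl_t <- t$mi_nats[t$condition == "control"]
  musc_t <- t$mi_nats[t$condition == "muscarine"]
  message(sprintf(
    "%2d Hz sum mode: control falls %.3f -> %.3f bits over 8 ISIs; muscarine range %.3f bits",
    f, ctrl_s[1], ctrl_s[8], max(musc_s) - min(musc_s)))
  message(sprintf(
    "%2d Hz tuple mode: control peaks at depth %d; muscarine peaks at depth %d; control > muscarine at all depths: %s",
    f, which.max(ctrl_t), which.max(musc_t), all(ctrl_t > musc_t)))
}
message("wrote results/history_mi_sum.csv, results/history_mi_tuple.csv")
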