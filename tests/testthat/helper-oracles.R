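# Independent grid-search oracle for the isoelectric point: evaluates
# the Bjellqvist charge model on a 1e-4 pH grid and returns the grid
# point of minimal |net charge|.
pi_grid_oracle <- function(seq) {
  aa <- strsplit(seq, "")[[1]]
  nt_pka <- c(A = 7.59, M = 7.0, S = 6.93, P = 8.36, T = 6.82, V = 7.44,
              E = 7.7)[aa[1]]
  if (is.na(nt_pka)) nt_pka <- 7.5
  acidic <- c(D = 4.05, E = 4.45, C = 9.0, Y = 10.0)
  basic <- c(H = 5.98, K = 10.0, R = 12.0)
  ph <- seq(0, 14, by = 1e-4)
  q <- 1 / (1 + 10^(ph - nt_pka)) - 1 / (1 + 10^(3.55 - ph))
  for (a in names(basic)) {
    q <- q + sum(aa == a) / (1 + 10^(ph - basic[[a]]))
  }
  for (a in names(acidic)) {
    q <- q - sum(aa == a) / (1 + 10^(acidic[[a]] - ph))
  }
  ph[which.min(abs(q))]
}
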