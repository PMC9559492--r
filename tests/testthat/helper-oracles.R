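# Independent oracles used across tests. These deliberately avoid the
# package's own code paths.

# composite Simpson quadrature with n panels (n even)
simpson <- function(f, a, b, n = 1e5) {
  if (n %% 2 == 1) n <- n + 1
  x <- seq(a, b, length.out = n + 1)
  h <- (b - a) / n
  w <- c(1, rep(c(4, 2), length.out = n - 1), 1)
  sum(w * f(x)) * h / 3
}

# the 4PL mean function written out independently
fpl_oracle <- function(x, bottom, top, log_ec50, hill) {
  bottom + (top - bottom) / (1 + 10^((log_ec50 - x) * hill))
}

# pooled-variance two-sample t statistic by the explicit formula
pooled_t_oracle <- function(x1, x2) {
  n1 <- length(x1); n2 <- length(x2)
  sp2 <- ((n1 - 1) * var(x1) + (n2 - 1) * var(x2)) / (n1 + n2 - 2)
  (mean(x1) - mean(x2)) / sqrt(sp2 * (1 / n1 + 1 / n2))
}

# per-well HSA delta by exhaustive loops
hsa_oracle <- function(resp, da, db) {
  ia0 <- which(da == 0); ib0 <- which(db == 0)
  out <- matrix(NA_real_, length(da), length(db))
  for (i in seq_along(da)) for (j in seq_along(db)) {
    if (da[i] > 0 && db[j] > 0) {
      out[i, j] <- resp[i, j] - max(resp[i, ib0], resp[ia0, j])
    }
  }
  out
}

# spreadsheet-style ddCt recomputation
ddct_oracle <- function(tab, control) {
  per_sample <- do.call(rbind, lapply(split(tab, tab$sample), function(d) {
    data.frame(sample = d$sample[1], group = d$group[1],
               dct = mean(d$target_ct) - mean(d$reference_ct))
  }))
  ctrl <- mean(per_sample$dct[per_sample$group == control])
  per_sample$fold <- 2^(-(per_sample$dct - ctrl))
  per_sample[order(per_sample$sample), ]
}
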