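# shared fixtures: trait pairs and small goodness-of-fit utilities

pair <- function(rA = 1, rB = 1, cA = 1, cB = 1) {
  list(species_traits("A", rA, cA), species_traits("B", rB, cB))
}

# total-variation distance between an empirical sample of counts on 0..N and
# a probability vector over 0..N, both aggregated to `n_bins` equal bins (the
# package's histogram resolution); raw per-atom TV carries an O(sqrt(N/n))
# sampling bias that would swamp any real simulator discrepancy
tv_distance <- function(sample_counts, probs, N, n_bins = 20) {
  emp <- tabulate(sample_counts + 1L, nbins = N + 1L) / length(sample_counts)
  grp <- pmin(floor((0:N) / (N + 1) * n_bins) + 1L, n_bins)
  sum(abs(tapply(emp, grp, sum) - tapply(probs, grp, sum))) / 2
}

# chi-square GoF p-value of integer sample on 0..N against probs, pooling
# bins so that every expected count is >= 5
chisq_gof_p <- function(sample_counts, probs, N, min_expected = 5) {
  n <- length(sample_counts)
  obs <- tabulate(sample_counts + 1L, nbins = N + 1L)
  ord <- seq_len(N + 1L)
  # pool adjacent support points until expected >= min_expected
  grp <- integer(N + 1L)
  g <- 1L; acc <- 0
  for (i in ord) {
    grp[i] <- g
    acc <- acc + n * probs[i]
    if (acc >= min_expected) { g <- g + 1L; acc <- 0 }
  }
  if (acc > 0 && g > 1L) grp[grp == g] <- g - 1L  # merge trailing remainder
  o <- tapply(obs, grp, sum)
  e <- tapply(n * probs, grp, sum)
  stat <- sum((o - e)^2 / e)
  stats::pchisq(stat, df = length(o) - 1, lower.tail = FALSE)
}

# two-sample chi-square p-value on shared quantile bins of the pooled data
chisq_two_sample_p <- function(x, y, n_bins = 10) {
  br <- unique(stats::quantile(c(x, y), probs = seq(0, 1, length.out = n_bins + 1)))
  br[1] <- -Inf; br[length(br)] <- Inf
  tab <- rbind(table(cut(x, br)), table(cut(y, br)))
  tab <- tab[, colSums(tab) > 0, drop = FALSE]
  suppressWarnings(stats::chisq.test(tab)$p.value)
}
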