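# Independent oracles used across the suite. These deliberately use the
# slowest, most literal formulation of each quantity so they share no code
# path with the package implementation.

# O(N^2) direct-sum DFT: X(n) = sum_m x(m) exp(-i 2 pi n (m-1)/N), n = 1..floor(N/2)
brute_dft <- function(x) {
  n_total <- length(x)
  vapply(seq_len(n_total %/% 2), function(n) {
    sum(x * exp(-2i * pi * n * (seq_len(n_total) - 1) / n_total))
  }, complex(1))
}

brute_spectrum <- function(x) Mod(brute_dft(x))^2

# Exact two-sided Mann-Whitney p by full enumeration of all C(m+n, m)
# assignments of the pooled tie-free values to group A.
enumerate_mwu_p <- function(a, b) {
  pooled <- c(a, b)
  m <- length(a)
  u_of <- function(idx) {
    r <- rank(pooled)
    sum(r[idx]) - m * (m + 1) / 2
  }
  u_obs <- u_of(seq_len(m))
  all_u <- apply(utils::combn(length(pooled), m), 2, u_of)
  p <- 2 * min(mean(all_u <= u_obs), mean(all_u >= u_obs))
  min(1, p)
}

# Two-sided Fisher p for a 2x2 table by enumerating all tables with the
# observed margins and summing hypergeometric probabilities not exceeding
# the observed one (with the standard relative-tolerance guard).
enumerate_fisher_p <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  a_range <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(a_range, c1, n - c1, r1)
  p_obs <- stats::dhyper(tab[1, 1], c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

random_protein_string <- function(n) {
  paste(sample(names(eiip_scale()), n, replace = TRUE), collapse = "")
}

# small labeled variant table written to a temp file
write_toy_variant_table <- function(rows, path = tempfile(fileext = ".tsv")) {
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
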