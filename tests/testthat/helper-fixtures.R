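# adjusted Rand index between two label vectors
ari <- function(a, b) {
  tab <- table(a, b)
  A <- sum(choose(tab, 2))
  B <- sum(choose(rowSums(tab), 2))
  C <- sum(choose(colSums(tab), 2))
  D <- choose(sum(tab), 2)
  (A - B * C / D) / ((B + C) / 2 - B * C / D)
}

# tiny probe-level two-color table: `m` per-probe true log2 ratios, one array
toy_array <- function(m, array_id = "a1", bg_r = 0, bg_g = 0,
                      probe_id = sprintf("P%03d", seq_along(m)),
                      gene_symbol = probe_id) {
  a <- runif(length(m), 8, 14)
  tibble::tibble(
    array_id = array_id,
    probe_id = probe_id,
    gene_symbol = gene_symbol,
    red_fg = 2^(a + m / 2) + bg_r,
    green_fg = 2^(a - m / 2) + bg_g,
    red_bg = bg_r,
    green_bg = bg_g,
    outlier_flag = FALSE,
    control_flag = FALSE
  )
}

# brute-force Spearman: rank both vectors (average ties), then Pearson
spearman_oracle <- function(x, y) {
  stats::cor(rank(x), rank(y))
}

# brute-force mHG: minimum over prefixes of exact hypergeometric tail sums
mhg_oracle <- function(is_member) {
  N <- length(is_member)
  B <- sum(is_member)
  b <- cumsum(is_member)
  best <- Inf
  n_best <- NA
  for (n in seq_len(N - 1L)) {
    tail <- sum(vapply(b[n]:min(n, B), function(j) {
      choose(B, j) * choose(N - B, n - j) / choose(N, n)
    }, numeric(1)))
    if (tail < best - 1e-15) {
      best <- tail
      n_best <- n
    }
  }
  list(mhg = best, n_opt = n_best)
}

# naive O(m^2) BH oracle: adj_i = min over j with p_j >= p_i of m * p_j / rank_j
bh_oracle <- function(p) {
  m <- length(p)
  r <- rank(p, ties.method = "first")
  vapply(seq_len(m), function(i) {
    cand <- which(r >= r[i])
    min(1, min(m * p[cand] / r[cand]))
  }, numeric(1))
}
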