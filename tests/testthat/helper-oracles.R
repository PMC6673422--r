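# Independent brute-force oracles used across the suite. These deliberately
# re-derive quantities by direct enumeration, sharing no code with the
# package implementations they check.

# gray-level co-occurrence contrast/correlation by direct pair enumeration
oracle_glcm <- function(px, levels = 32L, offset = c(0L, 1L)) {
  q <- pmin(floor(px * levels), levels - 1) + 1L
  counts <- matrix(0, levels, levels)
  for (i in seq_len(nrow(q) - offset[1])) {
    for (j in seq_len(ncol(q) - offset[2])) {
      a <- q[i, j]; b <- q[i + offset[1], j + offset[2]]
      counts[a, b] <- counts[a, b] + 1
      counts[b, a] <- counts[b, a] + 1
    }
  }
  P <- counts / sum(counts)
  mu <- 0; for (l in seq_len(levels)) mu <- mu + l * sum(P[l, ])
  va <- 0; for (l in seq_len(levels)) va <- va + (l - mu)^2 * sum(P[l, ])
  contrast <- 0; corr <- 0
  for (a in seq_len(levels)) for (b in seq_len(levels)) {
    contrast <- contrast + P[a, b] * (a - b)^2
    corr <- corr + P[a, b] * (a - mu) * (b - mu)
  }
  list(contrast = contrast,
       correlation = if (va > 0) corr / va else 0)
}

# signed window area by a plain loop over samples
oracle_window_area <- function(signal, center_index, t) {
  ct <- signal$times[center_index]
  s <- 0
  for (i in seq_along(signal$values)) {
    if (signal$times[i] >= ct - t / 2 - 1e-9 &&
        signal$times[i] <= ct + t / 2 + 1e-9)
      s <- s + signal$values[i] * signal$sample_interval
  }
  s
}

# full locator oracle: scan for insertion-to-withdrawal transitions
# (bridging zeros), score each by the loop-based window area, pick the
# candidate minimal in |area|, earliest on ties
oracle_locate <- function(signal, t) {
  v <- signal$values
  cand <- integer(0)
  last_nz <- 0
  for (i in seq_along(v)) {
    if (v[i] == 0) next
    if (last_nz > 0 && v[last_nz] == 1 && v[i] == -1) cand <- c(cand, i)
    last_nz <- i
  }
  if (length(cand) == 0) return(list(time = NA_real_, score = NA_real_))
  areas <- vapply(cand, function(i) oracle_window_area(signal, i, t), numeric(1))
  best <- 1
  for (j in seq_along(areas)) if (abs(areas[j]) < abs(areas[best])) best <- j
  list(time = signal$times[cand[best]], score = areas[best])
}

# a random direction signal (values and irregular-but-even times optional)
random_signal <- function(seed, n_max = 1000) {
  withr::with_seed(seed, {
    n <- sample(20:n_max, 1)
    vals <- sample(c(-1, 0, 1), n, replace = TRUE,
                   prob = c(0.35, 0.2, 0.45))
    direction_signal(vals, sample_interval = 0.5)
  })
}
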