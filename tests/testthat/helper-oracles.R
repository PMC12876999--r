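# Independent brute-force oracles. These deliberately avoid the package's
# code paths: plain double loops and explicit run scans.

# maximal-run point count over a logical sequence; a run counts when it has
# at least l_min points or fills the whole sequence (border completion)
oracle_run_points <- function(cells, l_min) {
  total <- 0L
  run <- 0L
  L <- length(cells)
  for (idx in seq_len(L)) {
    if (cells[idx]) run <- run + 1L
    if (!cells[idx] || idx == L) {
      if (run > 0L && (run >= l_min || run == L)) total <- total + run
      run <- 0L
    }
  }
  total
}

oracle_rqa <- function(x, y, eps, l_min = 2L) {
  n <- length(x)
  m <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    m[i, j] <- sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2) <= eps
  R <- 0L
  for (i in seq_len(n - 1)) for (j in (i + 1):n) if (m[i, j]) R <- R + 1L
  det_pts <- 0L
  for (k in seq_len(n - 1)) {
    cells <- logical(n - k)
    for (i in seq_len(n - k)) cells[i] <- m[i, i + k]
    det_pts <- det_pts + oracle_run_points(cells, l_min)
  }
  h_pts <- 0L
  for (i in seq_len(n - 1)) h_pts <- h_pts + oracle_run_points(m[i, (i + 1):n], l_min)
  v_pts <- 0L
  for (j in 2:n) v_pts <- v_pts + oracle_run_points(m[seq_len(j - 1), j], l_min)
  list(R = R,
       rec = 100 * 2 * R / (n * (n - 1)),
       det = if (R > 0) 100 * det_pts / R else 0,
       lam = if (R > 0) 100 * (h_pts + v_pts) / (2 * R) else 0)
}

# minimum monotone-path cost by exhaustive enumeration (feasible up to ~6x6)
oracle_align_cost <- function(cost) {
  m <- nrow(cost); n <- ncol(cost)
  best <- Inf
  recurse <- function(i, j, acc) {
    acc <- acc + cost[i, j]
    if (acc >= best) return(invisible(NULL))
    if (i == m && j == n) {
      best <<- acc
      return(invisible(NULL))
    }
    if (i < m && j < n) recurse(i + 1, j + 1, acc)
    if (i < m) recurse(i + 1, j, acc)
    if (j < n) recurse(i, j + 1, acc)
  }
  recurse(1L, 1L, 0)
  best
}
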