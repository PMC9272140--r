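# Independent oracles used to pin expected values. These deliberately use
# naive from-scratch computation (full rescans, explicit enumeration) so they
# share no mechanics with the package implementations they check.

# Greedy maximal-window dispersion segmentation, recomputing the dispersion
# from scratch at every expansion step.
oracle_idt <- function(t, x, y, dispersion, min_dur, dt = 1) {
  n <- length(t)
  starts <- integer(0); ends <- integer(0)
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n) {
      disp <- diff(range(x[i:(j + 1L)])) + diff(range(y[i:(j + 1L)]))
      if (disp > dispersion) break
      j <- j + 1L
    }
    if (t[j] - t[i] + dt >= min_dur) {
      starts <- c(starts, i); ends <- c(ends, j)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  data.frame(onset_ms = t[starts], offset_ms = t[ends] + dt,
             x_deg = vapply(seq_along(starts),
                            function(k) mean(x[starts[k]:ends[k]]), numeric(1)),
             y_deg = vapply(seq_along(starts),
                            function(k) mean(y[starts[k]:ends[k]]), numeric(1)))
}

# Exact two-tailed signed-rank p by enumeration of all 2^n sign patterns.
oracle_signed_rank <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  stopifnot(n <= 14)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  grid <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Ws <- grid %*% r
  p <- min(1, 2 * min(mean(Ws <= W + 1e-9), mean(Ws >= W - 1e-9)))
  list(W = W, p = p)
}

# Exact two-tailed rank-sum p by enumeration of all C(n, na) rank
# assignments (handles ties through average ranks).
oracle_rank_sum <- function(a, b) {
  na <- length(a)
  r <- rank(c(a, b))
  U <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  combs <- utils::combn(length(r), na)
  Us <- apply(combs, 2, function(idx) sum(r[idx])) - na * (na + 1) / 2
  p <- min(1, 2 * min(mean(Us <= U + 1e-9), mean(Us >= U - 1e-9)))
  list(U = U, p = p)
}

# Interval union by brute force on a 1 ms grid.
oracle_interval_union <- function(onsets, offsets, lo, hi) {
  grid <- seq(lo, hi - 1)
  covered <- rep(FALSE, length(grid))
  for (k in seq_along(onsets))
    covered <- covered | (grid >= onsets[k] & grid < offsets[k])
  r <- rle(covered)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  data.frame(onset_ms = grid[starts[keep]], offset_ms = grid[ends[keep]] + 1)
}

# Random gaze-like trace: stationary dwells joined by fast sweeps, plus
# Gaussian jitter. Returns a sample-series data frame.
random_trace <- function(n, jitter_sd = 0.12, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- numeric(0); y <- numeric(0)
  px <- 0; py <- 0
  while (length(x) < n) {
    dwell <- sample(30:400, 1)
    x <- c(x, rep(px, dwell)); y <- c(y, rep(py, dwell))
    nx <- stats::runif(1, -10, 10); ny <- stats::runif(1, -10, 10)
    sweep <- sample(10:40, 1)
    fr <- seq_len(sweep) / (sweep + 1)
    x <- c(x, px + fr * (nx - px)); y <- c(y, py + fr * (ny - py))
    px <- nx; py <- ny
  }
  x <- x[seq_len(n)] + stats::rnorm(n, 0, jitter_sd)
  y <- y[seq_len(n)] + stats::rnorm(n, 0, jitter_sd)
  data.frame(session = "T", trial = 1L, t_ms = seq_len(n) - 1,
             x_deg = x, y_deg = y, pupil_au = 2000, valid = TRUE)
}
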