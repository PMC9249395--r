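# Independent oracles used across the suite. These deliberately take naive,
# brute-force routes so they share no code with the implementation.

# O(n^2) topographic prominence scan over every local maximum
brute_peaks <- function(h, frac = 0.1) {
  n <- length(h)
  if (n == 0 || max(h) <= 0 || all(h == h[1])) return(numeric(0))
  pos <- c()
  for (j in seq_len(n)) {
    left <- if (j > 1) h[j - 1] else -Inf
    right <- if (j < n) h[j + 1] else -Inf
    if (!(h[j] > left && h[j] >= right)) next
    drops <- c()
    for (dir in c(-1, 1)) {
      run <- if (dir < 0) rev(seq_len(j - 1)) else seq(j + 1, n, length.out = max(0, n - j))
      low <- h[j]; drop <- NA
      for (k in run) {
        if (h[k] > h[j]) { drop <- h[j] - low; break }
        low <- min(low, h[k])
      }
      if (is.na(drop)) drop <- h[j] - ifelse(length(run), min(h[c(j, run)]), h[j])
      drops <- c(drops, drop)
    }
    if (min(drops) >= frac * max(h)) pos <- c(pos, j)
  }
  pos
}

# alternating-minimization GPA written independently: rotation found by
# numeric optimization over the angle, consensus by averaging
brute_gpa <- function(arr, iters = 200) {
  n <- dim(arr)[3]
  for (j in seq_len(n)) {
    m <- arr[, , j]
    m <- sweep(m, 2, colMeans(m))
    arr[, , j] <- m / sqrt(sum(m^2))
  }
  consensus <- arr[, , 1]
  for (it in seq_len(iters)) {
    for (j in seq_len(n)) {
      m <- arr[, , j]
      obj <- function(theta) {
        R <- matrix(c(cos(theta), -sin(theta), sin(theta), cos(theta)), 2, 2)
        sum((m %*% R - consensus)^2)
      }
      cand <- sapply(seq(0, 2 * pi, length.out = 73), obj)
      th0 <- seq(0, 2 * pi, length.out = 73)[which.min(cand)]
      th <- stats::optimize(obj, c(th0 - 0.2, th0 + 0.2), tol = 1e-14)$minimum
      R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)
      arr[, , j] <- m %*% R
    }
    new_c <- apply(arr, c(1, 2), mean)
    new_c <- sweep(new_c, 2, colMeans(new_c))
    new_c <- new_c / sqrt(sum(new_c^2))
    if (sqrt(sum((new_c - consensus)^2)) < 1e-13) { consensus <- new_c; break }
    consensus <- new_c
  }
  list(arr = arr, consensus = consensus)
}

random_config <- function(k, seed) {
  set.seed(seed)
  tibble::tibble(id = paste0("cfg", seed), landmark = seq_len(k),
                 x = rnorm(k), y = rnorm(k))
}

# params for fast simulator unit tests (same kinetics, fewer iterations)
quick_params <- function(n_iter = 3000, ...)
  sim_params(n_iter = n_iter, label = "quick", ...)

rot2 <- function(theta)
  matrix(c(cos(theta), -sin(theta), sin(theta), cos(theta)), 2, 2)

template_outline_for_test <- function() cuspkit:::template_outline()
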