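# Independent oracles kept deliberately naive.

# exhaustive breadth-first-search connected components under 3D minimum image
bfs_cluster_sizes <- function(co, box, cutoff) {
  n <- nrow(co)
  if (n == 0L) return(integer(0))
  near <- function(i, j) {
    d <- co[i, ] - co[j, ]
    d <- d - box * round(d / box)
    sum(d^2) < cutoff^2
  }
  visited <- rep(FALSE, n)
  sizes <- integer(0)
  for (s in seq_len(n)) {
    if (visited[s]) next
    queue <- s
    visited[s] <- TRUE
    cnt <- 0L
    while (length(queue)) {
      v <- queue[1]
      queue <- queue[-1]
      cnt <- cnt + 1L
      for (j in seq_len(n)) {
        if (!visited[j] && near(v, j)) {
          visited[j] <- TRUE
          queue <- c(queue, j)
        }
      }
    }
    sizes <- c(sizes, cnt)
  }
  sizes
}

# von Mises sampler by discrete inverse-CDF on a fine grid -- independent of
# the package's rejection sampler
rvm_grid <- function(n, mu_deg, kappa) {
  g <- seq(-180, 180, by = 0.01)
  dens <- exp(kappa * cos((g - mu_deg) * pi / 180))
  sample(g, n, replace = TRUE, prob = dens)
}

# fold an angle (deg) into the polar range [0, 180]
fold180 <- function(x) {
  x <- abs(x %% 360)
  ifelse(x > 180, 360 - x, x)
}

# brute-force local-extrema scan over all grid points
scan_extrema <- function(z, d, floor) {
  out <- data.frame(z_nm = numeric(0), amplitude = numeric(0))
  for (i in seq_along(d)) {
    if (i == 1L || i == length(d)) next
    ismax <- d[i] > d[i - 1] && d[i] >= d[i + 1]
    ismin <- d[i] < d[i - 1] && d[i] <= d[i + 1]
    if ((ismax || ismin) && abs(d[i]) > floor)
      out <- rbind(out, data.frame(z_nm = z[i], amplitude = d[i]))
  }
  out[order(-abs(out$amplitude)), , drop = FALSE]
}
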