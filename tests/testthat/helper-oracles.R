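# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: brute-force enumeration, direct formulas, and a
# separately written dynamic program.

# Optimal contiguous k-partition SSE by exhaustive enumeration (small n).
brute_force_partition_sse <- function(x, k) {
  xs <- sort(x)
  n <- length(xs)
  cuts <- utils::combn(n - 1, k - 1)
  best <- Inf
  for (ci in seq_len(ncol(cuts))) {
    b <- c(0, cuts[, ci], n)
    s <- 0
    for (q in seq_len(k)) {
      seg <- xs[(b[q] + 1):(b[q + 1])]
      s <- s + sum((seg - mean(seg))^2)
    }
    if (s < best) best <- s
  }
  best
}

# Independent DP for the optimal contiguous partition: backward recursion
# over suffixes, vectorised over the split point (structured differently
# from the package's forward scalar DP).
oracle_dp_sse <- function(x, k) {
  xs <- sort(x)
  n <- length(xs)
  # sse of segment i..j via suffix sums
  S <- c(rev(cumsum(rev(xs))), 0)       # S[i] = sum xs[i..n]
  S2 <- c(rev(cumsum(rev(xs^2))), 0)
  seg <- function(i, j) {
    s <- S[i] - S[j + 1]
    s2 <- S2[i] - S2[j + 1]
    pmax(s2 - s^2 / (j - i + 1), 0)
  }
  # G[q, i]: best SSE splitting xs[i..n] into q parts
  G <- matrix(Inf, k, n + 1)
  G[1, 1:n] <- seg(1:n, n)
  for (q in 2:k) {
    for (i in 1:(n - q + 1)) {
      j <- i:(n - q + 1)
      G[q, i] <- min(seg(i, j) + G[q - 1, j + 1])
    }
  }
  G[k, 1]
}

# Brute-force peak alignment: over all 180 integer shifts, the one whose
# 10-degree modal bin centre lands closest to 90.
oracle_align <- function(angles, bin = 10) {
  best_shift <- 0
  best_dist <- Inf
  for (s in 0:179) {
    a <- (angles + s) %% 180
    counts <- tabulate(floor(a / bin) + 1L, nbins = 180 / bin)
    peak <- (which.max(counts) - 0.5) * bin
    d <- abs(peak - 90)
    if (d < best_dist) { best_dist <- d; best_shift <- s }
  }
  (angles + best_shift) %% 180
}

# Analytic ellipse specification helper for render-and-measure tests.
single_ellipse_image <- function(minor, ar, angle, g = 0.6, pixel = 0.05) {
  major <- minor * ar
  fs <- major + 4
  ell <- data.frame(x = fs / 2, y = fs / 2, minor = minor, major = major,
                    minor_inner = g * minor, major_inner = g * major,
                    angle_deg = angle)
  p <- tissue_params(field_size = fs, pixel_size = pixel)
  render_micrograph(ell, p)
}

# Uniform-axes profile aspect ratios by direct Monte Carlo (no package
# sampling code): u = cos(theta) uniform on [0,1] for isotropic axial
# directions; flux weighting accepts with probability u.
oracle_isotropic_ar <- function(n, flux = FALSE, cap = 10) {
  u <- runif(n)
  if (flux) {
    u <- u[runif(n) < u]
    while (length(u) < n) {
      u2 <- runif(n)
      u <- c(u, u2[runif(n) < u2])
    }
    u <- u[seq_len(n)]
  }
  pmin(1 / u, cap)
}
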