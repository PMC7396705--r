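# Shared fixtures and independent oracles, all built in code.

# Sierpinski carpet raster: depth k gives a 3^k x 3^k logical matrix.
sierpinski_carpet <- function(depth) {
  m <- matrix(TRUE, 1, 1)
  for (k in seq_len(depth)) {
    z <- matrix(FALSE, nrow(m), ncol(m))
    m <- rbind(cbind(m, m, m), cbind(m, z, m), cbind(m, m, m))
  }
  m
}

# Brute-force distribution-function evaluation: explicit double sum over all
# N^2 cells, with the Mahalanobis form computed via base solve() — fully
# independent of the package's kernel-evaluation path.
brute_force_phi <- function(df, z) {
  z <- as.matrix(z)
  out <- numeric(nrow(z))
  for (i in seq_len(df$grid$N)) {
    for (j in seq_len(df$grid$N)) {
      m <- df$cells[[i, j]]
      if (m$count == 0 || is.null(m$Sigma)) next
      P <- solve(m$Sigma)
      for (k in seq_len(nrow(z))) {
        d <- z[k, ] - m$centroid
        out[k] <- out[k] + m$count * exp(-0.5 * drop(t(d) %*% P %*% d))
      }
    }
  }
  out
}

# Naive window counting: nested loops over set pixels, no summed-area table.
brute_force_curve <- function(img, i_max) {
  pos <- which(img, arr.ind = TRUE)
  h <- nrow(img); w <- ncol(img)
  sapply(seq_len(i_max), function(i) {
    mean(apply(pos, 1, function(p) {
      rows <- max(1, p[1] - i):min(h, p[1] + i)
      cols <- max(1, p[2] - i):min(w, p[2] + i)
      sum(img[rows, cols])
    }))
  })
}

# Random point cloud on a disc (polar sampling), for property tests.
random_cloud <- function(n, radius = 1) {
  r <- radius * sqrt(runif(n))
  th <- runif(n, 0, 2 * pi)
  data.frame(x = r * cos(th), y = r * sin(th))
}
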