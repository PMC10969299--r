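# Independent polygon-area oracle: ear-clipping triangulation for the
# unsigned area plus orientation read off the extreme vertex, so neither part
# shares the shoelace path under test.
point_in_tri <- function(px, py, tx, ty) {
  d1 <- (px - tx[2]) * (ty[1] - ty[2]) - (tx[1] - tx[2]) * (py - ty[2])
  d2 <- (px - tx[3]) * (ty[2] - ty[3]) - (tx[2] - tx[3]) * (py - ty[3])
  d3 <- (px - tx[1]) * (ty[3] - ty[1]) - (tx[3] - tx[1]) * (py - ty[1])
  neg <- (d1 < 0) || (d2 < 0) || (d3 < 0)
  pos <- (d1 > 0) || (d2 > 0) || (d3 > 0)
  !(neg && pos)
}

signed_area_oracle <- function(x, y) {
  n <- length(x)
  i0 <- which(y == min(y)); i0 <- i0[which.max(x[i0])]
  ip <- if (i0 == 1) n else i0 - 1; nx <- if (i0 == n) 1 else i0 + 1
  cr <- (x[i0] - x[ip]) * (y[nx] - y[i0]) - (y[i0] - y[ip]) * (x[nx] - x[i0])
  sgn <- sign(cr)                       # +1 = counter-clockwise
  tri_area <- function(a, b, c)
    abs((x[b] - x[a]) * (y[c] - y[a]) - (x[c] - x[a]) * (y[b] - y[a])) / 2
  idx <- seq_len(n); area <- 0
  while (length(idx) > 3) {
    m <- length(idx); clipped <- FALSE
    for (j in seq_len(m)) {
      a <- idx[if (j == 1) m else j - 1]; b <- idx[j]
      cc <- idx[if (j == m) 1 else j + 1]
      cross <- (x[b] - x[a]) * (y[cc] - y[b]) - (y[b] - y[a]) * (x[cc] - x[b])
      if (sgn * cross <= 0) next        # reflex corner, not an ear
      others <- setdiff(idx, c(a, b, cc))
      if (any(vapply(others, function(k)
        point_in_tri(x[k], y[k], x[c(a, b, cc)], y[c(a, b, cc)]), TRUE))) next
      area <- area + tri_area(a, b, cc)
      idx <- idx[-j]; clipped <- TRUE; break
    }
    if (!clipped) stop("ear clipping failed")
  }
  area <- area + tri_area(idx[1], idx[2], idx[3])
  -sgn * area                           # clockwise-positive convention
}


# independent loop-based ReliefF oracle for a tiny matrix (k neighbours,
# Manhattan distance, equal-weight neighbours)
relieff_oracle <- function(x, y, k) {
  n <- nrow(x)
  rng <- apply(x, 2, range)
  xs <- sweep(sweep(x, 2, rng[1, ]), 2, pmax(rng[2, ] - rng[1, ], 1e-12), `/`)
  prior <- table(y) / n
  w <- numeric(ncol(x))
  for (i in 1:n) {
    d <- apply(abs(sweep(xs, 2, xs[i, ])), 1, sum)
    for (cl in unique(y)) {
      pool <- setdiff(which(y == cl), i)
      nb <- pool[order(d[pool])][1:k]
      for (f in seq_len(ncol(x))) {
        diffs <- mean(abs(xs[nb, f] - xs[i, f]))
        if (cl == y[i]) w[f] <- w[f] - diffs / n
        else w[f] <- w[f] + (prior[[cl]] / (1 - prior[[y[i]]])) * diffs / n
      }
    }
  }
  w
}

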