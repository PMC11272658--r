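# Independent brute-force oracles used across the suite.

# 3x3 median filter on a binary matrix, zero-padded, triple loop
oracle_median3 <- function(mask) {
  m <- (mask != 0) * 1L
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(FALSE, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      vals <- integer(0)
      for (di in -1:1) for (dj in -1:1) {
        ii <- i + di; jj <- j + dj
        vals <- c(vals, if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc) {
          m[ii, jj]
        } else {
          0L
        })
      }
      out[i, j] <- stats::median(vals) >= 0.5
    }
  }
  out
}

# 8-connected component labeling by flood fill (stack-based)
oracle_label8 <- function(mask) {
  m <- mask != 0
  nr <- nrow(m); nc <- ncol(m)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (start in which(m)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    stack <- start
    while (length(stack)) {
      p <- stack[length(stack)]
      stack <- stack[-length(stack)]
      if (lab[p] != 0L) next
      lab[p] <- cur
      i <- (p - 1L) %% nr + 1L
      j <- (p - 1L) %/% nr + 1L
      for (di in -1:1) for (dj in -1:1) {
        ii <- i + di; jj <- j + dj
        if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc) {
          q <- (jj - 1L) * nr + ii
          if (m[q] && lab[q] == 0L) stack <- c(stack, q)
        }
      }
    }
  }
  lab
}

# do two labelings define the same partition of foreground pixels?
same_partition <- function(a, b) {
  fg <- a > 0
  if (!identical(fg, b > 0)) return(FALSE)
  key <- paste(a[fg], b[fg])
  length(unique(key)) == max(a) && max(a) == max(b)
}

# exact two-sided Mann-Whitney p by enumeration of group assignments
oracle_mw_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combos <- utils::combn(nx + ny, nx)
  u_all <- apply(combos, 2, function(idx) sum(r[idx]) - nx * (nx + 1) / 2)
  mu <- nx * ny / 2
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}

# draw a binary mask with given foreground density
random_mask <- function(nr, nc, p = 0.4) {
  matrix(stats::runif(nr * nc) < p, nr, nc)
}

# rasterize one ellipse on a zero background (ground-truth pixel set)
draw_ellipse_mask <- function(nr, nc, cx, cy, a, b, alpha = 0, px = 1) {
  cols <- matrix(rep((seq_len(nc) - 0.5) * px, each = nr), nr, nc)
  rows <- matrix(rep((seq_len(nr) - 0.5) * px, nc), nr, nc)
  x <- cols - cx; y <- rows - cy
  u <- (x * cos(alpha) + y * sin(alpha)) / a
  w <- (-x * sin(alpha) + y * cos(alpha)) / b
  u^2 + w^2 <= 1
}
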