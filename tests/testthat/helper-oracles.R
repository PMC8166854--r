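# Independent brute-force oracles: deliberately written as plain loops,
# sharing no code with the implementation they check.

oracle_median_filter <- function(img, n) {
  j <- nrow(img)
  k <- ncol(img)
  h <- (n - 1) / 2
  out <- img
  for (r in 1:j) {
    for (c in 1:k) {
      vals <- c()
      for (dr in -h:h) {
        for (dc in -h:h) {
          rr <- min(max(r + dr, 1), j)
          cc <- min(max(c + dc, 1), k)
          vals <- c(vals, img[rr, cc])
        }
      }
      out[r, c] <- median(vals)
    }
  }
  out
}

oracle_total_variation <- function(img) {
  j <- nrow(img)
  k <- ncol(img)
  s <- 0
  for (r in 1:j) {
    for (c in 1:k) {
      gx <- if (c < k) img[r, c + 1] - img[r, c] else 0
      gy <- if (r < j) img[r + 1, c] - img[r, c] else 0
      s <- s + sqrt(gx^2 + gy^2)
    }
  }
  s
}

oracle_mean_filter <- function(img, n) {
  j <- nrow(img)
  k <- ncol(img)
  h <- (n - 1) / 2
  out <- img
  for (r in 1:j) {
    for (c in 1:k) {
      vals <- c()
      for (dr in -h:h) {
        for (dc in -h:h) {
          rr <- min(max(r + dr, 1), j)
          cc <- min(max(c + dc, 1), k)
          vals <- c(vals, img[rr, cc])
        }
      }
      m <- mean(vals)
      out[r, c] <- sign(m) * floor(abs(m) + 0.5)
    }
  }
  out
}

# 1D Otsu by exhaustive scan, computing the two-class variance directly
# from the raw pixel values at every candidate threshold.
oracle_otsu_1d <- function(img) {
  v <- as.vector(img)
  best <- -Inf
  best_s <- NA
  for (s in 1:255) {
    lo <- v[v < s]
    hi <- v[v >= s]
    if (length(lo) == 0 || length(hi) == 0) next
    w0 <- length(lo) / length(v)
    w1 <- 1 - w0
    sb <- w0 * w1 * (mean(lo) - mean(hi))^2
    if (sb > best) {
      best <- sb
      best_s <- s
    }
  }
  best_s
}

# 2D Otsu by exhaustive double loop over (s,t), with class sums computed
# directly from the joint probability matrix by submatrix summation.
oracle_otsu_2d <- function(g, h) {
  L <- max(g, h)
  p <- matrix(0, L + 1, L + 1)
  for (i in seq_along(g)) {
    p[g[i] + 1, h[i] + 1] <- p[g[i] + 1, h[i] + 1] + 1
  }
  p <- p / length(g)
  iv <- 0:L
  mu_ti <- sum(outer(iv, rep(1, L + 1)) * p)
  mu_tj <- sum(outer(rep(1, L + 1), iv) * p)
  best <- -Inf
  best_st <- c(NA, NA)
  for (s in 1:L) {
    for (t in 1:L) {
      # class 0 = {g < s, h < t}, matching the g >= S binarization
      sub <- p[1:s, 1:t, drop = FALSE]
      w0 <- sum(sub)
      if (w0 <= 0 || w0 >= 1) next
      mi <- sum(outer(0:(s - 1), rep(1, t)) * sub)
      mj <- sum(outer(rep(1, s), 0:(t - 1)) * sub)
      tr <- ((mu_ti * w0 - mi)^2 + (mu_tj * w0 - mj)^2) / (w0 * (1 - w0))
      if (tr > best + 1e-12) {
        best <- tr
        best_st <- c(s, t)
      }
    }
  }
  best_st
}

# Connected-component labeling by explicit queue-based flood fill.
oracle_label <- function(mask, connectivity = 8) {
  j <- nrow(mask)
  k <- ncol(mask)
  lab <- matrix(0L, j, k)
  cur <- 0L
  offs <- if (connectivity == 8) {
    list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1), c(0, 1), c(1, -1), c(1, 0), c(1, 1))
  } else {
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  }
  for (r0 in 1:j) {
    for (c0 in 1:k) {
      if (mask[r0, c0] == 1 && lab[r0, c0] == 0L) {
        cur <- cur + 1L
        queue <- list(c(r0, c0))
        lab[r0, c0] <- cur
        while (length(queue)) {
          cell <- queue[[1]]
          queue <- queue[-1]
          for (o in offs) {
            rr <- cell[1] + o[1]
            cc <- cell[2] + o[2]
            if (rr >= 1 && rr <= j && cc >= 1 && cc <= k &&
              mask[rr, cc] == 1 && lab[rr, cc] == 0L) {
              lab[rr, cc] <- cur
              queue[[length(queue) + 1]] <- c(rr, cc)
            }
          }
        }
      }
    }
  }
  lab
}

# Hole filling by flood fill of the background from the border.
oracle_fill <- function(mask) {
  j <- nrow(mask)
  k <- ncol(mask)
  outside <- matrix(FALSE, j, k)
  queue <- list()
  for (r in 1:j) {
    for (c in 1:k) {
      if ((r == 1 || r == j || c == 1 || c == k) && mask[r, c] == 0) {
        queue[[length(queue) + 1]] <- c(r, c)
        outside[r, c] <- TRUE
      }
    }
  }
  while (length(queue)) {
    cell <- queue[[1]]
    queue <- queue[-1]
    for (o in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      rr <- cell[1] + o[1]
      cc <- cell[2] + o[2]
      if (rr >= 1 && rr <= j && cc >= 1 && cc <= k &&
        mask[rr, cc] == 0 && !outside[rr, cc]) {
        outside[rr, cc] <- TRUE
        queue[[length(queue) + 1]] <- c(rr, cc)
      }
    }
  }
  out <- mask
  out[mask == 0 & !outside] <- 1
  out
}

# Random uint8 test image with a controllable value range.
random_uint8 <- function(j, k, max_val = 255) {
  matrix(sample(0:max_val, j * k, replace = TRUE), j, k)
}

# A centred rasterized disk mask.
disk_mask <- function(j, k, cy, cx, r) {
  rows <- matrix(seq_len(j), j, k)
  cols <- matrix(seq_len(k), j, k, byrow = TRUE)
  ((rows - cy)^2 + (cols - cx)^2 <= r^2) * 1
}
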