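# Brute-force oracles, independent of the package implementations.

reflect_oracle <- function(i, n) {
  while (i < 1 || i > n) {
    if (i < 1) i <- 1 - i
    if (i > n) i <- 2 * n + 1 - i
  }
  i
}

# exact EDT with the one-pixel virtual background ring convention
brute_edt <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(0L, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- mask
  bg <- which(pad == 0L, arr.ind = TRUE)
  out <- matrix(0, nr, nc)
  fg <- which(mask == 1L, arr.ind = TRUE)
  if (nrow(fg) > 0) {
    for (k in seq_len(nrow(fg))) {
      dr <- bg[, 1] - (fg[k, 1] + 1)
      dc <- bg[, 2] - (fg[k, 2] + 1)
      out[fg[k, 1], fg[k, 2]] <- sqrt(min(dr * dr + dc * dc))
    }
  }
  out
}

brute_local_mean <- function(x, block) {
  h <- block %/% 2
  nr <- nrow(x); nc <- ncol(x)
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    s <- 0
    for (a in (i - h):(i + h)) for (b in (j - h):(j + h))
      s <- s + x[reflect_oracle(a, nr), reflect_oracle(b, nc)]
    out[i, j] <- s / block^2
  }
  out
}

brute_median_reflect <- function(x, k) {
  h <- k %/% 2
  nr <- nrow(x); nc <- ncol(x)
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    vals <- numeric(k * k)
    t <- 0
    for (a in (i - h):(i + h)) for (b in (j - h):(j + h)) {
      t <- t + 1
      vals[t] <- x[reflect_oracle(a, nr), reflect_oracle(b, nc)]
    }
    out[i, j] <- stats::median(vals)
  }
  out
}

brute_box_count <- function(mask, s) {
  nr <- nrow(mask); nc <- ncol(mask)
  cnt <- 0L
  for (i0 in seq(1, nr, by = s)) for (j0 in seq(1, nc, by = s)) {
    if (any(mask[i0:min(i0 + s - 1, nr), j0:min(j0 + s - 1, nc)] == 1L))
      cnt <- cnt + 1L
  }
  cnt
}

# connected-component count by BFS (conn = 4 or 8)
count_components <- function(mask, conn = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  seen <- matrix(FALSE, nr, nc)
  if (conn == 8) {
    dr <- c(-1, -1, -1, 0, 0, 1, 1, 1); dc <- c(-1, 0, 1, -1, 1, -1, 0, 1)
  } else {
    dr <- c(-1, 1, 0, 0); dc <- c(0, 0, -1, 1)
  }
  n <- 0L
  for (si in seq_len(nr)) for (sj in seq_len(nc)) {
    if (mask[si, sj] != 1L || seen[si, sj]) next
    n <- n + 1L
    stack <- list(c(si, sj)); seen[si, sj] <- TRUE
    while (length(stack) > 0) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (q in seq_along(dr)) {
        a <- p[1] + dr[q]; b <- p[2] + dc[q]
        if (a >= 1 && a <= nr && b >= 1 && b <= nc &&
            mask[a, b] == 1L && !seen[a, b]) {
          seen[a, b] <- TRUE
          stack[[length(stack) + 1]] <- c(a, b)
        }
      }
    }
  }
  n
}

# number of 8-neighbours of each foreground pixel
neighbour_counts <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(0L, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- mask
  s <- matrix(0L, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    s <- s + pad[2:(nr + 1) + dr, 2:(nc + 1) + dc]
  }
  s[mask == 0L] <- 0L
  s
}

# single straight tube phantom of radius r on a square frame
tube_phantom <- function(r, shape = c(256, 256), seed = 3, sigma = 0.02) {
  margin <- 30
  tree <- structure(list(segments = list(list(
    vertices = cbind(x = c(margin, shape[2] - margin),
                     y = c(shape[1] / 2, shape[1] / 2), r = c(r, r)),
    parent = NA_integer_, region = "control")), image_shape = shape),
    class = "vessel_tree")
  vessel_phantom(tree = tree, image_shape = shape, seed = seed,
                 noise_params = list(sigma = sigma),
                 intensity_params = list(tumor_factor = 0))
}

random_mask <- function(nr, nc, p = 0.4) {
  matrix(as.integer(stats::runif(nr * nc) < p), nr, nc)
}
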