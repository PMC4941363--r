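# Independent brute-force oracles. Deliberately naive: every one of these is
# an exhaustive per-pixel / per-pair computation with no shared code with the
# package's operators.

# grayscale opening with a flat disc: exhaustive min-then-max over the full
# set of disc offsets on an Inf/-Inf padded copy (no separable decomposition)
oracleOpening <- function(img, radius) {
  nr <- nrow(img); nc <- ncol(img)
  offs <- expand.grid(dr = -radius:radius, dc = -radius:radius)
  offs <- offs[offs$dr^2 + offs$dc^2 <= radius^2, ]
  sweep1 <- function(src, fun, init) {
    padded <- matrix(init, nr + 2 * radius, nc + 2 * radius)
    padded[radius + seq_len(nr), radius + seq_len(nc)] <- src
    out <- matrix(init, nr, nc)
    for (k in seq_len(nrow(offs))) {
      sub <- padded[radius + offs$dr[k] + seq_len(nr),
                    radius + offs$dc[k] + seq_len(nc)]
      out <- fun(out, sub)
    }
    out
  }
  er <- sweep1(img, pmin, Inf)
  sweep1(er, pmax, -Inf)
}

# local mean over window x window with symmetric mirror reflection,
# computed by explicit padding and full shift-and-add over all offsets
oracleLocalMean <- function(img, window) {
  nr <- nrow(img); nc <- ncol(img)
  k <- (window - 1) / 2
  refl1 <- function(i, n) {
    while (i < 1 || i > n) {
      if (i < 1) i <- 1 - i
      if (i > n) i <- 2 * n + 1 - i
    }
    i
  }
  ri <- vapply((1 - k):(nr + k), refl1, numeric(1), n = nr)
  ci <- vapply((1 - k):(nc + k), refl1, numeric(1), n = nc)
  padded <- img[ri, ci]
  acc <- matrix(0, nr, nc)
  for (di in 0:(window - 1)) for (dj in 0:(window - 1))
    acc <- acc + padded[di + seq_len(nr), dj + seq_len(nc)]
  acc / window^2
}

# contested dilation: for every pixel, the exhaustive minimum squared
# distance to each nucleus' pixels; assign nearest within radius, ties to
# the lower label
oracleNearestSeed <- function(labels, radius) {
  nr <- nrow(labels); nc <- ncol(labels)
  labs <- sort(unique(labels[labels > 0]))
  pix <- lapply(labs, function(L) which(labels == L, arr.ind = TRUE))
  out <- matrix(0L, nr, nc)
  r2 <- radius^2
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    bestD <- Inf; bestL <- 0L
    for (k in seq_along(labs)) {
      p <- pix[[k]]
      d <- min((p[, 1] - i)^2 + (p[, 2] - j)^2)
      if (d < bestD) { bestD <- d; bestL <- labs[k] }  # strict: lower label wins ties
    }
    if (bestD <= r2) out[i, j] <- bestL
  }
  out
}

# exhaustive average-linkage (UPGMA) agglomeration on rows of a matrix:
# cluster distance = mean of all member pairwise Euclidean distances,
# merge the global minimum each step (ties: lexicographically first pair)
oracleUPGMA <- function(mat) {
  d <- as.matrix(dist(mat))
  clusters <- as.list(seq_len(nrow(mat)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (a in seq_along(clusters)) for (b in seq_along(clusters)) {
      if (a >= b) next
      dd <- mean(d[clusters[[a]], clusters[[b]]])
      if (dd < best[1]) best <- c(dd, a, b)
    }
    heights <- c(heights, best[1])
    clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters[[best[3]]] <- NULL
  }
  heights
}

# disc mask fixture: logical matrix with discs at the given (row, col,
# radius) triples (1-based centers)
discMask <- function(nr, nc, discs) {
  m <- matrix(FALSE, nr, nc)
  for (k in seq_len(nrow(discs))) {
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
      if ((i - discs[k, 1])^2 + (j - discs[k, 2])^2 <= discs[k, 3]^2)
        m[i, j] <- TRUE
    }
  }
  m
}

# mask-algebra invariants that must hold after every segmentation stage
expectMaskAlgebra <- function(seg) {
  nm <- nuclearMask(seg); cm <- cellMask(seg)
  expect_identical(sort(unique(nm[nm > 0])), sort(unique(cm[cm > 0])))
  expect_true(all(cm[nm > 0] == nm[nm > 0]))  # nucleus subset of own cell
  labs <- unique(nm[nm > 0])
  if (length(labs))
    expect_identical(sort(labs), seq_along(labs))  # contiguous 1..N
}

# small zero-noise simulator config for measurement-exactness fixtures
quietConfig <- function(conds, ...) {
  plateSimConfig(conds, readNoiseSd = 0, shotScale = 0, background = 0,
                 backgroundGradient = 0, cellCv = 0, ratioCv = 0, ...)
}
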