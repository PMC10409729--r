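# Independent brute-force oracles and small shared fixtures. These
# deliberately avoid the package's C++ kernels: the MIND oracle works
# on explicitly zero-padded arrays with plain R index arithmetic, and
# the contour-distance oracle enumerates all point pairs.

# MIND descriptor by direct patch sums on a zero-padded copy
brute_mind <- function(v) {
  dm <- dim(v)
  P <- array(0, dm + 4L)
  P[3:(dm[1] + 2L), 3:(dm[2] + 2L), 3:(dm[3] + 2L)] <- v
  disp <- list(c(-1L, 0L, 0L), c(1L, 0L, 0L), c(0L, -1L, 0L),
               c(0L, 1L, 0L), c(0L, 0L, -1L), c(0L, 0L, 1L))
  core <- function(off) {
    P[(3L + off[1]):(dm[1] + 2L + off[1]),
      (3L + off[2]):(dm[2] + 2L + off[2]),
      (3L + off[3]):(dm[3] + 2L + off[3])]
  }
  D <- array(0, c(dm, 6L))
  for (r in 1:6) {
    acc <- array(0, dm)
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      d <- c(dx, dy, dz)
      acc <- acc + (core(d) - core(d + disp[[r]]))^2
    }
    D[, , , r] <- acc / 27
  }
  eps <- max(1e-6 * diff(range(v))^2, 1e-12)
  V <- pmax(apply(D, 1:3, mean), eps)
  E <- exp(-D / array(V, c(dm, 6L)))
  E / array(apply(E, 1:3, max), c(dm, 6L))
}

# all-pairs contour distances (mm)
brute_contour_metrics <- function(U, C) {
  du <- apply(U@points, 1, function(p)
    min(sqrt(colSums((t(C@points) - p)^2))))
  dc <- apply(C@points, 1, function(p)
    min(sqrt(colSums((t(U@points) - p)^2))))
  list(hd = max(max(du), max(dc)), mcd = mean(c(du, dc)))
}

# random blob mask for contour tests
random_blob <- function(n1, n2, seed) {
  set.seed(seed)
  cx <- runif(1, n1 * 0.3, n1 * 0.7)
  cy <- runif(1, n2 * 0.3, n2 * 0.7)
  rx <- runif(1, n1 * 0.12, n1 * 0.25)
  ry <- runif(1, n2 * 0.12, n2 * 0.25)
  ang <- runif(1, 0, pi)
  g <- expand.grid(x = seq_len(n1), y = seq_len(n2))
  xr <- (g$x - cx) * cos(ang) + (g$y - cy) * sin(ang)
  yr <- -(g$x - cx) * sin(ang) + (g$y - cy) * cos(ang)
  matrix(as.numeric((xr / rx)^2 + (yr / ry)^2 <= 1), n1, n2)
}

# one small cached phantom with a breathing sequence, shared by tests
local_phantom <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ph <- makeCTPhantom(phantomSpec(), seed = 11)
      resp <- respirationModel(period = 8,
                               translationAmplitude = c(0.3, 1, 4),
                               rotationAmplitude = c(1, 0.4, 0.4))
      sm <- simulateUSSequence(ph$ct, ph$mask, resp, nFrames = 12,
                               seed = 12)
      cache <<- list(ct = ph$ct, mask = ph$mask, sample = sm,
                     ctFmap = featureMap(voxels(ph$mask),
                                         spacing = voxelSpacing(ph$mask),
                                         modality = "CT"))
    }
    cache
  }
})

# canonical window pair built from the cached phantom
local_window_pair <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      px <- local_phantom()
      sp <- voxelSpacing(px$ct)[2:3]
      wins <- windowUS(px$sample@usFrames[1:5], 5L, spacing = sp)
      fwins <- windowUS(px$sample@usMasks[1:5], 5L, spacing = sp)
      cache <<- makeWindowPair(px$ct, px$ctFmap, wins[[1]], fwins[[1]])
    }
    cache
  }
})

rand_transform <- function(rotSd = 0.3, transSd = 4, centre = c(0, 0, 0)) {
  rigidTransform(rotation = rnorm(3, 0, rotSd),
                 translation = rnorm(3, 0, transSd), centre = centre)
}
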