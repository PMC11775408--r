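# In-code fixtures and independent oracles shared across tests.

# digital ball: voxel centre inside radius r_mm, isotropic spacing h
ball_mask <- function(r_mm, h, margin = 2L) {
  n <- 2L * ceiling(r_mm / h) + 2L * margin + 1L
  c0 <- (n - 1) / 2
  ax <- (seq_len(n) - 1 - c0) * h
  d2 <- outer(outer(ax^2, ax^2, "+"), ax^2, "+")
  lesion_mask(d2 <= r_mm^2, rep(h, 3), label = sprintf("ball%g", r_mm))
}

# axis-aligned filled cube of side s_mm
cube_mask <- function(s_mm, h, margin = 2L) {
  k <- round(s_mm / h)
  n <- k + 2L * margin
  g <- array(FALSE, c(n, n, n))
  g[margin + seq_len(k), margin + seq_len(k), margin + seq_len(k)] <- TRUE
  lesion_mask(g, rep(h, 3), label = "cube")
}

# straight 1-voxel rod of given length (voxels)
rod_mask <- function(len, h = 1) {
  g <- array(FALSE, c(len + 4L, 5L, 5L))
  g[2 + seq_len(len), 3, 3] <- TRUE
  lesion_mask(g, rep(h, 3), label = "rod")
}

# naive triple-loop box counter over a voxel index set (oracle for the fast
# hashed counter); origin at the minimal index
naive_box_count <- function(idx, s) {
  lo <- apply(idx, 2, min)
  cells <- floor(sweep(idx, 2, lo) / s)
  hi <- apply(cells, 2, max)
  cnt <- 0L
  for (cx in 0:hi[1]) for (cy in 0:hi[2]) for (cz in 0:hi[3]) {
    hit <- any(cells[, 1] == cx & cells[, 2] == cy & cells[, 3] == cz)
    if (hit) cnt <- cnt + 1L
  }
  cnt
}

# brute-force Wilcoxon signed-rank two-sided p by full enumeration of the 2^n
# sign assignments (symmetric-tail definition, mid-ranks for ties)
brute_wilcoxon_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  Tsum <- sum(r)
  obs <- sum(r[d > 0])
  hits <- 0L
  for (m in 0:(2^n - 1)) {
    signs <- bitwAnd(bitwShiftR(m, 0:(n - 1)), 1L)
    wp <- sum(r[signs == 1L])
    if (abs(wp - Tsum / 2) >= abs(obs - Tsum / 2) - 1e-9) hits <- hits + 1L
  }
  hits / 2^n
}

# brute-force flood fill with selectable connectivity (oracle for component
# labelling)
flood_components <- function(grid, connectivity = 26) {
  d <- dim(grid)
  lab <- array(0L, d)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  if (connectivity == 6) offs <- offs[rowSums(abs(offs)) == 1, ]
  nxt <- 0L
  for (i in which(grid & lab == 0L)) {
    if (lab[i] != 0L) next
    nxt <- nxt + 1L
    queue <- i
    lab[i] <- nxt
    while (length(queue)) {
      j <- queue[[1]]; queue <- queue[-1]
      z <- (j - 1) %/% (d[1] * d[2]); rem <- (j - 1) %% (d[1] * d[2])
      y <- rem %/% d[1]; x <- rem %% d[1]
      for (k in seq_len(nrow(offs))) {
        p <- c(x, y, z) + offs[k, ]
        if (any(p < 0) || any(p >= d)) next
        jj <- 1 + p[1] + d[1] * (p[2] + d[2] * p[3])
        if (grid[jj] && lab[jj] == 0L) { lab[jj] <- nxt; queue <- c(queue, jj) }
      }
    }
  }
  lab
}

scratch_nifti <- function(arr, spacing, dir = tempdir()) {
  path <- tempfile(fileext = ".nii.gz", tmpdir = dir)
  img <- RNifti::asNifti(arr)
  aff <- diag(4); aff[1:3, 1:3] <- diag(spacing, 3)
  xf <- structure(aff, code = 2L)
  img <- RNifti::`sform<-`(img, xf)
  RNifti::writeNifti(img, path)
  path
}
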