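# fixtures are built in code; nothing binary ships with the package

rand_volume <- function(dims = c(6, 5, 4), tl = 10, seed = 1, tr = 2.5) {
  set.seed(seed)
  new("Volume4D",
      data = array(rnorm(prod(dims) * tl), dim = c(dims, tl)),
      voxelSize = c(3, 3, 3), affine = diag(c(3, 3, 3, 1)), tr = tr)
}

rand_mask <- function(dims = c(6, 5, 4), p = 0.5, seed = 2) {
  set.seed(seed)
  new("Mask3D", data = array(runif(prod(dims)) < p, dim = dims),
      affine = diag(c(3, 3, 3, 1)))
}

full_mask <- function(dims = c(6, 5, 4)) {
  new("Mask3D", data = array(TRUE, dim = dims),
      affine = diag(c(3, 3, 3, 1)))
}

# independent dense-eigendecomposition oracle for the R+1 centrality
dense_ecm_oracle <- function(y) {
  r1 <- stats::cor(t(y)) + 1
  e <- eigen(r1, symmetric = TRUE)
  v <- e$vectors[, 1L]
  v * sign(sum(v))
}

# independent breadth-first flood fill for 3D component labelling
flood_fill_labels <- function(mask3d, connectivity = 26L) {
  d <- dim(mask3d)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  nz <- rowSums(abs(offs))
  offs <- offs[nz > 0 & nz <= switch(as.character(connectivity),
                                     "6" = 1, "18" = 2, "26" = 3), ]
  labels <- array(0L, dim = d)
  nxt <- 0L
  for (start in which(mask3d)) {
    if (labels[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    labels[start] <- nxt
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      co <- arrayInd(v, d)
      for (o in seq_len(nrow(offs))) {
        cc <- co + offs[o, ]
        if (any(cc < 1L) || any(cc > d)) next
        w <- (cc[3L] - 1L) * d[1L] * d[2L] + (cc[2L] - 1L) * d[1L] + cc[1L]
        if (mask3d[w] && labels[w] == 0L) {
          labels[w] <- nxt
          queue <- c(queue, w)
        }
      }
    }
  }
  labels
}

# tiny two-network cohort configuration used across heavier tests
small_cfg <- function(seed, effect = 0L, nPerGroup = 8L) {
  synthConfig(grid = c(10L, 10L, 6L), nTime = 40L, nNetworks = 2L,
              blobWidth = 1.5, nPerGroup = nPerGroup,
              effectNetwork = as.integer(effect), seed = as.integer(seed))
}
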