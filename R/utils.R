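# internal helpers shared across modules

# column-major linear index of (x,y,z) rows within a grid
lin_index <- function(xyz, grid) {
  (as.integer(xyz[, 3L]) - 1L) * grid[1L] * grid[2L] +
    (as.integer(xyz[, 2L]) - 1L) * grid[1L] + as.integer(xyz[, 1L])
}

# affine comparison with tolerance for last-digit header noise
same_grid <- function(dimA, affA, dimB, affB, tol = 1e-4) {
  if (!all(dimA == dimB)) return(FALSE)
  scale <- max(abs(affA), abs(affB), 1)
  all(abs(affA - affB) <= tol * scale)
}

stop_shape <- function(...) stop(sprintf(...), call. = FALSE)

# derive a stream of per-subject seeds below 2^31 from one master seed
derive_seeds <- function(master, n, stream = 0L) {
  (as.integer(master) + 10007L * stream + 271L * seq_len(n)) %% 2147483629L
}
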