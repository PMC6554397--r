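# shared geometries and independent oracles used across the suite

default_geometry <- function(width_um = 500) {
  channel_geometry(cm_to_m(1), um_to_m(width_um), um_to_m(90))
}

# velocity that realizes a given Peclet number in a geometry
velocity_for_pe <- function(pe, geometry, D = D_SWIM) {
  pe * D * geometry$length / geometry$height^2
}

# brute-force binary morphology with the same disc footprint as the
# implementation's brush: dilation ORs, erosion ANDs over the offsets.
# Independent of EBImage's morphology code path (plain shifts in R).
brute_closing <- function(mask, radius = 5) {
  brush <- EBImage::makeBrush(2 * radius + 1, shape = "disc")
  off <- which(brush == 1, arr.ind = TRUE) - (radius + 1)
  nx <- nrow(mask); ny <- ncol(mask)
  pad <- radius
  shift_apply <- function(m, combine, init) {
    big <- matrix(init, nx + 2 * pad, ny + 2 * pad)
    big[pad + seq_len(nx), pad + seq_len(ny)] <- m
    out <- matrix(combine == "or", nx + 2 * pad, ny + 2 * pad)
    out[] <- if (combine == "or") FALSE else TRUE
    for (k in seq_len(nrow(off))) {
      sh <- big[pad + seq_len(nx) + off[k, 1], pad + seq_len(ny) + off[k, 2]]
      full <- matrix(init, nx + 2 * pad, ny + 2 * pad)
      full[pad + seq_len(nx), pad + seq_len(ny)] <- sh
      out <- if (combine == "or") (out | full) else (out & full)
    }
    out[pad + seq_len(nx), pad + seq_len(ny)]
  }
  dil <- shift_apply(mask, "or", FALSE)
  shift_apply(dil, "and", TRUE)
}

# exhaustive 8-connected labelling by breadth-first flood fill (oracle for
# label8); returns the number of components
brute_n_components8 <- function(mask) {
  nx <- nrow(mask); ny <- ncol(mask)
  seen <- matrix(FALSE, nx, ny)
  n <- 0L
  for (j in seq_len(ny)) for (i in seq_len(nx)) {
    if (!mask[i, j] || seen[i, j]) next
    n <- n + 1L
    queue <- list(c(i, j)); seen[i, j] <- TRUE
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (di in -1:1) for (dj in -1:1) {
        a <- p[1] + di; b <- p[2] + dj
        if (a >= 1 && a <= nx && b >= 1 && b <= ny &&
            mask[a, b] && !seen[a, b]) {
          seen[a, b] <- TRUE
          queue[[length(queue) + 1]] <- c(a, b)
        }
      }
    }
  }
  n
}
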