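# Independent brute-force oracles and small fixture builders used across
# the suite. Everything here is deliberately naive (O(n^2) distance
# computation, plain R loops) and never calls the package's own
# surface/distance code paths.

# surface voxels of a binary array: foreground with a background 6-neighbour
# (out-of-grid counts as background); returns an n x 3 coordinate matrix
brute_surface <- function(m) {
  d <- dim(m)
  fg <- which(m != 0, arr.ind = TRUE)
  on_border <- apply(fg, 1, function(co) {
    for (ax in 1:3) {
      for (dir in c(-1, 1)) {
        nb <- co
        nb[ax] <- nb[ax] + dir
        if (nb[ax] < 1 || nb[ax] > d[ax]) return(TRUE)
        if (m[nb[1], nb[2], nb[3]] == 0) return(TRUE)
      }
    }
    FALSE
  })
  fg[on_border, , drop = FALSE]
}

# all-pairs directed distances (mm) from each row of `from` to set `to`
brute_directed <- function(from, to, spacing) {
  apply(from, 1, function(p) {
    dx <- sweep(to, 2, p, "-")
    dx <- sweep(dx, 2, spacing, "*")
    sqrt(min(rowSums(dx^2)))
  })
}

brute_hd95 <- function(a, b, spacing) {
  sa <- brute_surface(a)
  sb <- brute_surface(b)
  d_ab <- brute_directed(sa, sb, spacing)
  d_ba <- brute_directed(sb, sa, spacing)
  max(quantile(d_ab, 0.95, type = 7, names = FALSE),
      quantile(d_ba, 0.95, type = 7, names = FALSE))
}

brute_assd <- function(a, b, spacing) {
  sa <- brute_surface(a)
  sb <- brute_surface(b)
  mean(c(brute_directed(sa, sb, spacing), brute_directed(sb, sa, spacing)))
}

# random nonempty blob mask: union of 1-3 random boxes in a dims-sized grid
random_blob_mask <- function(dims) {
  m <- array(0, dims)
  for (k in seq_len(sample(1:3, 1))) {
    lo <- sapply(dims, function(n) sample.int(n, 1))
    hi <- pmin(lo + sapply(dims, function(n) sample.int(max(n %/% 2, 1), 1)),
               dims)
    m[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- 1
  }
  m
}

# solid cube mask helper
cube_mask <- function(dims, lo, size, spacing = c(1, 1, 1)) {
  m <- array(0, dims)
  m[lo[1]:(lo[1] + size - 1), lo[2]:(lo[2] + size - 1),
    lo[3]:(lo[3] + size - 1)] <- 1
  mask_volume(m, spacing)
}

# small fast phantom + network/training settings reused by several tests
tiny_phantom_config <- function(seed = 42) {
  phantom_config(grid_shape = c(32, 32, 32), tumor_volume_range = c(0.1, 0.5),
                 cystic_fraction = 0, noise_sigma = 0.03,
                 bias_field_amplitude = 0.1, seed = seed)
}

tiny_network_config <- function(...) {
  network_config(channels = c(4, 8), dropout_rate = 0, seed = 5, ...)
}
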