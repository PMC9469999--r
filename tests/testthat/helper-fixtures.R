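# Fixtures built in code: analytic rings, standard phantoms, small oracles.

# distance-from-center grid
radius_grid <- function(shape = c(128, 128), center = (shape + 1) / 2) {
  sqrt(outer((seq_len(shape[1]) - center[1])^2,
             (seq_len(shape[2]) - center[2])^2, "+"))
}

# noiseless bright ring (myocardium 200) on dark background, dark cavity
make_ring_image <- function(r_endo = 20, r_epi = 30, shape = c(128, 128),
                            value = 200) {
  rad <- radius_grid(shape)
  img <- matrix(0, shape[1], shape[2])
  img[rad > r_endo & rad <= r_epi] <- value
  img
}

# the standard benchmark phantom family: 70-degree full-transmural wedge
# (~300 px), %SE 300, Rician noise
bench_spec <- function(target_cnr = NULL, seed = 1, ...) {
  phantom_spec(lesion_extent_deg = 70, noise = "rician",
               target_cnr = target_cnr, seed = seed, ...)
}

# independent flood fill (queue BFS, 8-connectivity) used as oracle
flood_fill_oracle <- function(ok, seed) {
  visited <- matrix(FALSE, nrow(ok), ncol(ok))
  queue <- list(seed)
  visited[seed[1], seed[2]] <- TRUE
  offs <- rbind(c(-1,-1), c(-1,0), c(-1,1), c(0,-1), c(0,1),
                c(1,-1), c(1,0), c(1,1))
  while (length(queue)) {
    p <- queue[[1]]; queue <- queue[-1]
    for (k in 1:8) {
      q <- p + offs[k, ]
      if (q[1] >= 1 && q[1] <= nrow(ok) && q[2] >= 1 && q[2] <= ncol(ok) &&
          ok[q[1], q[2]] && !visited[q[1], q[2]]) {
        visited[q[1], q[2]] <- TRUE
        queue <- c(queue, list(q))
      }
    }
  }
  visited
}

dice_coef <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# remote fixture with exact population mean 100, SD 10
remote_fixture_values <- c(90, 110, 90, 110)
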