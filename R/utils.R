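# Separable Gaussian blur with replicate (clamped-index) edge handling.
blur3d <- function(arr, sigma) {
  if (sigma <= 0) return(arr)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  d <- dim(arr)
  for (ax in 1:3) {
    out <- array(0, d)
    n <- d[ax]
    for (j in -r:r) {
      idx <- pmin(pmax(seq_len(n) + j, 1L), n)
      out <- out + k[j + r + 1] * switch(ax,
        arr[idx, , , drop = FALSE],
        arr[, idx, , drop = FALSE],
        arr[, , idx, drop = FALSE])
    }
    arr <- out
  }
  arr
}

# Run an expression with a temporarily-seeded RNG, restoring global state.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
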