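# Separable 3D Gaussian smoothing with reflective edge padding. Used by the
# shape-feature surface estimator and by the synthetic phantom texture
# generator. sigma is in voxels; kernel radius = ceiling(3 sigma).
.gauss1d <- function(sigma) {
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k / sum(k)
}

.gaussSmooth3D <- function(a, sigma) {
  if (sigma <= 0) return(a)
  k <- .gauss1d(sigma)
  r <- (length(k) - 1L) / 2L
  convAxis <- function(a, axis) {
    d <- dim(a)
    perm <- switch(axis, c(1, 2, 3), c(2, 1, 3), c(3, 2, 1))
    b <- aperm(a, perm)
    db <- dim(b)
    m <- matrix(b, nrow = db[1])
    n <- db[1]
    padTop <- m[pmin(n, r:1), , drop = FALSE]
    padBot <- m[pmax(1, n:(n - r + 1)), , drop = FALSE]
    mp <- rbind(padTop, m, padBot)
    out <- matrix(0, n, ncol(m))
    for (j in seq_along(k))
      out <- out + k[j] * mp[(j - 1) + seq_len(n), , drop = FALSE]
    aperm(array(out, db), perm)
  }
  convAxis(convAxis(convAxis(a, 1L), 2L), 3L)
}
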