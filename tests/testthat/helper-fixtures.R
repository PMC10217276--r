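# Shared in-code fixtures: tiny spectrum sets built on short toy grids.

toy_set <- function(mat, wl = seq(400, by = 5, length.out = ncol(mat)), ...) {
  spectrum_set(mat, wl, ...)
}

# deterministic random matrix
rmat <- function(n, p, seed) {
  set.seed(seed)
  matrix(rnorm(n * p), n, p)
}

# linearly separable 2-class toy in 2D with margin >= 1 (classes 1 and 2)
separable_toy <- function(n_per = 10, seed = 42) {
  set.seed(seed)
  x1 <- cbind(runif(n_per, 1, 2), runif(n_per, 1, 2))
  x2 <- cbind(runif(n_per, -2, -1), runif(n_per, -2, -1))
  list(X = rbind(x1, x2), grade = rep(c(1L, 2L), each = n_per))
}
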