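# internal helpers shared across modules

# Node-centered uniform grid on [0, L] including both endpoints, with an even
# interval count so Simpson's rule applies. dx is adjusted minutely if
# round(L/dx) is odd. Nodes are generated as i*dx exactly (seq with `by`),
# which the C++ kernels rely on for exact mirror symmetry.
para_grid <- function(L, dx) {
  stopifnot(L > 0, dx > 0)
  n_int <- as.integer(round(L / dx))
  if (n_int < 2L) stop("grid too coarse: need at least 2 intervals on [0, L]")
  if (n_int %% 2L == 1L) n_int <- n_int + 1L
  dx_adj <- L / n_int
  if (abs(dx_adj - dx) > 0.5 * dx) {
    stop("dx inconsistent with L: cannot build an even-interval grid")
  }
  x <- seq(0, by = dx_adj, length.out = n_int + 1L)
  list(x = x, dx = dx_adj, L = L, n = n_int + 1L)
}

# Simpson weights (dx/3)*(1,4,2,...,2,4,1); n odd
simpson_weights <- function(n, dx) {
  if (n < 3 || n %% 2 == 0) stop("Simpson's rule needs an odd node count")
  w <- rep(c(2, 4), length.out = n)
  w[1] <- 1
  w[n] <- 1
  w * dx / 3
}

# run code under a given seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# index of the central node (bead start); grid has odd n so this is exact
center_index <- function(n) (n - 1L) %/% 2L + 1L

`%||%` <- function(a, b) if (is.null(a)) b else a
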