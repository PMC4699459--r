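# Brute-force oracles written as naive loops, independent of the package's
# quadrature/summation code paths, plus small fixture builders.

make_field <- function(values, L, x = NULL) {
  n <- length(values)
  dx <- L / (n - 1)
  structure(list(x = if (is.null(x)) seq(0, by = dx, length.out = n) else x,
                 values = values, dx = dx, L = L, n = n),
            class = "para_field")
}

make_field_2d <- function(values, L) {
  n <- nrow(values)
  dx <- L / (n - 1)
  g <- seq(0, by = dx, length.out = n)
  structure(list(x = g, y = g, values = values, dx = dx, L = L, n = n),
            class = "para_field_2d")
}

simpson_w_oracle <- function(n, dx) {
  w <- numeric(n)
  for (i in seq_len(n)) w[i] <- if (i == 1 || i == n) 1 else if (i %% 2 == 0) 4 else 2
  w * dx / 3
}

naive_speed_1d <- function(field, x_p, A0) {
  w <- simpson_w_oracle(field$n, field$dx)
  total <- 0
  for (i in seq_len(field$n)) {
    u <- field$x[i] - x_p
    total <- total + w[i] * exp(-u^2 / 2) * u / (1 + u^2) * field$values[i]
  }
  A0 * total
}

naive_removal_1d <- function(field, x_p, c) {
  out <- numeric(field$n)
  for (i in seq_len(field$n)) {
    u <- field$x[i] - x_p
    out[i] <- exp(-u^2 / (2 * c^2)) * field$values[i]
  }
  out
}

naive_velocity_2d <- function(field, x_p, y_p, A0) {
  w <- simpson_w_oracle(field$n, field$dx)
  vx <- 0
  vy <- 0
  for (i in seq_len(field$n)) {
    for (j in seq_len(field$n)) {
      ux <- field$x[i] - x_p
      uy <- field$y[j] - y_p
      r2 <- ux^2 + uy^2
      k <- w[i] * w[j] * exp(-r2 / 2) / (1 + r2) * field$values[i, j]
      vx <- vx + k * ux
      vy <- vy + k * uy
    }
  }
  c(A0 * vx, A0 * vy)
}

# one naive Euler step of the rebinding right-hand sides (Simpson-balanced)
naive_step_rebinding <- function(a, d, ab, x, x_p, c, kr, kc, dtau, L) {
  n <- length(a)
  w <- simpson_w_oracle(n, x[2] - x[1])
  rem <- numeric(n)
  reb <- numeric(n)
  for (i in seq_len(n)) {
    u <- x[i] - x_p
    rem[i] <- exp(-u^2 / (2 * c^2)) * a[i]
    reb[i] <- ab * (d[i] - a[i]) * (kr + kc * a[i])
  }
  list(a = a + dtau * (reb - rem),
       ab = ab + dtau * (sum(w * rem) - sum(w * reb)) / L)
}

trapz_mass <- function(field) {
  w <- simpson_w_oracle(field$n, field$dx)
  if (is.matrix(field$values)) as.numeric(t(w) %*% field$values %*% w)
  else sum(w * field$values)
}
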