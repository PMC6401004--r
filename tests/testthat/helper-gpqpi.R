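# shared fixtures built in code

mono600 <- make_spectrum(600, 0, 1)
band600 <- make_spectrum(600, 50, 7)

# wrapped principal value, duplicated here so tests do not rely on internals
wrap_pv <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y == -pi] <- pi
  y
}

# hand-applied 2x2 complex matrix product for Jones oracle checks
mat2 <- function(a11, a21, a12, a22) matrix(c(a11, a21, a12, a22), 2L, 2L)

expect_unitary <- function(op, tol = 1e-12) {
  m <- unclass(op)
  expect_lt(max(Mod(Conj(t(m)) %*% m - diag(2))), tol)
}
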