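# Shared 1D reaction-diffusion machinery: method of lines on a uniform grid
# over [0, 1] EL with second-order no-flux (reflecting ghost node) ends.
# Diffusion is advanced with Crank-Nicolson; the dense propagator
# M = (I - a L)^{-1} (I + a L) is precomputed once per simulation so each
# step is a single matrix-vector product. With trapezoidal quadrature
# weights the discrete Laplacian conserves mass exactly.

laplacian_noflux <- function(nx, dx) {
  L <- matrix(0, nx, nx)
  for (i in 2:(nx - 1L)) {
    L[i, i - 1L] <- 1
    L[i, i] <- -2
    L[i, i + 1L] <- 1
  }
  L[1L, 1L] <- -2; L[1L, 2L] <- 2
  L[nx, nx] <- -2; L[nx, nx - 1L] <- 2
  L / dx^2
}

# one Crank-Nicolson diffusion step as a dense propagator matrix
cn_propagator <- function(nx, dx, D, dt) {
  if (D <= 0) return(diag(nx))
  L <- laplacian_noflux(nx, dx)
  a <- D * dt / 2
  solve(diag(nx) - a * L, diag(nx) + a * L)
}

trapezoid_weights <- function(nx, dx) {
  w <- rep(dx, nx)
  w[c(1L, nx)] <- dx / 2
  w
}

#' Trapezoidal integral of a gridded concentration over [0, 1] EL
#' @param u Concentration vector on the uniform grid.
#' @param dx Grid spacing.
#' @return The integral.
#' @keywords internal
grid_integral <- function(u, dx) {
  sum(trapezoid_weights(length(u), dx) * u)
}
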