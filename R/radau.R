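# Radau IIA collocation scheme on [0, 1]: d collocation points in (0, 1]
# including the right endpoint, a differentiation matrix for the degree-d
# interpolant anchored at tau = 0, and quadrature weights exact for
# polynomials of degree 2d - 2 (collocation order 2d - 1).

polymul <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a)) out[i:(i + length(b) - 1L)] <-
      out[i:(i + length(b) - 1L)] + a[i] * b
  out
}
polyder <- function(a) {
  if (length(a) <= 1L) return(0)
  a[-1L] * seq_len(length(a) - 1L)
}
polyval <- function(a, x) {
  out <- 0
  for (i in rev(seq_along(a))) out <- out * x + a[i]
  out
}
polyint01 <- function(a) sum(a / seq_along(a))

legendre_coefs <- function(n) {
  # coefficients (ascending powers of s) of the Legendre polynomial P_n on [-1,1]
  if (n == 0L) return(1)
  if (n == 1L) return(c(0, 1))
  pm1 <- 1; p <- c(0, 1)
  for (k in 1:(n - 1L)) {
    np <- (2 * k + 1) / (k + 1) * c(0, p)
    np[seq_along(pm1)] <- np[seq_along(pm1)] - k / (k + 1) * pm1
    pm1 <- p; p <- np
  }
  p
}

lagrange_basis <- function(nodes) {
  # list of ascending-coefficient polynomials l_j with l_j(nodes[k]) = delta_jk
  lapply(seq_along(nodes), function(j) {
    p <- 1
    for (k in seq_along(nodes)) {
      if (k == j) next
      p <- polymul(p, c(-nodes[k], 1)) / (nodes[j] - nodes[k])
    }
    p
  })
}

#' Construct a Radau IIA collocation scheme
#'
#' Collocation points are the roots of `P_d(2*tau - 1) - P_{d-1}(2*tau - 1)`
#' on `(0, 1]` (the right endpoint is always included; `d = 1` is implicit
#' Euler). The differentiation matrix `D` maps the values of the degree-`d`
#' interpolant at `(0, c_1, ..., c_d)` to its derivatives at the collocation
#' points; the quadrature weights integrate polynomials up to degree
#' `2d - 2` exactly.
#'
#' @param d number of collocation points per mesh interval (default 3).
#' @return Object of class `tt_radau`: list with `degree`, `points` (length
#'   `d`, increasing, last equal to 1), `D` (`d x (d+1)`) and weights `w`
#'   (length `d`).
#' @export
make_radau <- function(d = 3L) {
  d <- as.integer(d)
  if (d < 1L) stop("degree must be at least 1")
  if (d > 9L) stop("unsupported degree ", d, " (maximum 9)")
  if (d == 1L) {
    pts <- 1
  } else {
    pd <- legendre_coefs(d)
    pdm1 <- legendre_coefs(d - 1L)
    dif <- pd
    dif[seq_along(pdm1)] <- dif[seq_along(pdm1)] - pdm1
    r <- polyroot(dif)
    r <- Re(r[abs(Im(r)) < 1e-9])
    pts <- sort((r + 1) / 2)
    pts <- pts[pts > 1e-12]
    # polish with Newton on the defining polynomial in s = 2 tau - 1
    ddif <- polyder(dif)
    for (it in 1:3) {
      s <- 2 * pts - 1
      s <- s - polyval(dif, s) / polyval(ddif, s)
      pts <- (s + 1) / 2
    }
    pts[length(pts)] <- 1
  }
  basis_full <- lagrange_basis(c(0, pts))
  D <- matrix(0, d, d + 1L)
  for (j in seq_len(d + 1L))
    D[, j] <- polyval(polyder(basis_full[[j]]), pts)
  basis_c <- lagrange_basis(pts)
  w <- vapply(basis_c, polyint01, 0)
  structure(list(degree = d, points = pts, D = D, w = w),
            class = "tt_radau")
}

#' @export
print.tt_radau <- function(x, ...) {
  cat("<tt_radau> degree", x$degree, "points:",
      paste(signif(x$points, 7), collapse = " "), "\n")
  invisible(x)
}

#' Radau quadrature of a function over an interval
#'
#' @param scheme a `tt_radau`.
#' @param f function of tau.
#' @param a,b interval endpoints.
#' @return Quadrature approximation of the integral (exact for polynomials of
#'   degree `2d - 2`).
#' @export
radau_quadrature <- function(scheme, f, a = 0, b = 1) {
  h <- b - a
  h * sum(scheme$w * vapply(a + h * scheme$points, f, 0))
}
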