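# Matern 5/2 kernel on descriptor-space Euclidean distance, its radial
# derivative factors, and assembly of the force (gradient-gradient) kernel
# matrix.
#
# For a stationary kernel kappa(d), d = |u|, u = D_a - D_b, write
#   g(d) = kappa'(d)/d,     h(d) = g'(d)/d.
# Then the cross Hessian in descriptor space is
#   B_ab = grad_{D_a} grad_{D_b}^T kappa = -g(d) I - h(d) u u^T,
# and the Cartesian force-kernel block follows by the chain rule through
# the descriptor Jacobians:  K_ab = J_a^T B_ab J_b.
# Both g and h are smooth at d = 0 for Matern 5/2, so no special-casing of
# coincident descriptors is needed.

#' Matern 5/2 kernel value
#'
#' k(d) = (1 + sqrt(5) d / sigma + 5 d^2 / (3 sigma^2)) exp(-sqrt(5) d / sigma):
#' twice continuously differentiable, k(0) = 1, strictly decreasing in d,
#' scale-invariant in the sense k(d; sigma) = k(c d; c sigma).
#'
#' @param d nonnegative distance(s) in descriptor space.
#' @param sigma length scale (> 0), same units as `d`.
#' @return Kernel value(s) in (0, 1].
#' @examples
#' maternKernel(0, 2)       # 1
#' maternKernel(1:3, 2.5)
#' @export
maternKernel <- function(d, sigma) {
  if (any(sigma <= 0)) stop("sigma must be > 0")
  if (any(d < 0)) stop("distances must be >= 0")
  s5 <- sqrt(5) * d / sigma
  (1 + s5 + s5^2 / 3) * exp(-s5)
}

# kappa'(d)/d  (negative, finite at d = 0: -5/(3 sigma^2))
.mat52g <- function(d, sigma) {
  -(5 / (3 * sigma^2)) * (1 + sqrt(5) * d / sigma) * exp(-sqrt(5) * d / sigma)
}

# g'(d)/d  (positive, finite at d = 0: 25/(3 sigma^4))
.mat52h <- function(d, sigma) {
  (25 / (3 * sigma^4)) * exp(-sqrt(5) * d / sigma)
}

# Internal: descriptors of a list/array of configurations under `spec`.
# coordsArr: natoms x 3 x M.  Returns list(D = d x M values, J = list of
# d x 3N Jacobians).
.descriptorSet <- function(coordsArr, spec) {
  M <- dim(coordsArr)[3]
  J <- vector("list", M)
  D <- matrix(0, sum(spec@active), M)
  for (a in seq_len(M)) {
    dsc <- .descriptor(coordsArr[, , a], spec)
    D[, a] <- dsc$values
    J[[a]] <- dsc$jac
  }
  list(D = D, J = J)
}

#' Assemble the force-kernel (Hessian) matrix
#'
#' Builds the M*3N x M*3N symmetric positive-semidefinite matrix whose
#' (a, b) block is the cross Hessian of the Matern 5/2 kernel between
#' configurations a and b, propagated through the analytic descriptor
#' Jacobians.  This is the Gram matrix of force observations that training
#' solves against.
#'
#' @param configs either a natoms x 3 x M array of coordinates or a list of
#'   [AtomicConfiguration-class] objects.
#' @param spec a [DescriptorSpec-class].
#' @param sigma kernel length scale in descriptor units.
#' @return A numeric M*3N x M*3N matrix.
#' @export
assembleForceKernel <- function(configs, spec, sigma) {
  if (is.list(configs)) {
    n <- nrow(if (is(configs[[1]], "AtomicConfiguration")) configs[[1]]@xyz
              else configs[[1]])
    arr <- array(0, c(n, 3, length(configs)))
    for (a in seq_along(configs))
      arr[, , a] <- if (is(configs[[a]], "AtomicConfiguration"))
        configs[[a]]@xyz else configs[[a]]
    configs <- arr
  }
  if (sigma <= 0) stop("sigma must be > 0")
  M <- dim(configs)[3]; n3 <- 3L * dim(configs)[1]
  ds <- .descriptorSet(configs, spec)
  K <- matrix(0, M * n3, M * n3)
  for (a in seq_len(M)) {
    ra <- (a - 1L) * n3 + seq_len(n3)
    Ja <- ds$J[[a]]
    for (b in a:M) {
      u <- ds$D[, a] - ds$D[, b]
      dd <- sqrt(sum(u * u))
      g <- .mat52g(dd, sigma); h <- .mat52h(dd, sigma)
      Jb <- ds$J[[b]]
      blk <- -g * crossprod(Ja, Jb)
      if (dd > 0) {
        va <- crossprod(Ja, u); vb <- crossprod(Jb, u)
        blk <- blk - h * tcrossprod(va, vb)
      }
      rb <- (b - 1L) * n3 + seq_len(n3)
      K[ra, rb] <- blk
      if (b > a) K[rb, ra] <- t(blk)
    }
  }
  K
}
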