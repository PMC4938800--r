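#' Kabsch least-squares superposition
#'
#' Finds the rigid-body transform (rotation + translation) that minimizes the
#' RMSD of `P` onto `Q`, by singular value decomposition of the cross
#' covariance with the usual determinant correction so the rotation is proper.
#'
#' @param P,Q numeric n x 3 coordinate matrices (rows are matched points).
#' @return list with `rotation` (3 x 3, applied to row vectors as
#'   `Pc %*% rotation`), `center_p`, `center_q`, `rmsd`, and `fitted`
#'   (the transformed `P`).
#' @export
kabsch <- function(P, Q) {
  stopifnot(is.matrix(P), is.matrix(Q), ncol(P) == 3, ncol(Q) == 3,
            nrow(P) == nrow(Q), nrow(P) >= 3)
  cp <- colMeans(P)
  cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp)
  Qc <- sweep(Q, 2, cq)
  s <- svd(crossprod(Pc, Qc))
  d <- sign(det(s$u) * det(s$v))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  fitted <- sweep(Pc %*% R, 2, cq, "+")
  list(rotation = R, center_p = cp, center_q = cq,
       rmsd = sqrt(mean(rowSums((fitted - Q)^2))), fitted = fitted)
}

# apply a kabsch() fit (estimated on a subset) to arbitrary coordinates
apply_fit <- function(X, fit) {
  sweep(sweep(X, 2, fit$center_p) %*% fit$rotation, 2, fit$center_q, "+")
}

# rotation matrix about an arbitrary unit axis (Rodrigues), angle in radians
rotation_about <- function(axis, theta) {
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-10) stop("cannot normalize a near-zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# internal-coordinate atom placement (NeRF): position a new atom at the given
# bond length / bond angle / torsion relative to atoms c -> b -> a
place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- deg2rad(angle)
  tor <- deg2rad(torsion)
  d <- c(-bond * cos(ang),
         bond * sin(ang) * cos(tor),
         bond * sin(ang) * sin(tor))
  bc <- unit(a - b)
  n <- unit(cross3(unit(b - c), bc))
  M <- cbind(bc, cross3(n, bc), n)
  as.numeric(a + M %*% d)
}
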