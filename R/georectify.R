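# Rectification of tilted scanner frames, scan-attribute derivation, and the
# seven-parameter Helmert similarity transform for georeferencing.

.deg2rad <- function(x) x * pi / 180
.rad2deg <- function(x) x * 180 / pi

#' Euler rotation matrix (Rz * Ry * Rx convention)
#'
#' Builds the passive rotation used to level a tilted scanner frame:
#' `R = Rz(kappa) %*% Ry(phi) %*% Rx(omega)`, each factor a right-handed
#' rotation about the named axis. The default pose of a mast-mounted scanner
#' tilted 60 degrees down corresponds to `(omega, phi, kappa) = (0, 60, 90)`.
#'
#' @param omega,phi,kappa Euler angles in degrees. A single length-3 vector
#'   may also be given as `omega`.
#' @return 3x3 orthonormal matrix with determinant +1.
#' @examples
#' rotationMatrix(0, 0, 0)          # identity
#' R <- rotationMatrix(0, 60, 90)
#' det(R)
#' @export
rotationMatrix <- function(omega = 0, phi = 60, kappa = 90) {
  if (length(omega) == 3 && missing(phi)) {
    kappa <- omega[3]; phi <- omega[2]; omega <- omega[1]
  }
  stopifnot(is.finite(omega), is.finite(phi), is.finite(kappa))
  o <- .deg2rad(omega); p <- .deg2rad(phi); k <- .deg2rad(kappa)
  Rx <- rbind(c(1, 0, 0), c(0, cos(o), -sin(o)), c(0, sin(o), cos(o)))
  Ry <- rbind(c(cos(p), 0, sin(p)), c(0, 1, 0), c(-sin(p), 0, cos(p)))
  Rz <- rbind(c(cos(k), -sin(k), 0), c(sin(k), cos(k), 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}

#' Rectify a scanner-frame cloud to a ground-normalized local frame
#'
#' Rotates the coordinates by [rotationMatrix()] about the scan origin; the
#' origin stays at the instrument, so for a mast-mounted scanner the ground
#' ends up near z = -(mast height) with Z up. Attributes are untouched. The
#' operation is an isometry.
#'
#' @param cloud a [PointCloud-class] in the scanner frame.
#' @param angles Euler angles in degrees, default `c(0, 60, 90)`.
#' @return the rotated [PointCloud-class].
#' @export
rectify <- function(cloud, angles = c(0, 60, 90)) {
  R <- rotationMatrix(angles[1], angles[2], angles[3])
  d <- pointData(cloud)
  if (nrow(d)) {
    xyz <- coords(cloud) %*% t(R)
    d$x <- xyz[, 1]; d$y <- xyz[, 2]; d$z <- xyz[, 3]
    pointData(cloud) <- d
  }
  cloud
}

#' Derive scan angles and range from coordinates
#'
#' Computed in the scanner-origin frame (before georeferencing), where they
#' describe the instrument geometry: `range` is the Euclidean distance to the
#' origin, `theta` the polar angle from +Z in degrees (0-180), and `phi_az`
#' the azimuth from +X towards +Y in degrees (0-360). A point exactly at the
#' origin gets range 0 and both angles 0, with a warning.
#'
#' @param cloud a [PointCloud-class] with origin at the scanner.
#' @return the cloud with `range`, `theta` and `phi_az` columns added.
#' @export
computeScanAttributes <- function(cloud) {
  d <- pointData(cloud)
  if (nrow(d) == 0) {
    d$range <- d$theta <- d$phi_az <- numeric(0)
    pointData(cloud) <- d
    return(cloud)
  }
  rng <- sqrt(d$x^2 + d$y^2 + d$z^2)
  at_origin <- rng == 0
  if (any(at_origin))
    warning(sum(at_origin), " point(s) at the exact scan origin; ",
            "angles set to 0")
  theta <- ifelse(at_origin, 0, .rad2deg(acos(pmin(1, pmax(-1, d$z / rng)))))
  phi_az <- ifelse(at_origin, 0, .rad2deg(atan2(d$y, d$x)) %% 360)
  d$range <- rng
  d$theta <- theta
  d$phi_az <- phi_az
  pointData(cloud) <- d
  cloud
}

#' Fit a seven-parameter Helmert transform to control-point pairs
#'
#' Least-squares similarity transform minimizing
#' `sum || target - (t + mu * R source) ||^2`, solved in closed form
#' (centroid alignment, orthogonal-Procrustes rotation via SVD, trace scale).
#' This attains the global optimum of the loss, so noise-free consistent
#' pairs are recovered exactly. Residual statistics are stored on the result:
#' `fitRMSE` is the 3-D RMSE `sqrt(mean(||residual||^2))` and `perAxisRMSE`
#' the per-axis RMSEs.
#'
#' @param pairs data.frame with columns `sx,sy,sz,tx,ty,tz` (see
#'   [readControlPoints()]).
#' @return a [HelmertTransform-class].
#' @examples
#' p <- data.frame(sx = c(0, 1, 0, 0), sy = c(0, 0, 1, 0),
#'                 sz = c(0, 0, 0, 1))
#' p[c("tx", "ty", "tz")] <- p[c("sx", "sy", "sz")] + 10
#' fitHelmert(p)
#' @export
fitHelmert <- function(pairs) {
  pairs <- as.data.frame(pairs)
  need <- c("sx", "sy", "sz", "tx", "ty", "tz")
  stopifnot(all(need %in% names(pairs)))
  n <- nrow(pairs)
  if (n < 3) stop("need >= 3 control point pairs, got ", n)
  S <- as.matrix(pairs[, c("sx", "sy", "sz")])
  T <- as.matrix(pairs[, c("tx", "ty", "tz")])
  sbar <- colMeans(S); tbar <- colMeans(T)
  Sc <- sweep(S, 2, sbar); Tc <- sweep(T, 2, tbar)
  H <- crossprod(Tc, Sc) / n                      # cov(target, source)
  sv <- svd(H)
  if (sv$d[2] < 1e-12 * max(sv$d[1], 1))
    stop("degenerate (collinear) control point configuration")
  D <- diag(c(1, 1, sign(det(sv$u %*% t(sv$v)))))
  R <- sv$u %*% D %*% t(sv$v)
  var_s <- sum(Sc^2) / n
  mu <- sum(diag(D) * sv$d) / var_s
  t <- tbar - mu * as.vector(R %*% sbar)
  res <- T - (matrix(t, n, 3, byrow = TRUE) + mu * S %*% t(R))
  HelmertTransform(
    translation = t, rotation = R, scale = mu,
    fitRMSE = sqrt(mean(rowSums(res^2))),
    perAxisRMSE = sqrt(colMeans(res^2)))
}

#' Apply (or invert) a Helmert transform
#'
#' Maps each point through `p' = t + mu * R p`; attributes are untouched.
#'
#' @param cloud a [PointCloud-class] (or numeric n x 3 matrix).
#' @param transform a [HelmertTransform-class].
#' @param crs optional CRS tag to stamp on the result (e.g. `"EPSG:3067"`).
#' @return the transformed cloud (or matrix).
#' @export
applyHelmert <- function(cloud, transform, crs = NULL) {
  stopifnot(is(transform, "HelmertTransform"))
  mapxyz <- function(xyz) {
    sweep(transform@scale * xyz %*% t(transform@rotation), 2,
          -transform@translation)
  }
  if (is.matrix(cloud)) return(mapxyz(cloud))
  d <- pointData(cloud)
  if (nrow(d)) {
    xyz <- mapxyz(coords(cloud))
    d$x <- xyz[, 1]; d$y <- xyz[, 2]; d$z <- xyz[, 3]
    pointData(cloud) <- d
  }
  if (!is.null(crs)) crs(cloud) <- crs
  cloud
}

#' @rdname applyHelmert
#' @details `invertHelmert()` returns the exact inverse transform
#'   (`p = R' (p' - t) / mu`), so apply-then-invert is the identity.
#' @export
invertHelmert <- function(transform) {
  Rinv <- t(transform@rotation)
  HelmertTransform(
    translation = as.vector(-Rinv %*% transform@translation) /
      transform@scale,
    rotation = Rinv, scale = 1 / transform@scale)
}

#' Pitch/roll/yaw angles of a Helmert rotation
#'
#' Extracts Euler angles under the same `Rz(kappa) Ry(phi) Rx(omega)`
#' convention used by [rotationMatrix()]. At gimbal lock (|phi| = 90 deg)
#' kappa is reported as 0 by convention.
#'
#' @param transform a [HelmertTransform-class] (or a 3x3 rotation matrix).
#' @return named numeric vector (omega = roll, phi = pitch, kappa = yaw),
#'   degrees.
#' @export
helmertAngles <- function(transform) {
  R <- if (is.matrix(transform)) transform else transform@rotation
  sp <- -R[3, 1]
  if (abs(sp) > 1 - 1e-9) {           # gimbal lock
    phi <- 90 * sign(sp)
    kappa <- 0
    omega <- .rad2deg(atan2(sign(sp) * R[1, 2], R[2, 2]))
  } else {
    phi <- .rad2deg(asin(sp))
    omega <- .rad2deg(atan2(R[3, 2], R[3, 3]))
    kappa <- .rad2deg(atan2(R[2, 1], R[1, 1]))
  }
  c(omega = omega, phi = phi, kappa = kappa)
}
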