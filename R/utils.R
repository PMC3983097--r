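# geometry and RNG helpers shared across modules

crossProd <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

unitVec <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("cannot normalize a zero vector")
  v / n
}

# rotation matrix about unit axis by angle (radians), Rodrigues form
rotationMatrix <- function(axis, angle) {
  u <- unitVec(axis)
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# rotation taking unit vector a onto unit vector b
rotationBetween <- function(a, b) {
  a <- unitVec(a); b <- unitVec(b)
  v <- crossProd(a, b)
  s <- sqrt(sum(v^2))
  c_ <- sum(a * b)
  if (s < 1e-12) {
    if (c_ > 0) return(diag(3))
    # antiparallel: rotate pi about any perpendicular axis
    p <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    return(rotationMatrix(crossProd(a, p), pi))
  }
  rotationMatrix(v / s, atan2(s, c_))
}

# NeRF internal-coordinate placement: position of atom d bonded to c with
# bond length r, angle(b, c, d) = theta and dihedral(a, b, c, d) = phi
# (both in degrees).
placeAtom <- function(a, b, c, r, theta, phi) {
  bc <- unitVec(c - b)
  n <- unitVec(crossProd(b - a, bc))
  m <- crossProd(n, bc)
  th <- theta * pi / 180
  ph <- phi * pi / 180
  c + (-r * cos(th)) * bc + (r * sin(th) * cos(ph)) * m + (r * sin(th) * sin(ph)) * n
}

vecAngle <- function(a, b) {
  ct <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  acos(max(-1, min(1, ct)))
}

# run expr with a private RNG stream, restoring the caller's state
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# principal axis (first PC, unit vector) of a point cloud
principalAxis <- function(xyz) {
  xyz <- sweep(xyz, 2, colMeans(xyz))
  sv <- svd(xyz, nu = 0, nv = 1)
  unitVec(sv$v[, 1])
}

atomicMass <- function(element) {
  m <- c(C = 12.011, H = 1.008, O = 15.999, N = 14.007, P = 30.973762)
  unname(m[element])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
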