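# Internal geometric primitives shared across modules.

.norm3 <- function(v) sqrt(sum(v * v))

.unit <- function(v) {
  n <- .norm3(v)
  if (n < 1e-12) stop("cannot normalise a near-zero vector")
  v / n
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

.deg <- function(rad) rad * 180 / pi
.rad <- function(deg) deg * pi / 180

# Rodrigues rotation matrix: rotate by `deg` degrees about unit axis `axis`.
.rotationMatrix <- function(axis, deg) {
  u <- .unit(axis)
  th <- .rad(deg)
  ct <- cos(th); st <- sin(th)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  K <- matrix(c(0, -uz, uy, uz, 0, -ux, -uy, ux, 0), 3, 3, byrow = TRUE)
  diag(3) * ct + st * K + (1 - ct) * (u %o% u)
}

# Rotate row-vector coordinates `xyz` (n x 3) about the line through `point`
# with direction `axis`, by `deg` degrees.
.rotateAbout <- function(xyz, axis, deg, point = c(0, 0, 0)) {
  R <- .rotationMatrix(axis, deg)
  sweep(sweep(xyz, 2, point) %*% t(R), 2, point, `+`)
}

# Closest points between finite segments p0-p1 and q0-q1 (clamped).
# Returns list(pa, pb, distance). Standard parametric algorithm.
.segmentClosestPoints <- function(p0, p1, q0, q1) {
  d1 <- p1 - p0
  d2 <- q1 - q0
  r <- p0 - q0
  a <- sum(d1 * d1); e <- sum(d2 * d2); f <- sum(d2 * r)
  eps <- 1e-12
  if (a <= eps && e <= eps) {
    s <- 0; t <- 0
  } else if (a <= eps) {
    s <- 0; t <- min(max(f / e, 0), 1)
  } else {
    cc <- sum(d1 * r)
    if (e <= eps) {
      t <- 0; s <- min(max(-cc / a, 0), 1)
    } else {
      b <- sum(d1 * d2)
      denom <- a * e - b * b
      s <- if (denom > eps) min(max((b * f - cc * e) / denom, 0), 1) else 0
      t <- (b * s + f) / e
      if (t < 0) {
        t <- 0; s <- min(max(-cc / a, 0), 1)
      } else if (t > 1) {
        t <- 1; s <- min(max((b - cc) / a, 0), 1)
      }
    }
  }
  pa <- p0 + s * d1
  pb <- q0 + t * d2
  list(pa = pa, pb = pb, distance = .norm3(pb - pa))
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the
# caller's RNG state is restored afterwards.
.withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

# Derive a stream-specific sub-seed (< 2^31) from a top-level seed.
.subSeed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 1009 + as.numeric(stream) * 7919) %% 2147480000)
}

# A random 3D rotation matrix (uniform axis, uniform angle) -- test helper
# used for rigid-invariance properties.
.randomRotation <- function() {
  ax <- stats::rnorm(3)
  .rotationMatrix(ax, stats::runif(1, 0, 360))
}
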