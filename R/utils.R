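# Geometry, RNG and small-object helpers shared across modules.

# van der Waals-like contact radii (Angstrom) used by the built-in score.
.element_radii <- c(C = 1.9, N = 1.8, O = 1.7, S = 2.0, P = 2.1)
.default_radius <- 1.8

element_radius <- function(element) {
  r <- .element_radii[element]
  r[is.na(r)] <- .default_radius
  unname(r)
}

# Periodic-table symbols accepted by the parsers (organic subset + common ions).
.known_elements <- c(
  "H", "B", "C", "N", "O", "F", "NA", "MG", "P", "S", "CL", "K", "CA",
  "MN", "FE", "CO", "NI", "CU", "ZN", "SE", "BR", "I"
)

normalize_element <- function(element) {
  e <- toupper(trimws(element))
  out <- ifelse(e %in% .known_elements, e, NA_character_)
  # canonical case: first letter upper, rest lower (Cl, Zn, ...)
  ifelse(is.na(out), out,
         paste0(substr(out, 1, 1), tolower(substr(out, 2, nchar(out)))))
}

is_heavy_element <- function(element) toupper(element) != "H"

#' @keywords internal
stopifnot_scalar_int <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x != round(x) || x < min)
    stop(sprintf("`%s` must be a single integer >= %d", name, min), call. = FALSE)
  as.integer(x)
}

# Evaluate `expr` under a fixed seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# MINSTD-style mixing of a master seed with stream indices; keeps every derived
# seed inside the 32-bit signed range so set.seed() always accepts it.
mix_seed <- function(master, a = 0L, b = 0L, c = 0L) {
  m <- 2147483647
  t <- (abs(as.numeric(master)) %% m + 7919 * a + 104729 * b + 130003 * c) %% m
  s <- (t * 48271) %% m
  as.integer(if (s == 0) 1 else s)
}

# --- rotations ----------------------------------------------------------------

# Rotation matrix for angle `theta` (radians) about unit axis `u`.
rotation_matrix <- function(u, theta) {
  u <- u / sqrt(sum(u^2))
  ct <- cos(theta); st <- sin(theta); vt <- 1 - ct
  x <- u[1]; y <- u[2]; z <- u[3]
  matrix(c(
    ct + x * x * vt,      x * y * vt - z * st,  x * z * vt + y * st,
    y * x * vt + z * st,  ct + y * y * vt,      y * z * vt - x * st,
    z * x * vt - y * st,  z * y * vt + x * st,  ct + z * z * vt
  ), nrow = 3, byrow = TRUE)
}

# Uniform random rotation matrix (random unit quaternion).
random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2),  2 * (x * y - w * z),  2 * (x * z + w * y),
    2 * (x * y + w * z),  1 - 2 * (x^2 + z^2),  2 * (y * z - w * x),
    2 * (x * z - w * y),  2 * (y * z + w * x),  1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

# Rotate the rows of `coords` (n x 3) about axis through point `p1` toward `p2`.
rotate_about_bond <- function(coords, p1, p2, theta) {
  axis <- p2 - p1
  R <- rotation_matrix(axis, theta)
  sweep(sweep(coords, 2, p1, "-") %*% t(R), 2, p1, "+")
}

#' Measure a torsion (dihedral) angle
#'
#' Standard signed dihedral defined by four points, in degrees in
#' \code{[-180, 180)}.
#'
#' @param p1,p2,p3,p4 numeric 3-vectors (Angstrom). The angle is measured
#'   about the \code{p2}-\code{p3} axis.
#' @return Angle in degrees.
#' @export
measure_dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  ang <- atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang >= 180) ang <- ang - 360
  ang
}

# Orthonormal frame from three points: origin a, x-axis toward b, plane (a,b,c).
# When (a, b, c) are nearly collinear the in-plane direction is completed
# deterministically from the coordinate axis least aligned with the bond axis,
# so that identical inputs always give identical frames.
local_frame <- function(a, b, c) {
  e1 <- b - a
  n1 <- sqrt(sum(e1^2))
  if (n1 < 1e-9) stop("degenerate frame: coincident anchor atoms", call. = FALSE)
  e1 <- e1 / n1
  v <- c - a
  v <- v - sum(v * e1) * e1
  nv <- sqrt(sum(v^2))
  if (nv < 1e-6) {
    axis <- diag(3)[, which.min(abs(e1))]
    v <- axis - sum(axis * e1) * e1
    nv <- sqrt(sum(v^2))
  }
  e2 <- v / nv
  e3 <- c(e1[2] * e2[3] - e1[3] * e2[2],
          e1[3] * e2[1] - e1[1] * e2[3],
          e1[1] * e2[2] - e1[2] * e2[1])
  cbind(e1, e2, e3)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
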