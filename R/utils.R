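# Internal helpers: seed derivation, geometry, small numerics.

# Deterministic sub-stream seed derived from a top-level seed and a stream
# name, kept inside the 32-bit integer range. Each generator draws from its
# own stream so stages can be re-run independently.
deriveSeed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((abs(seed) * 7919 + h * 104729 + 17) %% 2147483647)
}

withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Ray-casting point-in-polygon test (even-odd rule); polygon is an n x 2
# matrix, implicitly closed. Points exactly on an edge count as inside up to
# floating tolerance, which is all the package needs.
pointInPolygon <- function(x, y, poly) {
  nx <- length(x)
  px <- poly[, 1]; py <- poly[, 2]
  n <- length(px)
  inside <- logical(nx)
  j <- n
  crossings <- matrix(FALSE, nrow = nx, ncol = 1)
  for (i in seq_len(n)) {
    xi <- px[i]; yi <- py[i]; xj <- px[j]; yj <- py[j]
    denom <- yj - yi
    cond <- ((yi > y) != (yj > y))
    if (any(cond)) {
      xint <- xi + (y - yi) * (xj - xi) / denom
      flip <- cond & (x < xint)
      inside[flip] <- !inside[flip]
    }
    j <- i
  }
  inside
}

# Shoelace polygon area (absolute value).
polygonArea <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- nrow(poly)
  j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}

# Minimum distance from points to a polyline given as an m x 2 matrix.
distToPolyline <- function(x, y, line) {
  n <- nrow(line)
  if (n == 1L) return(sqrt((x - line[1, 1])^2 + (y - line[1, 2])^2))
  best <- rep(Inf, length(x))
  for (i in seq_len(n - 1L)) {
    ax <- line[i, 1]; ay <- line[i, 2]
    bx <- line[i + 1L, 1]; by <- line[i + 1L, 2]
    vx <- bx - ax; vy <- by - ay
    L2 <- vx * vx + vy * vy
    t <- if (L2 == 0) rep(0, length(x)) else
      pmin(1, pmax(0, ((x - ax) * vx + (y - ay) * vy) / L2))
    d2 <- (x - (ax + t * vx))^2 + (y - (ay + t * vy))^2
    best <- pmin(best, d2)
  }
  sqrt(best)
}

# Regular polygon approximation of a circle, used as the GC boundary.
discPolygon <- function(radius, center = c(0, 0), n = 256L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(x = center[1] + radius * cos(th), y = center[2] + radius * sin(th))
}

# x-position of the vertical chord that puts `fraction` of a disc's area on
# its left; solved from the circular-segment area formula.
chordForAreaFraction <- function(radius, fraction) {
  stopifnot(fraction > 0, fraction < 1)
  f <- function(c) {
    segRight <- radius^2 * acos(c / radius) - c * sqrt(radius^2 - c^2)
    (pi * radius^2 - segRight) / (pi * radius^2) - fraction
  }
  uniroot(f, c(-radius + 1e-9, radius - 1e-9), tol = 1e-10)$root
}

# Uniform points on a disc.
runifDisc <- function(n, radius, center = c(0, 0)) {
  r <- radius * sqrt(runif(n))
  th <- runif(n, 0, 2 * pi)
  cbind(x = center[1] + r * cos(th), y = center[2] + r * sin(th))
}

# Quantile convention used throughout the package: linear interpolation on
# sorted values (type 7).
pctl <- function(x, p) unname(quantile(x, p, type = 7, names = FALSE))

isCount <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x >= 0 && x == round(x)
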