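# Low-level binary-mask operations.
#
# All conventions here are deliberately exact and pixel-countable so that
# every quantity can be checked against a brute-force oracle:
#   * foreground is 8-connected;
#   * perimeter is the number of foreground pixel edges exposed to
#     background (or to the image border);
#   * convex area is the area of the convex hull of the foreground pixel
#     *squares* (corners, not centres), which guarantees hull area >= area.

# Label 8-connected components. Returns an integer matrix, 0 = background.
label_components <- function(mask) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  todo <- which(mask)
  if (length(todo) == 0L) {
    return(lab)
  }
  # neighbour offsets in linear indexing of an (nr+2) padded frame
  nrp <- nr + 2L
  pad <- matrix(FALSE, nrp, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- mask
  off <- c(-1L, 1L, -nrp, nrp, -nrp - 1L, -nrp + 1L, nrp - 1L, nrp + 1L)
  plab <- matrix(0L, nrp, nc + 2L)
  cur <- 0L
  seeds <- which(pad)
  for (s in seeds) {
    if (plab[s] != 0L) next
    cur <- cur + 1L
    frontier <- s
    plab[s] <- cur
    while (length(frontier) > 0L) {
      nb <- unique(as.vector(outer(frontier, off, `+`)))
      nb <- nb[pad[nb] & plab[nb] == 0L]
      plab[nb] <- cur
      frontier <- nb
    }
  }
  lab[, ] <- plab[2:(nr + 1L), 2:(nc + 1L)]
  lab
}

# Keep only the largest 8-connected component (ties: lowest label, i.e.
# the component whose first pixel comes first in column-major order).
largest_component <- function(mask) {
  lab <- label_components(mask)
  sizes <- tabulate(lab)
  if (length(sizes) == 0L) {
    return(mask & FALSE)
  }
  lab == which.max(sizes)
}

# Exposed-edge perimeter: for each of the 4 axis directions, count
# foreground pixels whose neighbour in that direction is background or
# outside the image.
mask_perimeter <- function(mask) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- mask
  core <- pad[2:(nr + 1L), 2:(nc + 1L)]
  up <- pad[1:nr, 2:(nc + 1L)]
  down <- pad[3:(nr + 2L), 2:(nc + 1L)]
  left <- pad[2:(nr + 1L), 1:nc]
  right <- pad[2:(nr + 1L), 3:(nc + 2L)]
  sum(core & !up) + sum(core & !down) + sum(core & !left) + sum(core & !right)
}

# Area of the convex hull of the foreground pixel squares (each pixel
# (r, c) contributes its 4 corners). Shoelace on the hull polygon.
mask_convex_area <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  r <- idx[, 1]
  c <- idx[, 2]
  x <- c(c - 0.5, c + 0.5, c - 0.5, c + 0.5)
  y <- c(r - 0.5, r - 0.5, r + 0.5, r + 0.5)
  h <- chull(x, y)
  hx <- x[h]
  hy <- y[h]
  m <- length(h)
  j <- c(2:m, 1L)
  abs(sum(hx * hy[j] - hx[j] * hy)) / 2
}

# Second-moment ellipse of the foreground pixel set. Each pixel is treated
# as a unit square, adding 1/12 to each axis variance, so a 1 x n bar has
# major-axis length exactly n and minor-axis length exactly 1.
mask_axes <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  r <- idx[, 1]
  c <- idx[, 2]
  n <- length(r)
  cr <- mean(r)
  cc <- mean(c)
  vrr <- mean((r - cr)^2) + 1 / 12
  vcc <- mean((c - cc)^2) + 1 / 12
  vrc <- mean((r - cr) * (c - cc))
  tr <- vrr + vcc
  det <- vrr * vcc - vrc^2
  disc <- sqrt(max(tr^2 / 4 - det, 0))
  l1 <- tr / 2 + disc
  l2 <- max(tr / 2 - disc, 1e-12)
  # principal direction (eigenvector of the larger eigenvalue), as a unit
  # vector (dr, dc); for an isotropic blob the direction is arbitrary and
  # fixed to the column axis.
  if (abs(vrc) > 1e-12) {
    dr <- l1 - vcc
    dc <- vrc
  } else if (vrr >= vcc) {
    dr <- 1
    dc <- 0
  } else {
    dr <- 0
    dc <- 1
  }
  nv <- sqrt(dr^2 + dc^2)
  dr <- dr / nv
  dc <- dc / nv
  list(
    centroid = c(cr, cc),
    major = sqrt(12 * l1),
    minor = sqrt(12 * l2),
    eccentricity = sqrt(max(1 - l2 / l1, 0)),
    dir_major = c(dr, dc),
    dir_minor = c(-dc, dr)
  )
}

# Reflection symmetry of the pixel set about an axis through the centroid.
# `axis_dir` is the direction of the mirror axis; the signed coordinate
# perpendicular to it is binned into unit bins and the overlap between the
# histogram and its mirror image is returned as a fraction in [0, 1].
mask_symmetry <- function(mask, axis_dir) {
  idx <- which(mask, arr.ind = TRUE)
  r <- idx[, 1] - mean(idx[, 1])
  c <- idx[, 2] - mean(idx[, 2])
  # perpendicular (signed) distance from the mirror axis
  u <- -r * axis_dir[2] + c * axis_dir[1]
  b <- round(u)
  m <- max(abs(b), 0)
  counts <- tabulate(b + m + 1L, nbins = 2L * m + 1L)
  sum(pmin(counts, rev(counts))) / length(u)
}
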