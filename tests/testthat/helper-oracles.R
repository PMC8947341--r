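# Independent brute-force oracles used to validate the vectorized
# implementations. These are deliberately written as naive loops / closed
# forms, sharing no code with the package internals.

# Centered inverse 2D DFT by explicit double loop over output pixels and
# input coefficients. K is stored DC-at-center (0-based center floor(n/2));
# normalization 1/(R*C).
oracle_centered_idft <- function(K) {
  R <- nrow(K); C <- ncol(K)
  r2 <- R %/% 2; c2 <- C %/% 2
  out <- matrix(complex(real = 0), R, C)
  for (x in 0:(R - 1)) for (y in 0:(C - 1)) {
    acc <- 0 + 0i
    for (u in 0:(R - 1)) for (v in 0:(C - 1)) {
      # frequency index of the DC-centered storage slot (u, v)
      fu <- u - r2; fv <- v - c2
      acc <- acc + K[u + 1, v + 1] *
        exp(2i * pi * (fu * x / R + fv * y / C))
    }
    out[x + 1, y + 1] <- acc / (R * C)
  }
  out
}

# winding-free even-odd point-in-polygon, one point at a time, using the
# classic ray casting formulation; boundary points counted inside via
# explicit distance-to-segment check
oracle_point_in_poly <- function(x, y, vx, vy) {
  n <- length(vx)
  for (i in seq_len(n)) {
    j <- if (i == 1L) n else i - 1L
    # distance from point to segment (vx[j],vy[j])-(vx[i],vy[i])
    ax <- vx[j]; ay <- vy[j]; bx <- vx[i]; by <- vy[i]
    L2 <- (bx - ax)^2 + (by - ay)^2
    t <- if (L2 == 0) 0 else
      max(0, min(1, ((x - ax) * (bx - ax) + (y - ay) * (by - ay)) / L2))
    d2 <- (x - (ax + t * (bx - ax)))^2 + (y - (ay + t * (by - ay)))^2
    if (d2 < 1e-18) return(TRUE)
  }
  crossings <- 0L
  for (i in seq_len(n)) {
    j <- if (i == 1L) n else i - 1L
    if ((vy[i] > y) != (vy[j] > y)) {
      xint <- vx[i] + (y - vy[i]) * (vx[j] - vx[i]) / (vy[j] - vy[i])
      if (x < xint) crossings <- crossings + 1L
    }
  }
  crossings %% 2L == 1L
}

# brute-force circle mask: enumerate every pixel center and test distance
oracle_circle_mask <- function(nr, nc, spacing, cx, cy, diameter) {
  m <- matrix(FALSE, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    px <- j - 0.5; py <- i - 0.5
    dmm2 <- ((px - cx) * spacing[2])^2 + ((py - cy) * spacing[1])^2
    m[i, j] <- dmm2 <= (diameter / 2)^2
  }
  m
}

# a small fixed-seed random magnitude image
rand_image <- function(nr, nc, seed = 1, spacing = c(0.25, 0.25)) {
  set.seed(seed)
  magnitude_image(matrix(runif(nr * nc), nr, nc), spacing)
}

# a small random complex k-space with a fixed seed
rand_kspace <- function(n, seed = 1, fov = c(64, 64)) {
  set.seed(seed)
  kspace(matrix(complex(real = rnorm(n * n), imaginary = rnorm(n * n)),
                n, n),
         nucleus = "Si29", fov_mm = fov)
}
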