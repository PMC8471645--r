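# digitized solid shapes used as analytic fixtures (built in code)

digitized_ball <- function(r, sp, margin = 5L) {
  n <- as.integer(ceiling(2 * r / sp)) + margin
  ctr <- (n + 1) / 2
  ax <- ((seq_len(n) - ctr) * sp)^2
  arr <- array(FALSE, c(n, n, n))
  yx <- outer(ax, ax, "+")
  for (i in seq_len(n)) arr[i, , ] <- ax[i] + yx <= r^2
  binary_mask(arr, c(sp, sp, sp))
}

# semi-axes (a, b, c) along (slice, row, column)
digitized_ellipsoid <- function(a, b, c, sp, margin = 5L) {
  nd <- as.integer(ceiling(2 * c(a, b, c) / sp)) + margin
  ctr <- (nd + 1) / 2
  zs <- ((seq_len(nd[1]) - ctr[1]) * sp / a)^2
  ys <- ((seq_len(nd[2]) - ctr[2]) * sp / b)^2
  xs <- ((seq_len(nd[3]) - ctr[3]) * sp / c)^2
  arr <- array(FALSE, nd)
  yx <- outer(ys, xs, "+")
  for (i in seq_len(nd[1])) arr[i, , ] <- zs[i] + yx <= 1
  binary_mask(arr, c(sp, sp, sp))
}

# axis-aligned solid box with exact physical extents (slice, row, column)
digitized_box <- function(extents, sp, margin = 4L) {
  nvox <- as.integer(round(extents / sp))
  nd <- nvox + 2L * margin
  arr <- array(FALSE, nd)
  arr[margin + seq_len(nvox[1]), margin + seq_len(nvox[2]),
      margin + seq_len(nvox[3])] <- TRUE
  binary_mask(arr, sp)
}

# analytic ellipsoid surface area by numerical integration
ellipsoid_area_numeric <- function(a, b, c) {
  outer_int <- Vectorize(function(th) {
    integrate(function(ph)
      sqrt((b * c * sin(th)^2 * cos(ph))^2 +
             (a * c * sin(th)^2 * sin(ph))^2 +
             (a * b * sin(th) * cos(th))^2),
      0, 2 * pi, rel.tol = 1e-9)$value
  })
  integrate(outer_int, 0, pi, rel.tol = 1e-8)$value
}

# hand-built closed unit-cube mesh (8 vertices, 12 outward-oriented faces)
unit_cube_mesh <- function() {
  v <- rbind(c(0,0,0), c(1,0,0), c(1,1,0), c(0,1,0),
             c(0,0,1), c(1,0,1), c(1,1,1), c(0,1,1))
  f <- rbind(c(1,3,2), c(1,4,3),    # bottom (z=0), normal -z
             c(5,6,7), c(5,7,8),    # top (z=1), normal +z
             c(1,2,6), c(1,6,5),    # y=0 side
             c(2,3,7), c(2,7,6),    # x=1 side
             c(3,4,8), c(3,8,7),    # y=1 side
             c(4,1,5), c(4,5,8))    # x=0 side
  structure(list(vertices = v, faces = f), class = "triangle_mesh")
}

# independent connected-component oracle: iterative minimum-label
# propagation over the chosen neighbourhood (vectorized array shifts),
# deliberately different from the package's stack-based flood fill
label_propagation_oracle <- function(mask, connectivity) {
  d <- dim(mask)
  offs <- list()
  for (ds in -1:1) for (dr in -1:1) for (dc in -1:1) {
    nz <- abs(ds) + abs(dr) + abs(dc)
    if (nz == 0) next
    if (connectivity == 6 && nz > 1) next
    if (connectivity == 18 && nz > 2) next
    offs[[length(offs) + 1L]] <- c(ds, dr, dc)
  }
  lab <- array(seq_len(prod(d)), d)
  lab[!mask] <- 0L
  shift_arr <- function(x, o) {
    out <- array(0L, d)
    src <- lapply(1:3, function(k) {
      i <- seq_len(d[k]) + o[k]
      i[i < 1 | i > d[k]] <- NA
      i
    })
    dst <- lapply(1:3, function(k) which(!is.na(src[[k]])))
    srcok <- lapply(1:3, function(k) src[[k]][!is.na(src[[k]])])
    out[dst[[1]], dst[[2]], dst[[3]]] <- x[srcok[[1]], srcok[[2]], srcok[[3]]]
    out
  }
  repeat {
    new <- lab
    for (o in offs) {
      sh <- shift_arr(lab, o)
      upd <- mask & sh > 0L & (new == 0L | sh < new)
      new[upd] <- sh[upd]
    }
    if (identical(new, lab)) break
    lab <- new
  }
  lab
}

# brute-force two-way ANOVA mean squares via stats::aov (independent of the
# package's closed-form sums of squares)
icc_aov_oracle <- function(m) {
  n <- nrow(m); k <- ncol(m)
  df <- data.frame(y = as.vector(m),
                   subj = factor(rep(seq_len(n), k)),
                   cond = factor(rep(seq_len(k), each = n)))
  ms <- summary(stats::aov(y ~ subj + cond, data = df))[[1]][["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

# paired two-scan table with a known true ICC (subject effect + noise)
simulate_icc_table <- function(n, icc_true, k = 2) {
  s <- rnorm(n, 0, sqrt(icc_true))
  s + matrix(rnorm(n * k, 0, sqrt(1 - icc_true)), n, k)
}
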