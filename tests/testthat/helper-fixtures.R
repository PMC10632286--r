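# Fixtures and independent oracles used across the suite. Oracles are kept
# deliberately naive (double loops, direct formulas) and never call the
# code paths they check.

unit_cube_mesh <- function(edge = 1, origin = c(0, 0, 0)) {
  v <- as.matrix(expand.grid(x = c(0, edge), y = c(0, edge), z = c(0, edge)))
  v <- sweep(unname(v), 2, origin, `+`)
  # 12 outward-wound triangles of the axis-aligned cube
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4),   # z = 0
    c(5, 6, 7), c(6, 8, 7),   # z = edge
    c(1, 2, 5), c(2, 6, 5),   # y = 0
    c(3, 7, 4), c(4, 7, 8),   # y = edge
    c(1, 5, 3), c(3, 5, 7),   # x = 0
    c(2, 4, 6), c(4, 8, 6))   # x = edge
  surface_mesh(v, f, name = "cube")
}

# geodesic rotation angle of a rigid transform (independent of the Euler path)
rotation_angle <- function(m) {
  R <- m$matrix[1:3, 1:3]
  acos(max(-1, min(1, (sum(diag(R)) - 1) / 2)))
}

# random blobby mask: union of a few random cuboids inside dims
random_mask <- function(dims, n_blobs = 3) {
  m <- array(FALSE, dims)
  for (i in seq_len(n_blobs)) {
    lo <- pmax(1, floor(runif(3, 1, dims - 2)))
    hi <- pmin(dims, lo + floor(runif(3, 1, dims / 2)))
    m[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
  }
  if (!any(m)) m[1, 1, 1] <- TRUE
  m
}

# oracle boundary extraction: 6-neighbour foreground/background test by
# explicit voxel loop over foreground voxels
oracle_boundary <- function(mask, spacing = 1) {
  d <- dim(mask)
  idx <- which(mask, arr.ind = TRUE)
  on_boundary <- apply(idx, 1, function(v) {
    for (s in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                   c(0, 0, 1), c(0, 0, -1))) {
      w <- v + s
      if (any(w < 1) || any(w > d)) return(TRUE)
      if (!mask[w[1], w[2], w[3]]) return(TRUE)
    }
    FALSE
  })
  (idx[on_boundary, , drop = FALSE] - 1) * spacing
}

# oracle agreement metrics by explicit double loop over boundary points
oracle_metrics <- function(a, b, spacing = 1) {
  pa <- oracle_boundary(a, spacing)
  pb <- oracle_boundary(b, spacing)
  dmat <- sqrt(outer(rowSums(pa^2), rowSums(pb^2), `+`) - 2 * pa %*% t(pb))
  dmat[dmat < 0 | is.nan(dmat)] <- 0
  dab <- apply(dmat, 1, min)
  dba <- apply(dmat, 2, min)
  pool <- c(dab, dba)
  list(dsc = 2 * sum(a & b) / (sum(a) + sum(b)),
       masd = mean(pool), hd = max(pool),
       hd95 = as.numeric(quantile(pool, 0.95, type = 7)))
}

# oracle ICC by explicit ANOVA sums of squares
oracle_icc <- function(tab) {
  n <- nrow(tab); k <- ncol(tab)
  gm <- mean(tab)
  ssr <- 0
  for (i in seq_len(n)) ssr <- ssr + k * (mean(tab[i, ]) - gm)^2
  ssc <- 0
  for (j in seq_len(k)) ssc <- ssc + n * (mean(tab[, j]) - gm)^2
  sst <- sum((tab - gm)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1); msc <- ssc / (k - 1); mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

# small default bone case shared by the planning tests
test_bone <- local({
  cache <- new.env()
  function(seed = 3, wedge_angle = 20 * pi / 180, wedge_station = 60) {
    key <- paste(seed, wedge_angle, wedge_station)
    if (is.null(cache[[key]])) {
      spec <- synthetic_case_spec(seed = seed, wedge_angle = wedge_angle,
                                  wedge_station = wedge_station)
      healthy <- make_healthy_bone(spec)
      wd <- apply_wedge(healthy, spec)
      cache[[key]] <- list(spec = spec, healthy = healthy,
                           contralateral = mirror_sagittal(healthy),
                           deformed = wd$deformed, truth = wd$truth)
    }
    cache[[key]]
  }
})
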