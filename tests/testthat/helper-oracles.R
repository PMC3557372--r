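# Independent oracles and fixture builders used across test files.
# Each oracle is deliberately naive (loops, exhaustive search) and shares
# no code with the implementation paths it checks.

# exhaustive nearest-cell-center search; ties toward lower (row, col)
brute_nearest_cell <- function(lon, lat, stack) {
  d <- dim(stack$layers[[1]])
  centers <- cell_centers(stack)
  best <- c(NA_integer_, NA_integer_)
  best_d2 <- Inf
  for (j in seq_len(d[2])) {
    for (i in seq_len(d[1])) {
      d2 <- (lon - centers$lon[j])^2 + (lat - centers$lat[i])^2
      if (d2 < best_d2 - 1e-12) {
        best_d2 <- d2
        best <- c(i, j)
      }
    }
  }
  best
}

# direct product-Gaussian mixture evaluation at every cell center
direct_kernel_density <- function(points, grid, bw) {
  r <- grid$r
  d <- grid$d
  cells <- as.matrix(expand.grid(lapply(seq_len(d),
                                        function(a) seq_len(r))))
  dens <- numeric(nrow(cells))
  for (ci in seq_len(nrow(cells))) {
    total <- 0
    for (p in seq_len(nrow(points))) {
      contrib <- 1
      for (a in seq_len(d)) {
        center <- grid$centers[[a]][cells[ci, a]]
        contrib <- contrib * exp(-0.5 * ((center - points[p, a]) / bw[a])^2) /
          (bw[a] * sqrt(2 * pi))
      }
      total <- total + contrib
    }
    dens[ci] <- total
  }
  out <- array(0, dim = rep(r, d))
  out[cells] <- dens
  out / sum(out)
}

# second, independent route to Schoener's D: sum of cellwise minima
# (valid because both surfaces are normalized to total mass 1)
direct_schoener <- function(z1, z2) {
  sum(pmin(as.numeric(z1), as.numeric(z2)))
}

# exhaustive nearest-hex-center search over a candidate neighborhood
brute_hex_assign <- function(lon, lat, grid) {
  x <- lon - grid$origin[1]
  y <- lat - grid$origin[2]
  s <- grid$size
  qf <- (sqrt(3) / 3 * x - 1 / 3 * y) / s
  rf <- (2 / 3 * y) / s
  cand <- expand.grid(q = round(qf) + (-2:2), r = round(rf) + (-2:2))
  cx <- grid$origin[1] + s * sqrt(3) * (cand$q + cand$r / 2)
  cy <- grid$origin[2] + s * 1.5 * cand$r
  k <- which.min((lon - cx)^2 + (lat - cy)^2)
  c(q = cand$q[k], r_ax = cand$r[k])
}

# small two-variable monthly stack with spatial structure
tiny_stack <- function(nrow = 8, ncol = 10, seed = 1, noise_sd = 0.5) {
  spec <- seasonal_field_spec(
    variables = tibble::tribble(
      ~variable, ~base, ~dlon, ~dlat, ~amplitude, ~amp_dlat, ~phase, ~noise_sd,
      "LST",      20,    0.3,   -0.8,  6,          0,          7,      noise_sd,
      "NDVI",      0.5,  -0.01,  0.01, 0.2,        0,          5,      noise_sd / 50
    ),
    nrow = nrow, ncol = ncol, origin = c(0, 40), cell_size = 0.5
  )
  simulate_raster_stack(spec, seed = seed)
}

# a stack whose cells belong to two spatial blocks with well-separated
# seasonal archetypes; returns the stack and the generating labels
archetype_stack <- function(nrow = 10, ncol = 12, seed = 1,
                            noise_sd = 0.5) {
  base <- withr::with_seed(seed, {
    labels <- matrix(rep(c(1L, 2L), each = nrow * ncol / 2), nrow = nrow)
    layers <- list()
    for (m in 1:12) {
      season <- cos(2 * pi * (m - 7) / 12)
      lst <- ifelse(labels == 1, 8 + 4 * season, 24 + 10 * season)
      ndvi <- ifelse(labels == 1, 0.7 - 0.2 * season, 0.3 + 0.1 * season)
      layers[[sprintf("LST_%02d", m)]] <-
        lst + matrix(rnorm(nrow * ncol, 0, noise_sd), nrow)
      layers[[sprintf("NDVI_%02d", m)]] <-
        ndvi + matrix(rnorm(nrow * ncol, 0, noise_sd / 25), nrow)
    }
    list(stack = raster_stack(layers, c(0, 40), 0.5), labels = labels)
  })
  base
}

write_records_csv <- function(rows, path = tempfile(fileext = ".csv")) {
  readr::write_csv(rows, path, na = "")
  path
}

# 200 null-calibration equivalency tests (n = 30 per sample from one
# niche, N = 99 permutations) are used both for the type-I-error rate and
# for p-value uniformity; computed once and cached for the session
.calib_cache <- new.env(parent = emptyenv())
null_calibration_pvalues <- function(n_rep = 200) {
  key <- paste0("p", n_rep)
  if (is.null(.calib_cache[[key]])) {
    .calib_cache[[key]] <- vapply(seq_len(n_rep), function(i) {
      s1 <- simulate_niche_scores(c(0, 0), c(1, 1), 30, seed = 2 * i)
      s2 <- simulate_niche_scores(c(0, 0), c(1, 1), 30, seed = 2 * i + 1)
      equivalency_test(s1, s2, correct = FALSE, n_perm = 99,
                       seed = 10000 + i)$p_value
    }, numeric(1))
  }
  .calib_cache[[key]]
}
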