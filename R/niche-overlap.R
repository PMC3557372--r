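#' Define a regular grid over climate space
#'
#' Divides each retained axis into `r` equal bins spanning the pooled range
#' of background and occurrence scores, optionally expanded by a margin
#' fraction so kernel mass near the data edge is not truncated. Bins are
#' half-open `[low, high)` with the last bin closed, so every point in
#' range falls in exactly one cell and a point exactly on an interior edge
#' belongs to the higher bin.
#'
#' @param background_scores,occurrence_scores Data frames or matrices of
#'   scores; columns beyond the first `d` named `axis1..axisd` (or the
#'   first `d` numeric columns) are used.
#' @param d Dimensionality of the grid (2 or 3).
#' @param r Bins per axis (default 100, the convention of kernel-based
#'   niche-overlap analyses).
#' @param margin Fractional expansion of each axis range (default 0.05).
#' @return A `climate_grid`: `d`, `r`, `bounds` (d x 2), per-axis `edges`
#'   and `centers`, `margin`.
#' @export
make_grid <- function(background_scores, occurrence_scores = NULL,
                      d = 2, r = 100, margin = 0.05) {
  if (r < 2) rlang::abort("r must be at least 2")
  pooled <- rbind(score_matrix(background_scores, d),
                  if (!is.null(occurrence_scores))
                    score_matrix(occurrence_scores, d))
  if (nrow(pooled) == 0) rlang::abort("no scores supplied")
  bounds <- t(apply(pooled, 2, range))
  span <- bounds[, 2] - bounds[, 1]
  if (any(span == 0)) {
    rlang::abort(paste0("degenerate axis (min = max): axis ",
                        which(span == 0)[1]))
  }
  bounds[, 1] <- bounds[, 1] - margin * span
  bounds[, 2] <- bounds[, 2] + margin * span
  edges <- lapply(seq_len(d), function(a)
    seq(bounds[a, 1], bounds[a, 2], length.out = r + 1))
  centers <- lapply(edges, function(e) (e[-1] + e[-length(e)]) / 2)
  structure(list(d = as.integer(d), r = as.integer(r), bounds = bounds,
                 edges = edges, centers = centers, margin = margin),
            class = "climate_grid")
}

#' @export
print.climate_grid <- function(x, ...) {
  cat(sprintf("<climate_grid> %d axes x %d bins\n", x$d, x$r))
  for (a in seq_len(x$d)) {
    cat(sprintf("  axis %d: [%.3f, %.3f]\n", a, x$bounds[a, 1],
                x$bounds[a, 2]))
  }
  invisible(x)
}

# coerce scores to an n x d numeric matrix
score_matrix <- function(scores, d) {
  if (is.null(scores)) return(NULL)
  if (is.data.frame(scores)) {
    axis_cols <- paste0("axis", seq_len(d))
    if (all(axis_cols %in% names(scores))) {
      scores <- scores[axis_cols]
    } else {
      scores <- scores[vapply(scores, is.numeric, logical(1))]
    }
  }
  m <- as.matrix(scores)
  if (ncol(m) < d) {
    rlang::abort(sprintf("scores have %d column(s); %d axes required",
                         ncol(m), d))
  }
  m[, seq_len(d), drop = FALSE]
}

#' Assign points to grid cells
#'
#' @param scores Points as in [make_grid()].
#' @param grid A `climate_grid`.
#' @return An integer matrix (n x d) of per-axis bin indices; `NA` for
#'   points outside the grid bounds.
#' @export
grid_cell <- function(scores, grid) {
  m <- score_matrix(scores, grid$d)
  idx <- vapply(seq_len(grid$d), function(a) {
    i <- findInterval(m[, a], grid$edges[[a]], rightmost.closed = TRUE)
    i[i < 1 | i > grid$r] <- NA_integer_
    as.integer(i)
  }, integer(nrow(m)))
  matrix(idx, ncol = grid$d,
         dimnames = list(NULL, paste0("axis", seq_len(grid$d))))
}

#' Silverman's rule-of-thumb bandwidths per axis
#'
#' @param scores Points as in [make_grid()]; at least 2.
#' @param d Number of axes.
#' @param mult Scalar multiplier applied to each rule-of-thumb bandwidth.
#' @return Numeric vector of `d` bandwidths.
#' @export
silverman_bandwidths <- function(scores, d = ncol(score_matrix(scores, 1)),
                                 mult = 1) {
  m <- score_matrix(scores, d)
  if (nrow(m) < 2) rlang::abort("need at least 2 points for a bandwidth")
  bw <- apply(m, 2, stats::bw.nrd0) * mult
  if (any(bw <= 0)) rlang::abort("degenerate bandwidth (zero spread?)")
  bw
}

#' Gaussian kernel density on a climate-space grid
#'
#' Evaluates a product-Gaussian mixture (one component per point, one
#' bandwidth per axis) at every cell center and normalizes the result to
#' sum to 1 over the grid. Evaluation is exact at cell centers — no
#' binning approximation — implemented as a separable tensor contraction.
#'
#' @param points Points as in [make_grid()].
#' @param grid A `climate_grid`.
#' @param bandwidths Positive per-axis bandwidths (length `d`), e.g. from
#'   [silverman_bandwidths()].
#' @return A `d`-dimensional array (`r` cells per axis) summing to 1.
#' @export
kernel_density <- function(points, grid, bandwidths) {
  m <- score_matrix(points, grid$d)
  if (nrow(m) < 1) rlang::abort("need at least 1 point")
  if (length(bandwidths) == 1) bandwidths <- rep(bandwidths, grid$d)
  if (length(bandwidths) != grid$d || any(bandwidths <= 0)) {
    rlang::abort("bandwidths must be positive, one per axis")
  }
  # per-axis kernel matrices: r x n
  g <- lapply(seq_len(grid$d), function(a) {
    outer(grid$centers[[a]], m[, a],
          function(c, p) stats::dnorm(c, p, bandwidths[a]))
  })
  if (grid$d == 1) {
    dens <- rowSums(g[[1]])
  } else {
    # khatri-rao over axes 1..d-1, then one matrix product with axis d
    w <- g[[1]]
    if (grid$d > 2) {
      for (a in 2:(grid$d - 1)) {
        nprev <- nrow(w)
        w <- w[rep(seq_len(nprev), times = grid$r), , drop = FALSE] *
          g[[a]][rep(seq_len(grid$r), each = nprev), , drop = FALSE]
      }
    }
    dens <- w %*% t(g[[grid$d]])
  }
  dens <- array(dens, dim = rep(grid$r, grid$d))
  total <- sum(dens)
  if (total <= 0) rlang::abort("kernel density vanished on the grid")
  dens / total
}

#' Availability-corrected occupancy
#'
#' Converts an occurrence density `o` and an availability (background
#' environment) density `e` on the same grid into a normalized occupancy
#' `z`. With correction on, `z` is proportional to `o / e` on cells where
#' availability exceeds a floor `eps` and 0 elsewhere — occupancy relative
#' to what the environment offers; with correction off, `z = o`.
#'
#' @param o,e Density arrays from [kernel_density()], each summing to 1.
#' @param correct Apply the availability correction? Default `TRUE`.
#' @param eps Availability floor as a fraction of total mass; cells below
#'   it are treated as uninhabitable. Default `1e-12`.
#' @return An array of the same shape summing to 1, zero wherever `e` is
#'   below the floor.
#' @export
occupancy <- function(o, e, correct = TRUE, eps = 1e-12) {
  if (!identical(dim(o), dim(e))) {
    rlang::abort("o and e must be on the same grid")
  }
  if (!correct) return(o / sum(o))
  habitable <- e > eps
  if (!any(habitable)) {
    rlang::abort("availability is below the floor everywhere; no environment to occupy")
  }
  z <- array(0, dim = dim(o))
  z[habitable] <- o[habitable] / e[habitable]
  total <- sum(z)
  if (total <= 0) {
    rlang::abort("occurrence density has no mass on habitable cells")
  }
  z / total
}

#' Schoener's D niche overlap
#'
#' `D = 1 - 0.5 * sum(|z1 - z2|)` over all grid cells, for two occupancy
#' distributions normalized on the same grid. Symmetric, bounded in
#' \[0, 1\]; 1 iff the distributions coincide cell-by-cell, 0 iff their
#' supports are disjoint.
#'
#' @param z1,z2 Arrays of identical shape, each summing to 1.
#' @return A single number in \[0, 1\].
#' @examples
#' schoener_d(c(0.5, 0.25, 0.25, 0), c(0.25, 0.25, 0.25, 0.25)) # 0.75
#' @export
schoener_d <- function(z1, z2) {
  if (!identical(dim(z1), dim(z2)) || length(z1) != length(z2)) {
    rlang::abort("z1 and z2 must be on the same grid")
  }
  1 - 0.5 * sum(abs(z1 - z2))
}

#' Kernel-smoothed occupancy density for one species
#'
#' Runs the full density pipeline: occurrence scores are kernel-smoothed on
#' the grid (Silverman bandwidths times `bandwidth_mult`), the background
#' scores provide the availability density, and [occupancy()] yields the
#' normalized occupancy `z`.
#'
#' @param occ_scores Occurrence scores (data frame with `axis*` columns or
#'   matrix).
#' @param background_scores Background scores on the same axes; required
#'   when `correct = TRUE`.
#' @param grid A `climate_grid`; built from the pooled scores when `NULL`.
#' @param bandwidth_mult Multiplier on the rule-of-thumb bandwidths.
#' @param correct Availability correction, see [occupancy()].
#' @param species Optional label carried in the result.
#' @return A `niche_density`: `species`, `grid`, arrays `o`, `e`, `z`,
#'   `bandwidths`, `n_occurrences`.
#' @export
niche_density <- function(occ_scores, background_scores = NULL, grid = NULL,
                          bandwidth_mult = 1, correct = TRUE,
                          species = NA_character_) {
  if (correct && is.null(background_scores)) {
    rlang::abort("background_scores required for availability correction")
  }
  if (is.null(grid)) {
    grid <- make_grid(if (is.null(background_scores)) occ_scores
                      else background_scores, occ_scores)
  }
  occ <- score_matrix(occ_scores, grid$d)
  bw <- silverman_bandwidths(occ, grid$d, bandwidth_mult)
  o <- kernel_density(occ, grid, bw)
  e <- NULL
  if (!is.null(background_scores)) {
    bg <- score_matrix(background_scores, grid$d)
    e <- kernel_density(bg, grid, silverman_bandwidths(bg, grid$d,
                                                       bandwidth_mult))
  }
  z <- if (correct) occupancy(o, e) else o
  structure(list(species = species, grid = grid, o = o, e = e, z = z,
                 bandwidths = bw, n_occurrences = nrow(occ)),
            class = "niche_density")
}

#' @export
print.niche_density <- function(x, ...) {
  cat(sprintf("<niche_density> %s: %d occurrences on a %d^%d grid\n",
              ifelse(is.na(x$species), "(unnamed)", x$species),
              x$n_occurrences, x$grid$r, x$grid$d))
  invisible(x)
}

#' Tidy a niche density into a cell table
#'
#' @param x A `niche_density`.
#' @param ... Unused.
#' @return A tibble with the cell-center coordinates (`axis1..axisd`) and
#'   columns `o`, `e` (if available) and `z`.
#' @export
tidy.niche_density <- function(x, ...) {
  # expand_grid varies the last column fastest; array storage varies the
  # first index fastest, so list axes in reverse and reorder the columns
  coords <- do.call(
    tidyr::expand_grid,
    rlang::set_names(x$grid$centers[rev(seq_len(x$grid$d))],
                     paste0("axis", rev(seq_len(x$grid$d))))
  )[, paste0("axis", seq_len(x$grid$d))]
  out <- tibble::tibble(!!!coords, o = as.numeric(x$o),
                        z = as.numeric(x$z))
  if (!is.null(x$e)) out$e <- as.numeric(x$e)
  out
}

#' Permutation test of niche equivalency
#'
#' Tests whether two species' occupancy of climate space is as similar as
#' expected when their occurrence points are interchangeable. Observed
#' Schoener's D comes from the full density pipeline; the null reallocates
#' the pooled occurrence scores at random into groups of the original sizes
#' (without replacement), recomputing the whole pipeline — bandwidths
#' included — per replicate. The p-value is one-sided on the lower tail
#' with the add-one convention, `p = (1 + #\{D_null <= D_obs\}) / (N + 1)`:
#' equivalency is rejected when the observed niches are less similar than
#' random reallocation produces.
#'
#' @inheritParams niche_density
#' @param occ1,occ2 Occurrence scores of the two species (>= 5 each).
#' @param n_perm Number of permutation replicates `N` (>= 19; default 99).
#' @param seed Integer seed making the permutations reproducible.
#' @param species Length-2 character label for the pair.
#' @return An `equivalency_test`: `species`, `D`, `null_D` (length `N`),
#'   `p_value`, `n_perm`, `seed`, `grid`.
#' @export
equivalency_test <- function(occ1, occ2, background_scores = NULL,
                             grid = NULL, d = 2, r = 100, margin = 0.05,
                             bandwidth_mult = 1,
                             correct = !is.null(background_scores),
                             n_perm = 99, seed = 1,
                             species = c("species 1", "species 2")) {
  m1 <- score_matrix(occ1, d)
  m2 <- score_matrix(occ2, d)
  if (nrow(m1) < 5) rlang::abort(paste0("too few occurrences for ", species[1]))
  if (nrow(m2) < 5) rlang::abort(paste0("too few occurrences for ", species[2]))
  if (n_perm < 19) rlang::abort("n_perm must be at least 19")
  pooled <- rbind(m1, m2)
  if (is.null(grid)) {
    grid <- make_grid(if (is.null(background_scores)) pooled
                      else rbind(score_matrix(background_scores, d), pooled),
                      d = d, r = r, margin = margin)
  }
  e <- NULL
  if (correct) {
    bg <- score_matrix(background_scores, grid$d)
    e <- kernel_density(bg, grid,
                        silverman_bandwidths(bg, grid$d, bandwidth_mult))
  }
  pair_d <- function(a, b) {
    za <- pipeline_z(a, grid, bandwidth_mult, e)
    zb <- pipeline_z(b, grid, bandwidth_mult, e)
    schoener_d(za, zb)
  }
  d_obs <- pair_d(m1, m2)
  n1 <- nrow(m1)
  n <- nrow(pooled)
  null_d <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      pick <- sample.int(n, n1)
      pair_d(pooled[pick, , drop = FALSE], pooled[-pick, , drop = FALSE])
    }, numeric(1))
  })
  p <- (1 + sum(null_d <= d_obs)) / (n_perm + 1)
  structure(list(species = species, D = d_obs, null_D = null_d,
                 p_value = p, n_perm = n_perm, seed = seed, grid = grid),
            class = "equivalency_test")
}

pipeline_z <- function(points, grid, bandwidth_mult, e) {
  o <- kernel_density(points, grid,
                      silverman_bandwidths(points, grid$d, bandwidth_mult))
  if (is.null(e)) o else occupancy(o, e)
}

#' @export
print.equivalency_test <- function(x, ...) {
  cat(sprintf("<equivalency_test> %s vs %s\n", x$species[1], x$species[2]))
  cat(sprintf("  Schoener's D = %.3f, p = %.4f (%d permutations)\n",
              x$D, x$p_value, x$n_perm))
  invisible(x)
}

#' @export
tidy.equivalency_test <- function(x, ...) {
  tibble::tibble(replicate = seq_along(x$null_D), null_D = x$null_D)
}

#' @export
glance.equivalency_test <- function(x, ...) {
  tibble::tibble(species_1 = x$species[1], species_2 = x$species[2],
                 D = x$D, p_value = x$p_value, n_perm = x$n_perm,
                 seed = x$seed)
}

#' Pairwise Schoener's D matrix
#'
#' Computes D for every pair of species densities sharing one grid. The
#' result is the upper triangle as a long tibble (the matrix is symmetric
#' with unit diagonal by definition).
#'
#' @param densities Named list of `niche_density` objects on a common grid
#'   (names fall back to each density's `species` field). Entries with no
#'   occurrences are omitted with a warning.
#' @return A tibble with `species_1`, `species_2`, `D`.
#' @export
overlap_matrix <- function(densities) {
  if (is.null(names(densities)) || any(names(densities) == "")) {
    names(densities) <- vapply(densities, function(d)
      as.character(d$species), character(1))
  }
  empty <- vapply(densities, function(d) d$n_occurrences == 0, logical(1))
  if (any(empty)) {
    rlang::warn(paste0("omitting species with no occurrences: ",
                       paste(names(densities)[empty], collapse = ", ")))
    densities <- densities[!empty]
  }
  if (length(densities) < 2) {
    rlang::abort("need at least 2 species with occurrences")
  }
  ref <- densities[[1]]$grid
  for (d_ in densities[-1]) {
    if (!isTRUE(all.equal(d_$grid$bounds, ref$bounds)) ||
        d_$grid$r != ref$r || d_$grid$d != ref$d) {
      rlang::abort("all densities must share one grid")
    }
  }
  nm <- names(densities)
  pairs <- utils::combn(seq_along(densities), 2)
  tibble::tibble(
    species_1 = nm[pairs[1, ]],
    species_2 = nm[pairs[2, ]],
    D = apply(pairs, 2, function(p)
      schoener_d(densities[[p[1]]]$z, densities[[p[2]]]$z))
  )
}
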