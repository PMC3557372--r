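#' Unsupervised k-means habitat classification of a territory
#'
#' Classifies every valid raster cell from its 24-value seasonal profile
#' (12 monthly LST + 12 monthly NDVI features, or whatever layers the stack
#' holds). Features are standardized per (variable, month) column; clusters
#' are found with Lloyd's algorithm under the Euclidean metric, seeded by
#' k-means++ and restarted `n_restarts` times, keeping the solution with
#' the smallest within-cluster sum of squares. A cluster that empties
#' during iteration is reseeded at the point farthest from its own
#' centroid. Deterministic for a fixed seed; nodata cells stay unlabeled.
#'
#' @param stack A [raster_stack()].
#' @param k Number of categories (no defensible universal default exists;
#'   it must be chosen for the territory at hand).
#' @param seed Integer seed.
#' @param n_restarts Independent k-means++ restarts (default 10).
#' @param max_iter,tol Lloyd iteration cap and relative-objective
#'   convergence tolerance.
#' @return A `habitat_classification`: `labels` (integer matrix shaped like
#'   the stack, `NA` on nodata), `k`, `centroids` (k x p, standardized
#'   units), `centers_raw` (original units), `scaling` (means/sds),
#'   `wss` (total within-cluster sum of squares), `seed`, plus the stack
#'   geometry for writing/cross-tabulation.
#' @export
kmeans_classify <- function(stack, k, seed = 1, n_restarts = 10,
                            max_iter = 300, tol = 1e-6) {
  stopifnot(inherits(stack, "raster_stack"), k >= 1)
  bg <- background_env(stack)
  feat_cols <- names(stack$layers)
  x <- as.matrix(bg[feat_cols])
  if (nrow(x) < k) {
    rlang::abort(sprintf("only %d valid cells but k = %d", nrow(x), k))
  }
  mu <- colMeans(x)
  sd_ <- apply(x, 2, stats::sd)
  sd_[sd_ == 0] <- 1   # constant feature: carries no information, scale 1
  z <- sweep(sweep(x, 2, mu, `-`), 2, sd_, `/`)

  best <- NULL
  withr::with_seed(seed, {
    for (i in seq_len(n_restarts)) {
      fit <- lloyd_kmeans(z, k, max_iter, tol)
      if (is.null(best) || fit$wss < best$wss) best <- fit
    }
  })

  labels <- matrix(NA_integer_, nrow = dim(stack)[1], ncol = dim(stack)[2])
  labels[cbind(bg$cell_row, bg$cell_col)] <- best$cluster
  centers_raw <- sweep(sweep(best$centers, 2, sd_, `*`), 2, mu, `+`)
  colnames(centers_raw) <- feat_cols
  structure(
    list(labels = labels, k = as.integer(k), centroids = best$centers,
         centers_raw = centers_raw,
         scaling = list(mean = mu, sd = sd_), wss = best$wss,
         seed = seed, origin = stack$origin, cell_size = stack$cell_size,
         nodata = stack$nodata),
    class = "habitat_classification"
  )
}

# Lloyd's algorithm with k-means++ seeding; x already standardized.
# Empty clusters are reseeded at the point farthest from its centroid.
lloyd_kmeans <- function(x, k, max_iter = 300, tol = 1e-6) {
  n <- nrow(x)
  centers <- x[kmeanspp_init(x, k), , drop = FALSE]
  obj_prev <- Inf
  cl <- rep(1L, n)
  for (it in seq_len(max_iter)) {
    d2 <- dist2_to_centers(x, centers)
    cl <- max.col(-d2, ties.method = "first")
    mind2 <- d2[cbind(seq_len(n), cl)]
    for (j in seq_len(k)) {
      members <- cl == j
      if (!any(members)) {
        far <- which.max(mind2)
        centers[j, ] <- x[far, ]
        cl[far] <- j
        members <- cl == j
        mind2[far] <- 0
      }
      centers[j, ] <- colMeans(x[members, , drop = FALSE])
    }
    obj <- sum(mind2)
    if (is.finite(obj_prev) &&
        abs(obj_prev - obj) <= tol * max(obj_prev, .Machine$double.eps)) {
      break
    }
    obj_prev <- obj
  }
  d2 <- dist2_to_centers(x, centers)
  cl <- max.col(-d2, ties.method = "first")
  list(cluster = cl, centers = centers,
       wss = sum(d2[cbind(seq_len(n), cl)]))
}

kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  idx <- integer(k)
  idx[1] <- sample.int(n, 1)
  if (k == 1) return(idx)
  d2 <- rowSums(sweep(x, 2, x[idx[1], ], `-`)^2)
  for (j in 2:k) {
    if (sum(d2) <= 0) {
      idx[j] <- sample.int(n, 1)   # all points coincide with a center
    } else {
      idx[j] <- sample.int(n, 1, prob = d2)
    }
    d2 <- pmin(d2, rowSums(sweep(x, 2, x[idx[j], ], `-`)^2))
  }
  idx
}

dist2_to_centers <- function(x, centers) {
  # ||x - c||^2 = ||x||^2 - 2 x.c + ||c||^2, clipped at 0 for roundoff
  d2 <- outer(rowSums(x^2), rowSums(centers^2), `+`) -
    2 * x %*% t(centers)
  d2[d2 < 0] <- 0
  d2
}

#' @export
print.habitat_classification <- function(x, ...) {
  cat(sprintf("<habitat_classification> k = %d over %d labeled cells (seed %d)\n",
              x$k, sum(!is.na(x$labels)), x$seed))
  cat(sprintf("  within-cluster SS (standardized): %.3f\n", x$wss))
  invisible(x)
}

#' Per-category seasonal statistics
#'
#' Mean and population standard deviation of every (variable, month) layer
#' over the member cells of each habitat category, with cell counts — the
#' seasonal signature of each class. An empty category is reported with
#' `n_cells = 0` and `NA` statistics.
#'
#' @param cls A `habitat_classification`.
#' @param stack The [raster_stack()] it was fitted on (co-registered).
#' @return A tibble with `category`, `variable`, `month`, `mean`, `sd`,
#'   `n_cells`.
#' @export
category_stats <- function(cls, stack) {
  stopifnot(inherits(cls, "habitat_classification"),
            inherits(stack, "raster_stack"))
  if (!identical(dim(cls$labels), dim(stack))) {
    rlang::abort("classification and stack are not co-registered")
  }
  lab <- as.integer(cls$labels)
  pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
  purrr::map_dfr(seq_len(cls$k), function(cat) {
    members <- !is.na(lab) & lab == cat
    purrr::map_dfr(seq_along(stack$layers), function(li) {
      v <- as.numeric(stack$layers[[li]])[members]
      v <- v[!is.na(v)]
      tibble::tibble(
        category = cat,
        variable = stack$index$variable[li],
        month = stack$index$month[li],
        mean = if (length(v)) mean(v) else NA_real_,
        sd = if (length(v)) pop_sd(v) else NA_real_,
        n_cells = sum(members)
      )
    })
  })
}

#' Construct a categorical raster
#'
#' A single integer-labeled grid (e.g. land biomes) on the same plain-text
#' raster geometry as a [raster_stack()], for cross-tabulation against
#' records.
#'
#' @param values Integer matrix, row 1 = southern edge; `NA` = nodata.
#' @param origin,cell_size,nodata As in [raster_stack()].
#' @return A `categorical_raster`.
#' @export
categorical_raster <- function(values, origin, cell_size, nodata = -9999) {
  structure(list(labels = values, origin = as.numeric(origin),
                 cell_size = cell_size, nodata = nodata),
            class = "categorical_raster")
}

#' Cross-tabulate records against a categorical raster
#'
#' Counts and row percentages of each species' records per category of a
#' habitat classification or categorical (e.g. biome) raster, using the
#' same nearest-cell lookup as [attach_environment()]. Records landing on
#' nodata cells or outside the extent are tallied in an `unassigned`
#' category — a normal outcome, not an error.
#'
#' @param records A record tibble with `species`, `lon`, `lat`.
#' @param categories A `habitat_classification` or [categorical_raster()].
#' @return A tibble with `species`, `category` (integer; `NA` =
#'   unassigned), `n`, `pct`. Percentages are over assigned records of the
#'   species and sum to 100 within rounding; the unassigned row carries
#'   `pct = NA`.
#' @export
crosstab_categorical <- function(records, categories) {
  check_columns(records, c("species", "lon", "lat"), "records")
  if (!inherits(categories, c("habitat_classification",
                              "categorical_raster"))) {
    rlang::abort("categories must be a habitat_classification or categorical_raster")
  }
  lab <- categories$labels
  d <- dim(lab)
  col <- nearest_index(records$lon, categories$origin[1],
                       categories$cell_size, d[2])
  row <- nearest_index(records$lat, categories$origin[2],
                       categories$cell_size, d[1])
  cat_ <- rep(NA_integer_, nrow(records))
  ok <- !is.na(col) & !is.na(row)
  cat_[ok] <- lab[cbind(row[ok], col[ok])]

  tibble::tibble(species = records$species, category = cat_) |>
    dplyr::count(.data$species, .data$category, name = "n") |>
    dplyr::group_by(.data$species) |>
    dplyr::mutate(pct = ifelse(
      is.na(.data$category), NA_real_,
      round_half_up(100 * .data$n / sum(.data$n[!is.na(.data$category)]),
                    1))) |>
    dplyr::ungroup()
}
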