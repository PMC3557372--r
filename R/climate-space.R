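#' Fit a reduced climate space by principal components analysis
#'
#' Reduces a matrix of monthly environmental covariates (rows = background
#' cells, columns = (variable, month) values such as `LST_01` ... `NDVI_12`)
#' to a low-dimensional climate space. The PCA is of the correlation matrix:
#' columns are standardized to zero mean and unit variance before
#' decomposition, because temperature and vegetation indices are on
#' incommensurable scales. Axis signs are arbitrary in PCA; here each axis
#' is oriented so that its largest-magnitude loading is positive, making
#' results reproducible across linear-algebra backends.
#'
#' @param env A data frame or matrix of numeric environmental columns with
#'   no missing values and no constant column. Non-numeric columns of a
#'   data frame (ids, coordinates) are ignored with a message.
#' @param n_axes Number of retained axes (2 for plotting, 3 by default).
#' @return A `climate_space` object: `variables` (column names), `means`,
#'   `sds` (standardization constants), `loadings` (columns orthonormal),
#'   `eigenvalues` (all axes, non-increasing), `n_axes`, and
#'   `background_scores` (tibble of training-row scores on retained axes).
#' @seealso [project_scores()], [interpret_axes()]
#' @export
fit_climate_space <- function(env, n_axes = 3) {
  x <- as.data.frame(env)
  numeric_cols <- vapply(x, is.numeric, logical(1))
  drop <- setdiff(names(x)[!numeric_cols],
                  c("cell_row", "cell_col", "lon", "lat"))
  if (length(drop) > 0) {
    rlang::inform(paste0("ignoring non-numeric column(s): ",
                         paste(drop, collapse = ", ")))
  }
  x <- x[numeric_cols]
  # geometry/bookkeeping columns from background_env() are not covariates
  x <- x[setdiff(names(x), c("cell_row", "cell_col", "lon", "lat"))]
  m <- as.matrix(x)
  if (nrow(m) < 2) rlang::abort("need at least 2 background rows")
  if (anyNA(m)) {
    rlang::abort(paste0(
      "environmental matrix contains missing values; drop incomplete ",
      "rows first (see attach_environment()'s env_complete flag)"))
  }
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0)) {
    rlang::abort(paste0("constant column(s): ",
                        paste(colnames(m)[sds == 0], collapse = ", ")))
  }
  if (!is.numeric(n_axes) || n_axes < 1 || n_axes > ncol(m)) {
    rlang::abort("n_axes must be between 1 and the number of columns")
  }

  pca <- stats::prcomp(m, center = TRUE, scale. = TRUE)
  loadings <- pca$rotation
  # orient each axis: largest-|loading| variable positive
  flip <- vapply(seq_len(ncol(loadings)), function(j) {
    sign(loadings[which.max(abs(loadings[, j])), j])
  }, numeric(1))
  loadings <- sweep(loadings, 2, flip, `*`)
  scores <- sweep(pca$x, 2, flip, `*`)

  cs <- structure(
    list(variables = colnames(m),
         means = pca$center, sds = pca$scale,
         loadings = loadings,
         eigenvalues = pca$sdev^2,
         n_axes = as.integer(n_axes),
         background_scores = tibble::as_tibble(
           scores[, seq_len(n_axes), drop = FALSE],
           .name_repair = ~ paste0("axis", seq_len(n_axes))),
         background_env = tibble::as_tibble(x)),
    class = "climate_space"
  )
  cs
}

#' @export
print.climate_space <- function(x, ...) {
  ve <- x$eigenvalues / sum(x$eigenvalues)
  cat(sprintf("<climate_space> %d variables, %d retained axes\n",
              length(x$variables), x$n_axes))
  cat(sprintf("  variance explained by retained axes: %.1f %%\n",
              100 * sum(ve[seq_len(x$n_axes)])))
  for (j in seq_len(x$n_axes)) {
    cat(sprintf("  axis %d: %.1f %%\n", j, 100 * ve[j]))
  }
  invisible(x)
}

#' Per-axis variance explained
#'
#' @param cs A `climate_space`.
#' @return A tibble with `axis`, `eigenvalue`, `prop_var`, `cum_var` over
#'   all axes (proportions sum to 1).
#' @export
variance_explained <- function(cs) {
  stopifnot(inherits(cs, "climate_space"))
  prop <- cs$eigenvalues / sum(cs$eigenvalues)
  tibble::tibble(axis = seq_along(prop), eigenvalue = cs$eigenvalues,
                 prop_var = prop, cum_var = cumsum(prop))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a climate space into a loadings table
#'
#' @param x A `climate_space`.
#' @param ... Unused.
#' @return A long tibble with `variable`, `axis`, `loading` for the
#'   retained axes.
#' @export
tidy.climate_space <- function(x, ...) {
  tibble::as_tibble(x$loadings[, seq_len(x$n_axes), drop = FALSE],
                    .name_repair = ~ paste0("axis", seq_len(x$n_axes))) |>
    dplyr::mutate(variable = x$variables, .before = 1) |>
    tidyr::pivot_longer(-"variable", names_to = "axis",
                        names_prefix = "axis", names_transform = as.integer,
                        values_to = "loading")
}

#' One-row summary of a climate space
#'
#' @param x A `climate_space`.
#' @param ... Unused.
#' @return A one-row tibble: `n_vars`, `n_axes`, `prop_var_retained`.
#' @export
glance.climate_space <- function(x, ...) {
  ve <- x$eigenvalues / sum(x$eigenvalues)
  tibble::tibble(n_vars = length(x$variables), n_axes = x$n_axes,
                 prop_var_retained = sum(ve[seq_len(x$n_axes)]))
}

#' Project environmental vectors into a fitted climate space
#'
#' Standardizes new rows with the training means/sds and multiplies by the
#' retained loadings; projecting the training background reproduces the
#' stored background scores.
#'
#' @param cs A `climate_space` from [fit_climate_space()].
#' @param env A data frame or matrix supplying every variable in
#'   `cs$variables` (extra columns such as record metadata are carried
#'   through untouched when `bind = TRUE`).
#' @param bind If `TRUE` (default) return `env` with score columns
#'   `axis1..axisK` appended; otherwise return only the score tibble.
#' @return A tibble of scores on the retained axes.
#' @export
project_scores <- function(cs, env, bind = TRUE) {
  stopifnot(inherits(cs, "climate_space"))
  x <- as.data.frame(env)
  missing <- setdiff(cs$variables, names(x))
  if (length(missing) > 0) {
    rlang::abort(paste0("env is missing climate-space variable(s): ",
                        paste(missing, collapse = ", ")))
  }
  m <- as.matrix(x[cs$variables])
  if (anyNA(m)) {
    rlang::abort("env has missing values on climate-space variables")
  }
  z <- sweep(sweep(m, 2, cs$means, `-`), 2, cs$sds, `/`)
  s <- z %*% cs$loadings[, seq_len(cs$n_axes), drop = FALSE]
  scores <- tibble::as_tibble(s, .name_repair = ~ paste0("axis",
                                                         seq_len(cs$n_axes)))
  if (bind && is.data.frame(env)) {
    dplyr::bind_cols(tibble::as_tibble(env), scores)
  } else {
    scores
  }
}

#' Correlate climate-space axes with interpretable derived variables
#'
#' The axes of a monthly-covariate PCA usually track simple summaries:
#' annual mean temperature, seasonal temperature amplitude, annual mean
#' greenness. This helper computes, over the training background, the
#' Pearson correlation of each retained axis with each derived variable so
#' the axes can be named. It is descriptive output, not a gate: signs are
#' reported but are a convention of axis orientation.
#'
#' @param cs A `climate_space`.
#' @param derived Optional data frame of derived variables (one row per
#'   background row). By default, for each variable prefix present
#'   (e.g. `LST`, `NDVI`): its annual mean (`<VAR>_mean`) and its annual
#'   range (`<VAR>_range`, max minus min over the 12 months).
#' @return A tibble with `axis`, `variable`, `r` (`NA` with a note for a
#'   zero-variance derived variable).
#' @export
interpret_axes <- function(cs, derived = NULL) {
  stopifnot(inherits(cs, "climate_space"))
  env <- cs$background_env
  if (is.null(derived)) {
    prefixes <- unique(sub("_[0-9]+$", "", cs$variables))
    derived <- purrr::map_dfc(rlang::set_names(prefixes), function(p) {
      cols <- grep(paste0("^", p, "_[0-9]+$"), names(env), value = TRUE)
      m <- as.matrix(env[cols])
      tibble::tibble("{p}_mean" := rowMeans(m),
                     "{p}_range" := apply(m, 1, max) - apply(m, 1, min))
    })
  }
  derived <- as.data.frame(derived)
  scores <- as.matrix(cs$background_scores)
  purrr::map_dfr(seq_len(cs$n_axes), function(j) {
    purrr::map_dfr(names(derived), function(v) {
      r <- if (stats::sd(derived[[v]]) == 0) NA_real_ else
        stats::cor(scores[, j], derived[[v]])
      tibble::tibble(axis = j, variable = v, r = r)
    })
  })
}
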