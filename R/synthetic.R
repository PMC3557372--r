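#' Specify synthetic seasonal environmental fields
#'
#' Describes smooth monthly fields with sinusoidal seasonal structure, one
#' row per variable: the monthly layer for variable *v* at month *m* is
#' `mean_surface + amplitude_surface * cos(2*pi*(m - phase)/12) + noise`,
#' where both surfaces are linear in lon/lat offsets from the grid origin.
#' The defaults emulate the western Palearctic at a desk scale: a 55 x 41
#' one-degree grid whose cell edges span 11°W–44°E, 29°N–70°N (nested
#' inside the 11°W–45°E, 29°N–71°N study window, so simulated records
#' jittered within edge cells stay inside it), land-surface temperature
#' warm in the south with a July peak and larger seasonal amplitude in the
#' north, and NDVI greener northward with a late-spring peak.
#'
#' @param variables Tibble with columns `variable`, `base`, `dlon`, `dlat`
#'   (mean surface), `amplitude`, `amp_dlat` (amplitude surface), `phase`
#'   (month of seasonal peak) and `noise_sd`.
#' @param nrow,ncol Grid shape (rows = latitude).
#' @param origin Lon/lat of the lower-left cell center.
#' @param cell_size Cell size in degrees.
#' @return A `seasonal_field_spec` object.
#' @export
seasonal_field_spec <- function(
    variables = tibble::tribble(
      ~variable, ~base, ~dlon,  ~dlat,  ~amplitude, ~amp_dlat, ~phase, ~noise_sd,
      "LST",      25,    0.02,  -0.45,   8,          0.10,       7,      1,
      "NDVI",      0.45, -0.001, 0.004,  0.15,       0.001,      5,      0.02
    ),
    nrow = 41, ncol = 55, origin = c(-10.5, 29.5), cell_size = 1) {
  check_columns(variables, c("variable", "base", "dlon", "dlat",
                             "amplitude", "amp_dlat", "phase", "noise_sd"),
                "variables")
  if (nrow < 1 || ncol < 1) rlang::abort("invalid grid shape")
  if (any(variables$amplitude < 0)) rlang::abort("amplitude must be >= 0")
  structure(list(variables = variables, nrow = as.integer(nrow),
                 ncol = as.integer(ncol), origin = as.numeric(origin),
                 cell_size = cell_size),
            class = "seasonal_field_spec")
}

#' Simulate a monthly raster stack with known seasonal structure
#'
#' Generates 12 layers per variable of a [seasonal_field_spec()]. A pure
#' function of (spec, seed): identical seeds give bit-identical stacks.
#' With zero noise, a least-squares cosine fit at any cell recovers the
#' cell's amplitude and phase exactly.
#'
#' @param spec A [seasonal_field_spec()].
#' @param seed Integer seed for the noise.
#' @return A [raster_stack()] of `12 * nrow(spec$variables)` layers.
#' @export
simulate_raster_stack <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "seasonal_field_spec"))
  lon <- spec$origin[1] + (seq_len(spec$ncol) - 1) * spec$cell_size
  lat <- spec$origin[2] + (seq_len(spec$nrow) - 1) * spec$cell_size
  dlon <- matrix(rep(lon - spec$origin[1], each = spec$nrow),
                 nrow = spec$nrow)
  dlat <- matrix(rep(lat - spec$origin[2], times = spec$ncol),
                 nrow = spec$nrow)
  layers <- withr::with_seed(seed, {
    out <- list()
    for (i in seq_len(nrow(spec$variables))) {
      v <- spec$variables[i, ]
      mean_surface <- v$base + v$dlon * dlon + v$dlat * dlat
      amp_surface <- pmax(v$amplitude + v$amp_dlat * dlat, 0)
      for (m in 1:12) {
        season <- cos(2 * pi * (m - v$phase) / 12)
        noise <- if (v$noise_sd > 0) {
          matrix(stats::rnorm(spec$nrow * spec$ncol, 0, v$noise_sd),
                 nrow = spec$nrow)
        } else 0
        out[[sprintf("%s_%02d", v$variable, m)]] <-
          mean_surface + amp_surface * season + noise
      }
    }
    out
  })
  raster_stack(layers, spec$origin, spec$cell_size)
}

#' Specify a Gaussian niche in environmental space
#'
#' A species' suitability over environmental conditions, as a Gaussian
#' density with mean `mu` and covariance `sigma` over named environmental
#' variables (layer names such as `LST_07`, or climate-space axes
#' `axis1..axisd` when used with [simulate_niche_scores()]).
#'
#' @param species Species label.
#' @param mu Named numeric mean vector.
#' @param sigma Covariance matrix (symmetric positive definite); a numeric
#'   vector is taken as a diagonal.
#' @param n_records Number of occurrence records to draw (>= 1).
#' @return A `niche_spec` object.
#' @export
niche_spec <- function(species, mu, sigma, n_records) {
  if (is.null(names(mu))) rlang::abort("mu must be a named vector")
  if (is.vector(sigma) && !is.matrix(sigma)) sigma <- diag(sigma,
                                                           length(mu))
  if (!isTRUE(all.equal(sigma, t(sigma))) ||
      any(eigen(sigma, symmetric = TRUE, only.values = TRUE)$values <= 0)) {
    rlang::abort("sigma must be symmetric positive definite")
  }
  if (n_records < 1) rlang::abort("n_records must be >= 1")
  structure(list(species = species, mu = mu, sigma = sigma,
                 n_records = as.integer(n_records)),
            class = "niche_spec")
}

# log Gaussian density (unnormalized constant is irrelevant for sampling
# weights but kept exact for the overlap oracle)
dmvn <- function(x, mu, sigma, log = FALSE) {
  ch <- chol(sigma)
  z <- forwardsolve(t(ch), t(x) - mu)
  logd <- -0.5 * colSums(z^2) - sum(log(diag(ch))) -
    0.5 * length(mu) * log(2 * pi)
  if (log) logd else exp(logd)
}

rmvn <- function(n, mu, sigma) {
  z <- matrix(stats::rnorm(n * length(mu)), nrow = n)
  sweep(z %*% chol(sigma), 2, mu, `+`)
}

#' Simulate occurrence records from Gaussian niches on a raster stack
#'
#' Draws each species' records by sampling grid cells with probability
#' proportional to the niche density evaluated at the cell's environmental
#' vector (optionally times a spatial sampling-bias field), jittering
#' coordinates uniformly within the source cell. Record metadata (hosts,
#' stages) and curation defects are injected at configured rates so the
#' validation filters can be exercised against known truth: defect counts
#' are exact (`round(rate * n)` records per defect, disjoint sets) and
#' recorded in the truth ledger retrievable with [simulation_truth()].
#'
#' Defect types map to [filter_records()] rules: `genus_only`,
#' `admin_division`, `ambiguous_name` set `locality_quality`;
#' `missing_coordinates` blanks the coordinates.
#'
#' @param niches List of [niche_spec()] objects (environmental-variable
#'   parametrization).
#' @param stack A [raster_stack()] supplying the environment.
#' @param seed Integer seed; generation is a pure function of
#'   (niches, stack, defect_rates, seed).
#' @param defect_rates Named list of rates in \[0, 1\] over defect types
#'   above (default: no defects).
#' @param bias Optional matrix (stack shape) of non-negative sampling
#'   weights multiplying the niche density.
#' @param hosts Tibble like [default_host_taxonomy()] from which host
#'   names are drawn (uniformly, with 30% of records left hostless).
#' @return A record tibble as from [read_records()], with attribute
#'   `"truth"`: the generating `niches`, the per-rule `defects` ledger
#'   (tibble `rule`, `n`, plus injected row ids), and `seed`.
#' @export
simulate_occurrences <- function(niches, stack, seed = 1,
                                 defect_rates = list(), bias = NULL,
                                 hosts = default_host_taxonomy()) {
  stopifnot(inherits(stack, "raster_stack"))
  if (inherits(niches, "niche_spec")) niches <- list(niches)
  bg <- background_env(stack)
  centers <- cell_centers(stack)

  records <- withr::with_seed(seed, {
    per_species <- purrr::map_dfr(niches, function(ns) {
      vars <- names(ns$mu)
      missing <- setdiff(vars, names(bg))
      if (length(missing) > 0) {
        rlang::abort(paste0("niche variable(s) not in stack: ",
                            paste(missing, collapse = ", ")))
      }
      # log scale, shifted by the maximum: a sharply peaked niche must
      # not underflow to zero suitability everywhere
      lw <- dmvn(as.matrix(bg[vars]), ns$mu, ns$sigma, log = TRUE)
      w <- exp(lw - max(lw))
      if (!is.null(bias)) w <- w * bias[cbind(bg$cell_row, bg$cell_col)]
      if (sum(w) <= 0 || !any(w > 0)) {
        rlang::abort(paste0("niche has zero suitability on the stack: ",
                            ns$species))
      }
      pick <- sample.int(nrow(bg), ns$n_records, replace = TRUE,
                         prob = w)
      jit_lon <- stats::runif(ns$n_records, -0.5, 0.5) * stack$cell_size
      jit_lat <- stats::runif(ns$n_records, -0.5, 0.5) * stack$cell_size
      has_host <- stats::runif(ns$n_records) < 0.7
      tibble::tibble(
        species_raw = ns$species,
        species = ns$species,
        lon = centers$lon[bg$cell_col[pick]] + jit_lon,
        lat = centers$lat[bg$cell_row[pick]] + jit_lat,
        year = sample(2000:2010, ns$n_records, replace = TRUE),
        day_of_year = NA_integer_,
        host_name = ifelse(has_host,
                           sample(hosts$host_name, ns$n_records,
                                  replace = TRUE), NA_character_),
        stage = sample(c("larva", "nymph", "adult"), ns$n_records,
                       replace = TRUE, prob = c(0.1, 0.2, 0.7)),
        collection_method = ifelse(has_host, "host", "dragging"),
        source_id = paste0("sim-", ns$species),
        locality_quality = "coordinates",
        region_tag = NA_character_
      )
    })
    per_species$.row <- seq_len(nrow(per_species))

    # inject curation defects on disjoint row sets with exact counts
    n <- nrow(per_species)
    available <- seq_len(n)
    ledger <- tibble::tibble(rule = character(), n = integer())
    injected <- list()
    for (rule in names(defect_rates)) {
      n_inject <- round(defect_rates[[rule]] * n)
      if (n_inject > length(available)) {
        rlang::abort("defect rates too high: fewer clean records than defects")
      }
      rows <- if (n_inject > 0) sort(sample(available, n_inject)) else integer()
      available <- setdiff(available, rows)
      if (rule %in% c("genus_only", "admin_division", "ambiguous_name")) {
        per_species$locality_quality[rows] <- rule
      } else if (rule == "missing_coordinates") {
        per_species$lon[rows] <- NA_real_
        per_species$lat[rows] <- NA_real_
        per_species$locality_quality[rows] <- "unambiguous_name"
      } else {
        rlang::abort(paste0("unknown defect type: ", rule))
      }
      ledger <- dplyr::bind_rows(ledger,
                                 tibble::tibble(rule = rule,
                                                n = length(rows)))
      injected[[rule]] <- rows
    }
    attr(per_species, "defect_ledger") <- ledger
    attr(per_species, "defect_rows") <- injected
    per_species
  })
  truth <- list(niches = niches,
                defects = attr(records, "defect_ledger"),
                defect_rows = attr(records, "defect_rows"),
                seed = seed)
  attr(records, "defect_ledger") <- NULL
  attr(records, "defect_rows") <- NULL
  attr(records, "truth") <- truth
  records
}

#' Generating truth of a simulated record set
#'
#' @param records A tibble from [simulate_occurrences()].
#' @return A list with elements `niches`, `defects` (tibble `rule`, `n`),
#'   `defect_rows`, `seed`.
#' @export
simulation_truth <- function(records) {
  attr(records, "truth")
}

#' Simulate occurrence scores directly in climate space
#'
#' Draws points from a Gaussian niche specified on climate-space axes —
#' the parametrization in which pairwise overlap has a numerical oracle
#' ([gaussian_overlap_d()]).
#'
#' @param mu,sigma Gaussian parameters over `d` axes (vector `sigma` is
#'   diagonal).
#' @param n Number of points.
#' @param seed Integer seed.
#' @return A tibble with columns `axis1..axisd`.
#' @export
simulate_niche_scores <- function(mu, sigma, n, seed = 1) {
  if (is.vector(sigma) && !is.matrix(sigma)) sigma <- diag(sigma,
                                                           length(mu))
  pts <- withr::with_seed(seed, rmvn(n, mu, sigma))
  tibble::as_tibble(matrix(pts, ncol = length(mu)),
                    .name_repair = ~ paste0("axis", seq_along(mu)))
}

#' Numerically integrated Schoener's D of two Gaussian niches
#'
#' The overlap oracle: evaluates both generating Gaussian densities at the
#' centers of a climate-space grid, normalizes each over the grid, and
#' applies the D formula directly — no sampling, no kernel smoothing.
#'
#' @param mu1,sigma1,mu2,sigma2 Gaussian parameters (vector sigmas are
#'   diagonal).
#' @param grid A `climate_grid` from [make_grid()] covering both niches.
#' @return Schoener's D of the discretized generating densities.
#' @export
gaussian_overlap_d <- function(mu1, sigma1, mu2, sigma2, grid) {
  if (is.vector(sigma1) && !is.matrix(sigma1)) sigma1 <- diag(sigma1, length(mu1))
  if (is.vector(sigma2) && !is.matrix(sigma2)) sigma2 <- diag(sigma2, length(mu2))
  centers <- do.call(
    tidyr::expand_grid,
    rlang::set_names(grid$centers[rev(seq_len(grid$d))],
                     paste0("axis", rev(seq_len(grid$d))))
  )[, paste0("axis", seq_len(grid$d))]
  m <- as.matrix(centers)
  p1 <- dmvn(m, mu1, sigma1)
  p2 <- dmvn(m, mu2, sigma2)
  schoener_d(p1 / sum(p1), p2 / sum(p2))
}

#' Published per-species record counts for tabulation checks
#'
#' The 16 species-level record counts of the western Palearctic tick
#' compilation (10,280 records in total), as printed in its summary table;
#' a fixture for exercising [summarize_counts()] arithmetic.
#'
#' @return A tibble with columns `species`, `n`.
#' @export
table1_counts <- function() {
  tibble::tribble(
    ~species,                          ~n,
    "Dermacentor marginatus",          734L,
    "Dermacentor reticulatus",         882L,
    "Haemaphysalis punctata",          479L,
    "Haemaphysalis sulcata",           298L,
    "Hyalomma anatolicum",             12L,
    "Hyalomma excavatum",              211L,
    "Hyalomma impeltatum",             8L,
    "Hyalomma lusitanicum",            526L,
    "Hyalomma marginatum",             787L,
    "Hyalomma scupense",               135L,
    "Ixodes canisuga",                 8L,
    "Ixodes hexagonus",                7L,
    "Ixodes ricinus",                  4554L,
    "Rhipicephalus annulatus",         201L,
    "Rhipicephalus bursa",             960L,
    "Rhipicephalus sanguineus group",  478L
  )
}
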