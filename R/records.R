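#' Occurrence-record column schema
#'
#' The delimited-text dialect for occurrence records: UTF-8, comma-separated,
#' one header row, decimal point in coordinates (WGS84 decimal degrees).
#' `species`, `lon` and `lat` are mandatory; all other columns are optional
#' and filled with `NA`/`"unknown"` when absent.
#'
#' @return Character vector of recognised column names.
#' @export
record_columns <- function() {
  c("species", "lon", "lat", "year", "day_of_year", "host_name",
    "stage", "collection_method", "source_id", "locality_quality",
    "region_tag")
}

#' Locality-quality levels
#'
#' Record-quality flags, from best to worst: explicit coordinates, an
#' unambiguous place name, a large administrative division only, an ambiguous
#' place name, or a record identified only to genus. Only the first two
#' survive [filter_records()].
#'
#' @return Character vector of the five levels.
#' @export
locality_quality_levels <- function() {
  c("coordinates", "unambiguous_name", "admin_division",
    "ambiguous_name", "genus_only")
}

#' Read occurrence records from delimited text
#'
#' Parses a CSV of occurrence records into a tibble, one row per record.
#' Well-formed rows always yield a record; rows whose coordinates cannot be
#' parsed, or whose locality quality claims coordinates that are absent, are
#' collected into a problems table (retrievable with [record_problems()])
#' rather than silently dropped. Input order is preserved. A missing
#' mandatory column (`species`, `lon`, `lat`) is a schema error.
#'
#' @param path Path to a CSV file following [record_columns()].
#' @return A tibble of records with columns `species_raw`, `species`, `lon`,
#'   `lat`, `year`, `day_of_year`, `host_name`, `stage`,
#'   `collection_method`, `source_id`, `locality_quality`, `region_tag`,
#'   and a `.row` column giving the source row number. The `"problems"`
#'   attribute holds a tibble (`row`, `column`, `issue`) of rejected rows.
#' @seealso [filter_records()], [harmonize_records()]
#' @export
read_records <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(paste0("file not found: ", path))
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  check_columns(raw, c("species", "lon", "lat"), "record file")

  n <- nrow(raw)
  # fill optional columns so downstream code sees a stable schema
  for (col in setdiff(record_columns(), names(raw))) {
    raw[[col]] <- NA_character_
  }

  lon <- suppressWarnings(as.numeric(raw$lon))
  lat <- suppressWarnings(as.numeric(raw$lat))
  quality <- dplyr::coalesce(raw$locality_quality, "coordinates")

  problems <- tibble::tibble(row = integer(), column = character(),
                             issue = character())
  bad <- logical(n)
  add_problem <- function(rows, column, issue) {
    if (any(rows)) {
      problems <<- dplyr::bind_rows(problems, tibble::tibble(
        row = which(rows), column = column, issue = issue))
      bad <<- bad | rows
    }
  }
  add_problem(!is.na(raw$lon) & is.na(lon), "lon", "unparsable coordinate")
  add_problem(!is.na(raw$lat) & is.na(lat), "lat", "unparsable coordinate")
  add_problem(quality == "coordinates" & (is.na(raw$lon) | is.na(raw$lat)),
              "lon/lat", "locality_quality is 'coordinates' but a coordinate is missing")
  add_problem(!is.na(lon) & (lon < -180 | lon > 180), "lon",
              "longitude outside [-180, 180]")
  add_problem(!is.na(lat) & (lat < -90 | lat > 90), "lat",
              "latitude outside [-90, 90]")
  add_problem(is.na(raw$species) | raw$species == "", "species",
              "missing species name")

  keep <- !bad
  records <- tibble::tibble(
    .row = which(keep),
    species_raw = raw$species[keep],
    species = raw$species[keep],
    lon = lon[keep],
    lat = lat[keep],
    year = suppressWarnings(as.integer(raw$year[keep])),
    day_of_year = suppressWarnings(as.integer(raw$day_of_year[keep])),
    host_name = raw$host_name[keep],
    stage = dplyr::coalesce(raw$stage[keep], "unknown"),
    collection_method = dplyr::coalesce(raw$collection_method[keep], "unknown"),
    source_id = raw$source_id[keep],
    locality_quality = quality[keep],
    region_tag = raw$region_tag[keep]
  )
  attr(records, "problems") <- dplyr::arrange(problems, row)
  records
}

#' Row-level parse problems from [read_records()]
#'
#' @param records A tibble returned by [read_records()].
#' @return A tibble with columns `row`, `column`, `issue`.
#' @export
record_problems <- function(records) {
  p <- attr(records, "problems")
  if (is.null(p)) {
    tibble::tibble(row = integer(), column = character(), issue = character())
  } else {
    p
  }
}

#' Define a rectangular study window
#'
#' Closed-interval bounding box in decimal degrees, plus region tags that
#' override pure geometry: records tagged with an inclusion exception are
#' kept even when outside the box (e.g. islands the survey covers although
#' they fall outside its nominal bounds), and records tagged with an
#' exclusion region are dropped even when inside it. Defaults describe the
#' western Palearctic as surveyed for ixodid ticks: 11°W–45°E, 29°N–71°N,
#' Canary Islands included, Iceland and the Azores excluded.
#'
#' @param lon_min,lon_max,lat_min,lat_max Window bounds, decimal degrees.
#' @param inclusion_exceptions Region tags retained regardless of geometry.
#' @param exclusion_regions Region tags rejected regardless of geometry.
#' @return A `study_window` object.
#' @export
study_window <- function(lon_min = -11, lon_max = 45,
                         lat_min = 29, lat_max = 71,
                         inclusion_exceptions = "Canary Islands",
                         exclusion_regions = c("Iceland", "Azores")) {
  stopifnot(lon_min < lon_max, lat_min < lat_max)
  structure(
    list(lon_min = lon_min, lon_max = lon_max,
         lat_min = lat_min, lat_max = lat_max,
         inclusion_exceptions = inclusion_exceptions,
         exclusion_regions = exclusion_regions),
    class = "study_window"
  )
}

#' @export
print.study_window <- function(x, ...) {
  cat(sprintf("<study_window> lon [%g, %g], lat [%g, %g]\n",
              x$lon_min, x$lon_max, x$lat_min, x$lat_max))
  if (length(x$inclusion_exceptions))
    cat("  include regardless:", paste(x$inclusion_exceptions, collapse = ", "), "\n")
  if (length(x$exclusion_regions))
    cat("  exclude regardless:", paste(x$exclusion_regions, collapse = ", "), "\n")
  invisible(x)
}

#' Filter occurrence records by quality, name level and study window
#'
#' Applies the inclusion criteria for curated occurrence data: a record is
#' retained when its locality quality is `coordinates` or
#' `unambiguous_name`, its name is resolved to species level (see
#' [harmonize_records()]; a `species_accepted` column, when present, gates
#' retention), and it falls inside the study window — a closed interval on
#' all bounds — or carries an inclusion-exception region tag. Each rejected
#' record is tallied under the first rule it violates; rejection is a normal
#' outcome, not an error. The operation is idempotent and order-preserving.
#'
#' Rule names, in the order tested: `missing_coordinates`, `genus_only`,
#' `admin_division`, `ambiguous_name`, `unaccepted_name`,
#' `excluded_region`, `outside_window`.
#'
#' @param records A record tibble (see [read_records()]).
#' @param window A [study_window()].
#' @return The retained records, with a `"rejections"` attribute
#'   (tibble `rule`, `n`) retrievable via [rejection_counts()].
#' @export
filter_records <- function(records, window = study_window()) {
  check_columns(records, c("species", "lon", "lat", "locality_quality"),
                "records")
  n <- nrow(records)
  rule <- rep(NA_character_, n)
  mark <- function(cond, name) {
    rule[is.na(rule) & cond] <<- name
  }

  mark(is.na(records$lon) | is.na(records$lat), "missing_coordinates")
  mark(records$locality_quality == "genus_only", "genus_only")
  mark(records$locality_quality == "admin_division", "admin_division")
  mark(records$locality_quality == "ambiguous_name", "ambiguous_name")
  if ("species_accepted" %in% names(records)) {
    mark(!records$species_accepted, "unaccepted_name")
  }
  region <- if ("region_tag" %in% names(records)) records$region_tag
            else rep(NA_character_, n)
  excluded <- !is.na(region) & region %in% window$exclusion_regions
  mark(excluded, "excluded_region")
  inside <- records$lon >= window$lon_min & records$lon <= window$lon_max &
            records$lat >= window$lat_min & records$lat <= window$lat_max
  excepted <- !is.na(region) & region %in% window$inclusion_exceptions
  mark(!is.na(records$lon) & !inside & !excepted, "outside_window")

  kept <- records[is.na(rule), , drop = FALSE]
  rejections <- tibble::tibble(rule = rule[!is.na(rule)]) |>
    dplyr::count(.data$rule, name = "n")
  attr(kept, "problems") <- attr(records, "problems")
  attr(kept, "rejections") <- rejections
  kept
}

#' Per-rule rejection tallies from [filter_records()]
#'
#' @param records A tibble returned by [filter_records()].
#' @return A tibble with columns `rule` and `n`; rows sum to the number of
#'   records removed.
#' @export
rejection_counts <- function(records) {
  r <- attr(records, "rejections")
  if (is.null(r)) tibble::tibble(rule = character(), n = integer()) else r
}

#' Built-in synonym table for western Palearctic ticks
#'
#' Maps names that current taxonomy folds into another label. The
#' morphologically confusable *Rhipicephalus sanguineus* and *R. turanicus*
#' are both collapsed into the *R. sanguineus* group label, and *Hyalomma
#' detritum* is treated as a synonym of *Hy. scupense*.
#'
#' @return A tibble with columns `from` and `to`.
#' @export
default_synonyms <- function() {
  tibble::tribble(
    ~from,                         ~to,
    "Rhipicephalus sanguineus",    "Rhipicephalus sanguineus group",
    "Rhipicephalus turanicus",     "Rhipicephalus sanguineus group",
    "Hyalomma detritum",           "Hyalomma scupense"
  )
}

#' Built-in accepted-name list for western Palearctic ticks
#'
#' The species-level labels (binomials plus the *R. sanguineus* group label)
#' under which curated records are tabulated.
#'
#' @return Character vector of accepted labels.
#' @export
default_accepted_names <- function() {
  c("Dermacentor marginatus", "Dermacentor reticulatus",
    "Haemaphysalis punctata", "Haemaphysalis sulcata",
    "Hyalomma anatolicum", "Hyalomma excavatum", "Hyalomma impeltatum",
    "Hyalomma lusitanicum", "Hyalomma marginatum", "Hyalomma scupense",
    "Ixodes canisuga", "Ixodes hexagonus", "Ixodes ricinus",
    "Ixodes gibbosus",
    "Rhipicephalus annulatus", "Rhipicephalus bursa",
    "Rhipicephalus sanguineus group")
}

#' Harmonize species names against synonym and accepted-name tables
#'
#' Pure function of its inputs: a name found in the synonym table is mapped
#' to its accepted label; a name already accepted is returned unchanged; any
#' other name is returned as-is but flagged unaccepted in the `"accepted"`
#' attribute (and warned about), never silently passed through.
#'
#' @param name Character vector of raw species names.
#' @param synonyms Tibble with columns `from`, `to` ([default_synonyms()]).
#' @param accepted Character vector of accepted labels
#'   ([default_accepted_names()]).
#' @return Character vector of harmonized labels with a logical
#'   `"accepted"` attribute of the same length.
#' @examples
#' harmonize_species("Rhipicephalus turanicus")
#' harmonize_species("Hyalomma detritum")
#' @export
harmonize_species <- function(name, synonyms = default_synonyms(),
                              accepted = default_accepted_names()) {
  idx <- match(name, synonyms$from)
  out <- ifelse(is.na(idx), name, synonyms$to[idx])
  ok <- out %in% accepted
  if (any(!ok & !is.na(name))) {
    rlang::warn(paste0(
      "unaccepted name(s): ",
      paste(unique(out[!ok & !is.na(name)]), collapse = ", ")
    ))
  }
  attr(out, "accepted") <- ok
  out
}

#' Harmonize the species column of a record tibble
#'
#' Applies [harmonize_species()] to `species_raw` (or `species` when no raw
#' column exists), writes the harmonized label into `species`, preserves the
#' raw name for audit, and adds a logical `species_accepted` column used by
#' [filter_records()] to reject unresolvable names.
#'
#' @inheritParams filter_records
#' @inheritParams harmonize_species
#' @return The record tibble with `species`, `species_raw` and
#'   `species_accepted` columns.
#' @export
harmonize_records <- function(records, synonyms = default_synonyms(),
                              accepted = default_accepted_names()) {
  check_columns(records, "species", "records")
  raw <- if ("species_raw" %in% names(records)) records$species_raw
         else records$species
  harm <- suppressWarnings(harmonize_species(raw, synonyms, accepted))
  records$species_raw <- raw
  records$species <- as.character(harm)
  records$species_accepted <- attr(harm, "accepted")
  if (any(!records$species_accepted)) {
    rlang::warn(sprintf("%d record(s) carry unaccepted species names",
                        sum(!records$species_accepted)))
  }
  records
}

#' Tabulate record counts and percentages per species
#'
#' One row per species with its record count and its percentage of the
#' total, rounded half-up to one decimal — the presentation convention of
#' published occurrence tables. Counts sum to the total number of records.
#'
#' @param data A record tibble (counted row-wise), or a pre-tabulated tibble
#'   when `n_col` names an existing count column.
#' @param n_col Optional name of a count column in `data`; when supplied,
#'   `data` must have one row per species.
#' @return A tibble with columns `species`, `n`, `pct`, sorted by
#'   decreasing `n`. An empty input gives an empty table.
#' @examples
#' summarize_counts(table1_counts(), n_col = "n")
#' @export
summarize_counts <- function(data, n_col = NULL) {
  check_columns(data, "species", "data")
  if (is.null(n_col)) {
    counts <- dplyr::count(data, .data$species, name = "n")
  } else {
    check_columns(data, n_col, "data")
    if (anyDuplicated(data$species) > 0) {
      rlang::abort("pre-tabulated data must have one row per species")
    }
    counts <- tibble::tibble(species = data$species,
                             n = as.integer(data[[n_col]]))
  }
  total <- sum(counts$n)
  if (total == 0) {
    return(tibble::tibble(species = character(), n = integer(),
                          pct = numeric()))
  }
  counts |>
    dplyr::mutate(pct = round_half_up(100 * .data$n / total, 1)) |>
    dplyr::arrange(dplyr::desc(.data$n), .data$species)
}

#' Built-in host-to-order taxonomy
#'
#' Maps common host names to taxonomic order labels, with Artiodactyla split
#' by family as host-usage tables for ticks conventionally present it.
#'
#' @return A tibble with columns `host_name`, `host_order`.
#' @export
default_host_taxonomy <- function() {
  tibble::tribble(
    ~host_name,      ~host_order,
    "cattle",        "Artiodactyla (Bovidae)",
    "cow",           "Artiodactyla (Bovidae)",
    "sheep",         "Artiodactyla (Ovidae)",
    "goat",          "Artiodactyla (Ovidae)",
    "wild boar",     "Artiodactyla (Suidae)",
    "pig",           "Artiodactyla (Suidae)",
    "camel",         "Artiodactyla (Camelidae)",
    "horse",         "Perissodactyla",
    "donkey",        "Perissodactyla",
    "dog",           "Carnivora",
    "red fox",       "Carnivora",
    "cat",           "Carnivora",
    "mouse",         "Rodentia",
    "vole",          "Rodentia",
    "hedgehog",      "Insectivora",
    "rabbit",        "Lagomorpha",
    "hare",          "Lagomorpha",
    "human",         "Hominidae",
    "bird",          "Aves",
    "blackbird",     "Aves",
    "lizard",        "Reptilia"
  )
}

#' Cross-tabulate species against host taxonomic order
#'
#' For each species, the percentage of its host-attributed records reported
#' from each host order. Denominators are per-species counts of records
#' whose host resolved through the taxonomy; records with no host, or a
#' host absent from the taxonomy, are excluded from denominators and
#' tallied separately (unresolved hosts additionally emit a warning). Row
#' percentages sum to 100 within rounding. The `"totals"` attribute (via
#' [host_order_totals()]) gives each order's share of all host-attributed
#' records, and `"unattributed"` counts records outside the denominators.
#'
#' @param records A record tibble with `species` and `host_name` columns.
#' @param taxonomy A tibble mapping `host_name` to `host_order`.
#' @return A long tibble with columns `species`, `host_order`, `n`, `pct`.
#' @export
host_crosstab <- function(records, taxonomy = default_host_taxonomy()) {
  check_columns(records, c("species", "host_name"), "records")
  check_columns(taxonomy, c("host_name", "host_order"), "taxonomy")

  has_host <- !is.na(records$host_name) & records$host_name != ""
  order <- taxonomy$host_order[match(records$host_name, taxonomy$host_name)]
  unresolved <- has_host & is.na(order)
  if (any(unresolved)) {
    rlang::warn(sprintf(
      "%d record(s) have hosts absent from the taxonomy: %s",
      sum(unresolved),
      paste(unique(records$host_name[unresolved]), collapse = ", ")))
  }
  attributed <- records[has_host & !is.na(order), , drop = FALSE]
  attributed$host_order <- order[has_host & !is.na(order)]

  tab <- attributed |>
    dplyr::count(.data$species, .data$host_order, name = "n") |>
    dplyr::group_by(.data$species) |>
    dplyr::mutate(pct = round_half_up(100 * .data$n / sum(.data$n), 1)) |>
    dplyr::ungroup()

  totals <- attributed |>
    dplyr::count(.data$host_order, name = "n") |>
    dplyr::mutate(pct = round_half_up(100 * .data$n / sum(.data$n), 1))

  attr(tab, "totals") <- totals
  attr(tab, "unattributed") <- sum(!has_host | unresolved)
  tab
}

#' Host-order share of all host-attributed records
#'
#' @param crosstab A tibble from [host_crosstab()].
#' @return A tibble with columns `host_order`, `n`, `pct` (the "Totals" row
#'   of a host-usage table).
#' @export
host_order_totals <- function(crosstab) {
  attr(crosstab, "totals")
}
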