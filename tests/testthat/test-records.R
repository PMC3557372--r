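test_that("read_records handles empty, complete and malformed input", {
  # header-only file -> empty record set
  p <- write_records_csv(tibble::tibble(species = character(),
                                        lon = numeric(), lat = numeric()))
  empty <- read_records(p)
  expect_equal(nrow(empty), 0)
  expect_equal(nrow(record_problems(empty)), 0)

  # one complete row -> one fully populated record
  p <- write_records_csv(tibble::tibble(
    species = "Ixodes ricinus", lon = 1.5, lat = 45.2, year = 2005,
    day_of_year = 121, host_name = "cattle", stage = "adult",
    collection_method = "host", source_id = "ref1",
    locality_quality = "coordinates", region_tag = NA))
  one <- read_records(p)
  expect_equal(nrow(one), 1)
  expect_equal(one$species, "Ixodes ricinus")
  expect_equal(one$lon, 1.5)
  expect_equal(one$year, 2005L)
  expect_equal(one$stage, "adult")

  # 10 rows, 2 with non-numeric lat -> 8 records + 2 row-level errors
  rows <- tibble::tibble(
    species = rep("Ixodes ricinus", 10),
    lon = as.character(seq(0, 9)),
    lat = c("40", "41", "oops", "43", "44", "45", "n/a", "47", "48", "49"),
    locality_quality = "coordinates")
  ten <- read_records(write_records_csv(rows))
  expect_equal(nrow(ten), 8)
  probs <- record_problems(ten)
  expect_equal(nrow(probs), 2)
  expect_setequal(probs$row, c(3, 7))
  expect_true(all(probs$issue == "unparsable coordinate"))
  # input order preserved
  expect_equal(ten$lon, c(0, 1, 3, 4, 5, 7, 8, 9))
})

test_that("read_records rejects a missing mandatory column", {
  p <- write_records_csv(tibble::tibble(species = "x", lon = 1))
  expect_error(read_records(p), class = "tickniche_schema_error")
})

test_that("filter_records applies quality, name and window rules with tallies", {
  recs <- tibble::tibble(
    species = c("Ixodes ricinus", "Ixodes ricinus", "Ixodes ricinus",
                "Ixodes ricinus", "Ixodes ricinus", "Ixodes ricinus",
                "Ixodes ricinus"),
    lon = c(2, 2, 2, 2, -15.5, 2, -20),
    lat = c(45, 45, 45, 45, 28.1, 45, 64),
    locality_quality = c("coordinates", "genus_only", "admin_division",
                         "ambiguous_name", "coordinates", "coordinates",
                         "coordinates"),
    region_tag = c(NA, NA, NA, NA, "Canary Islands", "Iceland", NA))
  kept <- filter_records(recs, study_window())
  rej <- rejection_counts(kept)

  # quality rules reject under their own names
  expect_equal(rej$n[rej$rule == "genus_only"], 1)
  expect_equal(rej$n[rej$rule == "admin_division"], 1)
  expect_equal(rej$n[rej$rule == "ambiguous_name"], 1)
  # Canary record retained via inclusion exception although south of 29N
  expect_true(any(kept$lon == -15.5))
  # Iceland tag rejected although inside the box
  expect_equal(rej$n[rej$rule == "excluded_region"], 1)
  # coordinates outside the window without an exception tag
  expect_equal(rej$n[rej$rule == "outside_window"], 1)
  # rejected + retained = input
  expect_equal(nrow(kept) + sum(rej$n), nrow(recs))
})

test_that("filter_records is idempotent and order-preserving", {
  set.seed(4)
  recs <- tibble::tibble(
    species = "Ixodes ricinus",
    lon = runif(50, -20, 50), lat = runif(50, 25, 75),
    locality_quality = sample(locality_quality_levels(), 50, TRUE),
    region_tag = NA_character_)
  once <- filter_records(recs)
  twice <- filter_records(once)
  strip <- function(x) {
    attr(x, "rejections") <- NULL
    tibble::as_tibble(x)
  }
  expect_identical(strip(once), strip(twice))
  # the second pass finds nothing left to reject
  expect_equal(sum(rejection_counts(twice)$n), 0)
  # retained rows appear in input order
  expect_true(!is.unsorted(match(paste(once$lon, once$lat),
                                 paste(recs$lon, recs$lat))))
})

test_that("filter_records gates on unaccepted names after harmonization", {
  recs <- tibble::tibble(
    species = c("Ixodes ricinus", "Made-up ticksson"),
    lon = c(2, 2), lat = c(45, 45),
    locality_quality = "coordinates")
  harm <- suppressWarnings(harmonize_records(recs))
  kept <- filter_records(harm)
  expect_equal(nrow(kept), 1)
  expect_equal(rejection_counts(kept)$rule, "unaccepted_name")
})

test_that("harmonize_species maps synonyms, keeps accepted names, flags unknowns", {
  expect_equal(as.character(harmonize_species("Rhipicephalus turanicus")),
               "Rhipicephalus sanguineus group")
  expect_equal(as.character(harmonize_species("Rhipicephalus sanguineus")),
               "Rhipicephalus sanguineus group")
  expect_equal(as.character(harmonize_species("Hyalomma detritum")),
               "Hyalomma scupense")
  expect_equal(as.character(harmonize_species("Ixodes ricinus")),
               "Ixodes ricinus")
  expect_warning(out <- harmonize_species("Nosuchus tickus"),
                 "unaccepted")
  expect_false(attr(out, "accepted"))
  # pure function: identical calls give identical results
  a <- suppressWarnings(harmonize_species(c("Ixodes ricinus", "x")))
  b <- suppressWarnings(harmonize_species(c("Ixodes ricinus", "x")))
  expect_identical(a, b)
})

test_that("harmonize_records preserves the raw name for audit", {
  recs <- tibble::tibble(species = "Rhipicephalus turanicus",
                         lon = 2, lat = 40,
                         locality_quality = "coordinates")
  harm <- harmonize_records(recs)
  expect_equal(harm$species, "Rhipicephalus sanguineus group")
  expect_equal(harm$species_raw, "Rhipicephalus turanicus")
  expect_true(harm$species_accepted)
})

test_that("summarize_counts reproduces printed-table arithmetic", {
  tab <- summarize_counts(table1_counts(), n_col = "n")
  expect_equal(sum(tab$n), 10280)
  expect_equal(tab$pct[tab$species == "Ixodes ricinus"], 44.3)
  # single species -> 100.0
  single <- summarize_counts(tibble::tibble(species = rep("A", 5)))
  expect_equal(single$pct, 100.0)
  # empty input -> empty table
  expect_equal(nrow(summarize_counts(tibble::tibble(species = character()))),
               0)
})

test_that("summarize_counts percentages sum to 100 within rounding", {
  set.seed(11)
  for (i in 1:20) {
    counts <- tibble::tibble(
      species = paste0("sp", 1:8),
      n = rpois(8, lambda = sample(c(5, 50, 500), 8, TRUE)) + 1L)
    tab <- summarize_counts(counts, n_col = "n")
    expect_lt(abs(sum(tab$pct) - 100), 0.1 * nrow(tab))
    expect_lt(abs(sum(tab$pct) - 100), 0.5)
  }
})

test_that("host_crosstab computes row percentages over attributed records", {
  # 4-record toy: 2 Bovidae, 1 Carnivora, 1 host missing -> denominator 3
  recs <- tibble::tibble(
    species = "Hyalomma marginatum",
    host_name = c("cattle", "cow", "dog", NA))
  tab <- host_crosstab(recs)
  expect_equal(tab$pct[tab$host_order == "Artiodactyla (Bovidae)"], 66.7)
  expect_equal(tab$pct[tab$host_order == "Carnivora"], 33.3)
  expect_equal(attr(tab, "unattributed"), 1)

  # single-host species -> 100 % in that order
  cattle_only <- tibble::tibble(species = "Rhipicephalus annulatus",
                                host_name = rep("cattle", 7))
  expect_equal(host_crosstab(cattle_only)$pct, 100)

  # all hosts empty -> empty table, everything unattributed
  hostless <- tibble::tibble(species = "A", host_name = rep(NA_character_, 4))
  empty <- host_crosstab(hostless)
  expect_equal(nrow(empty), 0)
  expect_equal(attr(empty, "unattributed"), 4)
})

test_that("host_crosstab warns on unresolvable hosts and totals are shares", {
  recs <- tibble::tibble(
    species = c("A", "A", "B"),
    host_name = c("cattle", "okapi", "dog"))
  expect_warning(tab <- host_crosstab(recs), "okapi")
  totals <- host_order_totals(tab)
  expect_equal(sum(totals$n), 2)
  expect_lt(abs(sum(totals$pct) - 100), 0.2)
})

test_that("read -> filter -> summarize is bit-identical across runs", {
  rows <- tibble::tibble(
    species = sample(c("Ixodes ricinus", "Rhipicephalus turanicus",
                       "Hyalomma detritum"), 30, TRUE),
    lon = round(runif(30, -10, 44), 3),
    lat = round(runif(30, 30, 70), 3),
    locality_quality = sample(locality_quality_levels(), 30, TRUE))
  p <- write_records_csv(rows)
  run <- function() {
    read_records(p) |>
      harmonize_records() |>
      filter_records() |>
      summarize_counts()
  }
  expect_identical(suppressWarnings(run()), suppressWarnings(run()))
})
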