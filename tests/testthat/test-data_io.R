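# Reading, validation, transition pairing and geometry.

test_that("catch reader computes log abundance and validates the schema", {
  path <- write_tmp_csv(tiny_catches(months = 1, counts = c(0L, 9L)))
  d <- read_catches(path)
  expect_equal(d$y, c(0, 1))  # log10(0+1), log10(9+1)
  expect_equal(nrow(d), 2)

  # missing column named in the error
  bad <- tiny_catches()[, -6]
  expect_error(read_catches(write_tmp_csv(bad)), "count",
               class = "geomoran_schema_error")

  # negative count reported with its row number
  neg <- tiny_catches(months = 1, counts = c(2L, -1L))
  expect_error(read_catches(write_tmp_csv(neg)), "row: 2",
               class = "geomoran_validation_error")

  # non-integer count refused
  frac <- tiny_catches(months = 1)
  frac$count <- c(1.5, 2)
  expect_error(validate_catches(frac), class = "geomoran_validation_error")

  # duplicate stop-month key refused
  dup <- dplyr::bind_rows(tiny_catches(months = 1), tiny_catches(months = 1))
  expect_error(validate_catches(dup), class = "geomoran_validation_error")

  # empty file is a schema error
  empty <- tempfile(fileext = ".csv")
  file.create(empty)
  expect_error(read_catches(empty), class = "geomoran_schema_error")
  expect_error(read_catches(tempfile()), class = "geomoran_schema_error")
})

test_that("catch tables round-trip through CSV unchanged", {
  sim <- simulate_population(synthetic_config(n_stops = c(5, 4)), seed = 3)
  path <- tempfile(fileext = ".csv")
  write_table_csv(dplyr::select(sim$catches, -"y"), path)
  back <- read_catches(path)
  expect_equal(as.data.frame(back), as.data.frame(sim$catches))
})

test_that("site totals agree with an independent accumulation", {
  sim <- simulate_population(synthetic_config(n_stops = c(6, 5, 4)), seed = 9)
  tot <- site_totals(sim$catches)
  oracle <- tapply(sim$catches$count, sim$catches$site, sum)
  expect_equal(unname(tot$total_catch), unname(c(oracle[tot$site])))
  # pooled total equals the sum over every record
  expect_equal(sum(tot$total_catch), sum(sim$catches$count))
})

test_that("visit-level input is aggregated by summing counts", {
  visits <- dplyr::bind_rows(
    tiny_catches(months = 1, counts = c(1L, 2L)),
    tiny_catches(months = 1, counts = c(3L, 0L))
  )
  agg <- aggregate_visits(visits)
  expect_equal(nrow(agg), 2)
  expect_equal(sort(agg$count), c(2L, 4L))
})

test_that("transition pairs follow consecutive months and break at gaps", {
  full <- validate_catches(tiny_catches(months = 1:12))
  tr <- build_transitions(full)
  expect_equal(nrow(tr), 2 * 11)  # T - 1 transitions per stop

  gappy <- validate_catches(tiny_catches(months = c(1, 2, 4, 5)))
  tr2 <- suppressMessages(build_transitions(gappy))
  expect_equal(sort(unique(tr2$t)), c(1, 4))  # 1->2 and 4->5 only
  expect_equal(nrow(tr2), 2 * 2)

  # no consecutive months anywhere -> empty-result error
  sparse <- validate_catches(tiny_catches(months = c(1, 3, 5)))
  expect_error(suppressMessages(build_transitions(sparse)),
               class = "geomoran_validation_error")
})

test_that("pair counts match brute-force enumeration over random month sets", {
  set.seed(42)
  for (rep in 1:5) {
    months_per_stop <- lapply(1:8, function(i) sort(sample(1:12, sample(2:12, 1))))
    rows <- purrr::imap(months_per_stop, function(ms, i) {
      tibble::tibble(site = "s1", stop_id = sprintf("p%02d", i),
                     lon = 31.8 + i / 1000, lat = -13.7,
                     month = ms, count = 1L)
    }) |> purrr::list_rbind()
    d <- validate_catches(rows)
    tr <- suppressMessages(build_transitions(d))
    # oracle: exhaustive scan of each stop's month set
    oracle <- sum(vapply(months_per_stop,
                         function(ms) sum(diff(ms) == 1), numeric(1)))
    expect_equal(nrow(tr), oracle)
  }
})

test_that("transition building is order-independent and idempotent", {
  d <- validate_catches(tiny_catches(months = 1:8))
  cov <- tidyr::expand_grid(site = "s1", stop_id = c("a", "b"), month = 1:8) |>
    dplyr::mutate(dlst = 30, nlst = 15, cattle = 50)
  t1 <- build_transitions(d, cov)
  set.seed(1)
  t2 <- build_transitions(d[sample(nrow(d)), ], cov[sample(nrow(cov)), ])
  expect_equal(t1, t2)
  expect_equal(build_transitions(d, cov), t1)
})

test_that("pairs lacking a covariate record at month t are dropped", {
  d <- validate_catches(tiny_catches(months = 1:4))
  cov <- tidyr::expand_grid(site = "s1", stop_id = c("a", "b"), month = 1:3) |>
    dplyr::mutate(dlst = 30, nlst = 15, cattle = 50)
  # stop a month 2 covariate missing: drops pair starting at t = 2 for stop a
  cov <- cov[!(cov$stop_id == "a" & cov$month == 2), ]
  tr <- suppressMessages(build_transitions(d, cov))
  expect_equal(nrow(tr), 2 * 3 - 1)
  expect_false(any(tr$stop_id == "a" & tr$t == 2))
})

test_that("geometry projects to km and matches a haversine oracle", {
  skip_if_not_installed("geosphere")
  # two stops 100 m apart along a transect
  df <- tibble::tibble(
    lon = c(31.8, 31.8 + 0.1 / (111.320 * cos(-13.7 * pi / 180))),
    lat = c(-13.7, -13.7), t = c(1, 1)
  )
  geo <- project_geometry(df)
  hav <- geosphere::distHaversine(c(df$lon[1], df$lat[1]),
                                  c(df$lon[2], df$lat[2])) / 1000
  expect_lt(abs(geo$d_space[1, 2] - hav), 1e-4)
  expect_lt(abs(geo$d_space[1, 2] - 0.1), 1e-3)

  # temporal distances in whole months; identical points at distance zero
  df2 <- tibble::tibble(lon = c(31.8, 31.8), lat = c(-13.7, -13.7), t = c(3, 5))
  geo2 <- project_geometry(df2)
  expect_equal(geo2$d_time[1, 2], 2)
  expect_equal(geo2$d_space[1, 2], 0)

  # matrices symmetric, zero diagonal, non-negative
  sim <- simulate_population(synthetic_config(n_stops = c(4, 3)), seed = 1)
  tr <- build_transitions(sim$catches, sim$covariates)
  g <- project_geometry(tr)
  expect_equal(g$d_space, t(g$d_space))
  expect_equal(unname(diag(g$d_space)), rep(0, nrow(tr)))
  expect_true(all(g$d_space >= 0) && all(g$d_time >= 0))

  expect_error(project_geometry(tibble::tibble(lon = 200, lat = 0)),
               class = "geomoran_validation_error")
})
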