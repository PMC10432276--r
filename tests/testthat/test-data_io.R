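test_that("community tables parse, validate and round-trip", {
  comm <- toy_community()
  expect_s3_class(comm, "fw_community")
  expect_equal(nrow(comm), 3L)

  # missing column
  bad <- as.data.frame(comm)[, -7]
  expect_error(as_fw_community(bad), "abundance")

  # negative abundance names offending rows
  neg <- as.data.frame(comm)
  neg$abundance[2] <- -1
  expect_error(as_fw_community(neg), "row\\(s\\): 2")

  # unparseable date
  ugly <- as.data.frame(comm)
  ugly$date <- c("2000-05-10", "not-a-date", "2000-05-10")
  expect_error(as_fw_community(ugly), "unparseable date")

  # round-trip equality, including generated tables
  set.seed(42)
  for (rep in 1:3) {
    events <- site_events(years = sort(sample(1990:2010, 9)),
                          n_taxa = sample(2:6, 1))
    events$abundance <- round(stats::runif(nrow(events), 0, 50), 6)
    orig <- as_fw_community(events)
    path <- withr::local_tempfile(fileext = ".csv")
    write_community_table(orig, path)
    back <- suppressMessages(read_community_table(path))
    expect_equal(as.data.frame(back), as.data.frame(orig),
                 ignore_attr = TRUE)
  }
})

test_that("time-series inclusion rules are enforced", {
  # 7 sampling years fails, 8 passes
  ev7 <- site_events(years = 2000:2006)
  ev8 <- site_events(years = 2000:2007)
  r7 <- validate_time_series(as_fw_community(ev7))
  r8 <- validate_time_series(as_fw_community(ev8))
  expect_false(r7$rules$min_years)
  expect_true(r8$pass)

  # spring + autumn sampling flags season selection
  two_seasons <- rbind(site_events(years = 2000:2007, month = 4),
                       site_events(years = 2000:2007, month = 10))
  v <- validate_time_series(as_fw_community(two_seasons))
  expect_true(v$season_selection_required)
  expect_false(v$rules$single_season)

  # duplicate event within a year
  dup <- rbind(site_events(years = 2000:2007),
               site_events(years = 2000, month = 5, day = 20))
  vd <- validate_time_series(as_fw_community(dup))
  expect_false(vd$rules$one_event_per_year)
})

test_that("season selection keeps the longest season and breaks ties", {
  # spring 12 years vs summer 9 years -> spring retained
  spring <- site_events(years = 1999:2010, month = 4)
  summer <- site_events(years = 2002:2010, month = 7)
  sel <- select_annual_series(as_fw_community(rbind(spring, summer)))
  expect_false(sel$excluded)
  expect_equal(sel$n_sampling_years, 12L)
  expect_true(all(format(sel$events$date, "%m") == "04"))

  # single-season input is unchanged
  solo <- as_fw_community(site_events(years = 2000:2009, month = 6))
  sel1 <- select_annual_series(solo)
  expect_equal(nrow(sel1$events), nrow(solo))

  # tie between two 10-year seasons: earlier median date wins
  a <- site_events(years = 2000:2009, month = 3)
  b <- site_events(years = 2000:2009, month = 8)
  sel2 <- select_annual_series(as_fw_community(rbind(a, b)))
  expect_equal(sel2$n_sampling_years, 10L)
  expect_true(all(as.integer(format(sel2$events$date, "%m")) <= 5))

  # no season reaches 8 years -> excluded with reason
  short <- as_fw_community(site_events(years = 2000:2005))
  sel3 <- select_annual_series(short)
  expect_true(sel3$excluded)
  expect_match(sel3$reason, "8 sampling years")
})

test_that("assemble_time_series accounts for every site", {
  comm <- as_fw_community(rbind(
    site_events(site = "ok", years = 2000:2009),
    site_events(site = "short", years = 2000:2004)))
  res <- assemble_time_series(comm)
  expect_equal(nrow(res$series) + nrow(res$exclusions), 2L)
  expect_equal(res$exclusions$site_id, "short")
})

test_that("community subsetting follows taxonomy and origin status", {
  tax <- toy_taxonomy()
  comm <- toy_community()   # Baetis (E), Perla (P), Lymnaea (mollusc)

  ept <- subset_community(comm, "EPT", taxonomy = tax)
  expect_setequal(unique(ept$taxon_id), c("Baetis", "Perla"))

  ins <- subset_community(comm, "insects", taxonomy = tax)
  expect_setequal(unique(ins$taxon_id), c("Baetis", "Perla"))

  # native/non-native split with one marked species
  lookup <- data.frame(species = "Lymnaea", country = "AA",
                       status = "non_native", stringsAsFactors = FALSE)
  res <- c(s1 = "species")
  nat <- subset_community(comm, "native", lookup = lookup,
                          site_resolution = res)
  expect_setequal(unique(nat$taxon_id), c("Baetis", "Perla"))
  nn <- subset_community(comm, "non_native", lookup = lookup,
                         site_resolution = res)
  expect_equal(unique(nn$taxon_id), "Lymnaea")

  # all-native community: empty non-native subset, flagged
  lookup0 <- lookup[0, ]
  nn0 <- subset_community(comm, "non_native", lookup = lookup0,
                          site_resolution = res)
  expect_equal(nrow(nn0), 0L)
  expect_equal(attr(nn0, "note"), "no non-natives detected")

  # family-resolution site skipped
  resF <- c(s1 = "family")
  skip <- subset_community(comm, "native", lookup = lookup,
                           site_resolution = resF)
  expect_equal(nrow(skip), 0L)
  expect_equal(attr(skip, "skipped_sites"), "s1")

  # subsetting is idempotent and never increases abundance
  twice <- subset_community(ept, "EPT", taxonomy = tax)
  expect_equal(as.data.frame(twice), as.data.frame(ept),
               ignore_attr = TRUE)
  expect_lte(sum(ept$abundance), sum(comm$abundance))
})

test_that("excluded-group filtering drops flagged taxa", {
  tax <- rbind(toy_taxonomy(),
               data.frame(taxon_id = "Hydracarina", genus = "",
                          family = "", order = "Trombidiformes",
                          class = "Arachnida", stringsAsFactors = FALSE))
  comm <- as_fw_community(rbind(
    as.data.frame(toy_community()),
    data.frame(site_id = "s1", study_id = "st1", country = "AA",
               date = as.Date("2000-05-10"), taxon_id = "Hydracarina",
               taxon_level = "genus", abundance = 5)))
  out <- remove_excluded_taxa(comm, tax)
  expect_false("Hydracarina" %in% out$taxon_id)
  expect_equal(attr(out, "n_excluded_rows"), 1L)
})
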