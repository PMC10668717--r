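test_that("cell indices are floor divisions with half-open boundaries", {
  expect_equal(cell_of(0, 0)$cell_id, "10kmE0N0")
  expect_equal(cell_of(9999.99, 0)$cell_id, "10kmE0N0")
  expect_equal(cell_of(10000, 0)$cell_id, "10kmE1N0")
  expect_equal(cell_of(432500, 2431200)$cell_id, "10kmE43N243")
  # km input against an independent floor-division oracle
  set.seed(7)
  x <- runif(50, 0, 640); y <- runif(50, 0, 320)
  cc <- cell_of(x, y, units = "km")
  expect_equal(cc$easting_index, as.integer(x %/% 10))
  expect_equal(cc$northing_index, as.integer(y %/% 10))
})

test_that("one C1 confirms a cell; one C2 does not; two independent C2 do", {
  one_c1 <- classify_signs(sign_row("a", "2015-12-01", x = 15, y = 15,
                                    evidence_type = "dna_sample",
                                    dna_confirmed_wolf = TRUE))
  m <- confirm_cells(one_c1, "2015-2016")
  expect_true(m$cells$confirmed[m$cells$cell_id == "10kmE1N1"])

  one_c2 <- classify_signs(sign_row("a", "2015-12-01", x = 15, y = 15,
                                    evidence_type = "track",
                                    typical_pattern = TRUE,
                                    track_length_m = 200))
  m <- confirm_cells(one_c2, "2015-2016")
  expect_false(any(m$cells$confirmed))

  two_c2 <- classify_signs(sign_table(
    sign_row("a", "2015-12-01", x = 15, y = 15, evidence_type = "track",
             typical_pattern = TRUE, track_length_m = 200),
    sign_row("b", "2016-01-07", x = 15.2, y = 15.1, evidence_type = "scat",
             expert_checked = TRUE)))
  m <- confirm_cells(two_c2, "2015-2016")
  expect_true(all(m$cells$confirmed))
})

test_that("same-day same-track C2 pairs are dependent; different days independent", {
  same_event <- classify_signs(sign_table(
    sign_row("a", "2015-12-01", x = 15.0, y = 15.0, evidence_type = "track",
             typical_pattern = TRUE, track_length_m = 200, track_id = "T1"),
    sign_row("b", "2015-12-01", x = 15.3, y = 15.0, evidence_type = "track",
             typical_pattern = TRUE, track_length_m = 150, track_id = "T1")))
  expect_false(any(confirm_cells(same_event, "2015-2016")$cells$confirmed))

  diff_days <- same_event
  diff_days$date[2] <- as.Date("2015-12-05")
  diff_days$track_id <- c("T1", "T2")
  expect_true(all(confirm_cells(diff_days, "2015-2016")$cells$confirmed))
})

test_that("signs from other monitoring years or C3 never contribute", {
  s <- classify_signs(sign_table(
    sign_row("a", "2014-12-01", x = 15, y = 15, evidence_type = "dna_sample",
             dna_confirmed_wolf = TRUE),               # previous year
    sign_row("b", "2015-12-01", x = 15, y = 15, evidence_type = "sighting")))
  m <- confirm_cells(s, "2015-2016")
  expect_false(any(m$cells$confirmed))
})

test_that("adding signs never unconfirms; removing a C3 never changes the map", {
  set.seed(11)
  base <- classify_signs(sign_table(
    sign_row("a", "2015-12-01", x = 15, y = 15, evidence_type = "dna_sample",
             dna_confirmed_wolf = TRUE),
    sign_row("b", "2015-12-02", x = 35, y = 15, evidence_type = "track",
             typical_pattern = TRUE, track_length_m = 200),
    sign_row("c", "2015-12-09", x = 82, y = 44, evidence_type = "sighting")))
  m0 <- confirm_cells(base, "2015-2016")
  added <- classify_signs(sign_table(
    sign_row("a", "2015-12-01", x = 15, y = 15, evidence_type = "dna_sample",
             dna_confirmed_wolf = TRUE),
    sign_row("b", "2015-12-02", x = 35, y = 15, evidence_type = "track",
             typical_pattern = TRUE, track_length_m = 200),
    sign_row("c", "2015-12-09", x = 82, y = 44, evidence_type = "sighting"),
    sign_row("d", "2016-02-01", x = 55, y = 75, evidence_type = "dna_sample",
             dna_confirmed_wolf = TRUE)))
  m1 <- confirm_cells(added, "2015-2016")
  conf0 <- m0$cells$cell_id[m0$cells$confirmed]
  conf1 <- m1$cells$cell_id[m1$cells$confirmed]
  expect_true(all(conf0 %in% conf1))

  no_c3 <- base[base$category != "C3", ]
  m2 <- confirm_cells(no_c3, "2015-2016")
  expect_equal(sort(m2$cells$cell_id[m2$cells$confirmed]), sort(conf0))
})

test_that("area of occurrence is 100 km2 per confirmed in-range cell", {
  # 3 confirmed cells, one outside the alpine ring
  s <- classify_signs(sign_table(
    sign_row("a", "2015-12-01", x = 55, y = 55, evidence_type = "dna_sample",
             dna_confirmed_wolf = TRUE),
    sign_row("b", "2015-12-01", x = 95, y = 95, evidence_type = "dna_sample",
             dna_confirmed_wolf = TRUE),
    sign_row("c", "2015-12-01", x = 5, y = 295, evidence_type = "dna_sample",
             dna_confirmed_wolf = TRUE)))
  m <- confirm_cells(s, "2015-2016")
  expect_equal(sum(m$cells$confirmed), 3)
  lay <- alpine_layout()   # alpine ring [40,600] x [40,280]
  a <- area_of_occurrence(m, lay)
  expect_equal(a, 200)     # the (5,295) cell centre is outside the range
  expect_equal(a %% 100, 0)
  expect_equal(area_of_occurrence(confirm_cells(s, "1999-2000"), lay), 0)
})

test_that("empty alpine polygon errors", {
  m <- confirm_cells(classify_signs(sign_row("a")), "2015-2016")
  degenerate <- cbind(c(0, 0, 0), c(0, 0, 0))
  expect_error(area_of_occurrence(m, degenerate), "empty")
})
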