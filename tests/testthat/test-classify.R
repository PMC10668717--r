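test_that("monitoring year runs 1 May to 30 April", {
  expect_equal(assign_monitoring_year(as.Date("2020-04-30")), "2019-2020")
  expect_equal(assign_monitoring_year(as.Date("2020-05-01")), "2020-2021")
  expect_equal(assign_monitoring_year(as.Date("1993-12-15")), "1993-1994")
  # vectorised, and stable across the year interior
  d <- seq(as.Date("2010-05-01"), as.Date("2011-04-30"), by = "day")
  expect_true(all(assign_monitoring_year(d) == "2010-2011"))
})

test_that("genuineness screening discards undocumented or suspect records", {
  s <- sign_table(
    sign_row("a", evidence_type = "kill", technically_documented = FALSE),
    sign_row("b", evidence_type = "dna_sample", dna_confirmed_wolf = TRUE),
    sign_row("c", evidence_type = "track", suspected_deception = TRUE)
  )
  expect_equal(screen_genuineness(s), c(FALSE, TRUE, FALSE))
  cl <- classify_signs(s)
  expect_equal(cl$category, c("discarded", "C1", "discarded"))
})

test_that("track length threshold is inclusive at 100 m", {
  s <- sign_table(
    sign_row("t80",  evidence_type = "track", typical_pattern = TRUE,
             track_length_m = 80, on_snow = TRUE),
    sign_row("t100", evidence_type = "track", typical_pattern = TRUE,
             track_length_m = 100),
    sign_row("t500", evidence_type = "track", typical_pattern = FALSE,
             track_length_m = 500)
  )
  expect_equal(classify_sign(s), c("C3", "C2", "C3"))
})

test_that("unknown evidence type is an explicit error", {
  s <- sign_row("x", evidence_type = "crop_circle")
  expect_error(classify_sign(s), "unknown evidence_type")
})

test_that("a scat on a C2 track is upgraded to C2", {
  s <- sign_table(
    sign_row("trk", evidence_type = "track", typical_pattern = TRUE,
             track_length_m = 300, track_id = "T1"),
    sign_row("sc1", evidence_type = "scat", expert_checked = FALSE,
             track_id = "T1"),
    sign_row("sc2", evidence_type = "scat", expert_checked = FALSE)
  )
  cl <- classify_signs(s)
  expect_equal(cl$category, c("C2", "C2", "C3"))
})

test_that("DNA collected on a track certifies the track as C1", {
  s <- sign_table(
    sign_row("trk", evidence_type = "track", typical_pattern = TRUE,
             track_length_m = 60, track_id = "T9"),
    sign_row("dna", evidence_type = "dna_sample", dna_confirmed_wolf = TRUE,
             track_id = "T9")
  )
  cl <- classify_signs(s)
  expect_equal(cl$category[cl$sign_id == "trk"], "C1")
})

test_that("kill combination rule uses nearby C2 data within 10 km / 14 days", {
  near <- sign_table(
    sign_row("k", "2015-11-01", x = 100, y = 100, evidence_type = "kill",
             typical_bites = TRUE),
    sign_row("t", "2015-11-10", x = 105, y = 100, evidence_type = "track",
             typical_pattern = TRUE, track_length_m = 200)
  )
  expect_equal(classify_signs(near)$category, c("C2", "C2"))
  far <- near
  far$x[2] <- 150  # 50 km away
  expect_equal(classify_signs(far)$category, c("C3", "C2"))
  late <- near
  late$date[2] <- as.Date("2015-12-24")
  expect_equal(classify_signs(late)$category, c("C3", "C2"))
  # an explicit flag short-circuits the linkage rule
  flagged <- sign_row("k", evidence_type = "kill", typical_bites = TRUE,
                      combined_with_C2 = TRUE)
  expect_equal(classify_signs(flagged)$category, "C2")
})

test_that("weakening any single attribute never raises the category", {
  set.seed(42)
  weaken <- list(
    function(r) { r$track_length_m <- min(r$track_length_m, 50); r },
    function(r) { r$expert_checked <- FALSE; r },
    function(r) { r$photo_quality <- "bad"; r },
    function(r) { r$dna_confirmed_wolf <- FALSE; r },
    function(r) { r$typical_pattern <- FALSE; r },
    function(r) { r$pups_heard <- FALSE; r },
    function(r) { r$typical_bites <- FALSE; r },
    function(r) { r$combined_with_C2 <- FALSE; r },
    function(r) { r$technically_documented <- FALSE; r }
  )
  types <- c("dna_sample", "photo_video", "track", "scat", "kill", "howl",
             "sighting", "telemetry", "dead_animal")
  for (i in 1:150) {
    r <- sign_row("f", evidence_type = sample(types, 1),
                  dna_confirmed_wolf = runif(1) < 0.3,
                  photo_quality = sample(c("good", "bad"), 1),
                  typical_pattern = runif(1) < 0.7,
                  track_length_m = sample(c(50, 100, 400), 1),
                  expert_checked = runif(1) < 0.5,
                  pups_heard = runif(1) < 0.5,
                  typical_bites = runif(1) < 0.5,
                  combined_with_C2 = runif(1) < 0.5,
                  technically_documented = TRUE)
    base <- classify_signs(r)$category
    w <- sample(weaken, 1)[[1]]
    weakened <- classify_signs(w(r))$category
    expect_lte(rank_category(weakened), rank_category(base))
  }
})

test_that("C1 assignment ignores location and date", {
  a <- sign_row("a", "2001-06-01", x = 0, y = 0, evidence_type = "dna_sample",
                dna_confirmed_wolf = TRUE)
  b <- sign_row("b", "2019-02-27", x = 600, y = 300,
                evidence_type = "dna_sample", dna_confirmed_wolf = TRUE)
  expect_equal(classify_sign(a), classify_sign(b))
})
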