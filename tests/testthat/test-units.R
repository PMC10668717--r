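lay <- alpine_layout()

test_that("genotype identity links signs regardless of distance", {
  s <- classify_signs(sign_table(
    dna_sign("a", 100, 100, "G1", "M"),
    dna_sign("b", 160, 100, "G1", "M", date = "2016-02-01")))
  terr <- cluster_signs(s, "2015-2016")
  expect_length(terr, 1)
})

test_that("clusters beyond the 15 km linkage threshold stay separate", {
  s <- classify_signs(sign_table(
    dna_sign("a1", 100, 100, "G1", "M"), dna_sign("a2", 102, 101, "G2", "F"),
    dna_sign("b1", 140, 100, "G3", "M"), dna_sign("b2", 141, 102, "G4", "F")))
  expect_length(cluster_signs(s, "2015-2016"), 2)
  # within threshold, no genetics to separate -> one component
  s2 <- classify_signs(sign_table(
    dna_sign("a1", 100, 100, "G1", "M"),
    dna_sign("b1", 110, 100, "G2", "F")))
  expect_length(cluster_signs(s2, "2015-2016"), 1)
  expect_length(cluster_signs(s[0, ], "2015-2016"), 0)
})

test_that("mixed-pedigree components are split by pedigree", {
  s <- classify_signs(sign_table(
    dna_sign("a1", 100, 100, "G1", "M", pedigree = "P1"),
    dna_sign("a2", 101, 100, "G2", "F", pedigree = "P1"),
    dna_sign("b1", 112, 100, "G3", "M", pedigree = "P2"),
    dna_sign("b2", 113, 100, "G4", "F", pedigree = "P2"),
    # ungenotyped track bridging the two, nearer the second
    sign_row("t", "2015-12-01", x = 110, y = 100, evidence_type = "track",
             typical_pattern = TRUE, track_length_m = 300)))
  terr <- cluster_signs(s, "2015-2016")
  expect_length(terr, 2)
  with_track <- vapply(terr, function(t) "t" %in% t$sign_ids, logical(1))
  expect_equal(sort(terr[[which(with_track)]]$genotypes), c("G3", "G4"))
})

test_that("territory representation circle is 200 km2 on the MCP centroid", {
  s <- classify_signs(sign_table(
    dna_sign("a", 100, 100, "G1", "M"), dna_sign("b", 104, 100, "G2", "F"),
    dna_sign("c", 102, 104, "G1", "M", date = "2016-01-05")))
  t <- cluster_signs(s, "2015-2016")[[1]]
  expect_equal(pi * t$radius_km^2, 200, tolerance = 1e-10)
  expect_equal(t$centroid, c(102, 100 + 4 / 3), tolerance = 1e-8)
})

test_that("pack and pair rules fire on the agreed evidence", {
  # expert-checked howl with pups (C2 reproduction) -> pack
  howl <- classify_signs(sign_table(
    sign_row("h", "2015-08-01", x = 100, y = 100, evidence_type = "howl",
             pups_heard = TRUE, expert_checked = TRUE),
    dna_sign("d", 101, 100, "G1", "M")))
  t <- cluster_signs(howl, "2015-2016")[[1]]
  expect_equal(classify_unit(t)$status, "pack")

  # C1 genetics: one male + one female, no pups -> pair
  pair <- classify_signs(sign_table(
    dna_sign("a", 100, 100, "G1", "M"),
    dna_sign("b", 101, 100, "G2", "F", date = "2016-01-10")))
  t <- cluster_signs(pair, "2015-2016")[[1]]
  expect_equal(classify_unit(t)$status, "pair")

  # >=3 C1 genotypes -> pack even without pup evidence
  trio <- classify_signs(sign_table(
    dna_sign("a", 100, 100, "G1", "M"), dna_sign("b", 101, 100, "G2", "F"),
    dna_sign("c", 100, 101, "G3", "M")))
  t <- cluster_signs(trio, "2015-2016")[[1]]
  expect_equal(classify_unit(t)$status, "pack")

  # two independent C2 tracks of >=3 traveling together -> pack
  tracks <- classify_signs(sign_table(
    sign_row("t1", "2015-12-01", x = 100, y = 100, evidence_type = "track",
             typical_pattern = TRUE, track_length_m = 500, n_individuals = 4,
             track_id = "TA"),
    sign_row("t2", "2016-01-15", x = 103, y = 100, evidence_type = "track",
             typical_pattern = TRUE, track_length_m = 800, n_individuals = 3,
             track_id = "TB")))
  t <- cluster_signs(tracks, "2015-2016")[[1]]
  expect_equal(classify_unit(t)$status, "pack")

  # pack precedence: pair bond plus pup evidence resolves to pack
  both <- classify_signs(sign_table(
    dna_sign("a", 100, 100, "G1", "M"), dna_sign("b", 101, 100, "G2", "F"),
    dna_sign("p", 100, 101, "G3", "M", age = "pup")))
  t <- cluster_signs(both, "2015-2016")[[1]]
  expect_equal(classify_unit(t)$status, "pack")
})

test_that("C3-only evidence yields no unit but keeps occurrence eligibility", {
  s <- classify_signs(sign_table(
    sign_row("s1", "2015-12-01", x = 100, y = 100, evidence_type = "sighting"),
    sign_row("s2", "2015-12-05", x = 101, y = 100, evidence_type = "sighting")))
  res <- resolve_units(s, "2015-2016", lay)
  expect_equal(nrow(res$units), 0)
})

test_that("indistinguishable adjacent candidates merge; distinguished ones do not", {
  # two clusters 10 km apart (overlapping circles) with interleaved pedigrees
  # absent; no reproduction evidence on either side
  mk <- function(x0, ids, genos) classify_signs(sign_table(
    dna_sign(ids[1], x0, 100, genos[1], "M"),
    dna_sign(ids[2], x0 + 1, 100, genos[2], "F", date = "2016-01-10")))
  merged <- rbind(mk(100, c("a1", "a2"), c("G1", "G2")),
                  mk(110, c("b1", "b2"), c("G1", "G2")))
  # same genotypes: clustered together already
  expect_length(cluster_signs(merged, "2015-2016"), 1)

  # disjoint genotypes with distinct pedigrees -> two units
  two <- classify_signs(sign_table(
    dna_sign("a1", 100, 100, "G1", "M", pedigree = "P1"),
    dna_sign("a2", 101, 100, "G2", "F", pedigree = "P1"),
    dna_sign("b1", 112, 100, "G3", "M", pedigree = "P2"),
    dna_sign("b2", 113, 100, "G4", "F", pedigree = "P2")))
  res <- resolve_units(two, "2015-2016", lay)
  expect_equal(nrow(res$units), 2)

  # disjoint genotypes but no pedigree assignment, overlapping circles,
  # no reproduction: cannot be told apart -> merged into one unit
  anon <- classify_signs(sign_table(
    dna_sign("a1", 100, 100, "G1", "M"),
    dna_sign("a2", 100.4, 100, "G2", "F"),
    dna_sign("b1", 115.6, 100, "G3", "M"),
    dna_sign("b2", 116, 100, "G4", "F")))
  terr <- cluster_signs(anon, "2015-2016")
  expect_length(terr, 2)  # 15.5 km apart: beyond spatial linkage
  cands <- lapply(terr, function(t) {
    cl <- classify_unit(t); list(territory = t, status = cl$status, basis = cl$basis)
  })
  merged_cands <- split_adjacent_packs(cands)
  expect_length(merged_cands, 1)
  expect_equal(merged_cands[[1]]$status, "pack")  # 4 C1 genotypes pooled

  # simultaneous reproduction in both -> stays two packs
  repro <- function(x0, id, geno, ped) classify_signs(sign_table(
    dna_sign(paste0(id, "1"), x0, 100, geno[1], "M", pedigree = ped),
    dna_sign(paste0(id, "p"), x0 + 1, 100, geno[2], "F", pedigree = ped,
             age = "pup")))
  s2 <- rbind(repro(100, "a", c("G1", "G2"), "P1"),
              repro(112, "b", c("G3", "G4"), "P2"))
  res <- resolve_units(s2, "2015-2016", lay)
  expect_equal(nrow(res$units), 2)
  expect_true(all(res$units$status == "pack"))
})

test_that("transboundary units are detected and counted once", {
  # same genotypes on both sides of the FR|CH border at x = 220
  s <- classify_signs(sign_table(
    dna_sign("f1", 215, 200, "G1", "M"),
    dna_sign("f2", 216, 201, "G2", "F"),
    dna_sign("c1", 224, 200, "G1", "M", date = "2016-02-01"),
    dna_sign("c2", 225, 199, "G3", "M", date = "2016-02-02")))
  res <- resolve_units(s, "2015-2016", lay)
  expect_equal(nrow(res$units), 1)
  expect_equal(res$units$transboundary_status, "TR")
  expect_equal(res$units$countries, "CH-FR")

  # wholly inside one country -> national
  nat <- classify_signs(sign_table(
    dna_sign("a", 100, 100, "G1", "M"), dna_sign("b", 101, 100, "G2", "F")))
  res <- resolve_units(nat, "2015-2016", lay)
  expect_equal(res$units$transboundary_status, "national")
  expect_equal(res$units$countries, "FR")

  # cross-border signs without genetic match, circle crossing -> LTR
  ltr <- classify_signs(sign_table(
    sign_row("t1", "2015-12-01", x = 216, y = 200, evidence_type = "track",
             typical_pattern = TRUE, track_length_m = 400, n_individuals = 3,
             track_id = "TA"),
    sign_row("t2", "2016-01-10", x = 224, y = 201, evidence_type = "track",
             typical_pattern = TRUE, track_length_m = 500, n_individuals = 4,
             track_id = "TB")))
  res <- resolve_units(ltr, "2015-2016", lay)
  expect_equal(nrow(res$units), 1)
  expect_equal(res$units$transboundary_status, "LTR")
})

test_that("duplicate national records of one TR pack deduplicate to one", {
  # national datasets processed separately produce two candidate territories
  fr <- classify_signs(sign_table(
    dna_sign("f1", 215, 200, "G1", "M"), dna_sign("f2", 216, 200, "G2", "F"),
    dna_sign("f3", 215, 201, "G5", "M")))
  ch <- classify_signs(sign_table(
    dna_sign("c1", 260, 200, "G1", "M", date = "2016-02-01"),
    dna_sign("c2", 261, 200, "G4", "F")))
  terr_fr <- cluster_signs(fr, "2015-2016")
  terr_ch <- cluster_signs(ch, "2015-2016")
  cands <- lapply(c(terr_fr, terr_ch), function(t) {
    cl <- classify_unit(t); list(territory = t, status = cl$status, basis = cl$basis)
  })
  expect_length(cands, 2)
  resolved <- resolve_transboundary(cands, lay)
  expect_length(resolved, 1)
  expect_equal(resolved[[1]]$transboundary_status, "TR")
  # idempotence
  expect_length(resolve_transboundary(resolved, lay), 1)
})

test_that("a genotype claimed in more than two countries is an integrity error", {
  s <- classify_signs(sign_table(
    dna_sign("a", 210, 200, "G1", "M"),            # FR
    dna_sign("b", 230, 200, "G1", "M"),            # CH
    dna_sign("c", 230, 100, "G1", "M")))           # IT
  terr <- cluster_signs(s, "2015-2016")
  cands <- lapply(terr, function(t) {
    cl <- classify_unit(t); list(territory = t, status = cl$status, basis = cl$basis)
  })
  expect_error(resolve_transboundary(cands, lay), "integrity")
})

test_that("no genotype belongs to two units after resolution", {
  set.seed(3)
  cfg <- sim_config(seed = 3, n_years = 6, initial_units = 3)
  tr <- simulate_population(cfg)
  cl <- classify_signs(generate_signs(tr)$signs)
  for (y in unique(tr$units$monitoring_year)) {
    res <- resolve_units(cl, y, cfg$layout)
    g <- unlist(lapply(res$cands, function(u) u$territory$genotypes))
    expect_false(any(duplicated(g)))
  }
})

test_that("population summary books transboundary units exactly once", {
  units <- unit_table("2015-2016",
    national = data.frame(country = c("IT", "FR"), packs = c(2, 1),
                          pairs = c(1, 0)),
    transboundary = data.frame(countries = "FR-IT", packs = 1, pairs = 0))
  sm <- summarize_units(units)
  expect_equal(sm$total_packs, 4)
  expect_equal(sm$total_pairs, 1)
  expect_equal(sm$total_units, 5)
  # totals invariant under row permutation
  sm2 <- summarize_units(units[sample(nrow(units)), ])
  expect_equal(sm2$total_units, sm$total_units)
  expect_equal(sm2$total_packs, sm$total_packs)
  # zero pairs -> zero pair fraction
  sm3 <- summarize_units(unit_table("2015-2016",
    national = data.frame(country = "IT", packs = 3, pairs = 0)))
  expect_equal(sm3$pair_fraction_pct, 0)
})
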