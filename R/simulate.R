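# Spatially explicit recolonisation simulator: a branching process of
# territorial pack/pair units on a planar multi-country region, with
# imperfect detection, genotyping failure, dispersers and noise signs.

#' Simulation configuration
#'
#' Defines the study conditions for the synthetic recolonisation generator.
#' Defaults emulate an expanding Alpine-type wolf population under intensive
#' multi-method national monitoring.
#'
#' @param seed integer RNG seed; identical config + seed gives bit-identical
#'   outputs.
#' @param n_years number of monitoring years simulated.
#' @param initial_units number of founding units in year 1.
#' @param growth_rate expected yearly multiplier of the unit count.
#' @param pair_fraction target share of pairs among units (pairs are newly
#'   bonded units that have not yet reproduced).
#' @param territory_area_km2 representation-circle area; the minimum spacing
#'   between territory centres is twice its radius (non-overlapping circles).
#' @param dispersal_scale_km scale of the short-range exponential founding
#'   kernel; a `long_range_fraction` of foundings instead lands uniformly in
#'   the region, creating stepping stones.
#' @param layout a `wolf_layout` (country partition + Alpine range).
#' @param detection_rates named numeric vector: expected signs per unit-year
#'   by evidence class (`dna_sample`, `photo_video`, `track`, `scat`,
#'   `howl`, `kill`).
#' @param genotyping_success probability a collected DNA sample yields a
#'   confirmed wolf genotype.
#' @param noise_sign_rate expected unverifiable/false signs per 100 km² per
#'   year; noise signs are attribute-poor by construction and can never
#'   reach C1.
#' @param survival yearly unit persistence probability; the founding
#'   probability is set so the expected multiplier equals `growth_rate`.
#' @param pack_reproduction_prob yearly reproduction probability of an
#'   established pack.
#' @param long_range_fraction share of long-range (uniform) foundings.
#' @param disperser_rate expected dispersing singletons per year.
#' @param start_year first calendar year (monitoring year 1 starts 1 May).
#' @return a `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_years = 10L, initial_units = 3L,
                       growth_rate = 1.22, pair_fraction = 0.15,
                       territory_area_km2 = 200, dispersal_scale_km = 40,
                       layout = alpine_layout(),
                       detection_rates = c(dna_sample = 8, photo_video = 2.5,
                                           track = 3, scat = 2, howl = 1.2,
                                           kill = 0.8),
                       genotyping_success = 0.85, noise_sign_rate = 0.2,
                       survival = 0.95, pack_reproduction_prob = 0.8,
                       long_range_fraction = 0.05, disperser_rate = 1.5,
                       start_year = 2000L) {
  stopifnot(pair_fraction >= 0, pair_fraction <= 1, growth_rate > 0,
            territory_area_km2 > 0, dispersal_scale_km > 0,
            all(detection_rates >= 0), genotyping_success >= 0,
            genotyping_success <= 1, noise_sign_rate >= 0,
            survival > 0, survival <= 1, n_years >= 1, initial_units >= 1,
            inherits(layout, "wolf_layout"))
  if (growth_rate / survival - 1 > 1)
    stop("growth_rate too large for the survival probability: a unit cannot ",
         "found more than one new unit per year")
  structure(as.list(environment()), class = "sim_config")
}

runif_in_ring <- function(ring, n = 1) {
  ring <- as_ring(ring)
  xr <- range(ring[, 1]); yr <- range(ring[, 2])
  out <- matrix(NA_real_, n, 2)
  for (i in seq_len(n)) {
    repeat {
      p <- c(stats::runif(1, xr[1], xr[2]), stats::runif(1, yr[1], yr[2]))
      if (point_in_ring(p[1], p[2], ring)) { out[i, ] <- p; break }
    }
  }
  out
}

#' Simulate the true recolonisation process
#'
#' A yearly branching process: each unit persists with probability
#' `survival`; each survivor founds a new unit with probability
#' `growth_rate / survival - 1`, so the expected yearly multiplier of the
#' unit count equals `growth_rate`. New centres are drawn from a mixture of
#' a short-range exponential kernel around the parent and a long-range
#' uniform component (stepping stones), rejecting locations that violate the
#' minimum centre spacing (non-overlapping 200 km² circles) or leave the
#' region. New units start as pairs (which reproduce — becoming packs — the
#' following year) or directly as budding packs, in proportions chosen so
#' the stationary pair share matches `pair_fraction`.
#'
#' @param config a [sim_config()].
#' @return a `wolf_truth` list: `units` (one row per unit-year), `members`
#'   (genotype labels with sex and age class per unit-year) and the config.
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  lay <- config$layout
  r <- territory_radius(config$territory_area_km2)
  spacing <- 2 * r
  f <- config$growth_rate / config$survival - 1
  q_pair <- min(1, config$pair_fraction * config$growth_rate /
                  max(config$growth_rate - config$survival, 1e-9))

  units <- list()   # live state: id, center, status, founded_year
  next_id <- 1L

  new_unit <- function(center, status, year_idx) {
    u <- list(id = next_id, center = center, status = status,
              founded = year_idx, reproduced = FALSE)
    next_id <<- next_id + 1L
    u
  }

  # founding placement
  for (i in seq_len(config$initial_units)) {
    placed <- FALSE
    for (try in 1:500) {
      p <- runif_in_ring(lay$alpine)
      ok <- TRUE
      for (u in units)
        if (sqrt(sum((u$center - p)^2)) < spacing) { ok <- FALSE; break }
      if (ok) {
        st <- if (stats::runif(1) < config$pair_fraction) "pair" else "pack"
        units[[length(units) + 1L]] <- new_unit(as.numeric(p), st, 1L)
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("region too small to place ", config$initial_units,
           " initial territories at ", round(spacing, 1), " km spacing")
  }

  rows <- list(); member_rows <- list()
  record <- function(u, year_idx) {
    ylab <- sprintf("%d-%d", config$start_year + year_idx - 1L,
                    config$start_year + year_idx)
    adults <- data.frame(
      genotype = sprintf("G%04d%s", u$id, c("a", "b")),
      sex = c("M", "F"), age_class = "adult", stringsAsFactors = FALSE)
    mem <- adults
    if (u$status == "pack") {
      off <- data.frame(
        genotype = sprintf("G%04do%d", u$id, 1:3),
        sex = sample(c("M", "F"), 3, replace = TRUE),
        age_class = if (u$reproduced) "pup" else "adult",
        stringsAsFactors = FALSE)
      mem <- rbind(adults, off)
    }
    mem$unit_id <- sprintf("U%04d", u$id)
    mem$monitoring_year <- ylab
    member_rows[[length(member_rows) + 1L]] <<- mem
    countries <- names(lay$countries)[vapply(names(lay$countries), function(cc)
      dist_to_ring(u$center[1], u$center[2], lay$countries[[cc]]) < r,
      logical(1))]
    rows[[length(rows) + 1L]] <<- data.frame(
      unit_id = sprintf("U%04d", u$id), monitoring_year = ylab,
      year_index = year_idx, status = u$status,
      center_x = u$center[1], center_y = u$center[2],
      n_members = nrow(mem), reproduced_this_year = u$reproduced,
      countries_overlapped = paste(sort(countries), collapse = "-"),
      stringsAsFactors = FALSE)
  }

  place_offspring <- function(parent_center, live) {
    xr <- range(lay$region[, 1]); yr <- range(lay$region[, 2])
    for (try in 1:200) {
      if (stats::runif(1) < config$long_range_fraction) {
        p <- as.numeric(runif_in_ring(lay$region))
      } else {
        d <- spacing + stats::rexp(1, 1 / config$dispersal_scale_km)
        th <- stats::runif(1, 0, 2 * pi)
        p <- parent_center + d * c(cos(th), sin(th))
        if (p[1] < xr[1] || p[1] > xr[2] || p[2] < yr[1] || p[2] > yr[2]) next
      }
      ok <- TRUE
      for (u in live) if (sqrt(sum((u$center - p)^2)) < spacing) { ok <- FALSE; break }
      if (ok) return(p)
    }
    NULL
  }

  for (year_idx in seq_len(config$n_years)) {
    if (year_idx > 1) {
      # survival
      alive <- vapply(units, function(u) stats::runif(1) < config$survival,
                      logical(1))
      units <- units[alive]
      # pair -> pack on first reproduction; pack reproduction
      for (k in seq_along(units)) {
        u <- units[[k]]
        if (u$status == "pair") {
          u$status <- "pack"; u$reproduced <- TRUE
        } else {
          u$reproduced <- stats::runif(1) < config$pack_reproduction_prob
        }
        units[[k]] <- u
      }
      # founding
      if (f > 0 && length(units)) {
        parents <- which(stats::runif(length(units)) < f)
        for (k in parents) {
          p <- place_offspring(units[[k]]$center, units)
          if (is.null(p)) next
          st <- if (stats::runif(1) < q_pair) "pair" else "pack"
          nu <- new_unit(p, st, year_idx)
          nu$reproduced <- FALSE
          units[[length(units) + 1L]] <- nu
        }
      }
    }
    for (u in units) record(u, year_idx)
    if (!length(units)) break
  }

  structure(list(units = do.call(rbind, rows),
                 members = do.call(rbind, member_rows),
                 config = config),
            class = "wolf_truth")
}

blank_sign <- function() {
  data.frame(sign_id = NA_character_, date = as.Date(NA), x = NA_real_,
             y = NA_real_, country = NA_character_,
             evidence_type = NA_character_, track_length_m = NA_real_,
             typical_pattern = NA, expert_checked = NA,
             dna_confirmed_wolf = NA, genotype_label = NA_character_,
             genotype_sex = NA_character_, age_class = NA_character_,
             pedigree_id = NA_character_, photo_quality = NA_character_,
             pups_heard = NA, pups_present = NA, n_individuals = NA_real_,
             typical_bites = NA, combined_with_C2 = NA,
             technically_documented = TRUE, suspected_deception = FALSE,
             on_snow = NA, track_id = NA_character_,
             stringsAsFactors = FALSE)
}

rand_date <- function(ylab, n = 1) {
  start <- as.Date(sprintf("%d-05-01", monitoring_year_start(ylab)))
  start + sample.int(365, n, replace = TRUE) - 1L
}

point_in_circle <- function(center, r, region, n = 1) {
  xr <- range(region[, 1]); yr <- range(region[, 2])
  out <- matrix(NA_real_, n, 2)
  for (i in seq_len(n)) {
    for (try in 1:50) {
      rr <- r * sqrt(stats::runif(1)); th <- stats::runif(1, 0, 2 * pi)
      p <- center + rr * c(cos(th), sin(th))
      if (p[1] >= xr[1] && p[1] <= xr[2] && p[2] >= yr[1] && p[2] <= yr[2]) break
    }
    out[i, ] <- pmin(pmax(p, c(xr[1], yr[1])), c(xr[2], yr[2]))
  }
  out
}

#' Generate sign-of-presence records from simulated truth
#'
#' Draws, per unit-year, Poisson numbers of signs of each evidence class at
#' the configured detection rates, placed uniformly in the 200 km² territory
#' circle and dated uniformly within the monitoring year. DNA samples yield
#' a member genotype (with sex, age class and the unit's pedigree label)
#' with probability `genotyping_success`. Adds disperser signs outside
#' territories and attribute-poor noise signs that can never reach C1.
#' Ground-truth linkage (true unit per sign) is returned as a separate
#' table.
#'
#' @param truth a `wolf_truth` from [simulate_population()].
#' @return list with `signs` (one row per record) and `links`
#'   (`sign_id` -> `true_unit_id`; noise signs link to `"noise"`).
#' @export
generate_signs <- function(truth) {
  stopifnot(inherits(truth, "wolf_truth"))
  config <- truth$config
  set.seed(config$seed + 1000003L)
  lay <- config$layout
  r <- territory_radius(config$territory_area_km2)
  rates <- config$detection_rates
  rate <- function(nm) if (nm %in% names(rates)) rates[[nm]] else 0

  rows <- list(); link_unit <- character(0)
  sid <- 0L
  emit <- function(row, unit) {
    sid <<- sid + 1L
    row$sign_id <- sprintf("S%06d", sid)
    rows[[length(rows) + 1L]] <<- row
    link_unit[length(link_unit) + 1L] <<- unit
  }

  units <- truth$units
  for (i in seq_len(nrow(units))) {
    u <- units[i, ]
    ylab <- u$monitoring_year
    center <- c(u$center_x, u$center_y)
    mem <- truth$members[truth$members$unit_id == u$unit_id &
                           truth$members$monitoring_year == ylab, , drop = FALSE]
    pedigree <- sprintf("P%04d", as.integer(sub("^U", "", u$unit_id)))
    is_pack <- u$status == "pack"

    n_dna <- stats::rpois(1, rate("dna_sample"))
    if (n_dna) {
      pos <- point_in_circle(center, r, lay$region, n_dna)
      pick <- sample.int(nrow(mem), n_dna, replace = TRUE)
      conf <- stats::runif(n_dna) < config$genotyping_success
      for (k in seq_len(n_dna)) {
        row <- blank_sign()
        row$date <- rand_date(ylab); row$x <- pos[k, 1]; row$y <- pos[k, 2]
        row$evidence_type <- "dna_sample"
        row$dna_confirmed_wolf <- conf[k]
        if (conf[k]) {
          row$genotype_label <- mem$genotype[pick[k]]
          row$genotype_sex <- mem$sex[pick[k]]
          row$age_class <- mem$age_class[pick[k]]
          row$pedigree_id <- pedigree
        }
        emit(row, u$unit_id)
      }
    }

    n_photo <- stats::rpois(1, rate("photo_video"))
    if (n_photo) {
      pos <- point_in_circle(center, r, lay$region, n_photo)
      for (k in seq_len(n_photo)) {
        row <- blank_sign()
        row$date <- rand_date(ylab); row$x <- pos[k, 1]; row$y <- pos[k, 2]
        row$evidence_type <- "photo_video"
        row$photo_quality <- if (stats::runif(1) < 0.9) "good" else "bad"
        if (is_pack) {
          with_pups <- u$reproduced_this_year && stats::runif(1) < 0.6
          row$n_individuals <- if (with_pups) sample(3:5, 1) else sample(1:3, 1)
          row$pups_present <- with_pups
        } else {
          row$n_individuals <- if (stats::runif(1) < 0.8) 2 else 1
          row$pups_present <- FALSE
        }
        emit(row, u$unit_id)
      }
    }

    n_track <- stats::rpois(1, rate("track"))
    if (n_track) {
      pos <- point_in_circle(center, r, lay$region, n_track)
      for (k in seq_len(n_track)) {
        row <- blank_sign()
        row$date <- rand_date(ylab); row$x <- pos[k, 1]; row$y <- pos[k, 2]
        row$evidence_type <- "track"
        row$typical_pattern <- TRUE
        row$track_length_m <- round(stats::rlnorm(1, log(400), 0.8))
        row$on_snow <- stats::runif(1) < 0.6
        row$n_individuals <- if (is_pack) sample(2:5, 1) else 2
        row$track_id <- sprintf("TRK%s_%d", u$unit_id, k)
        emit(row, u$unit_id)
      }
    }

    n_scat <- stats::rpois(1, rate("scat"))
    if (n_scat) {
      pos <- point_in_circle(center, r, lay$region, n_scat)
      for (k in seq_len(n_scat)) {
        row <- blank_sign()
        row$date <- rand_date(ylab); row$x <- pos[k, 1]; row$y <- pos[k, 2]
        row$evidence_type <- "scat"
        row$expert_checked <- stats::runif(1) < 0.7
        emit(row, u$unit_id)
      }
    }

    n_howl <- stats::rpois(1, rate("howl"))
    if (n_howl) {
      pos <- point_in_circle(center, r, lay$region, n_howl)
      for (k in seq_len(n_howl)) {
        row <- blank_sign()
        row$date <- rand_date(ylab); row$x <- pos[k, 1]; row$y <- pos[k, 2]
        row$evidence_type <- "howl"
        row$pups_heard <- isTRUE(u$reproduced_this_year)
        row$expert_checked <- stats::runif(1) < 0.9
        emit(row, u$unit_id)
      }
    }

    n_kill <- stats::rpois(1, rate("kill"))
    if (n_kill) {
      pos <- point_in_circle(center, r, lay$region, n_kill)
      for (k in seq_len(n_kill)) {
        row <- blank_sign()
        row$date <- rand_date(ylab); row$x <- pos[k, 1]; row$y <- pos[k, 2]
        row$evidence_type <- "kill"
        row$typical_bites <- stats::runif(1) < 0.8
        emit(row, u$unit_id)
      }
    }
  }

  # dispersers: solitary animals outside the resident territories
  years <- unique(units$monitoring_year)
  disp_id <- 0L
  for (ylab in years) {
    n_disp <- stats::rpois(1, config$disperser_rate)
    for (dd in seq_len(n_disp)) {
      disp_id <- disp_id + 1L
      uid <- sprintf("D%03d", disp_id)
      p <- as.numeric(runif_in_ring(lay$region))
      row <- blank_sign()
      row$date <- rand_date(ylab); row$x <- p[1]; row$y <- p[2]
      row$evidence_type <- "track"; row$typical_pattern <- TRUE
      row$track_length_m <- round(stats::rlnorm(1, log(600), 0.6))
      row$n_individuals <- 1; row$on_snow <- TRUE
      row$track_id <- sprintf("TRKD%03d", disp_id)
      emit(row, uid)
      if (stats::runif(1) < 0.5) {
        row <- blank_sign()
        row$date <- rand_date(ylab)
        q <- p + stats::rnorm(2, 0, 3)
        xr <- range(lay$region[, 1]); yr <- range(lay$region[, 2])
        row$x <- min(max(q[1], xr[1]), xr[2]); row$y <- min(max(q[2], yr[1]), yr[2])
        row$evidence_type <- "dna_sample"
        conf <- stats::runif(1) < config$genotyping_success
        row$dna_confirmed_wolf <- conf
        if (conf) {
          row$genotype_label <- sprintf("GD%03d", disp_id)
          row$genotype_sex <- sample(c("M", "F"), 1)
          row$age_class <- "adult"
        }
        emit(row, uid)
      }
    }
  }

  # noise: attribute-poor records that can never reach C1
  region_area <- abs(polygon_area(lay$region))
  for (ylab in years) {
    n_noise <- stats::rpois(1, config$noise_sign_rate * region_area / 100)
    for (k in seq_len(n_noise)) {
      p <- as.numeric(runif_in_ring(lay$region))
      row <- blank_sign()
      row$date <- rand_date(ylab); row$x <- p[1]; row$y <- p[2]
      kind <- sample(c("sighting", "short_track", "unchecked_scat",
                       "undocumented_kill"), 1)
      if (kind == "sighting") {
        row$evidence_type <- "sighting"
      } else if (kind == "short_track") {
        row$evidence_type <- "track"; row$typical_pattern <- TRUE
        row$track_length_m <- round(stats::runif(1, 10, 99)); row$on_snow <- TRUE
      } else if (kind == "unchecked_scat") {
        row$evidence_type <- "scat"; row$expert_checked <- FALSE
      } else {
        row$evidence_type <- "kill"; row$technically_documented <- FALSE
      }
      emit(row, "noise")
    }
  }

  signs <- do.call(rbind, rows)
  if (is.null(signs)) {
    signs <- blank_sign()[0, ]
  }
  signs$country <- country_of(signs$x, signs$y, lay)
  list(signs = signs,
       links = data.frame(sign_id = signs$sign_id, true_unit_id = link_unit,
                          stringsAsFactors = FALSE))
}

#' Write a synthetic dataset to plain-text files
#'
#' Writes `signs.csv`, `truth_units.csv`, `truth_links.csv`, `config.json`
#' and `region.geojson` into a directory.
#'
#' @param truth a `wolf_truth`.
#' @param gen output of [generate_signs()].
#' @param dir output directory (created if needed).
#' @export
write_simulation <- function(truth, gen, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(gen$signs, file.path(dir, "signs.csv"), row.names = FALSE)
  utils::write.csv(truth$units, file.path(dir, "truth_units.csv"), row.names = FALSE)
  utils::write.csv(gen$links, file.path(dir, "truth_links.csv"), row.names = FALSE)
  cfg <- truth$config
  cfg$layout <- NULL
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  write_layout_geojson(truth$config$layout, file.path(dir, "region.geojson"))
  invisible(dir)
}
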