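# Resolution of reproductive units (packs and pairs) from classified signs.
# Territories carry a fixed-area representation circle of 200 km^2 centred on
# the centroid of the MCP of the unit's C1-C2 signs.

territory_radius <- function(area_km2 = 200) sqrt(area_km2 / pi)

make_territory <- function(signs, id, year, area_km2 = 200) {
  pts <- unique(cbind(signs$x, signs$y))
  mcp <- if (nrow(pts) >= 3) pts[grDevices::chull(pts), , drop = FALSE] else pts
  centroid <- if (nrow(mcp) >= 3) polygon_centroid(mcp) else colMeans(mcp)
  g <- attr_col(signs, "genotype_label", NA_character_)
  p <- attr_col(signs, "pedigree_id", NA_character_)
  list(territory_id = id, monitoring_year = year, signs = signs,
       sign_ids = signs$sign_id,
       genotypes = sort(unique(g[!is.na(g)])),
       pedigrees = sort(unique(p[!is.na(p)])),
       mcp = mcp, centroid = as.numeric(centroid),
       radius_km = territory_radius(area_km2), area_km2 = area_km2)
}

#' Cluster classified signs into candidate territories
#'
#' Signs of one monitoring year with C1/C2 validation are linked when they
#' share a genotype label or a pedigree assignment (genetics overrides
#' distance), or fall within `linkage_km` of each other. Connected components
#' become candidate territories. A component that mixes two or more distinct
#' pedigrees — adjacent packs bridged by an ungenotyped sign — is split by
#' pedigree, unassigned signs joining the nearest pedigree group.
#'
#' @param classified output of [classify_signs()], coordinates in km.
#' @param year monitoring-year label.
#' @param linkage_km spatial linkage threshold (default 15 km, about twice
#'   the 200 km² representation radius).
#' @param area_km2 representation-circle area.
#' @return list of territory objects.
#' @export
cluster_signs <- function(classified, year, linkage_km = 15, area_km2 = 200) {
  s <- classified[!is.na(classified$monitoring_year) &
                    classified$monitoring_year == year &
                    classified$category %in% c("C1", "C2"), , drop = FALSE]
  if (nrow(s) == 0) return(list())
  n <- nrow(s)
  geno <- as.character(attr_col(s, "genotype_label", NA_character_))
  pedi <- as.character(attr_col(s, "pedigree_id", NA_character_))

  d <- as.matrix(stats::dist(cbind(s$x, s$y)))
  adj <- d <= linkage_km
  for (lab in unique(geno[!is.na(geno)])) {
    i <- which(!is.na(geno) & geno == lab)
    adj[i, i] <- TRUE
  }
  for (lab in unique(pedi[!is.na(pedi)])) {
    i <- which(!is.na(pedi) & pedi == lab)
    adj[i, i] <- TRUE
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected", diag = FALSE)
  comp <- igraph::components(g)$membership

  # split mixed-pedigree components
  group <- comp
  next_id <- max(comp) + 1L
  for (cid in unique(comp)) {
    idx <- which(comp == cid)
    peds <- unique(pedi[idx][!is.na(pedi[idx])])
    if (length(peds) < 2) next
    sub <- rep(NA_integer_, length(idx))
    ids <- seq(next_id, length.out = length(peds))
    for (k in seq_along(peds)) sub[!is.na(pedi[idx]) & pedi[idx] == peds[k]] <- ids[k]
    # unassigned signs join the nearest pedigree group
    for (j in which(is.na(sub))) {
      dd <- vapply(seq_along(peds), function(k) {
        members <- idx[which(sub == ids[k])]
        min(d[idx[j], members])
      }, numeric(1))
      sub[j] <- ids[which.min(dd)]
    }
    group[idx] <- sub
    next_id <- next_id + length(peds)
  }

  out <- list()
  for (gid in sort(unique(group))) {
    idx <- which(group == gid)
    tid <- sprintf("%s_T%02d", year, length(out) + 1L)
    out[[length(out) + 1L]] <- make_territory(s[idx, , drop = FALSE], tid, year,
                                              area_km2 = area_km2)
  }
  out
}

has_reproduction_evidence <- function(signs) {
  cat <- signs$category
  any((attr_col(signs, "pups_heard", FALSE) & cat == "C2") |
        (attr_col(signs, "pups_present", FALSE) & cat %in% c("C1", "C2")) |
        (as.character(attr_col(signs, "age_class", NA_character_)) %in% "pup" &
           cat == "C1"))
}

#' Classify a candidate territory as pack, pair or none
#'
#' Pack when reproduction is confirmed (C1 or C2 pup evidence), or at least
#' two independent C2 signs show three or more animals travelling together,
#' or at least three individuals are confirmed by C1 (distinct genotypes, or
#' a good-quality image of three or more). Pair when hard evidence documents
#' exactly one male and one female bonded together (a C1 image of the two,
#' or C1 genotypes of exactly one male plus one female). Reproduction
#' evidence takes precedence: a territory meeting both rules is a pack.
#' Anything else — dispersers, solitary residents — is `"none"` and is kept
#' out of unit counts (it still feeds the occurrence map).
#'
#' @param territory a territory from [cluster_signs()].
#' @return list with `status` (`"pack"/"pair"/"none"`) and `basis`.
#' @export
classify_unit <- function(territory) {
  s <- territory$signs
  cat <- s$category
  nind <- suppressWarnings(as.numeric(attr_col(s, "n_individuals", NA_real_)))
  geno <- as.character(attr_col(s, "genotype_label", NA_character_))
  sex  <- as.character(attr_col(s, "genotype_sex", NA_character_))

  if (has_reproduction_evidence(s))
    return(list(status = "pack", basis = "reproduction confirmed (C1/C2)"))

  grp <- which(cat == "C2" & s$evidence_type == "track" & !is.na(nind) & nind >= 3)
  if (length(grp) >= 2) {
    for (a in seq_len(length(grp) - 1)) for (b in seq(a + 1, length(grp))) {
      if (c2_independent(s[grp[a], , drop = FALSE], s[grp[b], , drop = FALSE]))
        return(list(status = "pack", basis = ">=2 independent C2 of >=3 traveling together"))
    }
  }

  c1 <- cat == "C1"
  c1_geno <- unique(geno[c1 & !is.na(geno)])
  if (length(c1_geno) >= 3)
    return(list(status = "pack", basis = ">=3 individuals by C1 genetics"))
  if (any(c1 & s$evidence_type == "photo_video" & !is.na(nind) & nind >= 3))
    return(list(status = "pack", basis = ">=3 individuals by C1 photo/video"))

  # pair: exactly 1 male + 1 female documented bonding by C1
  if (length(c1_geno) == 2) {
    sexes <- unique(sex[c1 & !is.na(geno)])
    if (setequal(sexes[!is.na(sexes)], c("F", "M")))
      return(list(status = "pair", basis = "C1 genetics: 1 male + 1 female"))
  }
  if (any(c1 & s$evidence_type == "photo_video" & !is.na(nind) & nind == 2))
    return(list(status = "pair", basis = "C1 photo/video of bonded pair"))

  list(status = "none", basis = "no pack/pair confirmation")
}

candidate_units <- function(territories) {
  out <- lapply(territories, function(t) {
    cl <- classify_unit(t)
    list(territory = t, status = cl$status, basis = cl$basis)
  })
  out
}

# Adjacent candidates count as distinct units only with (a) genetic pack
# identification: disjoint genotype sets assigned to distinct pedigrees,
# (b) simultaneous proof of reproduction in each, or (c) telemetry from a
# collared member. Disjoint genotypes without pedigree assignment do not
# suffice (they could be members of one unit).
units_distinguished <- function(a, b) {
  ga <- a$territory$genotypes; gb <- b$territory$genotypes
  pa <- a$territory$pedigrees; pb <- b$territory$pedigrees
  genetic <- length(ga) > 0 && length(gb) > 0 && !any(ga %in% gb) &&
    length(pa) > 0 && length(pb) > 0 && !any(pa %in% pb)
  simultaneous_repro <- has_reproduction_evidence(a$territory$signs) &&
    has_reproduction_evidence(b$territory$signs)
  telemetry <- any(a$territory$signs$evidence_type == "telemetry") ||
    any(b$territory$signs$evidence_type == "telemetry")
  genetic || simultaneous_repro || telemetry
}

#' Merge adjacent candidate units that cannot be told apart
#'
#' Two candidates whose 200 km² representation circles overlap count as two
#' units only when distinguished by genetics (disjoint genotype sets /
#' pedigrees), simultaneous proof of reproduction in each, or telemetry;
#' otherwise they merge into one unit, which is reclassified on the pooled
#' evidence. Applied repeatedly until stable.
#'
#' @param cands list of candidate units (territory + status) as produced
#'   internally by [resolve_units()]; exported for testing fixtures.
#' @return list of candidate units.
#' @export
split_adjacent_packs <- function(cands) {
  cands <- cands[vapply(cands, function(u) u$status != "none", logical(1))]
  repeat {
    merged <- FALSE
    n <- length(cands)
    if (n < 2) break
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        a <- cands[[i]]; b <- cands[[j]]
        dd <- sqrt(sum((a$territory$centroid - b$territory$centroid)^2))
        if (dd < a$territory$radius_km + b$territory$radius_km &&
            !units_distinguished(a, b)) {
          signs <- rbind(a$territory$signs, b$territory$signs)
          t <- make_territory(signs, a$territory$territory_id,
                              a$territory$monitoring_year,
                              area_km2 = a$territory$area_km2)
          cl <- classify_unit(t)
          cands[[i]] <- list(territory = t, status = cl$status, basis = cl$basis)
          cands[[j]] <- NULL
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) break
  }
  cands
}

geno_country_table <- function(signs) {
  g <- as.character(attr_col(signs, "genotype_label", NA_character_))
  keep <- !is.na(g) & !is.na(signs$country)
  unique(data.frame(genotype = g[keep], country = signs$country[keep],
                    stringsAsFactors = FALSE))
}

#' Resolve transboundary status and deduplicate cross-border units
#'
#' Units sharing a genotype label within the monitoring year — e.g. the same
#' pack recorded in two national datasets — are merged and counted once.
#' A unit whose presence is genetically documented on both sides of a border
#' is transboundary (TR); one whose representation circle crosses a border
#' with signs within `border_link_km` on both sides, but without a genetic
#' cross-match, is likely transboundary (LTR); all others are national.
#'
#' @param cands list of candidate units (pack/pair).
#' @param layout a `wolf_layout`.
#' @param border_link_km sign-to-border distance for the LTR rule.
#' @return list of candidate units with `countries` and
#'   `transboundary_status` fields added.
#' @export
resolve_transboundary <- function(cands, layout, border_link_km = 10) {
  stopifnot(inherits(layout, "wolf_layout"))

  # deduplicate: merge units claiming the same genotype in the same year
  repeat {
    merged <- FALSE
    n <- length(cands)
    if (n < 2) break
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        shared <- intersect(cands[[i]]$territory$genotypes,
                            cands[[j]]$territory$genotypes)
        if (length(shared)) {
          signs <- rbind(cands[[i]]$territory$signs, cands[[j]]$territory$signs)
          t <- make_territory(signs, cands[[i]]$territory$territory_id,
                              cands[[i]]$territory$monitoring_year,
                              area_km2 = cands[[i]]$territory$area_km2)
          cl <- classify_unit(t)
          cands[[i]] <- list(territory = t, status = cl$status, basis = cl$basis)
          cands[[j]] <- NULL
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) break
  }

  for (k in seq_along(cands)) {
    t <- cands[[k]]$territory
    s <- t$signs
    s$country <- country_of(s$x, s$y, layout)
    gc <- geno_country_table(s)
    if (nrow(gc)) {
      per_geno <- table(gc$genotype)
      if (any(per_geno > 2))
        stop("integrity error: genotype claimed in more than two countries: ",
             paste(names(per_geno)[per_geno > 2], collapse = ", "))
    }
    sign_countries <- sort(unique(stats::na.omit(s$country)))
    genetic_cross <- if (nrow(gc)) {
      tab <- table(gc$genotype)
      names(tab)[tab >= 2]
    } else character(0)

    if (length(genetic_cross)) {
      cn <- sort(unique(gc$country[gc$genotype %in% genetic_cross]))
      status <- "TR"
    } else {
      # circle-crossing test
      circle_countries <- names(layout$countries)[vapply(
        names(layout$countries), function(cc)
          dist_to_ring(t$centroid[1], t$centroid[2],
                       layout$countries[[cc]]) < t$radius_km, logical(1))]
      ltr <- FALSE
      cn <- sign_countries
      if (length(circle_countries) >= 2 && length(sign_countries) >= 2) {
        for (a in seq_len(length(sign_countries) - 1)) {
          for (b in seq(a + 1, length(sign_countries))) {
            A <- sign_countries[a]; B <- sign_countries[b]
            inA <- s[!is.na(s$country) & s$country == A, , drop = FALSE]
            inB <- s[!is.na(s$country) & s$country == B, , drop = FALSE]
            nearA <- any(dist_to_ring(inA$x, inA$y, layout$countries[[B]]) <=
                           border_link_km)
            nearB <- any(dist_to_ring(inB$x, inB$y, layout$countries[[A]]) <=
                           border_link_km)
            if (nearA && nearB) { ltr <- TRUE; cn <- sort(c(A, B)); break }
          }
          if (ltr) break
        }
      }
      if (ltr) status <- "LTR"
      else {
        status <- "national"
        tb <- table(stats::na.omit(s$country))
        cn <- if (length(tb)) names(tb)[which.max(tb)] else NA_character_
      }
    }
    cands[[k]]$countries <- cn
    cands[[k]]$transboundary_status <- status
  }
  cands
}

cands_to_units <- function(cands) {
  if (!length(cands)) {
    return(data.frame(unit_id = character(0), monitoring_year = character(0),
                      status = character(0), countries = character(0),
                      transboundary_status = character(0),
                      centroid_x = numeric(0), centroid_y = numeric(0),
                      n_signs = integer(0), genotypes = character(0),
                      evidence_basis = character(0), stringsAsFactors = FALSE))
  }
  data.frame(
    unit_id = vapply(cands, function(u) u$territory$territory_id, character(1)),
    monitoring_year = vapply(cands, function(u) u$territory$monitoring_year, character(1)),
    status = vapply(cands, function(u) u$status, character(1)),
    countries = vapply(cands, function(u) paste(u$countries, collapse = "-"), character(1)),
    transboundary_status = vapply(cands, function(u) u$transboundary_status, character(1)),
    centroid_x = vapply(cands, function(u) u$territory$centroid[1], numeric(1)),
    centroid_y = vapply(cands, function(u) u$territory$centroid[2], numeric(1)),
    n_signs = vapply(cands, function(u) nrow(u$territory$signs), integer(1)),
    genotypes = vapply(cands, function(u) paste(u$territory$genotypes, collapse = ";"),
                       character(1)),
    evidence_basis = vapply(cands, function(u) u$basis, character(1)),
    stringsAsFactors = FALSE)
}

#' Resolve reproductive units for one monitoring year
#'
#' Runs the whole unit-resolution chain: cluster C1/C2 signs into candidate
#' territories, classify each as pack / pair / none, merge indistinguishable
#' adjacent candidates, then resolve transboundary status and deduplicate
#' cross-border records.
#'
#' @inheritParams cluster_signs
#' @param layout a `wolf_layout`.
#' @param border_link_km LTR sign-to-border threshold (km).
#' @return list with `units` (data frame of resolved packs/pairs),
#'   `solitary` (data frame of non-unit territories: dispersers and
#'   solitary residents, excluded from totals) and `cands` (unit objects
#'   with territories).
#' @export
resolve_units <- function(classified, year, layout, linkage_km = 15,
                          area_km2 = 200, border_link_km = 10) {
  terr <- cluster_signs(classified, year, linkage_km = linkage_km,
                        area_km2 = area_km2)
  cands <- candidate_units(terr)
  solitary <- cands[vapply(cands, function(u) u$status == "none", logical(1))]
  for (k in seq_along(solitary)) {
    solitary[[k]]$countries <- unique(stats::na.omit(
      country_of(solitary[[k]]$territory$signs$x,
                 solitary[[k]]$territory$signs$y, layout)))
    solitary[[k]]$transboundary_status <- NA_character_
  }
  cands <- split_adjacent_packs(cands)
  cands <- resolve_transboundary(cands, layout, border_link_km = border_link_km)
  list(units = cands_to_units(cands),
       solitary = cands_to_units(solitary),
       cands = cands)
}

#' Expand per-country and transboundary counts into a resolved unit table
#'
#' Convenience constructor for encoding published per-country tallies as
#' resolved units, e.g. to check national + transboundary bookkeeping.
#'
#' @param year monitoring-year label.
#' @param national data frame with columns `country`, `packs`, `pairs`.
#' @param transboundary optional data frame with columns `countries`
#'   (e.g. `"IT-FR"`), `packs`, `pairs`.
#' @return a resolved-unit data frame accepted by [summarize_units()].
#' @export
unit_table <- function(year, national, transboundary = NULL) {
  rows <- list()
  add <- function(n, status, countries, tb) {
    if (n <= 0) return()
    for (i in seq_len(n)) {
      rows[[length(rows) + 1L]] <<- data.frame(
        unit_id = sprintf("%s_U%03d", year, length(rows) + 1L),
        monitoring_year = year, status = status, countries = countries,
        transboundary_status = tb, stringsAsFactors = FALSE)
    }
  }
  for (i in seq_len(nrow(national))) {
    add(national$packs[i], "pack", national$country[i], "national")
    add(national$pairs[i], "pair", national$country[i], "national")
  }
  if (!is.null(transboundary)) {
    for (i in seq_len(nrow(transboundary))) {
      cc <- paste(sort(strsplit(transboundary$countries[i], "-")[[1]]),
                  collapse = "-")
      add(transboundary$packs[i], "pack", cc, "TR")
      add(transboundary$pairs[i], "pair", cc, "TR")
    }
  }
  do.call(rbind, rows)
}

#' Population summary of resolved units
#'
#' Per-country counts of national packs and pairs, transboundary units by
#' country pair (each counted exactly once in the totals), totals and the
#' pair share of reproductive units.
#'
#' @param units resolved-unit data frame (`status`, `countries`,
#'   `transboundary_status`, `monitoring_year`).
#' @return a `population_summary` list.
#' @export
summarize_units <- function(units) {
  units <- as.data.frame(units)
  year <- if (nrow(units)) unique(units$monitoring_year)[1] else NA_character_
  nat <- units[units$transboundary_status %in% "national", , drop = FALSE]
  tb  <- units[units$transboundary_status %in% c("TR", "LTR"), , drop = FALSE]

  count_by <- function(df, key) {
    if (!nrow(df)) return(data.frame(key = character(0), packs = integer(0),
                                     pairs = integer(0)))
    ks <- sort(unique(df[[key]]))
    data.frame(key = ks,
               packs = vapply(ks, function(k)
                 sum(df[[key]] == k & df$status == "pack"), integer(1)),
               pairs = vapply(ks, function(k)
                 sum(df[[key]] == k & df$status == "pair"), integer(1)),
               row.names = NULL, stringsAsFactors = FALSE)
  }
  by_country <- count_by(nat, "countries")
  names(by_country)[1] <- "country"
  by_pair <- count_by(tb, "countries")
  names(by_pair)[1] <- "countries"

  total_packs <- sum(units$status == "pack")
  total_pairs <- sum(units$status == "pair")
  total_units <- total_packs + total_pairs
  structure(list(
    monitoring_year = year,
    by_country = by_country,
    transboundary = by_pair,
    total_packs = total_packs,
    total_pairs = total_pairs,
    total_units = total_units,
    pair_fraction = if (total_units > 0) total_pairs / total_units else 0,
    pair_fraction_pct = if (total_units > 0)
      round(100 * total_pairs / total_units, 1) else 0
  ), class = "population_summary")
}

#' @export
print.population_summary <- function(x, ...) {
  cat(sprintf("Monitoring year %s: %d packs, %d pairs (%d units, pairs %.1f%%)\n",
              x$monitoring_year, x$total_packs, x$total_pairs, x$total_units,
              x$pair_fraction_pct))
  if (nrow(x$by_country)) {
    cat("National units:\n"); print(x$by_country, row.names = FALSE)
  }
  if (nrow(x$transboundary)) {
    cat("Transboundary units (counted once):\n")
    print(x$transboundary, row.names = FALSE)
  }
  invisible(x)
}

#' Write resolved territories (MCP and representation circle) as GeoJSON
#'
#' @param cands candidate-unit list from [resolve_units()].
#' @param path output file.
#' @export
write_territories_geojson <- function(cands, path) {
  circle_ring <- function(center, r, n = 64) {
    th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
    cbind(center[1] + r * cos(th), center[2] + r * sin(th))
  }
  features <- list()
  for (u in cands) {
    t <- u$territory
    props <- list(unit_id = t$territory_id, monitoring_year = t$monitoring_year,
                  status = u$status,
                  transboundary_status = if (!is.null(u$transboundary_status))
                    u$transboundary_status else NA)
    if (nrow(t$mcp) >= 3)
      features[[length(features) + 1L]] <- list(
        type = "Feature", properties = c(props, list(role = "mcp")),
        geometry = list(type = "Polygon",
                        coordinates = list(ring_to_coords(t$mcp))))
    features[[length(features) + 1L]] <- list(
      type = "Feature", properties = c(props, list(role = "representation_circle")),
      geometry = list(type = "Polygon",
                      coordinates = list(ring_to_coords(
                        circle_ring(t$centroid, t$radius_km)))))
  }
  fc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
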