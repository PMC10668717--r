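#' Monitoring year of a date
#'
#' The biological wolf year runs from reproduction to the next reproduction:
#' 1 May of year Y through 30 April of year Y+1, labelled `"Y-Y+1"`.
#'
#' @param date a `Date` (or anything `as.Date()` accepts).
#' @return character vector of monitoring-year labels.
#' @examples
#' assign_monitoring_year(as.Date(c("2020-04-30", "2020-05-01")))
#' @export
assign_monitoring_year <- function(date) {
  date <- as.Date(date)
  y <- as.integer(format(date, "%Y"))
  m <- as.integer(format(date, "%m"))
  start <- ifelse(m >= 5L, y, y - 1L)
  ifelse(is.na(start), NA_character_, sprintf("%d-%d", start, start + 1L))
}

#' First calendar year of a monitoring-year label
#' @param label labels like `"1993-1994"`.
#' @return integer vector.
#' @export
monitoring_year_start <- function(label) {
  as.integer(sub("-.*$", "", label))
}

EVIDENCE_TYPES <- c("live_capture", "dead_animal", "dna_sample", "photo_video",
                    "telemetry", "track", "scat", "kill", "howl", "sighting")

# column accessor with default for absent attribute columns
attr_col <- function(df, name, default) {
  if (!name %in% names(df)) return(rep(default, nrow(df)))
  v <- df[[name]]
  if (is.logical(default)) {
    v <- as.logical(v)
    v[is.na(v)] <- default
  }
  v
}

#' Genuineness screening of sign records
#'
#' A record is kept only when it carries the minimum technical documentation
#' and intentional deception can be ruled out. Discarded records take no part
#' in classification, occurrence or unit resolution.
#'
#' @param signs data frame of sign records (see [classify_signs()] for the
#'   schema). Missing attribute columns default to documented / not suspect.
#' @return logical vector: `TRUE` = keep.
#' @export
screen_genuineness <- function(signs) {
  attr_col(signs, "technically_documented", TRUE) &
    !attr_col(signs, "suspected_deception", FALSE)
}

#' Classify sign records into validation categories C1/C2/C3
#'
#' Per-record decision table:
#' * **C1** (hard evidence): live captures or rescues, dead animals,
#'   telemetry locations, any sample whose wolf origin is confirmed by DNA,
#'   good-quality photo or video.
#' * **C2** (confirmed): documented tracks with a typical pattern followed
#'   for at least 100 m (inclusive threshold); scats checked by an expert;
#'   kills with typical bites combined with other C2 data; howls with pups
#'   heard, checked by an expert.
#' * **C3** (unconfirmed): everything else — short or single tracks,
#'   unchecked scats, heavily eaten or undocumented kills, single howls,
#'   unsupported sightings, bad-quality images, inconclusive DNA samples.
#'
#' Cross-record rules (a scat lying on a C2 track, a kill combined with
#' nearby C2 data, the C1 upgrade of a track certified by DNA collected on
#' it) live in [classify_signs()].
#'
#' @param signs data frame of kept sign records.
#' @return character vector `"C1"`, `"C2"` or `"C3"`.
#' @export
classify_sign <- function(signs) {
  type <- as.character(signs$evidence_type)
  bad <- setdiff(unique(type), EVIDENCE_TYPES)
  if (length(bad)) stop("unknown evidence_type: ", paste(bad, collapse = ", "))

  dna_ok  <- attr_col(signs, "dna_confirmed_wolf", FALSE)
  quality <- as.character(attr_col(signs, "photo_quality", NA_character_))
  typical <- attr_col(signs, "typical_pattern", FALSE)
  len     <- suppressWarnings(as.numeric(attr_col(signs, "track_length_m", NA_real_)))
  expert  <- attr_col(signs, "expert_checked", FALSE)
  bites   <- attr_col(signs, "typical_bites", FALSE)
  comb    <- attr_col(signs, "combined_with_C2", FALSE)
  pups    <- attr_col(signs, "pups_heard", FALSE)

  out <- rep("C3", nrow(signs))
  out[type %in% c("live_capture", "dead_animal", "telemetry")] <- "C1"
  out[dna_ok] <- "C1"  # whatever DNA evidence confirms the biological sample
  out[type == "photo_video" & !dna_ok] <-
    ifelse(!is.na(quality[type == "photo_video" & !dna_ok]) &
             quality[type == "photo_video" & !dna_ok] == "good", "C1", "C3")
  i <- type == "track" & !dna_ok
  out[i] <- ifelse(typical[i] & !is.na(len[i]) & len[i] >= 100, "C2", "C3")
  i <- type == "scat" & !dna_ok
  out[i] <- ifelse(expert[i], "C2", "C3")
  i <- type == "kill" & !dna_ok
  out[i] <- ifelse(bites[i] & comb[i], "C2", "C3")
  i <- type == "howl" & !dna_ok
  out[i] <- ifelse(pups[i] & expert[i], "C2", "C3")
  out
}

#' Full classification of a sign table
#'
#' Screens genuineness, stamps the monitoring year, applies the per-record
#' decision table, then three cross-record passes:
#' 1. a scat sharing `track_id` with a C2 track becomes C2 (scat found on a
#'    track classified as C2);
#' 2. a kill with typical bites and no explicit `combined_with_C2` flag is
#'    combined with other C2 data when another (non-kill) C2 sign lies
#'    within `kill_link_km` and `kill_link_days`;
#' 3. a track sharing `track_id` with a DNA-confirmed sample is upgraded to
#'    C1 (presence indirectly certified by the DNA evidence collected on it).
#'
#' @param signs data frame with columns `sign_id`, `date`, `x`, `y`,
#'   `country`, `evidence_type` and any of the attribute columns
#'   (`track_length_m`, `typical_pattern`, `expert_checked`,
#'   `dna_confirmed_wolf`, `genotype_label`, `photo_quality`, `pups_heard`,
#'   `typical_bites`, `combined_with_C2`, `technically_documented`,
#'   `suspected_deception`, `track_id`, ...). Coordinates in km.
#' @param kill_link_km,kill_link_days linkage rule for "combined with other
#'   C2 data" (defaults 10 km, 14 days).
#' @return the input with `category` (`"C1"/"C2"/"C3"/"discarded"`) and
#'   `monitoring_year` columns appended.
#' @export
classify_signs <- function(signs, kill_link_km = 10, kill_link_days = 14) {
  signs <- as.data.frame(signs)
  if (nrow(signs) == 0) {
    signs$category <- character(0)
    signs$monitoring_year <- character(0)
    return(signs)
  }
  keep <- screen_genuineness(signs)
  cat <- rep("discarded", nrow(signs))
  cat[keep] <- classify_sign(signs[keep, , drop = FALSE])

  track_id <- as.character(attr_col(signs, "track_id", NA_character_))
  type <- as.character(signs$evidence_type)

  # scat on a C2 track
  c2_tracks <- unique(track_id[keep & type == "track" & cat == "C2" & !is.na(track_id)])
  up <- keep & type == "scat" & cat == "C3" & track_id %in% c2_tracks
  cat[up] <- "C2"

  # kill combined with other C2 data (computed only when flag not supplied)
  if (!"combined_with_C2" %in% names(signs) ||
      any(is.na(signs$combined_with_C2))) {
    flag_na <- if ("combined_with_C2" %in% names(signs))
      is.na(signs$combined_with_C2) else rep(TRUE, nrow(signs))
    bites <- attr_col(signs, "typical_bites", FALSE)
    kills <- which(keep & type == "kill" & flag_na & bites)
    if (length(kills)) {
      others <- which(keep & cat == "C2" & type != "kill")
      d <- as.Date(signs$date)
      for (k in kills) {
        near <- abs(as.numeric(d[others] - d[k])) <= kill_link_days &
          sqrt((signs$x[others] - signs$x[k])^2 +
               (signs$y[others] - signs$y[k])^2) <= kill_link_km
        if (any(near, na.rm = TRUE)) cat[k] <- "C2"
      }
    }
  }

  # track indirectly certified by DNA collected on it
  dna_tracks <- unique(track_id[keep & attr_col(signs, "dna_confirmed_wolf", FALSE) &
                                  !is.na(track_id)])
  up <- keep & type == "track" & cat %in% c("C2", "C3") & track_id %in% dna_tracks
  cat[up] <- "C1"

  signs$category <- cat
  signs$monitoring_year <- assign_monitoring_year(signs$date)
  signs
}
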