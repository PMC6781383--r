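# Readers and writers for the exchange formats: GPS as CSV / GPX 1.1,
# accelerometer as CSV, timetables as CSV, diaries/networks/segments as
# GeoJSON, accuracy summaries as JSON/CSV.

# study origin for ISO-8601 export of internal second offsets
TW_ORIGIN <- "2014-01-06 00:00:00"

tw_time <- function(sec) {
  as.POSIXct(sec, origin = TW_ORIGIN, tz = "UTC")
}

iso8601 <- function(sec) {
  format(tw_time(sec), "%Y-%m-%dT%H:%M:%SZ")
}

#' Write / read GPS points as CSV
#'
#' Columns `timestamp` (ISO-8601 UTC), `lat`, `lon`.
#'
#' @param points data frame with `time`, `lon`, `lat`.
#' @param path file path.
#' @export
write_gps_csv <- function(points, path) {
  write.csv(data.frame(timestamp = iso8601(points$time),
                       lat = points$lat, lon = points$lon),
            path, row.names = FALSE, quote = FALSE)
}

#' @rdname write_gps_csv
#' @param participant_id id to attach to the read points.
#' @export
read_gps_csv <- function(path, participant_id = NA_character_) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  data.frame(participant_id = participant_id,
             time = as.numeric(as.POSIXct(d$timestamp, tz = "UTC",
                                          format = "%Y-%m-%dT%H:%M:%SZ")) -
               as.numeric(as.POSIXct(TW_ORIGIN, tz = "UTC")),
             lon = d$lon, lat = d$lat)
}

#' Write GPS points as GPX 1.1
#'
#' One track with a single segment.
#'
#' @param points data frame with `time`, `lon`, `lat`.
#' @param path file path.
#' @export
write_gpx <- function(points, path) {
  doc <- xml2::xml_new_root("gpx", version = "1.1", creator = "tripwalk",
                            xmlns = "http://www.topografix.com/GPX/1/1")
  trk <- xml2::xml_add_child(doc, "trk")
  seg <- xml2::xml_add_child(trk, "trkseg")
  for (i in seq_len(nrow(points))) {
    pt <- xml2::xml_add_child(seg, "trkpt",
                              lat = sprintf("%.7f", points$lat[i]),
                              lon = sprintf("%.7f", points$lon[i]))
    xml2::xml_add_child(pt, "time", iso8601(points$time[i]))
  }
  xml2::write_xml(doc, path)
}

#' @rdname write_gpx
#' @param participant_id id to attach to the read points.
#' @export
read_gpx <- function(path, participant_id = NA_character_) {
  doc <- xml2::read_xml(path)
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "g")
  pts <- xml2::xml_find_all(doc, ".//g:trkpt", ns)
  tms <- xml2::xml_text(xml2::xml_find_all(doc, ".//g:trkpt/g:time", ns))
  data.frame(
    participant_id = participant_id,
    time = as.numeric(as.POSIXct(tms, tz = "UTC",
                                 format = "%Y-%m-%dT%H:%M:%SZ")) -
      as.numeric(as.POSIXct(TW_ORIGIN, tz = "UTC")),
    lon = as.numeric(xml2::xml_attr(pts, "lon")),
    lat = as.numeric(xml2::xml_attr(pts, "lat")))
}

#' Write / read accelerometer epochs as CSV
#'
#' Columns `timestamp` (epoch start, ISO-8601), `vm`, `steps`.
#'
#' @param epochs epoch data frame.
#' @param path file path.
#' @export
write_accel_csv <- function(epochs, path) {
  write.csv(data.frame(timestamp = iso8601(epochs$start),
                       vm = epochs$vm, steps = epochs$steps),
            path, row.names = FALSE, quote = FALSE)
}

#' @rdname write_accel_csv
#' @param epoch_s epoch length (s).
#' @param participant_id id to attach.
#' @export
read_accel_csv <- function(path, epoch_s = 60,
                           participant_id = NA_character_) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  start <- as.numeric(as.POSIXct(d$timestamp, tz = "UTC",
                                 format = "%Y-%m-%dT%H:%M:%SZ")) -
    as.numeric(as.POSIXct(TW_ORIGIN, tz = "UTC"))
  data.frame(participant_id = participant_id, day = floor(start / 86400) + 1,
             start = start, end = start + epoch_s,
             vm = d$vm, steps = d$steps)
}

#' Write a timetable as the central exchange CSV
#'
#' Columns: participant, day, kind, trip_id, mode, start, end (ISO-8601),
#' length_m, steps, source.
#'
#' @param timetable a [reconcile()] timetable.
#' @param path file path.
#' @export
write_timetable_csv <- function(timetable, path) {
  write.csv(data.frame(
    participant = timetable$participant_id, day = timetable$day,
    kind = timetable$kind, trip_id = timetable$trip_id,
    mode = timetable$mode, start = iso8601(timetable$start),
    end = iso8601(timetable$end), length_m = round(timetable$length_m, 1),
    steps = if ("steps" %in% names(timetable)) timetable$steps else NA,
    source = timetable$source), path, row.names = FALSE)
}

#' Serialize segments as a GeoJSON FeatureCollection
#'
#' Visits and transfers become Points, stages LineStrings; properties
#' carry `kind`, `mode`, `start`, `end`.
#'
#' @param segments diary or timetable rows with a `geometry` list-column.
#' @param path file path.
#' @export
write_segments_geojson <- function(segments, path) {
  feats <- lapply(seq_len(nrow(segments)), function(i) {
    g <- segments$geometry[[i]][, 1:2, drop = FALSE]
    geom <- if (nrow(g) > 1) {
      list(type = "LineString", coordinates = unname(apply(g, 1, c,
                                                           simplify = FALSE)))
    } else {
      list(type = "Point", coordinates = c(g[1, 1], g[1, 2]))
    }
    list(type = "Feature", geometry = geom,
         properties = list(kind = segments$kind[i],
                           mode = segments$mode[i],
                           start = iso8601(segments$start[i]),
                           end = iso8601(segments$end[i])))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = 7, null = "null",
                       na = "null")
}

#' Serialize a transit network as GeoJSON
#'
#' One Point feature per station with `line_id` and `mode` properties.
#'
#' @param network a [transit_network()].
#' @param path file path.
#' @export
write_network_geojson <- function(network, path) {
  feats <- lapply(seq_len(nrow(network)), function(i) {
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = c(network$lon[i], network$lat[i])),
         properties = list(kind = "station", line_id = network$line_id[i],
                           mode = network$mode[i]))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = 7)
}

#' Serialize a mode-accuracy report
#'
#' JSON (full report) or flat CSV (mode, truth_s, correct_s, fraction).
#'
#' @param report a [mode_accuracy_report()] result.
#' @param path file path; `.json` or `.csv` by extension.
#' @export
write_mode_accuracy <- function(report, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                         digits = 10, dataframe = "rows")
  } else {
    write.csv(data.frame(mode = report$per_mode$mode,
                         truth_s = report$per_mode$truth_s,
                         correct_s = report$per_mode$agree_s,
                         fraction = report$per_mode$fraction),
              path, row.names = FALSE)
  }
}
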