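#' Read traced bundle contours from CSV
#'
#' Expected columns: `bundle_id`, `frame`, `point_index`, `x_um`, `y_um`
#' (header required; points are ordered by `point_index` within each
#' bundle/frame). An optional `time_s` column carries acquisition times;
#' otherwise time defaults to the frame index (1 Hz).
#'
#' @param path CSV file path.
#' @return A list of [planar_contour()], one per (bundle, frame).
#' @export
read_contours_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("bundle_id", "frame", "point_index", "x_um", "y_um")
  if (!all(need %in% names(df))) {
    stop(
      "contour CSV needs columns: ", paste(need, collapse = ", "),
      call. = FALSE
    )
  }
  groups <- split(df, list(df$bundle_id, df$frame), drop = TRUE)
  out <- lapply(groups, function(g) {
    g <- g[order(g$point_index), ]
    planar_contour(g$x_um, g$y_um,
      bundle_id = g$bundle_id[1],
      frame = g$frame[1],
      time = if ("time_s" %in% names(g)) g$time_s[1] else NULL
    )
  })
  ord <- order(
    vapply(out, function(pc) as.character(pc$bundle_id), ""),
    vapply(out, function(pc) pc$frame, integer(1))
  )
  unname(out[ord])
}

#' Write contours to the CSV dialect read by [read_contours_csv()]
#'
#' @param contours a list of [planar_contour()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_contours_csv <- function(contours, path) {
  if (inherits(contours, "planar_contour")) contours <- list(contours)
  rows <- lapply(contours, function(pc) {
    data.frame(
      bundle_id = pc$bundle_id,
      frame = pc$frame,
      point_index = seq_len(nrow(pc$points)),
      x_um = pc$points[, 1],
      y_um = pc$points[, 2],
      time_s = pc$time
    )
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read snake-style traced filaments
#'
#' Best-effort reader for the plain-text output of common filament tracers:
#' one filament per file, one frame per block of `x y` lines (whitespace
#' separated), frames separated by one or more blank lines. Lines starting
#' with `#` or `%` are skipped. Coordinates are multiplied by `scale` (use
#' the pixel size to convert pixel traces to um).
#'
#' @param path text file path.
#' @param bundle_id identifier for the filament (defaults to the file name).
#' @param scale coordinate scale factor (um per input unit, default 1).
#' @return A list of [planar_contour()], one per frame.
#' @export
read_snake_txt <- function(path, bundle_id = NULL, scale = 1) {
  if (is.null(bundle_id)) bundle_id <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*[#%]", lines)]
  blank <- grepl("^\\s*$", lines)
  grp <- cumsum(blank)
  blocks <- unname(split(lines[!blank], grp[!blank]))
  out <- lapply(seq_along(blocks), function(i) {
    xy <- do.call(rbind, lapply(strsplit(trimws(blocks[[i]]), "\\s+"), function(f) {
      as.numeric(f[1:2])
    }))
    if (any(!is.finite(xy))) {
      stop("malformed snake block ", i, " in ", path, call. = FALSE)
    }
    planar_contour(xy[, 1] * scale, xy[, 2] * scale,
      bundle_id = bundle_id, frame = i
    )
  })
  out
}

#' Read motor tracks from CSV
#'
#' Expected columns: `track_id`, `frame`, `t_s`, `x_um`, `y_um`; samples
#' are ordered by time within each track.
#'
#' @param path CSV file path.
#' @return A list of [motor_track()].
#' @export
read_tracks_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("track_id", "t_s", "x_um", "y_um")
  if (!all(need %in% names(df))) {
    stop("track CSV needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  lapply(split(df, df$track_id), function(g) {
    g <- g[order(g$t_s), ]
    motor_track(g$t_s, g$x_um, g$y_um, track_id = g$track_id[1])
  })
}

#' Write motor tracks to the CSV dialect read by [read_tracks_csv()]
#'
#' @param tracks a list of [motor_track()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tracks_csv <- function(tracks, path) {
  if (inherits(tracks, "motor_track")) tracks <- list(tracks)
  rows <- lapply(tracks, function(tr) {
    data.frame(
      track_id = tr$track_id,
      frame = seq_len(nrow(tr$samples)),
      t_s = tr$samples$t,
      x_um = tr$samples$x,
      y_um = tr$samples$y
    )
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read motor tracks from a TrackMate-style XML file
#'
#' Minimal reader for the spot-tracker XML dialect: spots are taken from
#' `Model/AllSpots/SpotsInFrame/Spot` (attributes `ID`, `POSITION_X`,
#' `POSITION_Y`, and `POSITION_T` or `FRAME`), track membership from the
#' edges `Model/AllTracks/Track/Edge` (attributes `SPOT_SOURCE_ID`,
#' `SPOT_TARGET_ID`). The linking itself is the upstream tracker's job and
#' is not recomputed. Positions are multiplied by `pixel_size`; times by
#' `frame_interval` when only frame indices are present.
#'
#' @param path XML file path.
#' @param pixel_size um per pixel applied to positions (default 1).
#' @param frame_interval seconds per frame, used when `POSITION_T` is
#'   absent (default 1).
#' @return A list of [motor_track()], one per `Track` element.
#' @export
read_trackmate_xml <- function(path, pixel_size = 1, frame_interval = 1) {
  doc <- xml2::read_xml(path)
  spots <- xml2::xml_find_all(doc, ".//Model/AllSpots/SpotsInFrame/Spot")
  if (length(spots) == 0) stop("no spots found in ", path, call. = FALSE)
  id <- xml2::xml_attr(spots, "ID")
  x <- as.numeric(xml2::xml_attr(spots, "POSITION_X")) * pixel_size
  y <- as.numeric(xml2::xml_attr(spots, "POSITION_Y")) * pixel_size
  t <- as.numeric(xml2::xml_attr(spots, "POSITION_T"))
  if (all(is.na(t))) {
    t <- as.numeric(xml2::xml_attr(spots, "FRAME")) * frame_interval
  }
  spot_tab <- data.frame(id = id, x = x, y = y, t = t, stringsAsFactors = FALSE)
  tracks <- xml2::xml_find_all(doc, ".//Model/AllTracks/Track")
  out <- lapply(tracks, function(tr) {
    tid <- xml2::xml_attr(tr, "TRACK_ID")
    if (is.na(tid)) tid <- xml2::xml_attr(tr, "name")
    edges <- xml2::xml_find_all(tr, "./Edge")
    ids <- unique(c(
      xml2::xml_attr(edges, "SPOT_SOURCE_ID"),
      xml2::xml_attr(edges, "SPOT_TARGET_ID")
    ))
    g <- spot_tab[spot_tab$id %in% ids, ]
    g <- g[order(g$t), ]
    if (nrow(g) < 2) return(NULL)
    motor_track(g$t, g$x, g$y, track_id = paste0("track", tid))
  })
  Filter(Negate(is.null), out)
}
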