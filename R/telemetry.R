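#' Fixed-width telemetry frames
#'
#' The low-energy radio link carries at most 20 bytes per frame, so each
#' sample's result is packed as four fixed-decimal text fields of exactly 5
#' bytes each — `"xx.xx"` — concatenated in the order x, y, z, speed.  The
#' format carries two decimal places and no sign: representable values are
#' 00.00 to 99.99.
#'
#' Positions can legitimately be negative, which the 5-character field
#' cannot express.  Two explicit behaviours are provided: `mode = "offset"`
#' (default) shifts each field by a per-capture constant reported alongside
#' the stream (a documented side channel, see [encode_track()]), while
#' `mode = "strict"` rejects any value outside 00.00-99.99.
#'
#' @name telemetry
NULL

# round half away from zero at 2 decimals, for cross-platform determinism
.quantize2 <- function(x) sign(x) * floor(abs(x) * 100 + 0.5) / 100

.format_field <- function(value, field) {
  q <- .quantize2(value)
  bad <- q < 0 | q > 99.99 | !is.finite(q)
  if (any(bad)) {
    stop("field '", field, "' value ", value[which(bad)[1]],
         " is not representable in the 00.00-99.99 frame format")
  }
  sprintf("%05.2f", q)
}

#' Encode one telemetry frame
#'
#' @param x,y,z position coordinates, m.
#' @param speed speed, m/s.
#' @return A 20-character (20-byte ASCII) frame string.
#' @examples
#' encode_frame(1.2, 3.4, 5.6, 7.8)
#' @export
encode_frame <- function(x, y, z, speed) {
  paste0(.format_field(x, "x"), .format_field(y, "y"),
         .format_field(z, "z"), .format_field(speed, "speed"))
}

#' Decode one telemetry frame
#'
#' @param payload a 20-byte frame (character scalar or raw vector).
#' @return Named numeric vector `c(x, y, z, speed)` at the format's
#'   two-decimal precision.
#' @export
decode_frame <- function(payload) {
  if (is.raw(payload)) payload <- rawToChar(payload)
  stopifnot(is.character(payload), length(payload) == 1)
  if (nchar(payload) != 20) {
    stop("frame must be exactly 20 bytes; got ", nchar(payload))
  }
  fields <- substring(payload, seq(1, 16, by = 5), seq(5, 20, by = 5))
  ok <- grepl("^[0-9]{2}\\.[0-9]{2}$", fields)
  if (!all(ok)) {
    off <- (which(!ok)[1] - 1) * 5
    stop("unparseable field '", fields[which(!ok)[1]],
         "' at byte offset ", off)
  }
  stats::setNames(as.numeric(fields), c("x", "y", "z", "speed"))
}

#' Encode a kinematic track as a telemetry stream
#'
#' One 20-byte frame per sample, in sample order — the frame count equals
#' the sample count.  In `"offset"` mode each of x, y, z is shifted by a
#' per-capture constant (the most negative value, rounded down to 2
#' decimals, when negative values occur) so that the unsigned field format
#' can carry it; the offsets are returned with the stream and subtracted
#' back on decode.
#'
#' @param track a `kinematic_track` (or any data frame with columns `x`,
#'   `y`, `z`, `speed`).
#' @param mode `"offset"` (default) or `"strict"`.
#' @return A list of class `telemetry_stream`: `frames` (character vector
#'   of 20-byte frames), `offsets` (named numeric, the per-field shifts),
#'   `n` (frame count).
#' @export
encode_track <- function(track, mode = c("offset", "strict")) {
  mode <- match.arg(mode)
  stopifnot(all(c("x", "y", "z", "speed") %in% names(track)))
  n <- nrow(track)
  offsets <- c(x = 0, y = 0, z = 0, speed = 0)
  if (n == 0) {
    return(structure(list(frames = character(0), offsets = offsets, n = 0L),
                     class = "telemetry_stream"))
  }
  vals <- list(x = track$x, y = track$y, z = track$z, speed = track$speed)
  if (mode == "offset") {
    for (f in c("x", "y", "z", "speed")) {
      mn <- min(vals[[f]])
      if (mn < 0) {
        offsets[[f]] <- floor(mn * 100) / 100
        vals[[f]] <- vals[[f]] - offsets[[f]]
      }
    }
  }
  frames <- tryCatch(
    paste0(.format_field(vals$x, "x"), .format_field(vals$y, "y"),
           .format_field(vals$z, "z"), .format_field(vals$speed, "speed")),
    error = function(e) stop("encoding failed: ", conditionMessage(e),
                             call. = FALSE))
  structure(list(frames = frames, offsets = offsets, n = as.integer(n)),
            class = "telemetry_stream")
}

#' Decode a telemetry stream back to track fields
#'
#' @param stream a `telemetry_stream`, a character vector of 20-byte
#'   frames, or a single concatenated payload string.
#' @param offsets per-field shifts to restore (taken from the stream object
#'   when given one).
#' @return A tibble with columns `x`, `y`, `z`, `speed`, one row per frame.
#' @export
decode_stream <- function(stream, offsets = c(x = 0, y = 0, z = 0, speed = 0)) {
  if (inherits(stream, "telemetry_stream")) {
    offsets <- stream$offsets
    frames <- stream$frames
  } else if (is.character(stream) && length(stream) == 1 && nchar(stream) > 20) {
    if (nchar(stream) %% 20 != 0) {
      stop("stream length ", nchar(stream), " is not a multiple of 20; ",
           "frame ", nchar(stream) %/% 20 + 1, " is truncated")
    }
    frames <- substring(stream, seq(1, nchar(stream), 20),
                        seq(20, nchar(stream), 20))
  } else {
    frames <- stream
  }
  if (length(frames) == 0) {
    return(tibble::tibble(x = numeric(0), y = numeric(0), z = numeric(0),
                          speed = numeric(0)))
  }
  bad_len <- nchar(frames) != 20
  if (any(bad_len)) {
    stop("frame ", which(bad_len)[1], " has ", nchar(frames[which(bad_len)[1]]),
         " bytes; frames must be exactly 20 bytes")
  }
  m <- matrix(NA_real_, length(frames), 4)
  for (j in 1:4) {
    fields <- substring(frames, (j - 1) * 5 + 1, j * 5)
    ok <- grepl("^[0-9]{2}\\.[0-9]{2}$", fields)
    if (!all(ok)) {
      i <- which(!ok)[1]
      stop("frame ", i, ": unparseable field '", fields[i],
           "' at byte offset ", (j - 1) * 5)
    }
    m[, j] <- as.numeric(fields)
  }
  tibble::tibble(x = m[, 1] + offsets[["x"]], y = m[, 2] + offsets[["y"]],
                 z = m[, 3] + offsets[["z"]],
                 speed = m[, 4] + offsets[["speed"]])
}

#' Write / read a telemetry stream file
#'
#' The stream file is the raw concatenation of the 20-byte ASCII frames
#' (`n * 20` bytes, no separators).  Nonzero offsets are written to a JSON
#' sidecar `<path>.offsets.json` and picked up automatically on read.
#'
#' @param stream a `telemetry_stream` from [encode_track()].
#' @param path output file path.
#' @return `write_stream()` returns `path` invisibly; `read_stream()`
#'   returns the decoded tibble of [decode_stream()].
#' @export
write_stream <- function(stream, path) {
  stopifnot(inherits(stream, "telemetry_stream"))
  con <- file(path, "wb")
  on.exit(close(con))
  if (stream$n > 0) {
    writeBin(charToRaw(paste0(stream$frames, collapse = "")), con)
  }
  if (any(stream$offsets != 0)) {
    jsonlite::write_json(as.list(stream$offsets),
                         paste0(path, ".offsets.json"), auto_unbox = TRUE)
  }
  invisible(path)
}

#' @rdname write_stream
#' @export
read_stream <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  txt <- rawToChar(raw)
  offsets <- c(x = 0, y = 0, z = 0, speed = 0)
  sidecar <- paste0(path, ".offsets.json")
  if (file.exists(sidecar)) {
    o <- jsonlite::read_json(sidecar)
    offsets[names(o)] <- unlist(o)
  }
  if (nchar(txt) == 0) return(decode_stream(character(0), offsets))
  if (nchar(txt) %% 20 != 0) {
    stop("stream length ", nchar(txt), " is not a multiple of 20; frame ",
         nchar(txt) %/% 20 + 1, " is truncated")
  }
  frames <- substring(txt, seq(1, nchar(txt), 20), seq(20, nchar(txt), 20))
  decode_stream(frames, offsets)
}
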