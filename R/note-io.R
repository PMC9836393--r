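#' Note-event tables
#'
#' A note sequence is a tibble with one row per note and columns
#' `composition_id`, `pitch` (integer MIDI pitch, 0--127, middle C = 60),
#' `onset` (seconds from composition start) and `duration` (seconds).
#' Sequences are monophonic: onsets are strictly increasing within a
#' composition. A corpus is simply a note table covering several
#' `composition_id`s.
#'
#' @param pitch integer vector of MIDI pitches (0--127).
#' @param onset numeric vector of onsets in seconds, strictly increasing.
#' @param duration numeric vector of positive note durations in seconds.
#' @param composition_id identifier for the composition.
#' @return A tibble of class `note_seq` with columns
#'   `composition_id`, `pitch`, `onset`, `duration`.
#' @examples
#' note_sequence(c(60, 62, 64), onset = c(0, 0.5, 1), duration = 0.4)
#' @export
note_sequence <- function(pitch, onset, duration, composition_id = "comp1") {
  notes <- tibble::tibble(
    composition_id = as.character(composition_id),
    pitch = as.integer(pitch),
    onset = as.double(onset),
    duration = rep_len(as.double(duration), length(pitch))
  )
  validate_notes(notes)
}

#' Validate a note table
#'
#' Checks the note-event invariants: pitch in 0--127, onsets non-negative and
#' strictly increasing within each composition, durations positive.
#' Violations raise an error; values are never silently clamped.
#'
#' @param notes a note table as returned by [note_sequence()].
#' @return `notes`, invisibly classed as `note_seq`.
#' @export
validate_notes <- function(notes) {
  req <- c("composition_id", "pitch", "onset", "duration")
  missing_cols <- setdiff(req, names(notes))
  if (length(missing_cols) > 0) {
    abort(paste0("note table is missing columns: ", paste(missing_cols, collapse = ", ")))
  }
  if (nrow(notes) == 0) abort("note table is empty")
  if (any(is.na(notes$pitch)) || any(notes$pitch < 0L | notes$pitch > 127L)) {
    abort("pitch values must be integers in [0, 127]")
  }
  if (any(notes$onset < 0)) abort("onsets must be non-negative")
  if (any(notes$duration <= 0)) abort("durations must be positive")
  bad <- notes |>
    dplyr::group_by(.data$composition_id) |>
    dplyr::summarise(ok = all(diff(.data$onset) > 0) || dplyr::n() == 1L) |>
    dplyr::filter(!.data$ok)
  if (nrow(bad) > 0) {
    abort(paste0("onsets must be strictly increasing (monophony) in: ",
                 paste(bad$composition_id, collapse = ", ")))
  }
  class(notes) <- unique(c("note_seq", class(notes)))
  notes
}

#' Read and write delimited note tables
#'
#' Comma-separated text with a header containing at least
#' `pitch,onset,duration` (and optionally `composition_id`). Reading
#' re-validates all note-event invariants.
#'
#' @param path file path.
#' @param composition_id id assigned when the file has no
#'   `composition_id` column; default is the file name.
#' @return [read_notes_table()] returns a validated note table;
#'   [write_notes_table()] returns `path` invisibly.
#' @export
read_notes_table <- function(path, composition_id = NULL) {
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  req <- c("pitch", "onset", "duration")
  if (!all(req %in% names(tab))) {
    abort(paste0("note table must have columns pitch,onset,duration; got: ",
                 paste(names(tab), collapse = ",")))
  }
  if (!"composition_id" %in% names(tab)) {
    tab$composition_id <- composition_id %||% basename(path)
  }
  tab <- tab |>
    dplyr::mutate(pitch = as.integer(.data$pitch)) |>
    dplyr::select("composition_id", "pitch", "onset", "duration")
  validate_notes(tibble::as_tibble(tab))
}

#' @param notes a validated note table.
#' @rdname read_notes_table
#' @export
write_notes_table <- function(notes, path) {
  notes <- validate_notes(notes)
  readr::write_csv(notes[, c("composition_id", "pitch", "onset", "duration")], path,
                   progress = FALSE)
  invisible(path)
}

# ---- standard MIDI file I/O -------------------------------------------------
# Minimal format-0/1 SMF support; ticks are converted to seconds using the
# file's tempo map. Only note-on/note-off events are interpreted.

vlq_decode <- function(bytes, pos) {
  val <- 0
  repeat {
    b <- bytes[pos]; pos <- pos + 1L
    val <- val * 128 + (b %% 128L)
    if (b < 128L) break
  }
  list(value = val, pos = pos)
}

vlq_encode <- function(value) {
  out <- as.raw(value %% 128L)
  value <- value %/% 128L
  while (value > 0) {
    out <- c(as.raw(128L + value %% 128L), out)
    value <- value %/% 128L
  }
  out
}

u32 <- function(bytes, pos) sum(as.double(bytes[pos:(pos + 3L)]) * 256^(3:0))
u16 <- function(bytes, pos) sum(as.double(bytes[pos:(pos + 1L)]) * 256^(1:0))

# Parse one track chunk into a table of (tick, type, channel, pitch, velocity)
# plus tempo meta events (type = "tempo", velocity = microseconds/quarter).
parse_track <- function(bytes) {
  pos <- 1L
  n <- length(bytes)
  tick <- 0
  status <- NULL
  ev <- list()
  while (pos <= n) {
    d <- vlq_decode(bytes, pos); pos <- d$pos
    tick <- tick + d$value
    b <- bytes[pos]
    if (b >= 128L) { status <- b; pos <- pos + 1L }
    if (is.null(status)) abort("malformed MIDI track: running status without status byte")
    hi <- status %/% 16L
    if (status == 255L) { # meta event
      type <- bytes[pos]; pos <- pos + 1L
      d <- vlq_decode(bytes, pos); pos <- d$pos
      dat <- if (d$value > 0) bytes[pos:(pos + d$value - 1L)] else integer(0)
      pos <- pos + d$value
      if (type == 81L) {
        ev[[length(ev) + 1L]] <- list(tick = tick, type = "tempo",
                                      value = sum(as.double(dat) * 256^((length(dat) - 1):0)))
      }
      if (type == 47L) break # end of track
      status <- NULL
    } else if (status >= 240L) { # sysex
      d <- vlq_decode(bytes, pos); pos <- d$pos + d$value
    } else if (hi %in% c(8L, 9L)) { # note off / note on
      pitch <- bytes[pos]; vel <- bytes[pos + 1L]; pos <- pos + 2L
      type <- if (hi == 9L && vel > 0L) "on" else "off"
      ev[[length(ev) + 1L]] <- list(tick = tick, type = type,
                                    pitch = as.integer(pitch), value = as.integer(vel))
    } else if (hi %in% c(10L, 11L, 14L)) {
      pos <- pos + 2L
    } else if (hi %in% c(12L, 13L)) {
      pos <- pos + 1L
    } else {
      abort(sprintf("unsupported MIDI status byte 0x%02x", status))
    }
  }
  ev
}

#' Read a standard MIDI file as a note table
#'
#' Parses a format 0 or 1 standard MIDI file, pairs note-on/note-off events,
#' and converts ticks to seconds using the file's tempo map. Files must be
#' monophonic; polyphony (temporally overlapping notes) is rejected by
#' default or flattened to the highest concurrently sounding onset order.
#'
#' @param path path to a `.mid` file.
#' @param composition_id id for the resulting sequence; default file name.
#' @param polyphony `"reject"` (default) errors on simultaneous or
#'   overlapping notes; `"flatten"` keeps each note but truncates overlaps.
#' @return a validated note table.
#' @export
read_midi <- function(path, composition_id = NULL, polyphony = c("reject", "flatten")) {
  polyphony <- match.arg(polyphony)
  bytes <- as.integer(readBin(path, "raw", n = file.info(path)$size))
  if (length(bytes) < 14 || rawToChar(as.raw(bytes[1:4])) != "MThd") {
    abort("not a standard MIDI file (missing MThd header)")
  }
  division <- u16(bytes, 13L)
  if (division >= 32768) abort("SMPTE time division is not supported")
  pos <- 9L + u32(bytes, 5L)
  events <- list()
  while (pos + 8L <= length(bytes)) {
    tag <- rawToChar(as.raw(bytes[pos:(pos + 3L)]))
    len <- u32(bytes, pos + 4L)
    if (tag == "MTrk") {
      events <- c(events, parse_track(bytes[(pos + 8L):(pos + 7L + len)]))
    }
    pos <- pos + 8L + len
  }
  if (length(events) == 0) abort("MIDI file contains no events")
  ev <- dplyr::bind_rows(lapply(events, tibble::as_tibble)) |>
    dplyr::arrange(.data$tick)

  # tick -> seconds via tempo map (default 500000 us/quarter)
  tempos <- dplyr::filter(ev, .data$type == "tempo")
  tmap <- tibble::tibble(tick = c(0, tempos$tick), usq = c(500000, tempos$value)) |>
    dplyr::distinct(.data$tick, .keep_all = TRUE) |>
    dplyr::arrange(.data$tick)
  tick_to_sec <- function(tick) {
    sec <- 0
    for (i in seq_len(nrow(tmap))) {
      seg_end <- if (i < nrow(tmap)) min(tmap$tick[i + 1], tick) else tick
      if (seg_end > tmap$tick[i]) {
        sec <- sec + (seg_end - tmap$tick[i]) * tmap$usq[i] / 1e6 / division
      }
      if (i < nrow(tmap) && tick <= tmap$tick[i + 1]) break
    }
    sec
  }

  notes_ev <- dplyr::filter(ev, .data$type %in% c("on", "off"))
  if (!any(notes_ev$type == "on")) abort("MIDI file contains no note-on events")
  active <- list()
  out <- list()
  for (i in seq_len(nrow(notes_ev))) {
    e <- notes_ev[i, ]
    key <- as.character(e$pitch)
    if (e$type == "on") {
      if (length(active) > 0 && polyphony == "reject") {
        abort("polyphonic MIDI file (overlapping notes); use polyphony = \"flatten\"")
      }
      active[[key]] <- e$tick
    } else if (!is.null(active[[key]])) {
      out[[length(out) + 1L]] <- tibble::tibble(
        pitch = e$pitch,
        onset = tick_to_sec(active[[key]]),
        offset = tick_to_sec(e$tick)
      )
      active[[key]] <- NULL
    }
  }
  if (length(out) == 0) abort("MIDI file contains no complete notes")
  notes <- dplyr::bind_rows(out) |> dplyr::arrange(.data$onset)
  if (polyphony == "flatten") {
    # truncate each note at the next onset
    nxt <- c(notes$onset[-1], Inf)
    notes$offset <- pmin(notes$offset, nxt)
    notes <- dplyr::filter(notes, .data$offset > .data$onset)
  }
  note_sequence(notes$pitch, notes$onset, notes$offset - notes$onset,
                composition_id = composition_id %||% basename(path))
}

#' Write a note table as a standard MIDI file
#'
#' Writes a single-track (format 0) file at 480 ticks per quarter and a fixed
#' tempo of 120 bpm, so `read_midi(write_midi(x))` round-trips onsets and
#' durations to tick resolution (about 1 ms).
#'
#' @param notes a validated note table for one composition.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_midi <- function(notes, path) {
  notes <- validate_notes(notes)
  if (dplyr::n_distinct(notes$composition_id) != 1) {
    abort("write_midi writes one composition at a time")
  }
  division <- 480L
  usq <- 500000 # 120 bpm
  to_tick <- function(sec) round_half_up(sec * 1e6 / usq * division)
  ev <- dplyr::bind_rows(
    tibble::tibble(tick = to_tick(notes$onset), msg = "on", pitch = notes$pitch),
    tibble::tibble(tick = to_tick(notes$onset + notes$duration), msg = "off", pitch = notes$pitch)
  ) |>
    dplyr::arrange(.data$tick, .data$msg == "on") # offs before ons at equal tick
  body <- c(
    vlq_encode(0L), as.raw(c(0xff, 0x51, 0x03)),
    as.raw(c(usq %/% 65536, (usq %/% 256) %% 256, usq %% 256))
  )
  last <- 0
  for (i in seq_len(nrow(ev))) {
    delta <- ev$tick[i] - last
    last <- ev$tick[i]
    status <- if (ev$msg[i] == "on") 0x90 else 0x80
    vel <- if (ev$msg[i] == "on") 100L else 0L
    body <- c(body, vlq_encode(delta), as.raw(c(status, ev$pitch[i], vel)))
  }
  body <- c(body, vlq_encode(0L), as.raw(c(0xff, 0x2f, 0x00)))
  be <- function(x, n) as.raw((x %/% 256^((n - 1):0)) %% 256)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(charToRaw("MThd"), be(6, 4), be(0, 2), be(1, 2), be(division, 2),
             charToRaw("MTrk"), be(length(body), 4), body), con)
  invisible(path)
}
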