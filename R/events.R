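## Event model: profiles, interval events, event sequences.

#' Construct an event sequence
#'
#' An event `(s, t, b)` adds `b` to every *nonzero* entry in positions
#' `s..t` (1-based, inclusive), clamping below at zero. `b > 0` is an
#' amplification, `b < 0` a deletion; the cost of the event is `|b|`.
#' An event sequence is an ordered `data.frame` with integer columns
#' `s`, `t`, `b`; order matters because clamping does not commute.
#'
#' @param s,t,b integer vectors of equal length: start position, end
#'   position (`s <= t`), signed magnitude (`b != 0`).
#' @return a `data.frame` with columns `s`, `t`, `b`, one row per event.
#' @examples
#' events(c(1, 2), c(3, 2), c(-1, 2))
#' events() # the empty sequence
#' @export
events <- function(s = integer(0), t = integer(0), b = integer(0)) {
  s <- as.integer(s); t <- as.integer(t); b <- as.integer(b)
  stopifnot(length(s) == length(t), length(s) == length(b))
  if (any(s < 1L) || any(t < s)) {
    stop("events require 1 <= s <= t", call. = FALSE)
  }
  if (any(b == 0L)) stop("events require b != 0", call. = FALSE)
  data.frame(s = s, t = t, b = b)
}

as_profile <- function(p) {
  p <- as.integer(p)
  if (length(p) < 1L) stop("a profile has at least one position", call. = FALSE)
  if (any(is.na(p)) || any(p < 0L)) {
    stop("profile entries must be non-negative integers", call. = FALSE)
  }
  p
}

#' Apply a single event to a profile
#'
#' Positions `s..t` with a nonzero copy number become `max(value + b, 0)`;
#' zero positions are frozen (a lost position can never be regained), and
#' positions outside `[s, t]` are untouched.
#'
#' @param profile integer vector of non-negative copy numbers.
#' @param s,t event interval, 1-based inclusive, `1 <= s <= t <= length(profile)`.
#' @param b signed integer magnitude, `b != 0`.
#' @return the new profile (integer vector).
#' @examples
#' apply_event(c(2, 2, 2), 1, 2, +1) # 3 3 2
#' apply_event(c(2, 0, 1), 1, 3, -2) # 0 0 0
#' apply_event(c(0, 2), 1, 2, +1)    # 0 3: the lost first position stays lost
#' @export
apply_event <- function(profile, s, t, b) {
  p <- as_profile(profile)
  s <- as.integer(s); t <- as.integer(t); b <- as.integer(b)
  if (s < 1L || t < s || t > length(p)) {
    stop("event (", s, ",", t, ",", b, ") out of range for n = ", length(p),
         call. = FALSE)
  }
  if (b == 0L) stop("event magnitude b must be nonzero", call. = FALSE)
  idx <- seq.int(s, t)
  live <- idx[p[idx] != 0L]
  p[live] <- pmax(p[live] + b, 0L)
  p
}

#' Apply an ordered event sequence to a profile
#'
#' Left fold of [apply_event()] in row order.
#'
#' @param profile integer vector of non-negative copy numbers.
#' @param ev an event sequence as returned by [events()].
#' @return the resulting profile.
#' @examples
#' apply_events(c(2, 2), events(c(2, 1), c(2, 1), c(-1, 1))) # 3 1
#' @export
apply_events <- function(profile, ev) {
  p <- as_profile(profile)
  if (is.null(ev) || nrow(ev) == 0L) return(p)
  for (r in seq_len(nrow(ev))) {
    p <- apply_event(p, ev$s[r], ev$t[r], ev$b[r])
  }
  p
}

#' Total cost of an event sequence
#'
#' The cost of an event is `|b|`; a sequence costs the sum over its events.
#'
#' @param ev an event sequence ([events()]).
#' @return non-negative integer.
#' @export
event_cost <- function(ev) {
  if (is.null(ev) || nrow(ev) == 0L) return(0L)
  sum(abs(ev$b))
}

#' Decompose events into unit events
#'
#' Replaces each event `(s, t, b)` with `|b|` copies of `(s, t, sign(b))`.
#' Total cost is unchanged and, because clamping commutes with the unit
#' decomposition, applying the result to any profile gives the same profile
#' as applying the original sequence.
#'
#' @param ev an event sequence.
#' @return an event sequence in which every `|b| == 1`.
#' @export
unit_events <- function(ev) {
  if (is.null(ev) || nrow(ev) == 0L) return(events())
  reps <- abs(ev$b)
  i <- rep.int(seq_len(nrow(ev)), reps)
  events(ev$s[i], ev$t[i], sign(ev$b)[i])
}

#' Is an event sequence sorted?
#'
#' A sequence is *sorted* when all deletions precede all amplifications.
#' Sorted sequences suffice: any sequence can be replaced by a sorted one of
#' no greater cost yielding the same profile.
#'
#' @param ev an event sequence.
#' @return `TRUE` or `FALSE`; the empty sequence is vacuously sorted.
#' @export
events_sorted <- function(ev) {
  if (is.null(ev) || nrow(ev) == 0L) return(TRUE)
  amp_seen <- cumsum(ev$b > 0L) > 0L
  !any(amp_seen & ev$b < 0L)
}

## Skyline decomposition: turn per-position coverage counts into maximal-run
## unit events. For level ell = 1, 2, ... every maximal run of positions with
## coverage >= ell becomes one unit event. The number of events equals
## sum_s max(track[s] - track[s-1], 0) with track[0] = 0.
skyline_events <- function(track, sign) {
  track <- as.integer(track)
  n <- length(track)
  if (n == 0L || all(track == 0L)) return(events())
  ss <- integer(0); tt <- integer(0)
  for (lev in seq_len(max(track))) {
    on <- track >= lev
    d <- diff(c(FALSE, on, FALSE))
    ss <- c(ss, which(d == 1L))
    tt <- c(tt, which(d == -1L) - 1L)
  }
  events(ss, tt, rep.int(as.integer(sign), length(ss)))
}

## Build a sorted unit-event sequence from deletion and amplification
## coverage tracks (deletions first).
tracks_to_events <- function(del_track, amp_track) {
  rbind(skyline_events(del_track, -1L), skyline_events(amp_track, +1L))
}
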