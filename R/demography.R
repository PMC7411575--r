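#' Specify a piecewise demography
#'
#' A demography is a set of demes with diploid effective sizes, optional
#' exponential growth, a backward-time migration matrix, and a time-ordered
#' list of demographic events (size changes, growth changes, migration
#' changes, lineage mass movements). Time is measured in generations before
#' present; sizes are diploid effective sizes, so a pair of lineages in a deme
#' of size N coalesces at rate 1/(2N) per generation. Exponential growth is
#' parameterized forward in time: a deme with current size N and rate r has
#' backward-time size N * exp(-r * t).
#'
#' @param sizes named numeric vector of current diploid effective sizes, one
#'   per deme; names become deme labels (defaults `deme1`, `deme2`, ...).
#' @param growth forward-time exponential growth rates per generation
#'   (recycled; default 0).
#' @param migration backward per-lineage per-generation migration probability:
#'   a single number applied to all ordered pairs, or a full matrix with
#'   `migration[i, j]` the rate at which a lineage in deme i jumps to deme j.
#' @param events list of events built with [ev_resize()], [ev_growth()],
#'   [ev_migration()], [ev_mass_move()]. Sorted by time (stably) on
#'   construction.
#' @param max_time generations after which a simulation with two or more
#'   surviving lineage groups aborts with a "cannot coalesce" error rather
#'   than hanging.
#' @return an object of class `"demography"`.
#' @examples
#' dem <- demography(c(N = 5000, S = 3000), migration = 1e-4,
#'                   events = list(ev_mass_move(1500, "S", "N"),
#'                                 ev_resize(1500, "N", 20000)))
#' @export
demography <- function(sizes, growth = 0, migration = 0, events = list(),
                       max_time = 1e9) {
  stopifnot(is.numeric(sizes), length(sizes) >= 1L)
  if (any(!is.finite(sizes)) || any(sizes <= 0))
    stop("all deme sizes must be finite and > 0")
  nd <- length(sizes)
  labels <- names(sizes)
  if (is.null(labels)) labels <- paste0("deme", seq_len(nd))
  if (anyDuplicated(labels)) stop("deme labels must be unique")
  growth <- rep_len(as.numeric(growth), nd)
  if (is.matrix(migration)) {
    if (!all(dim(migration) == nd)) stop("migration matrix must be n_demes x n_demes")
    mig <- migration
  } else {
    stopifnot(length(migration) == 1L)
    mig <- matrix(migration, nd, nd)
  }
  diag(mig) <- 0
  if (any(mig < 0)) stop("migration rates must be >= 0")
  dimnames(mig) <- list(labels, labels)

  events <- lapply(events, resolve_event, labels = labels)
  if (length(events)) {
    times <- vapply(events, `[[`, numeric(1), "time")
    if (any(times < 0)) stop("event times must be >= 0")
    events <- events[order(times)]
  }
  stopifnot(is.numeric(max_time), max_time > 0)
  structure(list(sizes = unname(sizes), growth = growth, mig = mig,
                 events = events, labels = labels, max_time = max_time),
            class = "demography")
}

#' Demographic events
#'
#' Event constructors for [demography()]. `time` is in generations before
#' present; demes are given by label or index.
#'
#' * `ev_resize(time, deme, size)` sets the deme's size to `size` at `time`
#'   (backward); the growth rate is unchanged.
#' * `ev_growth(time, deme, rate)` changes the forward growth rate, anchored
#'   at the deme's size at `time`.
#' * `ev_migration(time, demes, rate)` sets the symmetric migration rate
#'   between the two demes in `demes`.
#' * `ev_mass_move(time, from, to, fraction)` moves each lineage in `from` to
#'   `to` with probability `fraction` (backward view of a founding/dispersal
#'   event); `fraction = 1` merges the demes and deactivates `from`.
#'
#' @param time generations before present (>= 0).
#' @param deme,from,to,demes deme label(s) or index(es).
#' @param size new diploid effective size (> 0).
#' @param rate growth rate (`ev_growth`) or migration probability
#'   (`ev_migration`).
#' @param fraction probability in (0, 1] that a lineage moves.
#' @return an event record consumed by [demography()].
#' @name demographic_events
NULL

#' @rdname demographic_events
#' @export
ev_resize <- function(time, deme, size) {
  stopifnot(time >= 0, size > 0)
  list(time = time, kind = 1L, d1 = deme, d2 = deme, value = size)
}

#' @rdname demographic_events
#' @export
ev_growth <- function(time, deme, rate) {
  stopifnot(time >= 0, is.finite(rate))
  list(time = time, kind = 2L, d1 = deme, d2 = deme, value = rate)
}

#' @rdname demographic_events
#' @export
ev_migration <- function(time, demes, rate) {
  stopifnot(time >= 0, length(demes) == 2L, rate >= 0)
  list(time = time, kind = 3L, d1 = demes[[1L]], d2 = demes[[2L]], value = rate)
}

#' @rdname demographic_events
#' @export
ev_mass_move <- function(time, from, to, fraction = 1) {
  stopifnot(time >= 0, fraction > 0, fraction <= 1)
  list(time = time, kind = 4L, d1 = from, d2 = to, value = fraction)
}

resolve_event <- function(ev, labels) {
  stopifnot(is.list(ev), all(c("time", "kind", "d1", "d2", "value") %in% names(ev)))
  ev$d1 <- resolve_deme(ev$d1, labels)
  ev$d2 <- resolve_deme(ev$d2, labels)
  if (ev$kind %in% c(3L, 4L) && ev$d1 == ev$d2)
    stop("event requires two distinct demes")
  ev
}

resolve_deme <- function(d, labels) {
  if (is.character(d)) {
    i <- match(d, labels)
    if (is.na(i)) stop("unknown deme label: ", d)
    return(i)
  }
  d <- as.integer(d)
  if (d < 1L || d > length(labels)) stop("deme index out of range: ", d)
  d
}

# Flatten a demography into the list layout the C++ simulator consumes
# (0-based deme indices, event columns).
dem_to_cpp <- function(dem) {
  ev <- dem$events
  list(size = dem$sizes, growth = dem$growth, mig = dem$mig,
       ev_time = vapply(ev, `[[`, numeric(1), "time"),
       ev_kind = vapply(ev, `[[`, integer(1), "kind"),
       ev_d1 = vapply(ev, function(e) e$d1 - 1L, integer(1)),
       ev_d2 = vapply(ev, function(e) e$d2 - 1L, integer(1)),
       ev_value = vapply(ev, `[[`, numeric(1), "value"),
       max_time = dem$max_time)
}

#' @export
print.demography <- function(x, ...) {
  cat("Piecewise demography:", length(x$sizes), "deme(s)\n")
  df <- data.frame(deme = x$labels, size = x$sizes, growth = x$growth)
  print(df, row.names = FALSE)
  if (any(x$mig > 0)) {
    cat("migration (backward, per lineage per generation):\n")
    print(x$mig)
  }
  if (length(x$events)) {
    kinds <- c("resize", "set_growth", "set_migration", "mass_move")
    cat("events:\n")
    for (e in x$events)
      cat(sprintf("  t=%g %s %s->%s value=%g\n", e$time, kinds[e$kind],
                  x$labels[e$d1], x$labels[e$d2], e$value))
  }
  invisible(x)
}
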