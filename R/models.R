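#' Incursion model specifications
#'
#' Five two-deme model topologies for the history of a North (N) and South
#' (S) population pair, each available with or without symmetric migration:
#'
#' * `i` -- single route: N and S split from a local deme of size `N_NZ` at
#'   `T_split`; backward from the split the local deme shrinks exponentially
#'   to the founding bottleneck `N_B` at the introduction time `T_intro`,
#'   where it joins the source of size `N_A` (forward reading: introduction
#'   through a bottleneck, expansion, then dispersal). k = 7.
#' * `ii` -- single route, dispersal while small: N and S grow exponentially
#'   from `N_B` since `T_split`; the merged deme keeps size `N_B` back to
#'   `T_intro`, then the source `N_A`. k = 6.
#' * `iii` -- multiple routes with founding bottlenecks: N grows from `N_BN`
#'   and S from `N_BS` since `T_intro`, where both join the source `N_A`.
#'   k = 6.
#' * `iv` -- multiple routes, no size reduction: as `iii` with founding sizes
#'   equal to current sizes (no growth). k = 4.
#' * `v` -- isolated sources: N (from `N_BN`) and S (from `N_BS`) enter from
#'   two separate sources `N_A1`, `N_A2` at `T_intro`; the sources merge into
#'   a common ancestor `N_A` at `T_anc` > `T_intro`. k = 9.
#'
#' The migration variant adds one symmetric backward rate `m`, active from
#' the present back to the time the two sampled demes cease to exist
#' separately (`T_split` for i/ii, `T_intro` for iii/iv/v).
#'
#' @param model_id one of `"i"`, `"ii"`, `"iii"`, `"iv"`, `"v"`.
#' @param migration include the symmetric migration parameter.
#' @param bounds optional named list of `c(lower, upper)` overriding the
#'   default search bounds (sizes 10-1e7 diploids, times 10-1e5 generations,
#'   m 0-0.1). Setting `lower == upper` fixes a parameter: it is excluded
#'   from the search and not counted as free in k.
#' @return an object of class `"model_spec"` with fields `params` (names),
#'   `bounds`, `log_scale`, `k` (free parameter count).
#' @export
model_spec <- function(model_id = c("i", "ii", "iii", "iv", "v"),
                       migration = FALSE, bounds = NULL) {
  model_id <- match.arg(model_id)
  params <- switch(model_id,
    i   = c("N_N", "N_S", "N_NZ", "N_B", "T_split", "T_intro", "N_A"),
    ii  = c("N_N", "N_S", "N_B", "T_split", "T_intro", "N_A"),
    iii = c("N_N", "N_S", "N_BN", "N_BS", "T_intro", "N_A"),
    iv  = c("N_N", "N_S", "T_intro", "N_A"),
    v   = c("N_N", "N_S", "N_BN", "N_BS", "T_intro", "N_A1", "N_A2",
            "T_anc", "N_A"))
  if (migration) params <- c(params, "m")
  b <- lapply(params, function(p) {
    if (p == "m") c(0, 0.1)
    else if (startsWith(p, "T_")) c(10, 1e5)
    else c(10, 1e7)
  })
  names(b) <- params
  log_scale <- setNames(params != "m", params)
  if (!is.null(bounds)) {
    stopifnot(is.list(bounds))
    for (p in names(bounds)) {
      if (!p %in% params) stop("unknown parameter in bounds: ", p)
      stopifnot(length(bounds[[p]]) == 2L, bounds[[p]][1L] <= bounds[[p]][2L])
      b[[p]] <- as.numeric(bounds[[p]])
    }
  }
  free <- vapply(b, function(x) x[1L] < x[2L], logical(1))
  ordering <- switch(model_id,
    i = list(c("T_split", "T_intro")),
    ii = list(c("T_split", "T_intro")),
    v = list(c("T_intro", "T_anc")),
    list())
  structure(list(model_id = model_id, migration = migration, params = params,
                 bounds = b, log_scale = log_scale, free = free,
                 k = sum(free), ordering = ordering),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("Incursion model %s%s: parameters %s (k = %d free)\n",
              x$model_id, if (x$migration) " + migration" else "",
              paste(x$params, collapse = ", "), x$k))
  invisible(x)
}

#' Compile an incursion model into a demography
#'
#' Builds the backward-time [demography()] for a model topology (see
#' [model_spec()]) at a given parameter vector. Demes are labelled `N` and
#' `S`. Growth phases are parameterized so the deme's size interpolates
#' exponentially between its founding size at the older boundary and its
#' current/split-time size at the younger.
#'
#' @param model_id model identifier.
#' @param migration logical.
#' @param params named numeric vector/list with the model's parameters.
#' @return a [demography()].
#' @export
build_model <- function(model_id, migration, params) {
  spec_names <- model_spec(model_id, migration)$params
  params <- as.list(params)
  missing <- setdiff(spec_names, names(params))
  if (length(missing))
    stop("missing parameter(s): ", paste(missing, collapse = ", "))
  p <- lapply(params[spec_names], as.numeric)
  sizes <- unlist(p[startsWith(spec_names, "N_")])
  if (any(sizes <= 0)) stop("all sizes must be > 0")
  times <- unlist(p[startsWith(spec_names, "T_")])
  if (any(times <= 0)) stop("all times must be > 0")
  if (model_id %in% c("i", "ii") && p$T_split >= p$T_intro)
    stop("time ordering violated: T_split must be < T_intro ",
         "(the split postdates the introduction, forward in time)")
  if (model_id == "v" && p$T_anc <= p$T_intro)
    stop("time ordering violated: T_anc must be > T_intro")

  grw <- function(from_size, to_size, dt) log(from_size / to_size) / dt
  ev <- list()
  growth0 <- c(0, 0)
  m_end <- if (model_id %in% c("i", "ii")) p$T_split else p$T_intro

  if (model_id == "i") {
    r <- grw(p$N_NZ, p$N_B, p$T_intro - p$T_split)
    ev <- list(ev_mass_move(p$T_split, "S", "N"),
               ev_resize(p$T_split, "N", p$N_NZ),
               ev_growth(p$T_split, "N", r),
               ev_resize(p$T_intro, "N", p$N_A),
               ev_growth(p$T_intro, "N", 0))
  } else if (model_id == "ii") {
    growth0 <- c(grw(p$N_N, p$N_B, p$T_split), grw(p$N_S, p$N_B, p$T_split))
    ev <- list(ev_mass_move(p$T_split, "S", "N"),
               ev_resize(p$T_split, "N", p$N_B),
               ev_growth(p$T_split, "N", 0),
               ev_resize(p$T_intro, "N", p$N_A))
  } else if (model_id == "iii") {
    growth0 <- c(grw(p$N_N, p$N_BN, p$T_intro), grw(p$N_S, p$N_BS, p$T_intro))
    ev <- list(ev_mass_move(p$T_intro, "S", "N"),
               ev_resize(p$T_intro, "N", p$N_A),
               ev_growth(p$T_intro, "N", 0))
  } else if (model_id == "iv") {
    ev <- list(ev_mass_move(p$T_intro, "S", "N"),
               ev_resize(p$T_intro, "N", p$N_A))
  } else {  # v
    growth0 <- c(grw(p$N_N, p$N_BN, p$T_intro), grw(p$N_S, p$N_BS, p$T_intro))
    ev <- list(ev_resize(p$T_intro, "N", p$N_A1),
               ev_growth(p$T_intro, "N", 0),
               ev_resize(p$T_intro, "S", p$N_A2),
               ev_growth(p$T_intro, "S", 0),
               ev_mass_move(p$T_anc, "S", "N"),
               ev_resize(p$T_anc, "N", p$N_A))
  }
  mig0 <- 0
  if (migration) {
    if (is.null(p$m) || p$m < 0) stop("missing parameter(s): m")
    mig0 <- p$m
    if (model_id == "v")
      ev <- c(list(ev_migration(m_end, c("N", "S"), 0)), ev)
  }
  demography(c(N = p$N_N, S = p$N_S), growth = growth0, migration = mig0,
             events = ev)
}
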