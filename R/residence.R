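#' Extract binding events from an occupancy series
#'
#' A binding event is a maximal run of consecutive sampled frames with
#' zeta = 1 (species-level continuity: the occupant identity may change
#' within one event). Duration is the number of samples in the run times the
#' sampling interval, so an isolated single-sample contact has the duration
#' of one interval. Events truncated by the start or end of the trajectory
#' are flagged censored; mean-residence estimates should exclude them.
#'
#' @param series an \code{occupancy_series}.
#' @return data.frame with one row per event: \code{site_id},
#'   \code{species}, \code{start_idx}, \code{end_idx}, \code{start_ns},
#'   \code{end_ns}, \code{duration_ns}, \code{n_samples}, \code{exchanges},
#'   \code{single_fraction}, \code{max_occupants}, \code{censored}; plus the
#'   per-event occupant sequences in \code{attr(,"occupants")}.
#' @export
extract_events <- function(series) {
  z <- series$zeta
  interval <- series$interval
  if (is.na(interval)) interval <- 1
  empty <- data.frame(site_id = integer(), species = character(),
                      start_idx = integer(), end_idx = integer(),
                      start_ns = numeric(), end_ns = numeric(),
                      duration_ns = numeric(), n_samples = integer(),
                      exchanges = integer(), single_fraction = numeric(),
                      max_occupants = integer(), censored = logical(),
                      stringsAsFactors = FALSE)
  if (!length(z) || !any(z == 1L)) {
    attr(empty, "occupants") <- list()
    return(empty)
  }
  r <- rle(z)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  on <- r$values == 1L
  starts <- starts[on]; ends <- ends[on]
  occ_seqs <- lapply(seq_along(starts), function(i)
    series$occupants[starts[i]:ends[i]])
  ex <- lapply(occ_seqs, occupant_exchange_stats)
  out <- data.frame(
    site_id = if (!is.null(series$site)) series$site$site_id else NA_integer_,
    species = series$species %||% NA_character_,
    start_idx = starts, end_idx = ends,
    start_ns = series$time[starts], end_ns = series$time[ends],
    duration_ns = (ends - starts + 1L) * interval,
    n_samples = ends - starts + 1L,
    exchanges = vapply(ex, `[[`, integer(1), "exchanges"),
    single_fraction = vapply(ex, `[[`, numeric(1), "single_fraction"),
    max_occupants = vapply(occ_seqs, function(s)
      max(vapply(s, length, integer(1))), integer(1)),
    censored = starts == 1L | ends == length(z),
    stringsAsFactors = FALSE)
  attr(out, "occupants") <- occ_seqs
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Top-k longest binding events
#'
#' Sorted by decreasing duration; equal durations are broken by earlier
#' start time.
#'
#' @param events data.frame from \code{\link{extract_events}}.
#' @param k how many events (k > n returns all).
#' @return the top-k rows.
#' @export
longest_events <- function(events, k) {
  stopifnot(k >= 1)
  ord <- order(-events$duration_ns, events$start_idx)
  events[utils::head(ord, k), , drop = FALSE]
}

#' Cutoff-sensitivity scan of event durations
#'
#' Recomputes the occupancy series and its events for each cutoff in the
#' grid and reports the longest and mean event duration. Because the set of
#' contact frames can only grow with the cutoff, the longest duration is
#' non-decreasing in delta. The default grid spans 0.8 to 1.6 nm, the range
#' over which cardiolipin site lifetimes are conventionally scanned.
#'
#' @param traj,system,site,species,config as in
#'   \code{\link{occupancy_series}}.
#' @param delta_grid increasing cutoffs (nm).
#' @param censored include censored events in the summaries? (default FALSE
#'   for the mean, TRUE for the longest, mirroring how headline "longest
#'   stretch" numbers are read off raw trajectories).
#' @return data.frame (delta_nm, longest_ns, mean_ns, n_events).
#' @export
cutoff_sensitivity <- function(traj, system, site, species,
                               config = contact_config(),
                               delta_grid = seq(0.8, 1.6, by = 0.1)) {
  if (!length(delta_grid)) stop("delta_grid is empty")
  if (is.unsorted(delta_grid, strictly = TRUE))
    stop("delta_grid must be increasing")
  rows <- lapply(delta_grid, function(dlt) {
    ev <- extract_events(occupancy_series(traj, system, site, species,
                                          config, delta = dlt))
    comp <- ev[!ev$censored, , drop = FALSE]
    data.frame(delta_nm = dlt,
               longest_ns = if (nrow(ev)) max(ev$duration_ns) else 0,
               mean_ns = if (nrow(comp)) mean(comp$duration_ns) else NA_real_,
               n_events = nrow(ev))
  })
  do.call(rbind, rows)
}

# Exchange statistics of one occupant-set sequence, per the single-occupant
# rule: only samples whose occupant set has exactly one member enter the
# count; an exchange is a change of that single occupant between consecutive
# such samples. The single-occupancy fraction is single-occupant samples
# over occupied samples.
occupant_exchange_stats <- function(occ_seq) {
  sizes <- vapply(occ_seq, length, integer(1))
  occupied <- sum(sizes > 0L)
  singles <- which(sizes == 1L)
  ids <- vapply(occ_seq[singles], function(s) as.integer(s[1]), integer(1))
  exchanges <- if (length(ids) > 1L) sum(ids[-1] != ids[-length(ids)]) else 0L
  list(exchanges = as.integer(exchanges),
       single_fraction = if (occupied) length(singles) / occupied else NA_real_)
}

#' Single-lipid exchange count of one binding event
#'
#' Restricts the event's occupant-set sequence to samples occupied by
#' exactly one lipid and counts identity changes between consecutive such
#' samples (a single lipid replaced by a single lipid of the same species).
#' Also returns the fraction of occupied samples that are single-occupant.
#'
#' @param event either one row of the \code{\link{extract_events}} output
#'   (with its \code{occupants} attribute) or a plain list of occupant-id
#'   vectors.
#' @return list(exchanges, single_fraction).
#' @export
count_single_lipid_exchanges <- function(event) {
  occ_seq <- if (is.data.frame(event)) {
    seqs <- attr(event, "occupants")
    if (is.null(seqs) || nrow(event) != 1L)
      stop("pass a single event row carrying its occupants attribute, or a list of occupant sets")
    seqs[[1]]
  } else event
  if (!length(occ_seq)) return(list(exchanges = 0L, single_fraction = NA_real_))
  occupant_exchange_stats(occ_seq)
}

#' Mean residence time from completed events
#'
#' Mean duration of non-censored events, minus one sampling interval: a
#' capture is first seen on the sample at which it happens, so a dwell of
#' zero elapsed time already spans one full sample. Under exponential escape
#' with mean tau, the expected number of occupied samples is
#' 1/(1 - exp(-interval/tau)); subtracting one sample makes the corrected
#' mean agree with tau to within half a sampling interval.
#'
#' @param events output of \code{\link{extract_events}}.
#' @param interval sampling interval (ns); taken from the durations if not
#'   given.
#' @return list(mean_ns, n_events).
#' @export
mean_residence <- function(events, interval = NULL) {
  comp <- events[!events$censored, , drop = FALSE]
  if (!nrow(comp)) return(list(mean_ns = NA_real_, n_events = 0L))
  if (is.null(interval))
    interval <- min(comp$duration_ns / comp$n_samples)
  list(mean_ns = mean(comp$duration_ns - interval), n_events = nrow(comp))
}
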