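#' Track-linking and docking-classification parameters
#'
#' Dwell-time thresholds follow the standard TIRF docking criteria: a
#' granule that appears in the evanescent field and stays laterally
#' confined for at least \code{t_min} (2 s) counts as an approach; it is
#' docked if it remains confined for at least \code{t_dock} (25 s) and a
#' visitor if it leaves before that; stable docking for survival curves is
#' assessed \code{t_survival} (40 s) after the approach.
#'
#' @param link_radius max frame-to-frame displacement for linking, px.
#' @param max_gap frames a track may go undetected without being closed.
#' @param confine_radius max excursion from the track median position for
#'   the granule to count as laterally confined, px (default 1.5, i.e.
#'   150 nm at 100 nm/px).
#' @param t_min minimum confined residence for an approach, s.
#' @param t_dock minimum confined residence for docking, s.
#' @param t_survival survival horizon after approach, s.
#' @return an object of class \code{docking_params}.
#' @export
docking_params <- function(link_radius = 3, max_gap = 1,
                           confine_radius = 1.5, t_min = 2, t_dock = 25,
                           t_survival = 40) {
  if (confine_radius >= link_radius)
    stop("confine_radius must be < link_radius", call. = FALSE)
  if (!(t_min < t_dock && t_dock <= t_survival))
    stop("need t_min < t_dock <= t_survival", call. = FALSE)
  structure(list(link_radius = link_radius, max_gap = max_gap,
                 confine_radius = confine_radius, t_min = t_min,
                 t_dock = t_dock, t_survival = t_survival),
            class = "docking_params")
}

#' Link per-frame detections into granule tracks
#'
#' Greedy nearest-neighbour linking, closest pair first: at each frame,
#' candidate (track, detection) pairs within \code{link_radius} are
#' assigned in order of increasing distance, each detection joining at most
#' one track. A track survives up to \code{max_gap} missed frames.
#'
#' @param spots data.frame(frame, x, y, peak_intensity, ...) sorted or not;
#'   it is ordered by frame internally.
#' @param params a \code{\link{docking_params}}.
#' @param frame_interval seconds per frame, stored on each track.
#' @return list of tracks; each track is a list with \code{id},
#'   \code{frame}, \code{x}, \code{y}, \code{intensity},
#'   \code{start_frame}, \code{end_frame}, \code{frame_interval}
#'   (class \code{granule_track}).
#' @export
link_tracks <- function(spots, params = docking_params(),
                        frame_interval = 1) {
  if (nrow(spots) == 0L) return(list())
  spots <- spots[order(spots$frame), , drop = FALSE]
  frames <- split(spots, spots$frame)
  frame_ids <- as.integer(names(frames))

  tr_x <- list(); tr_y <- list(); tr_f <- list(); tr_i <- list()
  active <- integer()       # indices into tr_* of open tracks
  last_f <- numeric()       # last frame of each open track
  n_tr <- 0L

  for (fi in seq_along(frames)) {
    t <- frame_ids[fi]
    det <- frames[[fi]]
    # close tracks that exceeded the allowed gap
    if (length(active)) {
      open <- (t - last_f) <= (params$max_gap + 1L)
      active <- active[open]; last_f <- last_f[open]
    }
    nd <- nrow(det)
    assigned_det <- rep(FALSE, nd)
    if (length(active) && nd) {
      ax <- vapply(active, function(k) tr_x[[k]][length(tr_x[[k]])], 0)
      ay <- vapply(active, function(k) tr_y[[k]][length(tr_y[[k]])], 0)
      d <- sqrt(outer(ax, det$x, "-")^2 + outer(ay, det$y, "-")^2)
      cand <- which(d <= params$link_radius, arr.ind = TRUE)
      if (nrow(cand)) {
        cand <- cand[order(d[cand]), , drop = FALSE]
        used_tr <- rep(FALSE, length(active))
        for (r in seq_len(nrow(cand))) {
          i <- cand[r, 1]; j <- cand[r, 2]
          if (used_tr[i] || assigned_det[j]) next
          used_tr[i] <- TRUE; assigned_det[j] <- TRUE
          k <- active[i]
          tr_x[[k]] <- c(tr_x[[k]], det$x[j])
          tr_y[[k]] <- c(tr_y[[k]], det$y[j])
          tr_f[[k]] <- c(tr_f[[k]], t)
          tr_i[[k]] <- c(tr_i[[k]], det$peak_intensity[j])
          last_f[i] <- t
        }
      }
    }
    # unassigned detections found new tracks
    for (j in which(!assigned_det)) {
      n_tr <- n_tr + 1L
      tr_x[[n_tr]] <- det$x[j]; tr_y[[n_tr]] <- det$y[j]
      tr_f[[n_tr]] <- t; tr_i[[n_tr]] <- det$peak_intensity[j]
      active <- c(active, n_tr); last_f <- c(last_f, t)
    }
  }

  lapply(seq_len(n_tr), function(k) {
    structure(list(id = k, frame = tr_f[[k]], x = tr_x[[k]], y = tr_y[[k]],
                   intensity = tr_i[[k]], start_frame = tr_f[[k]][1],
                   end_frame = tr_f[[k]][length(tr_f[[k]])],
                   frame_interval = frame_interval),
              class = "granule_track")
  })
}

#' Residence time of a track in seconds
#' @param track a \code{granule_track}.
#' @return seconds at the membrane, (end - start + 1) x frame interval.
#' @export
residence_time <- function(track) {
  (track$end_frame - track$start_frame + 1) * track$frame_interval
}

#' Maximum excursion of a track from its median position
#' @param track a \code{granule_track}.
#' @return max distance (px) of any position from the track's median (x, y).
#' @export
max_excursion <- function(track) {
  mx <- stats::median(track$x); my <- stats::median(track$y)
  max(sqrt((track$x - mx)^2 + (track$y - my)^2))
}

#' Classify a track as docked, visitor, or transit
#'
#' A track is laterally confined iff its maximum excursion from the median
#' position stays within \code{confine_radius}. Confined tracks with
#' residence >= \code{t_dock} are docked (ties at exactly \code{t_dock}
#' classify as docked); confined tracks with residence in
#' [\code{t_min}, \code{t_dock}) are visitors; everything else — confined
#' residence below \code{t_min}, or the confinement criterion failed — is a
#' transit.
#'
#' @param track a \code{granule_track}.
#' @param params a \code{\link{docking_params}}.
#' @return data.frame(track_id, class, approach_frame, residence_s,
#'   max_excursion_px).
#' @export
classify_docking <- function(track, params = docking_params()) {
  if (!length(track$frame)) stop("empty track", call. = FALSE)
  if (is.null(track$frame_interval))
    stop("track carries no frame_interval", call. = FALSE)
  res <- residence_time(track)
  exc <- max_excursion(track)
  confined <- exc <= params$confine_radius
  cls <- if (!confined || res < params$t_min) "transit"
         else if (res >= params$t_dock) "docked"
         else "visitor"
  data.frame(track_id = track$id, class = cls,
             approach_frame = track$start_frame, residence_s = res,
             max_excursion_px = exc)
}

#' Classify every track in a list
#' @param tracks list of \code{granule_track}s.
#' @param params a \code{\link{docking_params}}.
#' @return data.frame, one row per track.
#' @export
classify_all <- function(tracks, params = docking_params()) {
  out <- do.call(rbind, lapply(tracks, classify_docking, params = params))
  if (is.null(out))
    out <- data.frame(track_id = integer(), class = character(),
                      approach_frame = integer(), residence_s = numeric(),
                      max_excursion_px = numeric())
  out
}

#' Stable-docking fraction among approaching granules
#'
#' An approach is a granule that appears after the first observed frame
#' (granules already present at the start belong to the standing docked
#' pool, not to the arrival count) and stays laterally confined for at
#' least \code{t_min}. Of these, the stably docked are the ones still
#' present \code{t_survival} seconds after the approach frame.
#'
#' A track that begins where another track ended moments earlier is a
#' re-detection of the same granule after a transient detection dropout
#' (for example saddle suppression by a passing neighbour), not a new
#' axial approach — a manual scorer would never count it as an arrival.
#' Such continuation fragments (gap at most \code{rejoin_gap} frames,
#' displacement at most \code{rejoin_radius} px) are therefore chained
#' back onto their predecessor before approaches and survival are counted.
#'
#' @param events classification table from \code{\link{classify_all}}
#'   (rows aligned with \code{tracks} via \code{track_id}).
#' @param tracks the corresponding list of tracks.
#' @param params a \code{\link{docking_params}}.
#' @param first_frame frame number regarded as the start of observation.
#' @param rejoin_gap maximum dropout (frames) across which a new track is
#'   treated as the continuation of a finished one.
#' @param rejoin_radius maximum displacement (px) for a continuation.
#' @return list(n_approach, n_stable, fraction); \code{fraction} is
#'   \code{NA} (with a warning) when no approaches were observed.
#' @export
docking_fraction <- function(events, tracks, params = docking_params(),
                             first_frame = 1L, rejoin_gap = 10,
                             rejoin_radius = 2) {
  if (!length(tracks)) {
    warning("no approaching granules; docking fraction undefined")
    return(list(n_approach = 0L, n_stable = 0L, fraction = NA_real_))
  }
  fi <- tracks[[1]]$frame_interval
  n <- length(tracks)
  starts <- vapply(tracks, function(tr) tr$start_frame, 0)
  ends <- vapply(tracks, function(tr) tr$end_frame, 0)
  head_x <- vapply(tracks, function(tr) tr$x[1], 0)
  head_y <- vapply(tracks, function(tr) tr$y[1], 0)
  tail_x <- vapply(tracks, function(tr) tr$x[length(tr$x)], 0)
  tail_y <- vapply(tracks, function(tr) tr$y[length(tr$y)], 0)
  confined <- vapply(tracks, max_excursion, 0) <= params$confine_radius

  # chain continuation fragments onto their predecessors
  parent <- seq_len(n)
  continued <- rep(FALSE, n)   # predecessor already has a continuation
  for (i in order(starts)) {
    gap <- starts[i] - ends - 1
    cand <- which(gap >= 0 & gap <= rejoin_gap & !continued &
                    seq_len(n) != i &
                    (tail_x - head_x[i])^2 + (tail_y - head_y[i])^2 <=
                      rejoin_radius^2)
    if (length(cand)) {
      u <- cand[which.max(ends[cand])]
      parent[i] <- u
      continued[u] <- TRUE
    }
  }
  root <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  chain <- vapply(seq_len(n), root, 0L)

  surv_frames <- params$t_survival / fi
  n_approach <- 0L; n_stable <- 0L
  for (r in unique(chain)) {
    members <- which(chain == r)
    c_start <- min(starts[members]); c_end <- max(ends[members])
    span_s <- (c_end - c_start + 1) * fi
    if (c_start <= first_frame) next           # pre-existing pool
    if (!all(confined[members])) next          # lateral confinement failed
    if (span_s < params$t_min) next            # too brief to be an approach
    n_approach <- n_approach + 1L
    if (c_end >= c_start + surv_frames) n_stable <- n_stable + 1L
  }
  frac <- if (n_approach == 0L) {
    warning("no approaching granules; docking fraction undefined")
    NA_real_
  } else n_stable / n_approach
  list(n_approach = n_approach, n_stable = n_stable, fraction = frac)
}
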