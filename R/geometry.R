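#' Event-anchored parameter snapshots
#'
#' Extracts the seven trajectory snapshots used by the parameter-space
#' analyses: just before each of the three perturbations, at the end of each
#' perturbation, and after the final wash — in chronological order. Each
#' snapshot is the mean of the parameter samples over a 20 s window from
#' 30 s to 10 s before the event time (half-open), where the parameters are
#' already stable so the averaging is insensitive to window placement. The
#' "after final wash" event anchors to the end of the schedule.
#'
#' @param time_p parameter sample times (s).
#' @param params sample matrix (rows = times; 7 conductance or 11 half-shift
#'   columns).
#' @param schedule the run's [build_schedule()] schedule (needs 3
#'   perturbation epochs).
#' @param window `c(before_start, before_end)` offsets (s) of the averaging
#'   window before each event.
#' @return A 7 x d matrix with rownames `before_pert1`, `end_pert1`, ...,
#'   `after_final_wash`.
#' @export
extract_snapshots <- function(time_p, params, schedule, window = c(30, 10)) {
  ep <- schedule$epochs
  pidx <- which(ep$label == "perturbation")
  if (length(pidx) != 3) stop("snapshot extraction expects 3 perturbations")
  events <- c(rbind(ep$start[pidx], ep$start[pidx] + ep$duration[pidx]))
  events <- c(events, schedule$total_duration)
  names(events) <- c("before_pert1", "end_pert1", "before_pert2", "end_pert2",
                     "before_pert3", "end_pert3", "after_final_wash")
  # chronological: before_pert2 coincides with end of wash 1, etc.
  params <- as.matrix(params)
  snaps <- do.call(rbind, lapply(events, function(tv) {
    keep <- time_p >= (tv - window[1]) & time_p < (tv - window[2])
    if (!any(keep)) stop("no parameter samples in snapshot window at t = ", tv)
    colMeans(params[keep, , drop = FALSE])
  }))
  rownames(snaps) <- names(events)
  snaps
}

#' Successive displacement vectors
#'
#' `v_k = p_(k+1) - p_k` for the seven snapshots, labeled in protocol order:
#' After Pert 1, After Wash 1, After Pert 2, After Wash 2, After Pert 3,
#' After Wash 3.
#'
#' @param points 7 x d snapshot matrix from [extract_snapshots()].
#' @return 6 x d matrix of displacement vectors.
#' @export
displacements <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) != 7) stop("need exactly 7 snapshot points")
  v <- points[-1, , drop = FALSE] - points[-7, , drop = FALSE]
  rownames(v) <- c("after_pert1", "after_wash1", "after_pert2",
                   "after_wash2", "after_pert3", "after_wash3")
  v
}

#' Euclidean norm
#'
#' @param v numeric vector.
#' @return `sqrt(sum(v^2))`.
#' @export
vector_norm <- function(v) sqrt(sum(v^2))

#' Mean-centered bounding sphere of the post-adaptation states
#'
#' Center = componentwise mean of snapshot points 2..7; radius = largest
#' Euclidean distance from the center to any of those points (the smallest
#' sphere centered at the mean enclosing all post-adaptation states).
#'
#' @param points 6 x d matrix (snapshot points 2..7).
#' @return List `center`, `radius`.
#' @export
bounding_sphere <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) != 6) stop("bounding sphere is built on points 2..7")
  center <- colMeans(points)
  d <- sqrt(rowSums(sweep(points, 2, center)^2))
  list(center = center, radius = max(d))
}

#' Signed distance from the initial state to the adapted sphere
#'
#' `||p1 - center|| - radius`; positive means the pre-perturbation state lay
#' outside the adapted region.
#'
#' @param point1 snapshot point 1 (pre-perturbation state).
#' @param sphere a [bounding_sphere()].
#' @return Signed distance (same units as the parameters).
#' @export
signed_outside_distance <- function(point1, sphere) {
  vector_norm(as.numeric(point1) - sphere$center) - sphere$radius
}

#' Angle between two displacement vectors
#'
#' Tail-to-tail angle `acos(u . v / (||u|| ||v||))` in degrees, cosine
#' clamped to [-1, 1]. Values above 90 degrees indicate a direction
#' reversal (negative dot product).
#'
#' @param u,v nonzero numeric vectors of equal length.
#' @return Angle in `[0, 180]` degrees.
#' @export
angle_between <- function(u, v) {
  nu <- vector_norm(u); nv <- vector_norm(v)
  if (nu == 0 || nv == 0) stop("angle undefined for zero vector")
  cosang <- sum(u * v) / (nu * nv)
  acos(max(-1, min(1, cosang))) * 180 / pi
}

#' Full trajectory summary of one trace
#'
#' Computes, for both parameter spaces (7-D conductances, 11-D half-shifts):
#' the six displacement norms, the mean-centered bounding sphere over
#' snapshot points 2..7, the signed outside distance of point 1, and the two
#' tail-to-tail angles in the full-dimensional half-shift space — the
#' perturbation-wash-perturbation angle (After Wash 2 vs After Pert 3) and
#' the wash-perturbation-wash angle (After Pert 3 vs After Wash 3).
#'
#' @param trace a `sim_trace`.
#' @return A `trajectory_summary` list with elements `conductance` and
#'   `halfshift` (each: snapshots, displacement norms, sphere radius,
#'   outside distance) and `angles` (`pwp`, `wpw`, degrees).
#' @export
trajectory_summary <- function(trace) {
  out <- lapply(list(conductance = trace$gmax, halfshift = trace$half_shifts),
                function(p) {
    snaps <- extract_snapshots(trace$time_p, p, trace$schedule)
    v <- displacements(snaps)
    sph <- bounding_sphere(snaps[2:7, , drop = FALSE])
    list(snapshots = snaps,
         norms = apply(v, 1, vector_norm),
         radius = sph$radius,
         outside_distance = signed_outside_distance(snaps[1, ], sph))
  })
  hsnaps <- out$halfshift$snapshots
  hv <- displacements(hsnaps)
  safe_angle <- function(u, v) {
    if (vector_norm(u) == 0 || vector_norm(v) == 0) return(NA_real_)
    angle_between(u, v)
  }
  out$angles <- c(
    pwp = safe_angle(hv["after_wash2", ], hv["after_pert3", ]),
    wpw = safe_angle(hv["after_pert3", ], hv["after_wash3", ]))
  structure(out, class = "trajectory_summary")
}

#' @export
print.trajectory_summary <- function(x, ...) {
  cat("<trajectory_summary>\n conductance norms (uS):\n")
  print(round(x$conductance$norms, 5))
  cat(" radius:", signif(x$conductance$radius, 5),
      " outside distance:", signif(x$conductance$outside_distance, 5), "\n")
  cat(" half-shift angles (deg): pwp", round(x$angles["pwp"], 1),
      " wpw", round(x$angles["wpw"], 1), "\n")
  invisible(x)
}
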