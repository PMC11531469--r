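## Trajectory analytics for histone recycling at a replication fork:
## contact time series and probabilities, association survival, the
## hub-ring coordinate frame with elevation/azimuth angles, spatial
## densities with iso-surfaces and region overlaps, recycling-pathway
## classification, and destination distances.

group_indices <- function(topology, group) {
  if (is.character(group)) beads_with_tag(topology, group) else as.integer(group)
}

#' Per-frame contact counts between two bead groups
#'
#' Counts, in every frame, the group-a beads having any group-b bead within
#' the cutoff; also exposes the per-frame contacting-bead indicator matrix.
#'
#' @param traj A `cg_trajectory`.
#' @param topology The matching `cg_topology`.
#' @param group_a,group_b Tag names or bead index vectors.
#' @param cutoff Contact cutoff, A (default 10).
#' @return List with `counts` (integer per frame) and `flags`
#'   (frames x length(group_a) logical matrix) and `indices_a`.
#' @export
contact_timeseries <- function(traj, topology, group_a, group_b, cutoff = 10) {
  ia <- group_indices(topology, group_a)
  ib <- group_indices(topology, group_b)
  stopifnot(length(ia) > 0, length(ib) > 0)
  flags <- cpp_contact_flags(traj$frames, as.integer(ia), as.integer(ib), cutoff)
  list(counts = as.integer(rowSums(flags)), flags = flags, indices_a = ia)
}

#' Per-bead contact probability across trajectories
#'
#' Fraction of frames (pooled over runs with equal frame weighting) in which
#' each group-a bead contacts any group-b bead.
#'
#' @param trajs A `cg_trajectory` or list of them.
#' @param topology The matching `cg_topology`.
#' @param group_a,group_b Tag names or bead index vectors.
#' @param cutoff Contact cutoff, A.
#' @return Data frame (bead index, probability).
#' @export
residue_contact_probability <- function(trajs, topology, group_a, group_b,
                                        cutoff = 10) {
  if (inherits(trajs, "cg_trajectory")) trajs <- list(trajs)
  ia <- group_indices(topology, group_a)
  ib <- group_indices(topology, group_b)
  tot <- numeric(length(ia)); nfr <- 0
  for (tr in trajs) {
    flags <- cpp_contact_flags(tr$frames, as.integer(ia), as.integer(ib), cutoff)
    tot <- tot + colSums(flags)
    nfr <- nfr + nrow(flags)
  }
  data.frame(index = ia, probability = tot / nfr)
}

# maximal runs of nonzero counts, merging interruptions shorter than min_gap
episodes_from_counts <- function(counts, min_gap_frames = 0) {
  on <- counts > 0
  if (min_gap_frames > 0 && any(on)) {
    r <- rle(on)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    for (q in seq_along(r$values)) {
      if (!r$values[q] && r$lengths[q] < min_gap_frames &&
          q > 1 && q < length(r$values))
        on[starts[q]:ends[q]] <- TRUE
    }
  }
  if (!any(on)) return(data.frame(start = integer(), end = integer(),
                                  duration = integer()))
  r <- rle(on)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  keep <- which(r$values)
  data.frame(start = starts[keep], end = ends[keep],
             duration = ends[keep] - starts[keep] + 1L)
}

#' Survival curve of association episodes
#'
#' Episodes are maximal runs of nonzero contact count (interruptions shorter
#' than `min_gap_frames` are bridged). S(t) is the fraction of episodes
#' lasting at least t frames; S(0) = 1 and S is non-increasing.
#'
#' @param trajs A `cg_trajectory` or list of them.
#' @param topology The matching `cg_topology`.
#' @param group_a,group_b Tag names or bead index vectors.
#' @param cutoff Contact cutoff, A.
#' @param min_gap_frames Interruptions shorter than this are merged.
#' @return List with `episodes` (data frame: traj, start, end, duration),
#'   `survival` (data frame: t_frames, S) and `defined` (FALSE when no
#'   episode exists anywhere).
#' @export
association_survival <- function(trajs, topology, group_a, group_b,
                                 cutoff = 10, min_gap_frames = 0) {
  if (inherits(trajs, "cg_trajectory")) trajs <- list(trajs)
  eps <- NULL
  for (q in seq_along(trajs)) {
    ct <- contact_timeseries(trajs[[q]], topology, group_a, group_b, cutoff)
    e <- episodes_from_counts(ct$counts, min_gap_frames)
    if (nrow(e)) eps <- rbind(eps, cbind(traj = q, e))
  }
  if (is.null(eps))
    return(list(episodes = data.frame(traj = integer(), start = integer(),
                                      end = integer(), duration = integer()),
                survival = NULL, defined = FALSE))
  ts <- 0:max(eps$duration)
  S <- vapply(ts, function(t) mean(eps$duration >= t), 1)
  list(episodes = eps, survival = data.frame(t_frames = ts, S = S),
       defined = TRUE)
}

#' Define the fork coordinate frame from the hub ring
#'
#' Origin: centre of mass of the ring beads. Z: unit normal of the ring's
#' best-fit plane, oriented toward the designated N-tier side. X: unit
#' projection of (COM(mcm2) - origin) orthogonal to Z. Y = Z x X
#' (right-handed).
#'
#' @param coords N x 3 coordinates.
#' @param ring Bead indices of the hub ring (>= 3, non-collinear).
#' @param mcm2 Bead indices whose COM fixes the X direction.
#' @param ntier Optional bead indices whose COM fixes the +Z side; when
#'   omitted, Z keeps the best-fit normal's arbitrary sign.
#' @return Object of class `fork_frame` with origin, X, Y, Z.
#' @export
define_fork_frame <- function(coords, ring, mcm2, ntier = NULL) {
  rc <- coords[ring, , drop = FALSE]
  if (nrow(rc) < 3) stop("ring selection needs at least 3 beads")
  origin <- colMeans(rc)
  ctr <- rc - matrix(origin, nrow(rc), 3, byrow = TRUE)
  sv <- svd(ctr)
  if (sv$d[2] < 1e-8 * sv$d[1]) stop("ring beads are collinear; frame undefined")
  Z <- sv$v[, 3]
  if (!is.null(ntier)) {
    side <- colMeans(coords[ntier, , drop = FALSE]) - origin
    if (sum(side * Z) < 0) Z <- -Z
  }
  xr <- colMeans(coords[mcm2, , drop = FALSE]) - origin
  X <- xr - sum(xr * Z) * Z
  nx <- sqrt(sum(X^2))
  if (nx < 1e-8) stop("mcm2 COM lies on the ring axis; X undefined")
  X <- X / nx
  Y <- c(Z[2] * X[3] - Z[3] * X[2], Z[3] * X[1] - Z[1] * X[3],
         Z[1] * X[2] - Z[2] * X[1])
  structure(list(origin = origin, X = X, Y = Y, Z = Z), class = "fork_frame")
}

#' Elevation and azimuth of a point in a fork frame
#'
#' With v = point - origin: elevation phi = atan2(v.Z, v.X) (angle to the
#' X-axis in the X-Z plane) and azimuth theta = atan2(v.Y, v.X) (angle to
#' the X-axis in the X-Y plane), both in degrees in (-180, 180].
#'
#' @param frame A [define_fork_frame()] result.
#' @param point Length-3 coordinate.
#' @return List with `elevation_phi` and `azimuth_theta` (degrees).
#' @export
orientation_angles <- function(frame, point) {
  v <- point - frame$origin
  if (sqrt(sum(v^2)) < 1e-12) stop("point coincides with the frame origin")
  list(elevation_phi = atan2(sum(v * frame$Z), sum(v * frame$X)) * 180 / pi,
       azimuth_theta = atan2(sum(v * frame$Y), sum(v * frame$X)) * 180 / pi)
}

#' Per-frame orientation angles of a tagged group's centre of mass
#'
#' @param traj A `cg_trajectory`.
#' @param topology The matching `cg_topology`.
#' @param point_group Tag or indices of the tracked group (COM is used).
#' @param ring,mcm2,ntier Frame-defining selections (tags or indices).
#' @return Data frame (frame, elevation_phi, azimuth_theta).
#' @export
angles_timeseries <- function(traj, topology, point_group,
                              ring = "hub_ring", mcm2 = "Mcm2_ring",
                              ntier = "hub_ntier") {
  ip <- group_indices(topology, point_group)
  ir <- group_indices(topology, ring)
  im <- group_indices(topology, mcm2)
  it <- if (is.null(ntier)) NULL else group_indices(topology, ntier)
  nf <- n_frames(traj)
  out <- data.frame(frame = seq_len(nf), elevation_phi = NA_real_,
                    azimuth_theta = NA_real_)
  for (f in seq_len(nf)) {
    xyz <- traj_frame(traj, f)
    fr <- define_fork_frame(xyz, ir, im, it)
    an <- orientation_angles(fr, colMeans(xyz[ip, , drop = FALSE]))
    out$elevation_phi[f] <- an$elevation_phi
    out$azimuth_theta[f] <- an$azimuth_theta
  }
  out
}

#' Circular mean and standard deviation of angles in degrees
#'
#' @param deg Angles in degrees.
#' @return List with `mean` and `sd`, both degrees; the mean is in
#'   (-180, 180].
#' @export
circular_stats <- function(deg) {
  a <- deg * pi / 180
  C <- mean(cos(a)); S <- mean(sin(a))
  R <- sqrt(C^2 + S^2)
  list(mean = atan2(S, C) * 180 / pi,
       sd = sqrt(-2 * log(max(R, 1e-12))) * 180 / pi)
}

#' Histogram a point cloud into a normalised 3-D density
#'
#' @param points M x 3 matrix of points (frame-local coordinates).
#' @param grid_spacing Voxel edge, A.
#' @param extent Optional list(x, y, z) of c(lo, hi) ranges; derived from the
#'   data (padded by one voxel) when omitted.
#' @return Object of class `density3d`: axis centres, the density array
#'   (integrates to 1 over the grid when all points fall inside), the voxel
#'   volume and the point count.
#' @export
density_grid <- function(points, grid_spacing = 5, extent = NULL) {
  stopifnot(nrow(points) >= 1)
  if (is.null(extent)) {
    extent <- lapply(1:3, function(k)
      c(floor(min(points[, k]) - grid_spacing),
        ceiling(max(points[, k]) + grid_spacing)))
    names(extent) <- c("x", "y", "z")
  }
  brk <- lapply(extent, function(e) seq(e[1], e[2] + grid_spacing - 1e-9,
                                        by = grid_spacing))
  nb <- vapply(brk, length, 1L) - 1L
  ix <- findInterval(points[, 1], brk$x, rightmost.closed = TRUE)
  iy <- findInterval(points[, 2], brk$y, rightmost.closed = TRUE)
  iz <- findInterval(points[, 3], brk$z, rightmost.closed = TRUE)
  ok <- ix >= 1 & ix <= nb[1] & iy >= 1 & iy <= nb[2] & iz >= 1 & iz <= nb[3]
  counts <- array(0, nb)
  for (q in which(ok))
    counts[ix[q], iy[q], iz[q]] <- counts[ix[q], iy[q], iz[q]] + 1
  vv <- grid_spacing^3
  structure(list(
    x = (head(brk$x, -1) + tail(brk$x, -1)) / 2,
    y = (head(brk$y, -1) + tail(brk$y, -1)) / 2,
    z = (head(brk$z, -1) + tail(brk$z, -1)) / 2,
    breaks = brk,
    density = counts / (nrow(points) * vv),
    voxel_volume = vv, n_points = nrow(points),
    grid_spacing = grid_spacing), class = "density3d")
}

#' Spatial density of a tracked point in the per-frame fork frame
#'
#' Expresses the tracked group's COM in the frame computed from each
#' snapshot, pools the points over trajectories and histograms them.
#'
#' @param trajs A `cg_trajectory` or list of them.
#' @param topology The matching `cg_topology`.
#' @param point_group Tag or indices of the tracked group.
#' @param ring,mcm2,ntier Frame-defining selections.
#' @param grid_spacing Voxel edge, A (default 5).
#' @param extent Optional fixed grid extent (needed to compare densities).
#' @return A `density3d`.
#' @export
spatial_density <- function(trajs, topology, point_group,
                            ring = "hub_ring", mcm2 = "Mcm2_ring",
                            ntier = "hub_ntier", grid_spacing = 5,
                            extent = NULL) {
  if (inherits(trajs, "cg_trajectory")) trajs <- list(trajs)
  ip <- group_indices(topology, point_group)
  stopifnot(length(ip) > 0)
  ir <- group_indices(topology, ring)
  im <- group_indices(topology, mcm2)
  it <- if (is.null(ntier)) NULL else group_indices(topology, ntier)
  pts <- NULL
  for (tr in trajs) {
    for (f in seq_len(n_frames(tr))) {
      xyz <- traj_frame(tr, f)
      fr <- define_fork_frame(xyz, ir, im, it)
      v <- colMeans(xyz[ip, , drop = FALSE]) - fr$origin
      pts <- rbind(pts, c(sum(v * fr$X), sum(v * fr$Y), sum(v * fr$Z)))
    }
  }
  density_grid(pts, grid_spacing, extent)
}

#' Iso-surface mesh of a 3-D density
#'
#' Extracts the polygon mesh bounding the super-level set
#' \{density >= level\}: the quadrilateral faces between voxels inside and
#' outside the set (a voxel-boundary mesh on the histogram grid).
#'
#' @param density A `density3d`.
#' @param level Iso-level in A^-3 (default 1e-4).
#' @return List with `vertices` (V x 3) and `faces` (F x 4 vertex indices),
#'   plus the enclosed `volume` (A^3).
#' @export
iso_surface <- function(density, level = 1e-4) {
  d <- density$density >= level
  nb <- dim(d)
  verts <- list(); vkey <- new.env(hash = TRUE)
  faces <- list()
  brk <- density$breaks
  vid <- function(i, j, k) {
    key <- paste(i, j, k, sep = ",")
    id <- vkey[[key]]
    if (is.null(id)) {
      verts[[length(verts) + 1]] <<- c(brk$x[i], brk$y[j], brk$z[k])
      id <- length(verts)
      vkey[[key]] <- id
    }
    id
  }
  inside <- function(i, j, k) {
    i >= 1 && i <= nb[1] && j >= 1 && j <= nb[2] && k >= 1 && k <= nb[3] &&
      d[i, j, k]
  }
  for (i in seq_len(nb[1])) for (j in seq_len(nb[2])) for (k in seq_len(nb[3])) {
    if (!d[i, j, k]) next
    if (!inside(i - 1, j, k))
      faces[[length(faces) + 1]] <- c(vid(i, j, k), vid(i, j + 1, k),
                                      vid(i, j + 1, k + 1), vid(i, j, k + 1))
    if (!inside(i + 1, j, k))
      faces[[length(faces) + 1]] <- c(vid(i + 1, j, k), vid(i + 1, j + 1, k),
                                      vid(i + 1, j + 1, k + 1), vid(i + 1, j, k + 1))
    if (!inside(i, j - 1, k))
      faces[[length(faces) + 1]] <- c(vid(i, j, k), vid(i + 1, j, k),
                                      vid(i + 1, j, k + 1), vid(i, j, k + 1))
    if (!inside(i, j + 1, k))
      faces[[length(faces) + 1]] <- c(vid(i, j + 1, k), vid(i + 1, j + 1, k),
                                      vid(i + 1, j + 1, k + 1), vid(i, j + 1, k + 1))
    if (!inside(i, j, k - 1))
      faces[[length(faces) + 1]] <- c(vid(i, j, k), vid(i + 1, j, k),
                                      vid(i + 1, j + 1, k), vid(i, j + 1, k))
    if (!inside(i, j, k + 1))
      faces[[length(faces) + 1]] <- c(vid(i, j, k + 1), vid(i + 1, j, k + 1),
                                      vid(i + 1, j + 1, k + 1), vid(i, j + 1, k + 1))
  }
  list(vertices = do.call(rbind, verts),
       faces = do.call(rbind, faces),
       volume = sum(d) * density$voxel_volume,
       level = level)
}

#' Volume of a density's super-level set
#'
#' @param density A `density3d`.
#' @param level Iso-level, A^-3.
#' @return Volume in A^3.
#' @export
superlevel_volume <- function(density, level) {
  sum(density$density >= level) * density$voxel_volume
}

#' Overlap fraction of two density regions
#'
#' Fraction vol(A and B)/vol(reference) of the super-level sets of two
#' densities on the same grid. The intersection volume is symmetric in the
#' two sets; the denominator is the chosen reference set.
#'
#' @param a,b `density3d` objects on identical grids.
#' @param level Iso-level, A^-3.
#' @param reference `"a"` or `"b"`: whose volume is the denominator.
#' @return Overlap fraction in \[0, 1\].
#' @export
overlap_fraction <- function(a, b, level, reference = c("a", "b")) {
  reference <- match.arg(reference)
  if (!identical(dim(a$density), dim(b$density)))
    stop("densities must share one grid (fix `extent` in spatial_density)")
  A <- a$density >= level
  B <- b$density >= level
  inter <- sum(A & B)
  ref <- if (reference == "a") sum(A) else sum(B)
  if (ref == 0) return(0)
  inter / ref
}

#' Classifier thresholds for recycling detection
#'
#' @param cutoff Bead-bead contact cutoff, A.
#' @param n_dep Minimum cargo beads in contact with one duplex group.
#' @param t_dep Minimum consecutive frames above `n_dep` (deposition dwell).
#' @param n_tail Maximum cargo-donor-tail contacts during deposition.
#' @param n_car Cargo-carrier contacts defining a carrier visit.
#' @param window Frames before deposition searched for a carrier visit.
#' @return Named list of thresholds.
#' @export
recycling_thresholds <- function(cutoff = 10, n_dep = 30, t_dep = 50,
                                 n_tail = 5, n_car = 10, window = 200) {
  list(cutoff = cutoff, n_dep = n_dep, t_dep = t_dep, n_tail = n_tail,
       n_car = n_car, window = window)
}

#' Classify the recycling outcome of one trajectory
#'
#' Deposition is detected when the cargo's contact count with a single
#' duplex group stays at or above `n_dep` for at least `t_dep` consecutive
#' frames while donor-tail contacts stay at or below `n_tail`. The
#' destination is that duplex group (parental allowed). The pathway is
#' carrier-mediated iff the cargo-carrier contact count reaches `n_car` in
#' any frame within `window` frames preceding deposition.
#'
#' @param traj A `cg_trajectory`.
#' @param topology The matching `cg_topology`.
#' @param thresholds A [recycling_thresholds()].
#' @param tags Tag names of the cargo, carrier, donor tail and candidate
#'   destination duplex groups.
#' @return A `recycling_outcome`: destination (leading/lagging/parental/
#'   none), carrier_mediated (logical, NA when no deposition),
#'   deposition_step, deposition_frame, dyad_nt_from_junction,
#'   junction_distance_A.
#' @export
classify_recycling <- function(traj, topology,
                               thresholds = recycling_thresholds(),
                               tags = list(cargo = "H3H4", carrier = "Cdc45",
                                           tail = "Mcm2_Ntail",
                                           duplexes = c("leading_duplex",
                                                        "lagging_duplex",
                                                        "parental_duplex"))) {
  for (tg in c(tags$cargo, tags$carrier, tags$tail, tags$duplexes))
    if (!tg %in% names(topology$tags)) stop("missing tag: ", tg)
  th <- thresholds
  dup_counts <- lapply(tags$duplexes, function(tg)
    contact_timeseries(traj, topology, tags$cargo, tg, th$cutoff)$counts)
  names(dup_counts) <- tags$duplexes
  tail_counts <- contact_timeseries(traj, topology, tags$cargo, tags$tail,
                                    th$cutoff)$counts
  car_counts <- contact_timeseries(traj, topology, tags$cargo, tags$carrier,
                                   th$cutoff)$counts
  nf <- n_frames(traj)
  best <- NULL
  for (tg in tags$duplexes) {
    ok <- dup_counts[[tg]] >= th$n_dep & tail_counts <= th$n_tail
    r <- rle(ok)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    hit <- which(r$values & r$lengths >= th$t_dep)
    if (length(hit)) {
      f0 <- starts[hit[1]]
      if (is.null(best) || f0 < best$frame ||
          (f0 == best$frame && dup_counts[[tg]][f0] > best$count))
        best <- list(tag = tg, frame = f0, count = dup_counts[[tg]][f0])
    }
  }
  if (is.null(best)) {
    return(structure(list(destination = "none", carrier_mediated = NA,
                          deposition_step = NA_integer_,
                          deposition_frame = NA_integer_,
                          dyad_nt_from_junction = NA_integer_,
                          junction_distance_A = NA_real_),
                     class = "recycling_outcome"))
  }
  w0 <- max(1, best$frame - th$window)
  mediated <- any(car_counts[w0:best$frame] >= th$n_car)
  dep_xyz <- traj_frame(traj, best$frame)
  dyad <- dyad_distance_nt(dep_xyz, topology, best$tag, tags$cargo, th$cutoff)
  structure(list(
    destination = sub("_duplex$", "", best$tag),
    carrier_mediated = mediated,
    deposition_step = if (length(traj$step_ids)) traj$step_ids[best$frame] else best$frame,
    deposition_frame = best$frame,
    dyad_nt_from_junction = dyad,
    junction_distance_A = junction_distance_3d(dep_xyz, topology, tags$cargo)),
    class = "recycling_outcome")
}

#' @export
print.recycling_outcome <- function(x, ...) {
  cat(sprintf("recycling outcome: %s (%s)%s\n", x$destination,
              if (is.na(x$carrier_mediated)) "n/a"
              else if (x$carrier_mediated) "carrier-mediated" else "unmediated",
              if (!is.na(x$dyad_nt_from_junction))
                sprintf(", dyad %d nt from junction", x$dyad_nt_from_junction)
              else ""))
  invisible(x)
}

#' Destination distance of the recycled tetrasome in nucleotides
#'
#' The dyad is the median distance-from-junction among destination-strand
#' nucleotides having any site bead within the cutoff of the cargo; the
#' result is that dyad's distance from the fork junction in nucleotides
#' (counting through any single-stranded gap).
#'
#' @param coords Coordinates at the deposition frame.
#' @param topology The matching `cg_topology` (nucleotides must carry
#'   `nt_from_junction` annotations).
#' @param destination Tag of the destination duplex group.
#' @param cargo Tag or indices of the cargo.
#' @param cutoff Footprint contact cutoff, A.
#' @return Integer nucleotide distance.
#' @export
dyad_distance_nt <- function(coords, topology, destination, cargo, cutoff = 10) {
  idx <- group_indices(topology, destination)
  ic <- group_indices(topology, cargo)
  cxyz <- coords[ic, , drop = FALSE]
  hit <- vapply(idx, function(q)
    min(rowSums((cxyz - matrix(coords[q, ], nrow(cxyz), 3, byrow = TRUE))^2)) <
      cutoff^2, TRUE)
  nts <- topology$beads$nt_from_junction[idx[hit]]
  nts <- nts[!is.na(nts)]
  if (!length(nts)) stop("empty cargo footprint on ", destination)
  as.integer(round(median(nts)))
}

#' 3-D distance from the fork junction to the cargo
#'
#' Euclidean distance from the cargo's centre of mass to the midpoint of the
#' junction base pair.
#'
#' @param coords N x 3 coordinates.
#' @param topology The matching `cg_topology` (with a junction bead).
#' @param cargo Tag or indices of the cargo.
#' @return Distance in A.
#' @export
junction_distance_3d <- function(coords, topology, cargo) {
  if (is.na(topology$junction_index)) stop("topology has no designated junction")
  j1 <- topology$junction_index
  b <- topology$beads
  j2 <- which(b$site_kind == "base" & !is.na(b$nt_from_junction) &
                b$nt_from_junction == b$nt_from_junction[j1] &
                b$chain_id != b$chain_id[j1] &
                grepl("^parental", b$chain_id))
  jmid <- if (length(j2)) (coords[j1, ] + coords[j2[1], ]) / 2 else coords[j1, ]
  ic <- group_indices(topology, cargo)
  com <- colMeans(coords[ic, , drop = FALSE])
  sqrt(sum((com - jmid)^2))
}
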