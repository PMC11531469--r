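# static multi-frame trajectory from a list of coordinate matrices
traj_from_coords <- function(coord_list) {
  n <- nrow(coord_list[[1]])
  fr <- array(NA_real_, c(length(coord_list), n, 3))
  for (f in seq_along(coord_list)) fr[f, , ] <- coord_list[[f]]
  cgfork:::new_trajectory(fr, seq_along(coord_list), numeric(0), numeric(0),
                          NULL, list())
}

test_that("contact time series counts group-a beads near group-b and exposes index sets", {
  topo <- bare_beads(4)
  topo <- add_tag(topo, "a", 1:2)
  topo <- add_tag(topo, "b", 3:4)
  near <- rbind(c(0, 0, 0), c(0, 30, 0), c(5, 0, 0), c(50, 50, 50))
  tr <- traj_from_coords(list(near, near, near))
  ct <- contact_timeseries(tr, topo, "a", "b", cutoff = 10)
  expect_equal(ct$counts, c(1L, 1L, 1L))
  expect_equal(unname(ct$flags[1, ]), c(TRUE, FALSE))
  allfar <- near; allfar[1:2, ] <- allfar[1:2, ] + 500
  expect_equal(contact_timeseries(traj_from_coords(list(allfar)), topo,
                                  "a", "b", 10)$counts, 0L)
  expect_error(contact_timeseries(tr, topo, "nope", "b", 10), "unknown tag")
})

test_that("a scripted approach gives a non-decreasing contact count up to its plateau", {
  topo <- bare_beads(11)
  topo <- add_tag(topo, "mob", 1:10)
  topo <- add_tag(topo, "fix", 11L)
  frames <- lapply(seq(60, 0, by = -6), function(d) {
    x <- cbind(seq(0, 27, by = 3) + d, 0, 0)
    rbind(x, c(0, 0, 0))
  })
  ct <- contact_timeseries(traj_from_coords(frames), topo, "mob", "fix", 10)
  expect_true(all(diff(ct$counts) >= 0))
  expect_equal(max(ct$counts), sum(seq(0, 27, by = 3) < 10))
})

test_that("per-bead contact probabilities are exact on constructed fixtures", {
  topo <- bare_beads(3)
  topo <- add_tag(topo, "a", 1:2)
  topo <- add_tag(topo, "b", 3L)
  inc <- rbind(c(5, 0, 0), c(100, 0, 0), c(0, 0, 0))
  outc <- rbind(c(50, 0, 0), c(100, 0, 0), c(0, 0, 0))
  tr <- traj_from_coords(list(inc, outc, inc, outc))
  pr <- residue_contact_probability(tr, topo, "a", "b", 10)
  expect_equal(pr$probability, c(0.5, 0.0))
  # pooled over two runs with equal frame weighting
  pr2 <- residue_contact_probability(list(tr, traj_from_coords(list(inc))),
                                     topo, "a", "b", 10)
  expect_equal(pr2$probability, c(3 / 5, 0))
})

test_that("survival curve identities: single episode, S(0)=1, non-increasing", {
  counts <- c(rep(0, 5), rep(3, 100), rep(0, 7))
  ep <- cgfork:::episodes_from_counts(counts)
  expect_equal(nrow(ep), 1)
  expect_equal(ep$duration, 100L)
  topo <- bare_beads(2)
  topo <- add_tag(topo, "a", 1L)
  topo <- add_tag(topo, "b", 2L)
  frames <- lapply(counts, function(k)
    rbind(c(0, 0, 0), if (k > 0) c(5, 0, 0) else c(500, 0, 0)))
  surv <- association_survival(traj_from_coords(frames), topo, "a", "b", 10)
  S <- surv$survival
  expect_equal(S$S[S$t_frames == 0], 1)
  expect_true(all(S$S[S$t_frames <= 100 & S$t_frames >= 1] == 1))
  expect_true(all(diff(S$S) <= 0))
  expect_equal(surv$episodes$duration, 100L)
})

test_that("short interruptions merge below min_gap_frames; none -> undefined flag", {
  counts <- c(rep(2, 20), 0, 0, rep(2, 20))
  expect_equal(nrow(cgfork:::episodes_from_counts(counts, min_gap_frames = 0)), 2)
  merged <- cgfork:::episodes_from_counts(counts, min_gap_frames = 3)
  expect_equal(nrow(merged), 1)
  expect_equal(merged$duration, 42L)
  topo <- bare_beads(2)
  topo <- add_tag(topo, "a", 1L)
  topo <- add_tag(topo, "b", 2L)
  far <- traj_from_coords(list(rbind(c(0, 0, 0), c(900, 0, 0))))
  surv <- association_survival(far, topo, "a", "b", 10)
  expect_false(surv$defined)
  expect_equal(nrow(surv$episodes), 0)
})

test_that("episode durations recover the mean of an exponential generator", {
  set.seed(8)
  lambda <- 1 / 20
  durs <- pmax(1, round(stats::rexp(500, lambda)))
  counts <- unlist(lapply(durs, function(d) c(rep(1, d), 0, 0)))
  ep <- cgfork:::episodes_from_counts(counts)
  expect_equal(nrow(ep), 500)
  expect_lt(abs(mean(ep$duration) - mean(durs)), 1e-9)
  expect_lt(abs(mean(ep$duration) - 1 / lambda) / (1 / lambda), 0.1)
})

test_that("the fork frame axes follow the ring plane, the hub side, and the Mcm2 direction", {
  th <- seq(0, 2 * pi, length.out = 37)[-37]
  ring <- cbind(30 * cos(th), 30 * sin(th), 0)
  mcm2 <- rbind(c(40, 0, 0), c(44, 0, 2))
  ntier <- rbind(c(0, 0, 10))
  coords <- rbind(ring, mcm2, ntier)
  fr <- define_fork_frame(coords, 1:36, 37:38, 39)
  expect_equal(fr$Z, c(0, 0, 1), tolerance = 1e-9)
  expect_equal(fr$X, c(1, 0, 0), tolerance = 1e-9)
  expect_equal(fr$Y, c(0, 1, 0), tolerance = 1e-9)
  expect_equal(fr$origin, c(0, 0, 0), tolerance = 1e-9)
})

test_that("the fork frame is equivariant under rigid rotation", {
  th <- seq(0, 2 * pi, length.out = 25)[-25]
  coords <- rbind(cbind(30 * cos(th), 30 * sin(th), 0), c(40, 5, 0), c(0, 0, 8))
  fr <- define_fork_frame(coords, 1:24, 25, 26)
  rt <- random_rototranslation(5)
  fr2 <- define_fork_frame(apply_rt(coords, rt), 1:24, 25, 26)
  expect_equal(fr2$X, as.numeric(rt$R %*% fr$X), tolerance = 1e-9)
  expect_equal(fr2$Y, as.numeric(rt$R %*% fr$Y), tolerance = 1e-9)
  expect_equal(fr2$Z, as.numeric(rt$R %*% fr$Z), tolerance = 1e-9)
  # degenerate ring: collinear beads
  line <- cbind(1:12, 0, 0)
  expect_error(define_fork_frame(rbind(line, c(0, 5, 0)), 1:12, 13), "collinear")
})

test_that("plane fitting tolerates small out-of-plane noise (within 2 degrees at 1 A SD)", {
  th <- seq(0, 2 * pi, length.out = 61)[-61]
  set.seed(12)
  ring <- cbind(35 * cos(th), 35 * sin(th), rnorm(60, 0, 1))
  coords <- rbind(ring, c(45, 0, 0), c(0, 0, 9))
  fr <- define_fork_frame(coords, 1:60, 61, 62)
  ang <- acos(abs(sum(fr$Z * c(0, 0, 1)))) * 180 / pi
  expect_lt(ang, 2)
})

test_that("elevation and azimuth angle identities hold", {
  fr <- structure(list(origin = c(0, 0, 0), X = c(1, 0, 0), Y = c(0, 1, 0),
                       Z = c(0, 0, 1)), class = "fork_frame")
  a <- orientation_angles(fr, c(5, 0, 0))
  expect_equal(c(a$elevation_phi, a$azimuth_theta), c(0, 0))
  expect_equal(orientation_angles(fr, c(0, 0, 7))$elevation_phi, 90)
  d <- orientation_angles(fr, c(1, 1, 0) / sqrt(2))
  expect_equal(d$azimuth_theta, 45)
  expect_equal(d$elevation_phi, 0)
  expect_error(orientation_angles(fr, c(0, 0, 0)), "origin")
})

test_that("circular statistics handle distributions straddling the 180-degree cut", {
  x <- c(175, -175, 170, -170)
  cs <- circular_stats(x)
  expect_equal(abs(cs$mean), 180, tolerance = 1e-6)
  expect_lt(cs$sd, 10)
})

test_that("densities normalise to one and concentrate mass correctly", {
  pts <- matrix(rep(c(1.2, 2.3, -0.7), 50), ncol = 3, byrow = TRUE)
  d <- density_grid(pts, grid_spacing = 5)
  expect_equal(sum(d$density) * d$voxel_volume, 1, tolerance = 1e-9)
  expect_equal(sum(d$density > 0), 1)
  # uniform box: per-voxel density ~ 1/volume
  set.seed(3)
  u <- cbind(runif(20000, 0, 20), runif(20000, 0, 20), runif(20000, 0, 20))
  du <- density_grid(u, grid_spacing = 5, extent = list(x = c(0, 20),
                                                        y = c(0, 20),
                                                        z = c(0, 20)))
  expect_equal(sum(du$density) * du$voxel_volume, 1, tolerance = 1e-9)
  inner <- du$density[2:3, 2:3, 2:3]
  expect_lt(max(abs(inner - 1 / 8000)) / (1 / 8000), 0.25)
})

test_that("Gaussian cloud super-level volume matches the closed form within 5%", {
  set.seed(9)
  s <- 6
  n <- 8e4
  pts <- matrix(rnorm(3 * n, 0, s), ncol = 3)
  d <- density_grid(pts, grid_spacing = 3,
                    extent = list(x = c(-24, 24), y = c(-24, 24), z = c(-24, 24)))
  lev <- 1e-4  # A^-3, the iso-level used for the spatial maps
  # analytic: density rho(r) = (2 pi s^2)^(-3/2) exp(-r^2/(2 s^2)) >= lev
  rho0 <- (2 * pi * s^2)^(-1.5)
  r2 <- -2 * s^2 * log(lev / rho0)
  vol_analytic <- 4 / 3 * pi * r2^1.5
  expect_lt(abs(superlevel_volume(d, lev) - vol_analytic) / vol_analytic, 0.05)
})

test_that("iso-surface meshes enclose the super-level set and overlaps are symmetric", {
  pts <- matrix(rep(c(0, 0, 0), 10), ncol = 3, byrow = TRUE)
  ext <- list(x = c(-10, 10), y = c(-10, 10), z = c(-10, 10))
  d1 <- density_grid(pts, 5, ext)
  mesh <- iso_surface(d1, 1e-9)
  expect_equal(nrow(mesh$faces), 6)   # one voxel -> cube
  expect_equal(mesh$volume, 125)
  pts2 <- rbind(pts, matrix(rep(c(6, 0, 0), 10), ncol = 3, byrow = TRUE))
  d2 <- density_grid(pts2, 5, ext)
  ov_ab <- overlap_fraction(d1, d2, 1e-9, reference = "a")
  ov_ba <- overlap_fraction(d2, d1, 1e-9, reference = "b")
  expect_equal(ov_ab, 1)      # d1's voxel is inside d2's set
  expect_equal(ov_ab, ov_ba)  # same intersection, same reference volume
  expect_gte(ov_ab, 0); expect_lte(ov_ab, 1)
})

test_that("spatial densities of a tracked group integrate to one on the toy system", {
  lab <- generate_labeled_trajectories("leading-mediated", n_per_scenario = 1,
                                      seed = 2, n_frames = 40)
  d <- spatial_density(lab$trajectories[[1]], lab$topology, "H3H4",
                       grid_spacing = 5)
  expect_equal(sum(d$density) * d$voxel_volume, 1, tolerance = 1e-9)
})

test_that("dyad and junction distances follow their definitions", {
  fk <- assemble_fork(6, 30, 30, 0, 0, seed = 3)
  topo <- fk$topology
  b <- topo$beads
  lead <- beads_with_tag(topo, "leading_duplex")
  # synthetic cargo: one bead placed on the leading arm at a known nucleotide
  target_nt <- 13
  sel <- lead[!is.na(b$nt_from_junction[lead]) &
                b$nt_from_junction[lead] %in% (target_nt - 2):(target_nt + 2)]
  cargo_xyz <- colMeans(fk$coords[sel, , drop = FALSE])
  topo2 <- topo
  topo2$beads <- rbind(topo2$beads, data.frame(
    index = nrow(b) + 1L, chain_id = "cargo", site_kind = "residue",
    name = "K", charge = 1, radius = 2.5, nt_index = NA_integer_,
    nt_from_junction = NA_integer_))
  topo2$chains <- rbind(topo2$chains, data.frame(
    chain_id = "cargo", molecule_class = "protein",
    first = nrow(b) + 1L, last = nrow(b) + 1L))
  topo2 <- add_tag(topo2, "H3H4", nrow(b) + 1L)
  coords <- rbind(fk$coords, cargo_xyz)
  dy <- dyad_distance_nt(coords, topo2, "leading_duplex", "H3H4", cutoff = 12)
  expect_lt(abs(dy - target_nt), 2)
  # symmetric footprint: median recovers the centre exactly
  nts <- b$nt_from_junction[lead]
  sel21 <- lead[!is.na(nts) & nts %in% (target_nt - 10):(target_nt + 10) &
                  b$chain_id[lead] == "leading_1"]
  expect_equal(as.integer(round(median(b$nt_from_junction[sel21]))), target_nt)
  # junction distance: cargo at a known offset from the junction midpoint
  j1 <- topo$junction_index
  b2 <- which(b$site_kind == "base" & b$nt_from_junction == 0 &
                b$chain_id == "parental_2")
  jmid <- (fk$coords[j1, ] + fk$coords[b2, ]) / 2
  coords[nrow(coords), ] <- jmid + c(150, 0, 0)
  expect_equal(junction_distance_3d(coords, topo2, "H3H4"), 150,
               tolerance = 1e-9)
  coords[nrow(coords), ] <- jmid
  expect_equal(junction_distance_3d(coords, topo2, "H3H4"), 0, tolerance = 1e-9)
  # translation invariance
  coords2 <- coords + matrix(c(11, -4, 7), nrow(coords), 3, byrow = TRUE)
  expect_equal(junction_distance_3d(coords2, topo2, "H3H4"), 0, tolerance = 1e-9)
  # empty footprint errors
  coords[nrow(coords), ] <- jmid + c(500, 500, 500)
  expect_error(dyad_distance_nt(coords, topo2, "leading_duplex", "H3H4", 10),
               "empty")
})

test_that("the classifier reports held cargo as no deposition", {
  lab <- generate_labeled_trajectories("none", n_per_scenario = 1, seed = 5,
                                      n_frames = 80)
  oc <- classify_recycling(lab$trajectories[[1]], lab$topology,
                           recycling_thresholds(t_dep = 20))
  expect_equal(oc$destination, "none")
  expect_true(is.na(oc$carrier_mediated))
  expect_true(is.na(oc$dyad_nt_from_junction))
})

test_that("scripted mediated and unmediated handovers classify with full annotation", {
  lab <- generate_labeled_trajectories(c("leading-mediated", "lagging-unmediated"),
                                      n_per_scenario = 1, seed = 6)
  oc1 <- classify_recycling(lab$trajectories[[1]], lab$topology)
  expect_equal(oc1$destination, "leading")
  expect_true(oc1$carrier_mediated)
  expect_false(is.na(oc1$dyad_nt_from_junction))
  expect_gt(oc1$junction_distance_A, 0)
  oc2 <- classify_recycling(lab$trajectories[[2]], lab$topology)
  expect_equal(oc2$destination, "lagging")
  expect_false(oc2$carrier_mediated)
  expect_error(classify_recycling(lab$trajectories[[1]], lab$topology,
                                  tags = list(cargo = "missing_tag",
                                              carrier = "Cdc45",
                                              tail = "Mcm2_Ntail",
                                              duplexes = "leading_duplex")),
               "missing tag")
})
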