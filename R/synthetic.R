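## Desk-scale synthetic systems: a toy replisome (hub ring + disordered
## donor tail + acidic-loop carrier + basic cargo + forked DNA + optional
## ssDNA binders) whose tags mirror the real-system labels, a two-chain
## dimer benchmark for binding calibration, and scripted ground-truth
## labelled trajectories for the recycling classifier.

TOY_KBOND <- 20
TOY_KANGLE <- 10
TOY_KDIH <- 1

#' Specification of the toy replisome
#'
#' @param ring_chains Number of hub-ring chains.
#' @param ring_chain_length Beads per ring chain.
#' @param ring_radius Hub-ring radius, A.
#' @param tail_length Donor-tail residues (charged pattern: every 4th
#'   residue K, every 9th E, rest neutral).
#' @param carrier_length Carrier-chain residues; residues 20-35 form the
#'   acidic loop (all E).
#' @param cargo_helices,cargo_helix_length Cargo 4-helix-bundle mimic
#'   (alternate residues K: basic cargo).
#' @param fork Fork geometry: parental/leading/lagging duplex bp and
#'   leading/lagging ssDNA gap nt.
#' @param binder_count ssDNA-occluding rigid binders on the lagging gap
#'   (each lengthens the gap by 10 nt).
#' @param binder_length Beads per binder.
#' @param sigma Global scale of the donor-tail/cargo native contact set.
#' @param seed Build seed; construction is deterministic given the seed.
#' @return Object of class `toy_spec`.
#' @export
toy_spec <- function(ring_chains = 6, ring_chain_length = 60, ring_radius = 35,
                     tail_length = 80, carrier_length = 50,
                     cargo_helices = 4, cargo_helix_length = 15,
                     fork = list(parental_bp = 12, leading_bp = 24,
                                 lagging_bp = 24, leading_gap_nt = 6,
                                 lagging_gap_nt = 8),
                     binder_count = 0, binder_length = 12,
                     sigma = 0.7, seed = 1) {
  stopifnot(ring_chains >= 3, ring_chain_length >= 6, tail_length >= 0,
            binder_count >= 0, binder_count <= 2)
  structure(list(ring_chains = ring_chains, ring_chain_length = ring_chain_length,
                 ring_radius = ring_radius, tail_length = tail_length,
                 carrier_length = carrier_length, cargo_helices = cargo_helices,
                 cargo_helix_length = cargo_helix_length, fork = fork,
                 binder_count = binder_count, binder_length = binder_length,
                 sigma = sigma, seed = seed), class = "toy_spec")
}

# folded chain topology from built coordinates (native-anchored local terms)
chain_topology <- function(coords, chain_id, names1, kb = TOY_KBOND,
                           ka = TOY_KANGLE, kd = TOY_KDIH, folded = TRUE) {
  n <- nrow(coords)
  topo <- new_topology()
  topo$beads <- data.frame(
    index = seq_len(n), chain_id = chain_id, site_kind = "residue",
    name = names1, charge = residue_formal_charge(names1),
    radius = BEAD_RADII[["residue"]], nt_index = NA_integer_,
    nt_from_junction = NA_integer_, stringsAsFactors = FALSE)
  topo$chains <- data.frame(chain_id = chain_id, molecule_class = "protein",
                            first = 1L, last = n, stringsAsFactors = FALSE)
  if (n >= 2) {
    i <- seq_len(n - 1)
    r0 <- sqrt(rowSums((coords[i, , drop = FALSE] - coords[i + 1, , drop = FALSE])^2))
    topo$bonds <- rbind(topo$bonds, cbind(i, i + 1, r0, kb, as.numeric(folded)))
  }
  if (n >= 3) {
    i <- seq_len(n - 2)
    if (folded) {
      th0 <- vapply(i, function(q) bead_angle(coords[q, ], coords[q + 1, ],
                                              coords[q + 2, ]), 1)
      topo$angles <- rbind(topo$angles, cbind(i, i + 1, i + 2, th0, ka, 1))
    } else {
      topo$angles <- rbind(topo$angles,
                           cbind(i, i + 1, i + 2, IDR_THETA0, IDR_KANGLE, 0))
    }
  }
  if (folded && n >= 4) {
    i <- seq_len(n - 3)
    ph0 <- vapply(i, function(q) bead_dihedral(coords[q, ], coords[q + 1, ],
                                               coords[q + 2, ], coords[q + 3, ]), 1)
    topo$dihedrals <- rbind(topo$dihedrals, cbind(i, i + 1, i + 2, i + 3, ph0, kd, 1))
  }
  topo
}

# alpha-helix-like bead path: radius 2.3 A, rise 1.5 A, 100 deg per bead
helix_path <- function(n, origin = c(0, 0, 0), axis = c(0, 0, 1), phase0 = 0) {
  R <- rotation_to(axis)
  q <- seq_len(n) - 1
  local <- cbind(2.3 * cos(phase0 + q * 100 * pi / 180),
                 2.3 * sin(phase0 + q * 100 * pi / 180),
                 1.5 * q)
  local %*% t(R) + matrix(origin, n, 3, byrow = TRUE)
}

#' Build the toy replisome
#'
#' Constructs, deterministically for a given seed, a ring-shaped multi-chain
#' hub, a flexible charged donor tail carrying a basic globular cargo, an
#' acidic-loop carrier chain, a forked DNA with configurable arms and
#' single-stranded gaps, and optional ssDNA binders. Tags mirror the
#' real-system labels (`hub_ring`, `Mcm2_ring`, `Mcm2_Ntail`, `Cdc45`,
#' `Cdc45_acidic_loop`, `H3H4`, `parental_duplex`, `leading_duplex`,
#' `lagging_duplex`, ...) so the fork analytics run unchanged on toy and
#' real systems.
#'
#' @param spec A [toy_spec()].
#' @param components Subset of
#'   `c("ring", "tail", "carrier", "cargo", "fork", "binders")` to include.
#' @return List with `topology`, `coords` and the resolved `spec`.
#' @export
build_toy_replisome <- function(spec = toy_spec(),
                                components = c("ring", "tail", "carrier",
                                               "cargo", "fork", "binders")) {
  with_seed(spec$seed, {
    topo <- new_topology()
    coords <- NULL

    if ("ring" %in% components) {
      L <- spec$ring_chain_length
      a_h <- sqrt(max(0.5, CA_STEP^2 - (2 * pi * spec$ring_radius /
                                          (spec$ring_chains * L))^2))
      for (c in seq_len(spec$ring_chains)) {
        alpha0 <- (c - 1) * 2 * pi / spec$ring_chains
        q <- seq_len(L) - 1
        alpha <- alpha0 + (q + 0.5) * 2 * pi / (spec$ring_chains * L)
        phi <- q * pi / 3
        r <- spec$ring_radius + a_h * cos(phi)
        xyz <- cbind(r * cos(alpha), r * sin(alpha), a_h * sin(phi))
        ct <- chain_topology(xyz, sprintf("ring_%d", c), rep("A", L))
        off <- n_beads(topo)
        topo <- merge_topologies(topo, ct)
        coords <- rbind(coords, xyz)
        topo <- add_tag(topo, "hub_ring", off + seq_len(L))
        if (c == 1) topo <- add_tag(topo, "Mcm2_ring", off + seq_len(L))
        topo <- add_tag(topo, "hub_ntier", off + which(xyz[, 3] > 0.4 * a_h))
      }
      ring_cs <- derive_native_contacts(topo, coords, cutoff = 6.5, sigma = 1,
                                        eps_rule = 0.6, label = "hub_intra")
      topo <- add_contact_set(topo, ring_cs)
    }

    if ("carrier" %in% components) {
      n <- spec$carrier_length
      xyz <- helix_path(n, origin = c(40, 45, 5 - 0.75 * n), axis = c(0, 0, 1))
      loop <- intersect(20:35, seq_len(n))
      nm <- rep("A", n); nm[loop] <- "E"
      ct <- chain_topology(xyz, "carrier", nm)
      off <- n_beads(topo)
      topo <- merge_topologies(topo, ct)
      coords <- rbind(coords, xyz)
      topo <- add_tag(topo, "Cdc45", off + seq_len(n))
      topo <- add_tag(topo, "Cdc45_acidic_loop", off + loop)
    }

    if ("fork" %in% components) {
      fk <- spec$fork
      lag_gap <- fk$lagging_gap_nt + 10 * spec$binder_count
      fork <- assemble_fork(fk$parental_bp, fk$leading_bp, fk$lagging_bp,
                            fk$leading_gap_nt, lag_gap,
                            seed = spec$seed + 101)
      fork$coords <- fork$coords + matrix(c(0, 0, -10), nrow(fork$coords), 3,
                                          byrow = TRUE)
      off <- n_beads(topo)
      topo <- merge_topologies(topo, fork$topology)
      coords <- rbind(coords, fork$coords)
    }

    if ("binders" %in% components && spec$binder_count > 0 &&
        "fork" %in% components && "lagging_ssDNA" %in% names(topo$tags)) {
      ss <- beads_with_tag(topo, "lagging_ssDNA")
      sug <- ss[topo$beads$site_kind[ss] == "sugar"]
      per <- floor(length(sug) / spec$binder_count)
      for (b in seq_len(spec$binder_count)) {
        seg <- sug[((b - 1) * per + 1):min(b * per, length(sug))]
        base <- coords[seg[round(length(seg) / 2)], ]
        xyz <- helix_path(spec$binder_length, origin = base + c(0, 4, 0))
        ct <- chain_topology(xyz, sprintf("binder_%d", b),
                             rep("S", spec$binder_length))
        off <- n_beads(topo)
        topo <- merge_topologies(topo, ct)
        coords <- rbind(coords, xyz)
        topo <- add_tag(topo, "ssdna_binder", off + seq_len(spec$binder_length))
      }
    }

    if ("tail" %in% components && spec$tail_length > 0) {
      anchor_pool <- beads_with_tag(topo, "Mcm2_ring")
      mid <- anchor_pool[seq(round(length(anchor_pool) / 3),
                             round(2 * length(anchor_pool) / 3))]
      anchor <- coords[mid[which.max(coords[mid, 3])], ]
      # obstacles the tail and cargo must stand clear of (contact analyses
      # assume the cargo starts away from carrier and DNA)
      obst_car <- if ("Cdc45" %in% names(topo$tags))
        coords[beads_with_tag(topo, "Cdc45"), , drop = FALSE] else NULL
      dna_idx <- which(topo$beads$site_kind != "residue")
      obst_dna <- if (length(dna_idx)) coords[dna_idx, , drop = FALSE] else NULL
      wps <- NULL
      if (!is.null(obst_dna)) {
        wps <- t(vapply(intersect(c("leading_duplex", "lagging_duplex",
                                    "parental_duplex"), names(topo$tags)),
                        function(tg) deposit_waypoint(topo, coords, tg),
                        numeric(3)))
      }
      min_to <- function(pts, obst) {
        if (is.null(obst) || is.null(pts)) return(Inf)
        min(vapply(seq_len(nrow(pts)), function(q)
          min(rowSums((obst - matrix(pts[q, ], nrow(obst), 3,
                                     byrow = TRUE))^2)), 1))^0.5
      }
      cargo_shape <- NULL
      if ("cargo" %in% components) {
        m <- spec$cargo_helix_length
        hl <- m * 1.5
        for (h in seq_len(spec$cargo_helices)) {
          dx <- 6.5 * ((h - 1) %% 2) - 3.25
          dy <- 6.5 * ((h - 1) %/% 2) - 3.25
          up <- h %% 2 == 1
          cargo_shape <- rbind(cargo_shape, helix_path(
            m, origin = c(dx, dy, if (up) -hl / 2 else hl / 2),
            axis = if (up) c(0, 0, 1) else c(0, 0, -1), phase0 = h * pi / 2))
        }
        cargo_shape <- cargo_shape -
          matrix(colMeans(cargo_shape), nrow(cargo_shape), 3, byrow = TRUE)
      }
      path <- NULL
      for (attempt in 1:200) {
        cand <- matrix(NA_real_, spec$tail_length, 3)
        p <- anchor
        bias <- c(0.55, 0, 0.83)
        dead_end <- FALSE
        for (q in seq_len(spec$tail_length)) {
          placed <- FALSE
          for (try in 1:50) {  # self-avoiding step
            dirv <- 0.3 * bias + rnorm(3, 0, 0.8)
            pn <- p + CA_STEP * dirv / sqrt(sum(dirv^2))
            prev <- cand[seq_len(max(0, q - 2)), , drop = FALSE]
            if (nrow(prev) == 0 ||
                min(rowSums((prev - matrix(pn, nrow(prev), 3,
                                           byrow = TRUE))^2)) >= 9) {
              placed <- TRUE
              break
            }
          }
          if (!placed) { dead_end <- TRUE; break }
          p <- pn
          cand[q, ] <- p
        }
        if (dead_end) next
        cargo_pts <- if (is.null(cargo_shape)) NULL else
          cargo_shape + matrix(cand[spec$tail_length, ] + c(8, 0, 4),
                               nrow(cargo_shape), 3, byrow = TRUE)
        cargo_clear <- is.null(cargo_pts) ||
          min_to(cargo_pts, cand) >= 3.0   # tail may touch, not overlap
        if (cargo_clear &&
            min_to(cand, obst_car) >= 16 && min_to(cand, obst_dna) >= 16 &&
            min_to(cand, wps) >= 30 &&
            min_to(cargo_pts, obst_car) >= 30 &&
            min_to(cargo_pts, obst_dna) >= 30) {
          path <- cand
          break
        }
      }
      if (is.null(path))
        stop("could not place the donor tail clear of carrier/DNA after 200 attempts")
      nm <- ifelse(seq_len(spec$tail_length) %% 4 == 1, "K",
                   ifelse(seq_len(spec$tail_length) %% 9 == 0, "E", "G"))
      ct <- chain_topology(path, "tail", nm, folded = FALSE)
      off <- n_beads(topo)
      topo <- merge_topologies(topo, ct)
      coords <- rbind(coords, path)
      topo <- add_tag(topo, "Mcm2_Ntail", off + seq_len(spec$tail_length))
      topo <- add_tag(topo, "tail_tip",
                      off + seq(max(1, spec$tail_length - 7), spec$tail_length))

      if ("cargo" %in% components) {
        xyz <- cargo_shape + matrix(path[spec$tail_length, ] + c(8, 0, 4),
                                    nrow(cargo_shape), 3, byrow = TRUE)
        n <- nrow(xyz)
        nm <- ifelse(seq_len(n) %% 2 == 1, "K", "A")
        ct <- chain_topology(xyz, "cargo", nm)
        off <- n_beads(topo)
        topo <- merge_topologies(topo, ct)
        coords <- rbind(coords, xyz)
        topo <- add_tag(topo, "H3H4", off + seq_len(n))
        cargo_cs <- derive_native_contacts(topo, coords, cutoff = 6.5,
                                           sigma = 1, eps_rule = 0.3,
                                           label = "cargo_intra",
                                           between = list("H3H4", "H3H4"))
        topo <- add_contact_set(topo, cargo_cs)
        cross <- derive_native_contacts(topo, coords, cutoff = 10,
                                        sigma = spec$sigma, eps_rule = 0.3,
                                        label = "Mcm2_H3H4",
                                        between = list("tail_tip", "H3H4"))
        topo <- add_contact_set(topo, cross)
      }
    } else if ("cargo" %in% components) {
      # cargo without a tail: free basic bundle near the ring top
      m <- spec$cargo_helix_length
      hl <- m * 1.5
      xyz <- NULL
      for (h in seq_len(spec$cargo_helices)) {
        dx <- 6.5 * ((h - 1) %% 2) - 3.25
        dy <- 6.5 * ((h - 1) %/% 2) - 3.25
        up <- h %% 2 == 1
        xyz <- rbind(xyz, helix_path(
          m, origin = c(60 + dx, dy, if (up) 40 - hl / 2 else 40 + hl / 2),
          axis = if (up) c(0, 0, 1) else c(0, 0, -1), phase0 = h * pi / 2))
      }
      n <- nrow(xyz)
      nm <- ifelse(seq_len(n) %% 2 == 1, "K", "A")
      ct <- chain_topology(xyz, "cargo", nm)
      off <- n_beads(topo)
      topo <- merge_topologies(topo, ct)
      coords <- rbind(coords, xyz)
      topo <- add_tag(topo, "H3H4", off + seq_len(n))
      cargo_cs <- derive_native_contacts(topo, coords, cutoff = 6.5, sigma = 1,
                                         eps_rule = 0.3, label = "cargo_intra",
                                         between = list("H3H4", "H3H4"))
      topo <- add_contact_set(topo, cargo_cs)
    }
    rownames(coords) <- NULL
    list(topology = topo, coords = coords, spec = spec)
  })
}

#' Build a two-chain dimer benchmark for binding calibration
#'
#' Two short chains with a designed cross native-contact set whose binding
#' free energy as a function of sigma is measurable in minutes. With
#' single-bead chains the bound-state statistics have a one-dimensional
#' radial closed form, which the calibration tests use as an oracle.
#'
#' @param n_contacts Number of cross contacts (>= 1).
#' @param well_geometry List: `chain_lengths` (two integers), `r0` (native
#'   separation, A), `eps` (per-contact strength, kcal/mol).
#' @param seed Build seed.
#' @return List with `topology`, `coords`, and the cross `contact_set` label
#'   `"dimer_cross"` installed in the topology with sigma = 1 (scale it via
#'   `sigma_overrides` in [cg_system()]).
#' @export
build_dimer_benchmark <- function(n_contacts = 8,
                                  well_geometry = list(), seed = 1) {
  g <- modifyList(list(chain_lengths = c(4, 4), r0 = 5.0, eps = 1.0),
                  well_geometry)
  stopifnot(n_contacts >= 1)
  with_seed(seed, {
    cluster <- function(m) {
      # compact cluster with ~3.8 A neighbour spacing
      base <- rbind(c(0, 0, 0), c(3.8, 0, 0), c(1.9, 3.29, 0), c(1.9, 1.1, 3.1),
                    c(-1.9, 3.29, 0), c(5.7, 3.29, 0), c(1.9, 4.39, 3.1),
                    c(0, 0, 3.8))
      base[seq_len(m), , drop = FALSE]
    }
    ma <- g$chain_lengths[1]; mb <- g$chain_lengths[2]
    A <- cluster(ma)
    A <- A - matrix(colMeans(A), ma, 3, byrow = TRUE)
    B <- cluster(mb)
    B <- B - matrix(colMeans(B), mb, 3, byrow = TRUE)
    gap <- g$r0 + if (ma > 1 || mb > 1) 2 else 0
    B <- B %*% diag(c(-1, 1, -1)) + matrix(c(gap, 0, 0), mb, 3, byrow = TRUE)
    ta <- chain_topology(A, "chain_a", rep("A", ma))
    tb <- chain_topology(B, "chain_b", rep("A", mb))
    topo <- merge_topologies(ta, tb)
    coords <- rbind(A, B)
    topo <- add_tag(topo, "receptor", seq_len(ma))
    topo <- add_tag(topo, "ligand", ma + seq_len(mb))
    cand <- expand.grid(i = seq_len(ma), j = ma + seq_len(mb))
    cand$r0 <- sqrt(rowSums((coords[cand$i, , drop = FALSE] -
                               coords[cand$j, , drop = FALSE])^2))
    cand <- cand[order(cand$r0), ]
    k <- min(n_contacts, nrow(cand))
    pairs <- data.frame(i = cand$i[seq_len(k)], j = cand$j[seq_len(k)],
                        r0 = cand$r0[seq_len(k)], eps = g$eps)
    topo <- add_contact_set(topo, contact_set(pairs, sigma = 1,
                                              label = "dimer_cross"))
    list(topology = topo, coords = coords)
  })
}

#' Simulation system for the dimer benchmark
#'
#' Restrains the receptor chain at its native position, confines everything
#' to a sphere and applies the requested sigma to the cross contact set.
#'
#' @param bench Result of [build_dimer_benchmark()].
#' @param sigma Global scale of the cross contact set.
#' @param sphere_radius Confinement radius, A.
#' @param wall_k,restraint_k Harmonic constants, kcal/mol/A^2.
#' @param ... Passed to [cg_system()].
#' @return A [cg_system()].
#' @export
dimer_system <- function(bench, sigma, sphere_radius = 25, wall_k = 10,
                         restraint_k = 10, ...) {
  rec <- beads_with_tag(bench$topology, "receptor")
  rest <- data.frame(index = rec, x = bench$coords[rec, 1],
                     y = bench$coords[rec, 2], z = bench$coords[rec, 3],
                     k = restraint_k)
  center <- colMeans(bench$coords[rec, , drop = FALSE])
  cg_system(bench$topology, bench$coords,
            sigma_overrides = c(dimer_cross = sigma),
            confinement = list(radius = sphere_radius, k = wall_k,
                               center = center),
            restraints = rest, ...)
}

RECYCLING_SCENARIOS <- c("leading-mediated", "lagging-mediated",
                         "leading-unmediated", "lagging-unmediated",
                         "parental", "none")

# deposition waypoint: COM of a mid-arm band of the destination duplex
deposit_waypoint <- function(topology, coords, tag) {
  idx <- beads_with_tag(topology, tag)
  nfj <- topology$beads$nt_from_junction[idx]
  band <- if (tag == "parental_duplex") {
    maxn <- max(nfj, na.rm = TRUE)
    c(min(4, maxn - 1), min(8, maxn))
  } else {
    mid <- round(stats::quantile(nfj, 0.6, na.rm = TRUE))
    c(mid - 2, mid + 2)
  }
  sel <- idx[!is.na(nfj) & nfj >= band[1] & nfj <= band[2]]
  colMeans(coords[sel, , drop = FALSE])
}

#' Generate scripted, ground-truth-labelled recycling trajectories
#'
#' Kinematic (non-dynamical) trajectories on the toy replisome: the cargo
#' follows piecewise-linear paths that satisfy or violate the classifier's
#' defining events by construction, with configurable jitter noise on every
#' bead. Scenarios cover all destination x pathway combinations.
#'
#' @param scenario_set Subset of
#'   `c("leading-mediated", "lagging-mediated", "leading-unmediated",
#'   "lagging-unmediated", "parental", "none")`.
#' @param n_per_scenario Trajectories per scenario.
#' @param seed Master seed.
#' @param spec Toy specification used for the underlying system.
#' @param n_frames Frames per trajectory.
#' @param jitter_sd Per-frame, per-coordinate Gaussian jitter, A.
#' @return List with `trajectories` (list of `cg_trajectory`), `labels`
#'   (data frame: scenario, destination, carrier_mediated), `topology` and
#'   `spec`.
#' @export
generate_labeled_trajectories <- function(scenario_set = RECYCLING_SCENARIOS,
                                          n_per_scenario = 7, seed = 1,
                                          spec = toy_spec(),
                                          n_frames = 320, jitter_sd = 0.5) {
  unknown <- setdiff(scenario_set, RECYCLING_SCENARIOS)
  if (length(unknown)) stop("unknown scenario(s): ", paste(unknown, collapse = ", "))
  toy <- build_toy_replisome(spec)
  topo <- toy$topology
  base <- toy$coords
  cargo <- beads_with_tag(topo, "H3H4")
  start <- colMeans(base[cargo, , drop = FALSE])
  carrier_wp <- colMeans(base[beads_with_tag(topo, "Cdc45_acidic_loop"), ,
                              drop = FALSE])
  wp <- list(leading = deposit_waypoint(topo, base, "leading_duplex"),
             lagging = deposit_waypoint(topo, base, "lagging_duplex"),
             parental = deposit_waypoint(topo, base, "parental_duplex"))
  via <- c(10, -55, 10)   # detour keeping the cargo far from the carrier

  path_for <- function(scenario) {
    lerp <- function(a, b, n) {
      t <- seq_len(n) / n
      outer(t, b - a) + matrix(a, n, 3, byrow = TRUE)
    }
    hold <- function(p, n) matrix(p, n, 3, byrow = TRUE)
    if (scenario == "none") return(hold(start, n_frames))
    med <- grepl("mediated$", scenario) && !grepl("unmediated$", scenario)
    dest <- sub("-.*", "", scenario)
    dp <- wp[[dest]]
    seg <- function(f) max(1L, round(f * n_frames))
    if (med) {
      head(rbind(hold(start, seg(0.19)), lerp(start, carrier_wp, seg(0.12)),
                 hold(carrier_wp, seg(0.12)), lerp(carrier_wp, dp, seg(0.09)),
                 hold(dp, n_frames)), n_frames)
    } else {
      head(rbind(hold(start, seg(0.19)), lerp(start, via, seg(0.09)),
                 lerp(via, dp, seg(0.09)), hold(dp, n_frames)), n_frames)
    }
  }

  trajs <- list(); labels <- NULL
  idx <- 0
  for (sc in scenario_set) {
    for (rep in seq_len(n_per_scenario)) {
      idx <- idx + 1
      path <- path_for(sc)
      fr <- with_seed(seed * 1000 + idx, {
        frames <- array(NA_real_, c(n_frames, nrow(base), 3))
        for (f in seq_len(n_frames)) {
          xyz <- base + matrix(rnorm(length(base), 0, jitter_sd),
                               nrow(base), 3)
          xyz[cargo, ] <- xyz[cargo, ] +
            matrix(path[f, ] - start, length(cargo), 3, byrow = TRUE)
          frames[f, , ] <- xyz
        }
        frames
      })
      trajs[[idx]] <- new_trajectory(fr, seq_len(n_frames), numeric(0),
                                     numeric(0), NULL,
                                     metadata = list(scripted = TRUE,
                                                     scenario = sc,
                                                     seed = seed * 1000 + idx))
      labels <- rbind(labels, data.frame(
        scenario = sc,
        destination = if (sc == "none") "none" else sub("-.*", "", sc),
        carrier_mediated = if (sc == "none") NA
        else grepl("mediated$", sc) && !grepl("unmediated$", sc)))
    }
  }
  list(trajectories = trajs, labels = labels, topology = topo, spec = spec)
}
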