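test_that("the toy replisome honours its specification and is seed-deterministic", {
  spec <- toy_spec()
  toy <- build_toy_replisome(spec)
  ring <- beads_with_tag(toy$topology, "hub_ring")
  expect_equal(length(ring), 6 * 60)
  expect_equal(sum(toy$topology$chains$chain_id %in% sprintf("ring_%d", 1:6)), 6)
  expect_equal(length(beads_with_tag(toy$topology, "Mcm2_Ntail")), 80)
  toy2 <- build_toy_replisome(toy_spec())
  expect_identical(toy$coords, toy2$coords)
  toy3 <- build_toy_replisome(toy_spec(seed = 2))
  expect_false(identical(toy3$coords, toy$coords))
})

test_that("binders lengthen the lagging gap and sit on the single-stranded segment", {
  toy0 <- build_toy_replisome(toy_spec(seed = 3))
  toy2 <- build_toy_replisome(toy_spec(binder_count = 2, seed = 3))
  gap0 <- max(toy0$topology$beads$nt_index[beads_with_tag(toy0$topology,
                                                          "lagging_ssDNA")])
  gap2 <- max(toy2$topology$beads$nt_index[beads_with_tag(toy2$topology,
                                                          "lagging_ssDNA")])
  expect_equal(gap2, gap0 + 20)
  binders <- beads_with_tag(toy2$topology, "ssdna_binder")
  expect_equal(length(binders), 2 * 12)
  ss <- toy2$coords[beads_with_tag(toy2$topology, "lagging_ssDNA"), , drop = FALSE]
  mind <- min(vapply(binders, function(q)
    min(rowSums((ss - matrix(toy2$coords[q, ], nrow(ss), 3, byrow = TRUE))^2)), 1))
  expect_lt(sqrt(mind), 15)
})

test_that("the toy's cargo is basic and the carrier loop acidic", {
  toy <- build_toy_replisome(toy_spec(), components = c("ring", "tail",
                                                        "carrier", "cargo"))
  ch <- assign_charges(toy$topology)
  cargo <- beads_with_tag(toy$topology, "H3H4")
  loop <- beads_with_tag(toy$topology, "Cdc45_acidic_loop")
  expect_gt(sum(ch$q_protein_ctx[cargo]), 0)
  expect_lt(sum(ch$q_protein_ctx[loop]), 0)
})

test_that("the dimer benchmark is seed-deterministic with a designed cross contact set", {
  b1 <- build_dimer_benchmark(8, seed = 4)
  b2 <- build_dimer_benchmark(8, seed = 4)
  expect_identical(b1$coords, b2$coords)
  expect_equal(nrow(b1$topology$contacts$dimer_cross$pairs), 8)
  ca <- beads_with_tag(b1$topology, "receptor")
  cb <- beads_with_tag(b1$topology, "ligand")
  expect_true(all(b1$topology$contacts$dimer_cross$pairs$i %in% ca))
  expect_true(all(b1$topology$contacts$dimer_cross$pairs$j %in% cb))
})

test_that("at zero coupling the bound fraction matches a rigid-placement geometric oracle", {
  bench <- build_dimer_benchmark(4, well_geometry = list(chain_lengths = c(4, 4)),
                                 seed = 2)
  contacts <- bench$topology$contacts$dimer_cross
  R <- 20
  sys <- dimer_system(bench, sigma = 0, sphere_radius = R)
  tr <- run_langevin(sys, langevin_params(1.2e6, save_interval = 100, seed = 8))
  bound <- bound_series(tr, bound_state_criterion("q_positive"), contacts)
  p_sim <- mean(bound[-seq_len(1000)])
  # oracle: Boltzmann-weighted rigid placements of the ligand cluster
  # (uniform COM in an enlarged sphere, uniform orientation; weights from
  # the confinement wall and the receptor excluded volume)
  set.seed(99)
  kT <- KB * 300
  lig <- bench$coords[5:8, ]
  lig <- lig - matrix(colMeans(lig), 4, 3, byrow = TRUE)
  rec <- bench$coords[1:4, ]
  center <- colMeans(rec)
  pmap <- cbind(match(contacts$pairs$i, 1:4), match(contacts$pairs$j, 5:8))
  n_mc <- 40000
  w_sum <- 0; w_hit <- 0
  for (q in seq_len(n_mc)) {
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    r <- (R + 2) * runif(1)^(1 / 3)
    ang <- runif(2, 0, 2 * pi)
    Rz <- matrix(c(cos(ang[1]), -sin(ang[1]), 0, sin(ang[1]), cos(ang[1]), 0,
                   0, 0, 1), 3, 3, byrow = TRUE)
    Rx <- matrix(c(1, 0, 0, 0, cos(ang[2]), -sin(ang[2]),
                   0, sin(ang[2]), cos(ang[2])), 3, 3, byrow = TRUE)
    lp <- lig %*% (Rz %*% Rx) + matrix(center + r * u, 4, 3, byrow = TRUE)
    dw <- sqrt(rowSums((lp - matrix(center, 4, 3, byrow = TRUE))^2))
    e <- sum(10 * pmax(0, dw - R)^2)
    dd <- sqrt(outer(rowSums(rec^2), rowSums(lp^2), "+") - 2 * rec %*% t(lp))
    ev <- 0.6 * pmax(0, (5 / dd)^12 - 1)
    e <- e + sum(ev[dd < 5])
    w <- exp(-e / kT)
    d <- sqrt(rowSums((rec[pmap[, 1], ] - lp[pmap[, 2], ])^2))
    w_sum <- w_sum + w
    if (any(d < 1.2 * contacts$pairs$r0)) w_hit <- w_hit + w
  }
  p_mc <- w_hit / w_sum
  expect_lt(abs(log(p_sim / p_mc)), log(1.8))  # within a factor of 1.8
})

test_that("a deep well (sigma >= 2) keeps the dimer bound essentially always", {
  bench <- build_dimer_benchmark(8, seed = 1)
  contacts <- bench$topology$contacts$dimer_cross
  sys <- dimer_system(bench, sigma = 2, sphere_radius = 15)
  tr <- run_langevin(sys, langevin_params(1e6, save_interval = 200, seed = 6))
  bound <- bound_series(tr, bound_state_criterion("q_positive"), contacts)
  expect_gt(mean(bound), 0.99)
})

test_that("labelled trajectory generation validates scenarios and is reproducible", {
  expect_error(generate_labeled_trajectories("sideways"), "unknown scenario")
  l1 <- generate_labeled_trajectories("leading-mediated", 1, seed = 3,
                                     n_frames = 30)
  l2 <- generate_labeled_trajectories("leading-mediated", 1, seed = 3,
                                     n_frames = 30)
  expect_identical(l1$trajectories[[1]]$frames, l2$trajectories[[1]]$frames)
  expect_equal(l1$labels$destination, "leading")
  expect_true(l1$labels$carrier_mediated)
})

test_that("a held cargo stays on the donor tail in the 'none' scenario", {
  lab <- generate_labeled_trajectories("none", 1, seed = 4, n_frames = 40)
  ct <- contact_timeseries(lab$trajectories[[1]], lab$topology, "H3H4",
                           "Mcm2_Ntail", 10)
  expect_true(all(ct$counts > 0))
  for (tg in c("leading_duplex", "lagging_duplex", "parental_duplex")) {
    cd <- contact_timeseries(lab$trajectories[[1]], lab$topology, "H3H4", tg, 12)
    expect_true(all(cd$counts == 0))
  }
})

test_that("charged versus neutralized carrier loop changes carrier-cargo association", {
  # equilibrium smoke test of the qualitative electrostatic-capture effect
  toy <- build_toy_replisome(toy_spec(carrier_length = 30, tail_length = 0,
                                      cargo_helix_length = 8, seed = 6),
                             components = c("carrier", "cargo"))
  cargo <- beads_with_tag(toy$topology, "H3H4")
  # start the cargo 18 A from the acidic loop
  loop <- beads_with_tag(toy$topology, "Cdc45_acidic_loop")
  shift <- colMeans(toy$coords[loop, , drop = FALSE]) +
    c(18, 0, 0) - colMeans(toy$coords[cargo, , drop = FALSE])
  coords <- toy$coords
  coords[cargo, ] <- coords[cargo, ] + matrix(shift, length(cargo), 3,
                                              byrow = TRUE)
  conf <- list(radius = 45, k = 5,
               center = colMeans(coords[beads_with_tag(toy$topology, "Cdc45"), ]))
  run_counts <- function(neutralize) {
    ch <- assign_charges(toy$topology,
                         neutralize_tags = if (neutralize) "Cdc45_acidic_loop"
                         else character())
    sys <- cg_system(toy$topology, coords, charges = ch, confinement = conf)
    tr <- run_langevin(sys, langevin_params(1.5e5, save_interval = 200,
                                            seed = 31))
    contact_timeseries(tr, toy$topology, "H3H4", "Cdc45_acidic_loop", 10)$counts
  }
  wt <- run_counts(FALSE)
  mut <- run_counts(TRUE)
  # charged loop: association episodes occur; neutral loop: clearly fewer
  expect_gt(sum(wt > 0), 0)
  expect_gt(mean(wt), mean(mut))
})
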