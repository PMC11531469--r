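test_that("coarse-graining a resolved helix gives one bead per residue with native local terms", {
  p <- write_mini_pdb(tempfile(fileext = ".pdb"), chains = list(A = 10))
  st <- read_pdb(p)
  cg <- coarse_grain_protein(st, list(A = list(tags = "frag")))
  expect_equal(nrow(cg$coords), 10)
  expect_equal(nrow(cg$topology$bonds), 9)
  expect_equal(nrow(cg$topology$angles), 8)
  expect_equal(nrow(cg$topology$dihedrals), 7)
  # all local terms native-anchored when no residue is disordered
  expect_true(all(cg$topology$bonds[, "native"] == 1))
  expect_true(all(cg$topology$angles[, "native"] == 1))
  # bond reference lengths are the native CA-CA distances
  d12 <- sqrt(sum((cg$coords[1, ] - cg$coords[2, ])^2))
  expect_equal(unname(cg$topology$bonds[1, "r0"]), d12)
})

test_that("disordered spans lose native reference values but keep bonds and weak angles", {
  p <- write_mini_pdb(tempfile(fileext = ".pdb"), chains = list(A = 10))
  cg <- coarse_grain_protein(read_pdb(p), list(A = list()),
                             idr_ranges = list(A = list(c(1, 5))))
  b <- cg$topology$bonds
  a <- cg$topology$angles
  d <- cg$topology$dihedrals
  # bonds touching the span are generic 3.8 A
  expect_true(all(b[b[, "native"] == 0, "r0"] == 3.8))
  expect_true(all(b[b[, "i"] <= 4, "native"] == 0))
  # angles touching the span are the weak generic term, not native-anchored
  touching <- a[, "i"] <= 5
  expect_true(all(a[touching, "native"] == 0))
  k_native <- a[a[, "native"] == 1, "ktheta"]
  expect_true(all(a[touching, "ktheta"] < min(k_native)))
  # no dihedral reference values inside the span
  expect_true(all(d[, "i"] >= 5))
  expect_equal(unname(cg$topology$idr_ranges$A[[1]]), c(1, 5))
})

test_that("missing C-alpha and missing chain are hard errors", {
  p <- tempfile(fileext = ".pdb")
  con <- file(p, "w")
  writeLines(c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CB  GLY A   2       3.800   0.000   0.000  1.00  0.00           C",
    "ATOM      3  CA  LEU A   3       7.600   0.000   0.000  1.00  0.00           C",
    "END"), con)
  close(con)
  st <- read_pdb(p)
  expect_error(coarse_grain_protein(st, list(A = list())), "missing CA.*GLY2")
  expect_error(coarse_grain_protein(st, list(B = list())), "chain not found")
})

test_that("B-form duplex has the ideal fiber rise and twist", {
  d <- generate_bform_duplex(paste(rep("ACGT", 5), collapse = ""))
  b <- d$topology$beads
  base1 <- which(b$site_kind == "base" & b$chain_id == "dna_1")
  xyz <- d$coords[base1[order(b$nt_index[base1])], ]
  rises <- diff(xyz[, 3])
  expect_equal(rises, rep(3.38, 19), tolerance = 1e-8)
  ang <- atan2(xyz[, 2], xyz[, 1]) * 180 / pi
  twists <- diff(ang) %% 360
  expect_equal(twists, rep(36, 19), tolerance = 1e-6)
})

test_that("duplex bead counts follow the 5'-phosphate-omitted convention", {
  d <- generate_bform_duplex("AC")
  k <- table(d$topology$beads$site_kind)
  expect_equal(unname(k[["base"]]), 4)
  expect_equal(unname(k[["sugar"]]), 4)
  expect_equal(unname(k[["phosphate"]]), 2)  # one 5' terminus per strand
  # general rule: 3*nt - n_strands beads
  d2 <- generate_bform_duplex("ACGTACG")
  expect_equal(nrow(d2$topology$beads), 3 * 14 - 2)
  expect_error(generate_bform_duplex("ACGX"), "invalid nucleotide")
  expect_error(generate_bform_duplex("A"), "at least 2")
})

test_that("fork assembly tags strands, counts gap nucleotides and defines the junction", {
  fk <- assemble_fork(23, 90, 96, 33, 56, seed = 2)
  topo <- fk$topology
  for (tg in c("parental_duplex", "leading_duplex", "lagging_duplex",
               "leading_ssDNA", "lagging_ssDNA"))
    expect_true(tg %in% names(topo$tags))
  b <- topo$beads
  lead_ss <- beads_with_tag(topo, "leading_ssDNA")
  lag_ss <- beads_with_tag(topo, "lagging_ssDNA")
  expect_equal(max(b$nt_index[lead_ss]), 33)
  expect_equal(max(b$nt_index[lag_ss]), 56)
  expect_equal(length(unique(b$nt_index[beads_with_tag(topo, "parental_duplex")])), 23)
  # junction is the last parental base pair, at distance 0
  expect_false(is.na(topo$junction_index))
  expect_equal(b$nt_from_junction[topo$junction_index], 0)
  # daughter-arm distances count through the gap
  lead_d <- beads_with_tag(topo, "leading_duplex")
  expect_equal(min(b$nt_from_junction[lead_d]), 33)
  expect_equal(max(b$nt_from_junction[lead_d]), 33 + 90 - 1)
})

test_that("zero-gap fork is a fully duplex Y with a defined junction", {
  fk <- assemble_fork(6, 8, 8, 0, 0, seed = 1)
  expect_false("leading_ssDNA" %in% names(fk$topology$tags))
  expect_false(is.na(fk$topology$junction_index))
})

test_that("fork assembly is bitwise reproducible for identical seeds", {
  f1 <- assemble_fork(8, 10, 10, 4, 5, seed = 7)
  f2 <- assemble_fork(8, 10, 10, 4, 5, seed = 7)
  expect_identical(f1$coords, f2$coords)
  f3 <- assemble_fork(8, 10, 10, 4, 5, seed = 8)
  expect_false(identical(f3$coords, f1$coords))
})

test_that("native-contact criterion applies the cutoff and sequence separation", {
  topo <- bare_beads(12)
  coords <- cbind(seq(0, by = 8, length.out = 12), 0, 0)
  # bring beads 1 and 8 to exactly 6.4 A, beads 2 and 9 to 6.6 A
  coords[8, ] <- coords[1, ] + c(6.4, 0, 0)
  coords[9, ] <- coords[2, ] + c(0, 6.6, 0)
  cs <- derive_native_contacts(topo, coords, cutoff = 6.5)
  expect_true(any(cs$pairs$i == 1 & cs$pairs$j == 8))
  expect_false(any(cs$pairs$i == 2 & cs$pairs$j == 9))
  # |i-j| >= 4 within one chain: beads 8,9 are 8.0+ apart; make 3,5 close
  coords[5, ] <- coords[3, ] + c(0, 0, 5)
  cs2 <- derive_native_contacts(topo, coords, cutoff = 6.5)
  expect_false(any(cs2$pairs$i == 3 & cs2$pairs$j == 5))
})

test_that("contact derivation is invariant under rigid rototranslation", {
  toy <- build_toy_replisome(toy_spec(ring_chain_length = 12),
                             components = "ring")
  cs <- derive_native_contacts(toy$topology, toy$coords, cutoff = 6.5)
  rt <- random_rototranslation(3)
  cs2 <- derive_native_contacts(toy$topology, apply_rt(toy$coords, rt),
                                cutoff = 6.5)
  expect_equal(cs$pairs$i, cs2$pairs$i)
  expect_equal(cs$pairs$j, cs2$pairs$j)
  expect_equal(cs$pairs$r0, cs2$pairs$r0, tolerance = 1e-9)
})

test_that("cross-chain contact sets from a two-chain structure are non-empty", {
  # synthetic mini-complex standing in for a bound peptide pair
  p <- write_mini_pdb(tempfile(fileext = ".pdb"), chains = list(A = 8, B = 8),
                      offset_chain2 = c(7, 0, 0))
  st <- read_pdb(p)
  cg <- coarse_grain_protein(st, list(A = list(tags = "rec"),
                                      B = list(tags = "lig")))
  ham <- heavy_atom_map(st, cg$topology)
  cs <- derive_native_contacts(cg$topology, cg$coords, ham, cutoff = 6.5,
                               between = list("rec", "lig"),
                               label = "cross")
  expect_gt(nrow(cs$pairs), 0)
  chain_of <- c(rep("A", 8), rep("B", 8))
  expect_true(all(chain_of[cs$pairs$i] != chain_of[cs$pairs$j]))
})

test_that("formal charges follow the K/R/D/E rule and phosphates are dual-valued", {
  topo <- bare_beads(3, names = c("K", "A", "E"))
  ch <- assign_charges(topo)
  expect_equal(ch$q_protein_ctx, c(1, 0, -1))
  expect_equal(ch$q_dna_ctx, c(1, 0, -1))

  d <- generate_bform_duplex("ACGT")
  chd <- assign_charges(d$topology)
  isp <- d$topology$beads$site_kind == "phosphate"
  expect_true(all(chd$q_dna_ctx[isp] == -0.6))
  expect_true(all(chd$q_protein_ctx[isp] == -1.0))
  expect_true(all(chd$q_dna_ctx[!isp] == 0))
})

test_that("charge bookkeeping: totals, neutralization and overrides", {
  nm <- c("K", "R", "D", "E", "A", "K", "G", "E")
  topo <- bare_beads(8, names = nm)
  topo <- add_tag(topo, "loop", c(3, 4))
  ch <- assign_charges(topo)
  expect_equal(sum(ch$q_protein_ctx), sum(nm %in% c("K", "R")) - sum(nm %in% c("D", "E")))
  chn <- assign_charges(topo, neutralize_tags = "loop")
  expect_equal(chn$q_protein_ctx[3:4], c(0, 0))
  expect_equal(chn$q_protein_ctx[-(3:4)], ch$q_protein_ctx[-(3:4)])
  cho <- assign_charges(topo, charge_context(overrides = data.frame(index = 5, charge = 0.25)))
  expect_equal(cho$q_protein_ctx[5], 0.25)
  expect_error(assign_charges(topo, charge_context(
    overrides = data.frame(index = 99, charge = 1))), "out of range")
})

test_that("acidic-loop neutralization zeroes exactly the tagged beads of the toy carrier", {
  toy <- build_toy_replisome(toy_spec(ring_chain_length = 12),
                             components = c("ring", "carrier"))
  loop <- beads_with_tag(toy$topology, "Cdc45_acidic_loop")
  ch0 <- assign_charges(toy$topology)
  expect_true(all(ch0$q_protein_ctx[loop] == -1))
  ch1 <- assign_charges(toy$topology, neutralize_tags = "Cdc45_acidic_loop")
  expect_true(all(ch1$q_protein_ctx[loop] == 0))
  expect_equal(ch1$q_protein_ctx[-loop], ch0$q_protein_ctx[-loop])
})

test_that("disordered-span modelling bridges anchors with exact 3.8 A steps", {
  topo <- bare_beads(9)
  fc <- matrix(NA_real_, 9, 3)
  fc[1:2, ] <- rbind(c(0, 0, 0), c(3.8, 0, 0))
  fc[8:9, ] <- rbind(c(3.8 + 12, 0, 0), c(3.8 + 15.8, 0, 0))
  out <- model_idr_conformation(topo, fc, seed = 4)
  steps <- sqrt(rowSums(diff(out[2:8, ])^2))
  expect_equal(steps[1:5], rep(3.8, 5), tolerance = 1e-9)
  expect_identical(out, model_idr_conformation(topo, fc, seed = 4))
  expect_false(identical(out, model_idr_conformation(topo, fc, seed = 5)))
  # unbridgeable span: 5 beads cannot span 40 A
  fc2 <- fc
  fc2[8:9, 1] <- c(3.8 + 40, 3.8 + 43.8)
  expect_error(model_idr_conformation(topo, fc2, seed = 1), "cannot bridge")
})

test_that("bead-count invariants hold for proteins and DNA assemblies", {
  p <- write_mini_pdb(tempfile(fileext = ".pdb"), chains = list(A = 7))
  cg <- coarse_grain_protein(read_pdb(p), list(A = list()))
  expect_equal(nrow(cg$topology$beads), 7)
  fk <- assemble_fork(5, 6, 6, 3, 4, seed = 2)
  b <- fk$topology$beads
  n_nt <- sum(!is.na(b$nt_index) & b$site_kind == "base")
  n_strands <- sum(fk$topology$chains$molecule_class == "dna_strand")
  expect_equal(nrow(b), 3 * n_nt - n_strands)
})
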