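## Potential-energy model: structure-based (Go) native contacts, Debye-Huckel
## electrostatics with partner-class-dependent phosphate charges, purely
## repulsive excluded volume, and harmonic/periodic bonded terms. All terms
## have exact analytic forces (C++ kernels); the R functions here assemble
## systems and provide reference implementations of the pair potentials.

#' Electrostatic parameters
#'
#' @param ionic_strength Monovalent ionic strength, mol/L.
#' @param dielectric Relative dielectric constant.
#' @param temperature Temperature, K (enters the Debye length).
#' @param cutoff Truncation distance, A; energies are shifted to zero at the
#'   cutoff. Use `Inf` for no truncation.
#' @return Object of class `electrostatic_params` with the derived Debye
#'   length in `$debye_length` (A).
#' @export
electrostatic_params <- function(ionic_strength = 0.3, dielectric = 78.0,
                                 temperature = 300, cutoff = 50) {
  stopifnot(ionic_strength > 0, dielectric > 0, temperature > 0, cutoff > 0)
  structure(list(ionic_strength = ionic_strength, dielectric = dielectric,
                 temperature = temperature, cutoff = cutoff,
                 debye_length = debye_length(ionic_strength, dielectric,
                                             temperature)),
            class = "electrostatic_params")
}

#' Screened-Coulomb pair energy
#'
#' Debye-Huckel interaction energy of a charge pair, optionally with the
#' energy-shift truncation applied by the simulation engine.
#'
#' @param r Separation(s), A.
#' @param qq Product of the two charges, e^2.
#' @param params An [electrostatic_params()].
#' @param shifted Apply the cutoff energy shift (default: only when the
#'   cutoff is finite).
#' @return Energy in kcal/mol.
#' @export
dh_pair_energy <- function(r, qq, params, shifted = is.finite(params$cutoff)) {
  kappa <- 1 / params$debye_length
  u <- KE_COULOMB * qq * exp(-kappa * r) / (params$dielectric * r)
  if (shifted) {
    rc <- params$cutoff
    u <- ifelse(r < rc,
                u - KE_COULOMB * qq * exp(-kappa * rc) / (params$dielectric * rc),
                0)
  }
  u
}

#' Go (native-contact) energy and forces
#'
#' Evaluates the non-local structure-based term
#' V = sigma * sum_ij eps_ij \[5 (r0/r)^12 - 6 (r0/r)^10\]
#' over a contact set, with exact analytic forces.
#'
#' @param coords N x 3 coordinates, A.
#' @param contacts A [contact_set()].
#' @return List with `energy` (kcal/mol) and `forces` (N x 3).
#' @export
go_energy <- function(coords, contacts) {
  p <- contacts$pairs
  d <- coords[p$i, , drop = FALSE] - coords[p$j, , drop = FALSE]
  r <- sqrt(rowSums(d^2))
  if (any(r <= 0)) stop("zero distance in native-contact pair (bead overlap)")
  s <- p$r0 / r
  e <- contacts$sigma * p$eps * (5 * s^12 - 6 * s^10)
  dV <- contacts$sigma * p$eps * 60 * (s^10 - s^12) / r
  f <- matrix(0, nrow(coords), 3)
  fac <- -dV / r
  for (k in 1:3) {
    fk <- fac * d[, k]
    f[, k] <- f[, k] + tapply_add(fk, p$i, nrow(coords)) -
      tapply_add(fk, p$j, nrow(coords))
  }
  list(energy = sum(e), forces = f, per_pair = e)
}

tapply_add <- function(values, idx, n) {
  out <- numeric(n)
  agg <- rowsum(values, idx)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

#' Debye-Huckel energy and forces over bead pairs
#'
#' Sums the screened-Coulomb interaction over all supplied pairs, resolving
#' the partner-class-dependent phosphate charge for each pair.
#'
#' @param coords N x 3 coordinates.
#' @param charges Charge table from [assign_charges()].
#' @param is_dna Logical vector: bead belongs to a DNA strand.
#' @param params An [electrostatic_params()].
#' @param pairs Optional 2-column matrix of pairs; all pairs by default.
#' @return List with `energy` and `forces`.
#' @export
debye_huckel_energy <- function(coords, charges, is_dna, params,
                                pairs = NULL) {
  n <- nrow(coords)
  if (is.null(pairs)) {
    pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  }
  i <- pairs[, 1]; j <- pairs[, 2]
  qi <- ifelse(is_dna[j], charges$q_dna_ctx[i], charges$q_protein_ctx[i])
  qj <- ifelse(is_dna[i], charges$q_dna_ctx[j], charges$q_protein_ctx[j])
  qq <- qi * qj
  d <- coords[i, , drop = FALSE] - coords[j, , drop = FALSE]
  r <- sqrt(rowSums(d^2))
  if (any(r[qq != 0] <= 0)) stop("zero distance between charged beads")
  act <- qq != 0 & r < params$cutoff
  e <- numeric(length(r))
  e[act] <- dh_pair_energy(r[act], qq[act], params)
  kappa <- 1 / params$debye_length
  u_raw <- KE_COULOMB * qq * exp(-kappa * r) / (params$dielectric * r)
  dV <- ifelse(act, -u_raw * (kappa + 1 / r), 0)
  f <- matrix(0, n, 3)
  fac <- -dV / r
  for (k in 1:3) {
    fk <- fac * d[, k]
    f[, k] <- f[, k] + tapply_add(fk, i, n) - tapply_add(fk, j, n)
  }
  list(energy = sum(e), forces = f)
}

#' Excluded-volume energy and forces
#'
#' Purely repulsive pair term eps_ev \[(d_ij/r)^12 - 1\] for r below the
#' contact distance d_ij = r_i + r_j, zero (value and by shift) beyond it.
#'
#' @param coords N x 3 coordinates.
#' @param radii Per-bead radii, A.
#' @param eps_ev Repulsion strength, kcal/mol.
#' @param pairs Optional pair matrix; all pairs by default.
#' @return List with `energy` and `forces`.
#' @export
excluded_volume_energy <- function(coords, radii, eps_ev = 0.6, pairs = NULL) {
  stopifnot(all(radii > 0))
  n <- nrow(coords)
  if (is.null(pairs)) {
    pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  }
  i <- pairs[, 1]; j <- pairs[, 2]
  d <- coords[i, , drop = FALSE] - coords[j, , drop = FALSE]
  r <- sqrt(rowSums(d^2))
  dij <- radii[i] + radii[j]
  act <- r < dij
  if (any(r[act] <= 0)) stop("zero distance between overlapping beads")
  s <- ifelse(act, dij / r, 0)
  e <- ifelse(act, eps_ev * (s^12 - 1), 0)
  dV <- ifelse(act, -12 * eps_ev * s^12 / r, 0)
  f <- matrix(0, n, 3)
  fac <- ifelse(act, -dV / r, 0)
  for (k in 1:3) {
    fk <- fac * d[, k]
    f[, k] <- f[, k] + tapply_add(fk, i, n) - tapply_add(fk, j, n)
  }
  list(energy = sum(e), forces = f)
}

#' Assemble a simulation-ready system
#'
#' Combines a topology, coordinates, charges and interaction parameters into
#' a `cg_system` consumed by the energy and dynamics routines.
#'
#' @param topology A `cg_topology`.
#' @param coords N x 3 reference/initial coordinates.
#' @param charges Charge table from [assign_charges()]; computed with default
#'   context if omitted.
#' @param elec An [electrostatic_params()].
#' @param eps_ev Excluded-volume strength, kcal/mol.
#' @param sigma_overrides Named numeric vector: per-contact-set-label global
#'   scales replacing the set's own sigma.
#' @param confinement Optional list(radius, k, center): half-harmonic
#'   spherical wall applied to all beads outside the radius.
#' @param restraints Optional data frame (index, x, y, z, k): harmonic
#'   position restraints.
#' @return Object of class `cg_system`.
#' @export
cg_system <- function(topology, coords, charges = NULL,
                      elec = electrostatic_params(), eps_ev = 0.6,
                      sigma_overrides = NULL, confinement = NULL,
                      restraints = NULL) {
  stopifnot(inherits(topology, "cg_topology"), nrow(coords) == n_beads(topology))
  if (is.null(charges)) charges <- assign_charges(topology)
  sys <- structure(list(topology = topology, coords = coords,
                        charges = charges, elec = elec, eps_ev = eps_ev,
                        sigma_overrides = sigma_overrides,
                        confinement = confinement, restraints = restraints),
                   class = "cg_system")
  sys$compiled <- compile_system(sys)
  sys
}

# Flatten a cg_system into the plain-array form the C++ kernels expect.
compile_system <- function(sys) {
  topo <- sys$topology
  n <- n_beads(topo)
  is_dna <- rep(0L, n)
  for (q in seq_len(nrow(topo$chains)))
    if (topo$chains$molecule_class[q] == "dna_strand")
      is_dna[topo$chains$first[q]:topo$chains$last[q]] <- 1L

  labels <- names(topo$contacts)
  cmat <- matrix(numeric(0), 0, 5)
  for (q in seq_along(topo$contacts)) {
    cs <- topo$contacts[[q]]
    sg <- cs$sigma
    if (!is.null(sys$sigma_overrides) && cs$label %in% names(sys$sigma_overrides))
      sg <- sys$sigma_overrides[[cs$label]]
    if (nrow(cs$pairs))
      cmat <- rbind(cmat, cbind(cs$pairs$i, cs$pairs$j, cs$pairs$r0,
                                sg * cs$pairs$eps, q))
  }
  b <- topo$bonds; a <- topo$angles; d <- topo$dihedrals
  excl <- NULL
  if (nrow(b)) excl <- rbind(excl, cbind(b[, 1], b[, 2]))
  if (nrow(a)) excl <- rbind(excl, cbind(a[, 1], a[, 3]))
  if (is.null(excl)) excl <- matrix(integer(0), 0, 2)
  ev_excl <- if (nrow(cmat)) cmat[, 1:2, drop = FALSE] else matrix(integer(0), 0, 2)
  conf <- sys$confinement
  if (is.null(conf)) conf <- list(radius = 0, k = 0, center = c(0, 0, 0))
  if (is.null(conf$center)) conf$center <- c(0, 0, 0)
  if (is.null(conf$k)) conf$k <- 10
  rest <- sys$restraints
  rmat <- if (is.null(rest)) matrix(numeric(0), 0, 5) else
    cbind(rest$index, rest$x, rest$y, rest$z, rest$k)
  list(n = n,
       bonds = b[, 1:4, drop = FALSE],
       angles = a[, 1:5, drop = FALSE],
       dihedrals = d[, 1:6, drop = FALSE],
       contacts = cmat, n_labels = max(1L, length(labels)),
       labels = labels,
       q_dna = sys$charges$q_dna_ctx, q_pro = sys$charges$q_protein_ctx,
       radius = topo$beads$radius, is_dna = is_dna,
       eps_ev = sys$eps_ev,
       ke_eps = KE_COULOMB / sys$elec$dielectric,
       kappa = 1 / sys$elec$debye_length,
       elec_cutoff = sys$elec$cutoff,
       excl_nb = matrix(as.integer(excl), ncol = 2),
       excl_ev = matrix(as.integer(ev_excl), ncol = 2),
       restraints = rmat,
       confinement = conf,
       mass = rep(BEAD_MASS, n))
}

#' Total energy and forces
#'
#' Evaluates every potential term of a `cg_system` at the given coordinates;
#' the force array is the exact negative gradient of the total.
#'
#' @param system A [cg_system()].
#' @param coords Coordinates (defaults to the system's stored coordinates).
#' @return List with `breakdown` (named energies, kcal/mol; `go` is a named
#'   vector per contact-set label; `total` is their sum) and `forces` (N x 3).
#' @export
total_energy_forces <- function(system, coords = system$coords) {
  res <- cpp_energy_forces(coords, system$compiled)
  go <- as.numeric(res$go)
  labs <- system$compiled$labels
  if (length(labs)) names(go) <- labs else go <- go[0]
  br <- list(bonded = res$bond + res$angle + res$dihedral,
             bond = res$bond, angle = res$angle, dihedral = res$dihedral,
             go_native = go,
             excluded_volume = res$excluded_volume,
             electrostatic = res$electrostatic,
             restraint = res$restraint, confinement = res$confinement,
             total = res$total)
  for (nm in c("bond", "angle", "dihedral", "excluded_volume", "electrostatic",
               "restraint", "confinement")) {
    if (!is.finite(br[[nm]]))
      stop("non-finite energy in term: ", nm)
  }
  if (length(go) && any(!is.finite(go)))
    stop("non-finite energy in go term: ",
         paste(names(go)[!is.finite(go)], collapse = ","))
  list(breakdown = br, forces = res$forces)
}

#' Relax a configuration by capped gradient descent
#'
#' Removes residual steric strain from constructed initial structures
#' before dynamics: steepest descent along the forces with a hard cap on
#' the per-step bead displacement.
#'
#' @param system A [cg_system()].
#' @param coords Starting coordinates (defaults to the system's).
#' @param n_steps Maximum descent steps.
#' @param max_move Per-step displacement cap, A.
#' @param tol Stop when the maximum force falls below this, kcal/mol/A.
#' @return Relaxed N x 3 coordinates.
#' @export
minimize_energy <- function(system, coords = system$coords, n_steps = 200,
                            max_move = 0.2, tol = 10) {
  for (q in seq_len(n_steps)) {
    ef <- total_energy_forces(system, coords)
    fmax <- max(abs(ef$forces))
    if (fmax < tol) break
    coords <- coords + ef$forces * (max_move / fmax)
  }
  coords
}

#' Tabular energy report
#'
#' @param breakdown The `breakdown` element of [total_energy_forces()].
#' @return Data frame (term, label, energy) suitable for TSV serialisation.
#' @export
energy_report <- function(breakdown) {
  rows <- data.frame(term = character(), label = character(),
                     energy = numeric(), stringsAsFactors = FALSE)
  for (nm in c("bond", "angle", "dihedral", "excluded_volume",
               "electrostatic", "restraint", "confinement")) {
    rows <- rbind(rows, data.frame(term = nm, label = "", energy = breakdown[[nm]]))
  }
  for (lb in names(breakdown$go_native))
    rows <- rbind(rows, data.frame(term = "go_native", label = lb,
                                   energy = breakdown$go_native[[lb]]))
  rbind(rows, data.frame(term = "total", label = "", energy = breakdown$total))
}
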