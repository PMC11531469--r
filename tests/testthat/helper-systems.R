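# Shared fixture builders. Everything is generated in code at test time.

KB <- 0.0019872

# a single bead held by a harmonic position restraint (V = k * |dx|^2)
single_bead_system <- function(k = 0.5, radius = 2.5) {
  topo <- cgfork:::new_topology()
  topo$beads <- data.frame(index = 1L, chain_id = "c", site_kind = "residue",
                           name = "A", charge = 0, radius = radius,
                           nt_index = NA_integer_,
                           nt_from_junction = NA_integer_)
  topo$chains <- data.frame(chain_id = "c", molecule_class = "protein",
                            first = 1L, last = 1L)
  cg_system(topo, matrix(0, 1, 3),
            restraints = data.frame(index = 1, x = 0, y = 0, z = 0, k = k))
}

# minimal n-bead protein topology with no bonded terms
bare_beads <- function(n, names = rep("A", n), radius = 2.5) {
  topo <- cgfork:::new_topology()
  topo$beads <- data.frame(index = seq_len(n), chain_id = "c",
                           site_kind = "residue", name = names, charge = 0,
                           radius = radius, nt_index = NA_integer_,
                           nt_from_junction = NA_integer_)
  topo$chains <- data.frame(chain_id = "c", molecule_class = "protein",
                            first = 1L, last = as.integer(n))
  topo
}

# write a small synthetic PDB: one or two chains of alpha-helical residues
# with CA and CB atoms (all coordinates generated here)
write_mini_pdb <- function(path, chains = list(A = 10),
                           aa_cycle = c("ALA", "LYS", "GLU", "GLY", "LEU",
                                        "SER", "THR", "VAL", "ASP", "ARG"),
                           altloc_res = integer(), offset_chain2 = c(8, 0, 0)) {
  con <- file(path, "w")
  on.exit(close(con))
  no <- 0
  ci <- 0
  for (ch in names(chains)) {
    ci <- ci + 1
    off <- if (ci == 1) c(0, 0, 0) else offset_chain2
    for (q in seq_len(chains[[ch]])) {
      a <- (q - 1) * 100 * pi / 180
      xyz <- c(2.3 * cos(a), 2.3 * sin(a), 1.5 * (q - 1)) + off
      aa <- aa_cycle[(q - 1) %% length(aa_cycle) + 1]
      alts <- if (q %in% altloc_res && ci == 1) c("A", "B") else ""
      for (al in alts) {
        occ <- if (al == "B") 0.3 else if (al == "A") 0.7 else 1.0
        dx <- if (al == "B") 0.5 else 0
        no <- no + 1
        writeLines(sprintf(
          "ATOM  %5d  CA %1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
          no, if (al == "") " " else al, aa, ch, q,
          xyz[1] + dx, xyz[2], xyz[3], occ, 0), con)
      }
      no <- no + 1
      writeLines(sprintf(
        "ATOM  %5d  CB  %s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
        no, aa, ch, q, xyz[1] * 1.4, xyz[2] * 1.4, xyz[3], 1.0, 0), con)
    }
  }
  writeLines("END", con)
  path
}

random_rototranslation <- function(seed = 1) {
  set.seed(seed)
  ang <- runif(3, 0, 2 * pi)
  Rx <- matrix(c(1, 0, 0, 0, cos(ang[1]), -sin(ang[1]),
                 0, sin(ang[1]), cos(ang[1])), 3, 3, byrow = TRUE)
  Ry <- matrix(c(cos(ang[2]), 0, sin(ang[2]), 0, 1, 0,
                 -sin(ang[2]), 0, cos(ang[2])), 3, 3, byrow = TRUE)
  Rz <- matrix(c(cos(ang[3]), -sin(ang[3]), 0, sin(ang[3]), cos(ang[3]), 0,
                 0, 0, 1), 3, 3, byrow = TRUE)
  list(R = Rx %*% Ry %*% Rz, t = runif(3, -20, 20))
}

apply_rt <- function(coords, rt) {
  coords %*% t(rt$R) + matrix(rt$t, nrow(coords), 3, byrow = TRUE)
}
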