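## Coarse-grained model construction: one bead per amino acid at the C-alpha
## position, three beads per nucleotide (base, sugar, phosphate), native-
## anchored local terms for folded regions, flexible terms for disordered
## regions, native-contact sets, and context-dependent charges.

# local-term stiffnesses (kcal/mol/A^2 or kcal/mol/rad^2); V = k * dx^2
PROT_KBOND <- 110.4
PROT_KANGLE <- 20.0
PROT_KDIH <- 1.0
IDR_KANGLE <- 1.0
IDR_THETA0 <- 2.1817  # ~125 deg, generic Calpha pseudo-angle
DNA_KBOND <- 60.0
DNA_KANGLE <- 20.0
DNA_KDIH <- 1.0
SS_KANGLE <- 1.0
CA_STEP <- 3.8        # consecutive Calpha distance, A
SS_STEP <- 6.0        # consecutive ssDNA sugar-sugar distance, A

# default bead radii by site kind, A; DNA site radii sized so the ideal
# B-form fiber is clash-free (stacked base sites sit 4.2 A apart)
BEAD_RADII <- c(residue = 2.5, base = 2.0, sugar = 2.5, phosphate = 2.0)

AA3TO1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
            GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
            LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
            SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

residue_formal_charge <- function(one_letter) {
  q <- rep(0, length(one_letter))
  q[one_letter %in% c("K", "R")] <- 1
  q[one_letter %in% c("D", "E")] <- -1
  q
}

#' Create an empty coarse-grained topology
#'
#' A `cg_topology` holds the bead table, chain records, bonded terms
#' (bonds/angles/dihedrals with reference values and stiffnesses), group
#' tags, disordered-region annotations and native-contact sets.
#'
#' @return An empty object of class `cg_topology`.
#' @export
new_topology <- function() {
  structure(list(
    beads = data.frame(index = integer(), chain_id = character(),
                       site_kind = character(), name = character(),
                       charge = numeric(), radius = numeric(),
                       nt_index = integer(), nt_from_junction = integer(),
                       stringsAsFactors = FALSE),
    chains = data.frame(chain_id = character(), molecule_class = character(),
                        first = integer(), last = integer(),
                        stringsAsFactors = FALSE),
    bonds = matrix(numeric(0), 0, 5,
                   dimnames = list(NULL, c("i", "j", "r0", "k", "native"))),
    angles = matrix(numeric(0), 0, 6,
                    dimnames = list(NULL, c("i", "j", "k", "theta0", "ktheta", "native"))),
    dihedrals = matrix(numeric(0), 0, 7,
                       dimnames = list(NULL, c("i", "j", "k", "l", "phi0", "kphi", "native"))),
    tags = list(),
    idr_ranges = list(),
    contacts = list(),
    junction_index = NA_integer_
  ), class = "cg_topology")
}

#' @export
print.cg_topology <- function(x, ...) {
  cat(sprintf("cg_topology: %d beads, %d chains, %d bonds, %d angles, %d dihedrals\n",
              nrow(x$beads), nrow(x$chains), nrow(x$bonds), nrow(x$angles),
              nrow(x$dihedrals)))
  if (length(x$tags))
    cat("tags:", paste(sprintf("%s(%d)", names(x$tags),
                               vapply(x$tags, length, 1L)), collapse = ", "), "\n")
  if (length(x$contacts))
    cat("contact sets:",
        paste(vapply(x$contacts, function(cs)
          sprintf("%s(%d, sigma=%g)", cs$label, nrow(cs$pairs), cs$sigma), ""),
          collapse = ", "), "\n")
  invisible(x)
}

n_beads <- function(topology) nrow(topology$beads)

#' Tag a set of beads
#'
#' @param topology A `cg_topology`.
#' @param tag Tag label.
#' @param indices Bead indices to tag.
#' @return The modified topology.
#' @export
add_tag <- function(topology, tag, indices) {
  stopifnot(all(indices >= 1), all(indices <= n_beads(topology)))
  topology$tags[[tag]] <- sort(unique(c(topology$tags[[tag]], as.integer(indices))))
  topology
}

#' Bead indices carrying a tag
#'
#' @param topology A `cg_topology`.
#' @param tag Tag label (single string).
#' @return Integer vector of bead indices.
#' @export
beads_with_tag <- function(topology, tag) {
  if (!tag %in% names(topology$tags))
    stop("unknown tag: ", tag)
  topology$tags[[tag]]
}

#' Native-contact set
#'
#' Holds pairs (i, j) with native distances `r0` (A) and per-pair strengths
#' `eps` (kcal/mol), plus the global scale `sigma` applied to the whole set.
#'
#' @param pairs Data frame with columns i, j, r0, eps.
#' @param sigma Global dimensionless scale multiplying every pair strength.
#' @param label Provenance label (e.g. "Mcm2_H3H4", "intra", "duplex").
#' @return Object of class `contact_set`.
#' @export
contact_set <- function(pairs, sigma = 1, label = "contacts") {
  stopifnot(is.data.frame(pairs), all(c("i", "j", "r0", "eps") %in% names(pairs)))
  if (nrow(pairs)) {
    stopifnot(all(pairs$i < pairs$j), all(pairs$r0 > 0), all(pairs$eps > 0))
  }
  stopifnot(sigma >= 0)
  structure(list(pairs = pairs, sigma = sigma, label = label),
            class = "contact_set")
}

add_contact_set <- function(topology, cs) {
  stopifnot(inherits(cs, "contact_set"))
  topology$contacts[[cs$label]] <- cs
  topology
}

# Concatenate topology b after topology a, offsetting indices.
merge_topologies <- function(a, b) {
  off <- n_beads(a)
  b$beads$index <- b$beads$index + off
  shift <- function(m, cols) { if (nrow(m)) m[, cols] <- m[, cols] + off; m }
  a$beads <- rbind(a$beads, b$beads)
  a$chains <- rbind(a$chains,
                    transform(b$chains, first = first + off, last = last + off))
  a$bonds <- rbind(a$bonds, shift(b$bonds, 1:2))
  a$angles <- rbind(a$angles, shift(b$angles, 1:3))
  a$dihedrals <- rbind(a$dihedrals, shift(b$dihedrals, 1:4))
  for (tg in names(b$tags))
    a <- add_tag(a, tg, b$tags[[tg]] + off)
  for (cs in b$contacts) {
    cs$pairs$i <- cs$pairs$i + off
    cs$pairs$j <- cs$pairs$j + off
    a <- add_contact_set(a, cs)
  }
  a$idr_ranges <- c(a$idr_ranges, b$idr_ranges)
  if (is.na(a$junction_index) && !is.na(b$junction_index))
    a$junction_index <- b$junction_index + off
  a
}

in_ranges <- function(pos, ranges) {
  if (is.null(ranges) || length(ranges) == 0) return(rep(FALSE, length(pos)))
  out <- rep(FALSE, length(pos))
  for (rg in ranges) out <- out | (pos >= rg[1] & pos <= rg[2])
  out
}

#' Coarse-grain a protein structure to one bead per residue
#'
#' Places one bead at each C-alpha position. Folded regions receive
#' native-anchored bond, angle and dihedral terms; residues inside
#' disordered ranges receive 3.8 A harmonic bonds plus a weak generic angle
#' term and no dihedral, keeping the chain flexible.
#'
#' @param structure Parsed structure from [read_pdb()].
#' @param chain_spec Named list keyed by PDB chain id. Each element may
#'   contain `tags` (character vector applied to the whole chain) and
#'   `range_tags` (named list of residue ranges `c(from, to)` in the chain's
#'   own residue numbering).
#' @param idr_ranges Named list keyed by chain id; each element a list of
#'   residue-number ranges `c(from, to)` treated as intrinsically disordered.
#' @return List with `topology` (a `cg_topology`) and `coords` (N x 3 matrix, A).
#' @export
coarse_grain_protein <- function(structure, chain_spec, idr_ranges = list()) {
  if (is.character(chain_spec))
    chain_spec <- setNames(replicate(length(chain_spec), list(), simplify = FALSE),
                           chain_spec)
  topo <- new_topology()
  coords <- NULL
  for (ch in names(chain_spec)) {
    at <- structure$atoms[structure$atoms$chain == ch, , drop = FALSE]
    if (nrow(at) == 0) stop("chain not found in structure: ", ch)
    resnos <- sort(unique(at$resno))
    n <- length(resnos)
    xyz <- matrix(NA_real_, n, 3)
    names1 <- character(n)
    for (q in seq_len(n)) {
      rows <- at[at$resno == resnos[q], , drop = FALSE]
      ca <- rows[rows$elety == "CA", , drop = FALSE]
      if (nrow(ca) == 0)
        stop(sprintf("missing CA atom for residue %s%d of chain %s",
                     rows$resid[1], resnos[q], ch))
      xyz[q, ] <- as.numeric(ca[1, c("x", "y", "z")])
      aa <- AA3TO1[rows$resid[1]]
      names1[q] <- if (is.na(aa)) "X" else aa
    }
    idr <- in_ranges(resnos, idr_ranges[[ch]])
    off <- n_beads(topo)
    topo$beads <- rbind(topo$beads, data.frame(
      index = off + seq_len(n), chain_id = ch, site_kind = "residue",
      name = names1, charge = residue_formal_charge(names1),
      radius = BEAD_RADII[["residue"]],
      nt_index = NA_integer_, nt_from_junction = NA_integer_,
      stringsAsFactors = FALSE))
    topo$chains <- rbind(topo$chains, data.frame(
      chain_id = ch, molecule_class = "protein",
      first = off + 1L, last = off + n, stringsAsFactors = FALSE))
    if (n >= 2) {
      i <- seq_len(n - 1)
      nat <- !(idr[i] | idr[i + 1])
      r0 <- sqrt(rowSums((xyz[i, , drop = FALSE] - xyz[i + 1, , drop = FALSE])^2))
      r0[!nat] <- CA_STEP
      topo$bonds <- rbind(topo$bonds,
                          cbind(off + i, off + i + 1, r0, PROT_KBOND, as.numeric(nat)))
    }
    if (n >= 3) {
      i <- seq_len(n - 2)
      nat <- !(idr[i] | idr[i + 1] | idr[i + 2])
      th0 <- vapply(i, function(q) bead_angle(xyz[q, ], xyz[q + 1, ], xyz[q + 2, ]), 1)
      th0[!nat] <- IDR_THETA0
      kth <- ifelse(nat, PROT_KANGLE, IDR_KANGLE)
      topo$angles <- rbind(topo$angles,
                           cbind(off + i, off + i + 1, off + i + 2, th0, kth, as.numeric(nat)))
    }
    if (n >= 4) {
      i <- seq_len(n - 3)
      nat <- !(idr[i] | idr[i + 1] | idr[i + 2] | idr[i + 3])
      if (any(nat)) {
        ii <- i[nat]
        ph0 <- vapply(ii, function(q)
          bead_dihedral(xyz[q, ], xyz[q + 1, ], xyz[q + 2, ], xyz[q + 3, ]), 1)
        topo$dihedrals <- rbind(topo$dihedrals,
                                cbind(off + ii, off + ii + 1, off + ii + 2, off + ii + 3,
                                      ph0, PROT_KDIH, 1))
      }
    }
    if (any(idr)) {
      rr <- rle(idr)
      ends <- cumsum(rr$lengths)
      starts <- ends - rr$lengths + 1
      topo$idr_ranges[[ch]] <- lapply(which(rr$values), function(q)
        c(resnos[starts[q]], resnos[ends[q]]))
    }
    spec <- chain_spec[[ch]]
    for (tg in spec$tags) topo <- add_tag(topo, tg, off + seq_len(n))
    for (tg in names(spec$range_tags)) {
      rg <- spec$range_tags[[tg]]
      topo <- add_tag(topo, tg, off + which(resnos >= rg[1] & resnos <= rg[2]))
    }
    coords <- rbind(coords, xyz)
  }
  list(topology = topo, coords = coords)
}

bead_angle <- function(a, b, c) {
  u <- a - b; v <- c - b
  acos(max(-1, min(1, sum(u * v) / sqrt(sum(u^2) * sum(v^2)))))
}

bead_dihedral <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2], n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1])
  atan2(sum(m1 * n2) / sqrt(sum(b2^2)), sum(n1 * n2))
}

DNA_COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

# cylindrical placement of the three sites per nucleotide: radius (A),
# angular offset (deg) relative to the nucleotide phase, z offset (A).
# Strand 2 sites are the C2 image (negated offsets) so paired bases face
# each other across the helix axis and backbones sit across the grooves.
FIBER_SITES <- list(base = c(r = 4.0, dphi = -35, dz = 0),
                    sugar = c(r = 6.9, dphi = -40, dz = 1.0),
                    phosphate = c(r = 8.9, dphi = -70, dz = 2.2))
BDNA_RISE <- 3.38  # A per bp
BDNA_TWIST <- 36   # deg per bp

site_xyz <- function(phase_deg, z, site, flip = 1) {
  p <- FIBER_SITES[[site]]
  a <- (phase_deg + flip * p[["dphi"]]) * pi / 180
  c(p[["r"]] * cos(a), p[["r"]] * sin(a), z + flip * p[["dz"]])
}

# Build one strand's beads (5'->3'). Orientation: strand 1 runs 5'->3' with
# increasing z; strand 2 (complement) runs 5'->3' with decreasing z on the
# opposite side of the helix. The 5'-terminal nucleotide carries no phosphate.
strand_beads <- function(seq_chars, chain_id, strand2 = FALSE, n_bp = length(seq_chars)) {
  out <- list()
  for (q in seq_along(seq_chars)) {
    bp_index <- if (strand2) n_bp + 1 - q else q      # paired bp position
    phase <- (bp_index - 1) * BDNA_TWIST
    z <- (bp_index - 1) * BDNA_RISE
    flip <- if (strand2) -1 else 1
    sites <- if (q == 1) c("sugar", "base") else c("phosphate", "sugar", "base")
    for (s in sites) {
      out[[length(out) + 1]] <- list(
        chain_id = chain_id, site_kind = s, name = seq_chars[q],
        nt_index = q, xyz = site_xyz(phase, z, s, flip))
    }
  }
  out
}

#' Generate an ideal B-form DNA duplex
#'
#' Builds both complementary strands on an ideal B-form fiber (rise 3.38 A,
#' twist 36 deg/bp) with three beads per nucleotide at the base, sugar and
#' phosphate sites. By convention the 5'-terminal nucleotide of each strand
#' carries no phosphate bead. Native-anchored local terms stabilise the
#' backbone and a cross-strand native-contact set stabilises base pairing.
#'
#' @param sequence String over A/C/G/T (the 5'->3' sequence of strand 1).
#' @param chain_prefix Prefix for the two chain ids.
#' @return List with `topology` and `coords`; the duplex axis is +z with
#'   base pair 1 at z = 0.
#' @export
generate_bform_duplex <- function(sequence, chain_prefix = "dna") {
  chars <- strsplit(toupper(sequence), "")[[1]]
  if (length(chars) < 2) stop("sequence must contain at least 2 nucleotides")
  bad <- setdiff(unique(chars), names(DNA_COMPLEMENT))
  if (length(bad)) stop("invalid nucleotide(s) in sequence: ", paste(bad, collapse = ","))
  n <- length(chars)
  comp <- rev(unname(DNA_COMPLEMENT[chars]))   # complement strand, its 5'->3'
  b1 <- strand_beads(chars, paste0(chain_prefix, "_1"))
  b2 <- strand_beads(comp, paste0(chain_prefix, "_2"), strand2 = TRUE, n_bp = n)
  topo <- new_topology()
  all <- c(b1, b2)
  coords <- t(vapply(all, function(b) b$xyz, numeric(3)))
  topo$beads <- data.frame(
    index = seq_along(all),
    chain_id = vapply(all, function(b) b$chain_id, ""),
    site_kind = vapply(all, function(b) b$site_kind, ""),
    name = vapply(all, function(b) b$name, ""),
    charge = ifelse(vapply(all, function(b) b$site_kind, "") == "phosphate", -0.6, 0),
    radius = BEAD_RADII[vapply(all, function(b) b$site_kind, "")],
    nt_index = vapply(all, function(b) b$nt_index, 1L),
    nt_from_junction = NA_integer_, stringsAsFactors = FALSE)
  topo$chains <- data.frame(
    chain_id = c(paste0(chain_prefix, "_1"), paste0(chain_prefix, "_2")),
    molecule_class = "dna_strand",
    first = c(1L, length(b1) + 1L),
    last = c(length(b1), length(all)), stringsAsFactors = FALSE)
  for (ch in seq_len(2)) {
    rng <- topo$chains$first[ch]:topo$chains$last[ch]
    topo <- add_strand_local_terms(topo, coords, rng)
  }
  # base-pair and cross-stack contacts keep the duplex double-stranded
  base1 <- which(topo$beads$site_kind == "base" &
                   topo$beads$chain_id == paste0(chain_prefix, "_1"))
  base2 <- which(topo$beads$site_kind == "base" &
                   topo$beads$chain_id == paste0(chain_prefix, "_2"))
  prs <- NULL
  for (q in seq_len(n)) {
    i <- base1[q]
    partner_nt <- n + 1 - q
    for (dq in c(-1, 0, 1)) {
      pq <- partner_nt + dq
      if (pq >= 1 && pq <= n) {
        j <- base2[[which(topo$beads$nt_index[base2] == pq)]]
        ii <- min(i, j); jj <- max(i, j)
        prs <- rbind(prs, c(ii, jj, sqrt(sum((coords[ii, ] - coords[jj, ])^2))))
      }
    }
  }
  prs <- unique(as.data.frame(prs))
  names(prs) <- c("i", "j", "r0")
  prs$eps <- 1.0
  topo <- add_contact_set(topo, contact_set(prs, sigma = 1,
                                            label = paste0(chain_prefix, "_pairing")))
  list(topology = topo, coords = coords)
}

# backbone/base local terms for one strand given built coordinates
add_strand_local_terms <- function(topo, coords, rng, k_angle = DNA_KANGLE,
                                   with_dihedrals = TRUE) {
  kind <- topo$beads$site_kind[rng]
  nt <- topo$beads$nt_index[rng]
  idx <- function(q, s) {
    w <- rng[nt == q & kind == s]
    if (length(w)) w[1] else NA_integer_
  }
  nts <- sort(unique(nt))
  d <- function(i, j) sqrt(sum((coords[i, ] - coords[j, ])^2))
  for (q in nts) {
    S <- idx(q, "sugar"); B <- idx(q, "base"); P <- idx(q, "phosphate")
    if (!is.na(P)) topo$bonds <- rbind(topo$bonds, c(P, S, d(P, S), DNA_KBOND, 1))
    topo$bonds <- rbind(topo$bonds, c(min(S, B), max(S, B), d(S, B), DNA_KBOND, 1))
    Pn <- idx(q + 1, "phosphate")
    if (!is.na(Pn)) {
      topo$bonds <- rbind(topo$bonds, c(S, Pn, d(S, Pn), DNA_KBOND, 1))
      Sn <- idx(q + 1, "sugar")
      topo$angles <- rbind(topo$angles,
                           c(S, Pn, Sn, bead_angle(coords[S, ], coords[Pn, ], coords[Sn, ]),
                             k_angle, 1),
                           c(B, S, Pn, bead_angle(coords[B, ], coords[S, ], coords[Pn, ]),
                             k_angle, 1))
      if (!is.na(P))
        topo$angles <- rbind(topo$angles,
                             c(P, S, Pn, bead_angle(coords[P, ], coords[S, ], coords[Pn, ]),
                               k_angle, 1))
      if (with_dihedrals) {
        Pnn <- idx(q + 2, "phosphate")
        if (!is.na(Pnn))
          topo$dihedrals <- rbind(topo$dihedrals,
                                  c(S, Pn, Sn, Pnn,
                                    bead_dihedral(coords[S, ], coords[Pn, ],
                                                  coords[Sn, ], coords[Pnn, ]),
                                    DNA_KDIH, 1))
      }
    }
  }
  topo
}

rotation_to <- function(u) {
  # rotation matrix mapping +z onto unit vector u
  u <- u / sqrt(sum(u^2))
  z <- c(0, 0, 1)
  v <- c(z[2] * u[3] - z[3] * u[2], z[3] * u[1] - z[1] * u[3], z[1] * u[2] - z[2] * u[1])
  s <- sqrt(sum(v^2)); cth <- sum(z * u)
  if (s < 1e-12) {
    if (cth > 0) return(diag(3))
    return(diag(c(1, -1, -1)))
  }
  V <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3, byrow = TRUE)
  diag(3) + V + V %*% V * ((1 - cth) / s^2)
}

random_sequence <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                     collapse = "")

#' Assemble a replication-fork DNA topology
#'
#' Builds a branched DNA assembly: a parental duplex, leading and lagging
#' daughter-arm duplexes splayed away from the fork junction, and seeded
#' single-stranded gaps joining the junction to each arm. The last parental
#' base pair is the designated fork junction. Each nucleotide is annotated
#' with its distance (in nucleotides) from the junction, counting through
#' the single-stranded gap for daughter arms.
#'
#' @param parental_bp,leading_bp,lagging_bp Duplex lengths in base pairs.
#' @param leading_gap_nt,lagging_gap_nt Single-stranded gap lengths in nt.
#' @param seed Integer seed; assembly is bitwise reproducible.
#' @param splay_deg Half-angle between each daughter arm and the parental axis.
#' @return List with `topology` and `coords`. The parental duplex runs along
#'   +z with the junction base pair at the origin; daughter arms descend into
#'   z < 0.
#' @export
assemble_fork <- function(parental_bp, leading_bp, lagging_bp,
                          leading_gap_nt = 0, lagging_gap_nt = 0,
                          seed = 1, splay_deg = 50) {
  stopifnot(parental_bp >= 2, leading_bp >= 2, lagging_bp >= 2,
            leading_gap_nt >= 0, lagging_gap_nt >= 0)
  with_seed(seed, {
    par <- generate_bform_duplex(random_sequence(parental_bp), "parental")
    lead <- generate_bform_duplex(random_sequence(leading_bp), "leading")
    lag <- generate_bform_duplex(random_sequence(lagging_bp), "lagging")
    # parental: bp parental_bp at origin, extending to +z
    par$coords[, 3] <- par$coords[, 3] - (parental_bp - 1) * BDNA_RISE
    par$coords <- par$coords %*% diag(c(1, 1, -1))  # junction at z=0, body at +z
    th <- splay_deg * pi / 180
    place_arm <- function(arm, u, gap_nt) {
      R <- rotation_to(u)
      start <- u * (gap_nt * 3.6 + 8)
      arm$coords <- arm$coords %*% t(R) + matrix(start, nrow(arm$coords), 3, byrow = TRUE)
      arm
    }
    lead <- place_arm(lead, c(sin(th), 0, -cos(th)), leading_gap_nt)
    lag <- place_arm(lag, c(-sin(th), 0, -cos(th)), lagging_gap_nt)

    topo <- par$topology
    coords <- par$coords
    topo <- add_tag(topo, "parental_duplex", seq_len(n_beads(topo)))
    # distance from junction in bp for parental nucleotides
    nt <- topo$beads$nt_index
    ch1 <- topo$beads$chain_id == "parental_1"
    topo$beads$nt_from_junction <- ifelse(ch1, parental_bp - nt, nt - 1)
    base1 <- which(topo$beads$site_kind == "base" & ch1 &
                     topo$beads$nt_index == parental_bp)
    topo$junction_index <- base1[1]

    attach_arm <- function(topo, coords, arm, label, gap_nt, u) {
      off <- nrow(coords)
      arm$topology$beads$nt_from_junction <-
        gap_nt + ifelse(arm$topology$beads$chain_id == paste0(sub("_.*", "", label), "_1"),
                        arm$topology$beads$nt_index - 1,
                        max(arm$topology$beads$nt_index) - arm$topology$beads$nt_index)
      topo <- merge_topologies(topo, arm$topology)
      coords <- rbind(coords, arm$coords)
      topo <- add_tag(topo, label, off + seq_len(nrow(arm$coords)))
      list(topo, coords)
    }
    res <- attach_arm(topo, coords, lead, "leading_duplex", leading_gap_nt,
                      c(sin(th), 0, -cos(th)))
    topo <- res[[1]]; coords <- res[[2]]
    res <- attach_arm(topo, coords, lag, "lagging_duplex", lagging_gap_nt,
                      c(-sin(th), 0, -cos(th)))
    topo <- res[[1]]; coords <- res[[2]]

    add_gap <- function(topo, coords, gap_nt, label, from_xyz, to_xyz) {
      if (gap_nt == 0) return(list(topo, coords))
      res <- build_ssdna_chain(gap_nt, paste0(label, "_chain"), from_xyz, to_xyz,
                               fixed = coords)
      off <- nrow(coords)
      res$topology$beads$nt_from_junction <- res$topology$beads$nt_index
      topo <- merge_topologies(topo, res$topology)
      coords <- rbind(coords, res$coords)
      topo <- add_tag(topo, label, off + seq_len(nrow(res$coords)))
      list(topo, coords)
    }
    jxyz <- coords[topo$junction_index, ]
    lead_start <- coords[beads_with_tag(topo, "leading_duplex")[1], ]
    lag_start <- coords[beads_with_tag(topo, "lagging_duplex")[1], ]
    res <- add_gap(topo, coords, leading_gap_nt, "leading_ssDNA", jxyz, lead_start)
    topo <- res[[1]]; coords <- res[[2]]
    res <- add_gap(topo, coords, lagging_gap_nt, "lagging_ssDNA", jxyz, lag_start)
    topo <- res[[1]]; coords <- res[[2]]
    list(topology = topo, coords = coords)
  })
}

# single-stranded DNA chain whose sugar backbone follows a seeded
# self-avoiding bridge between two anchor points
build_ssdna_chain <- function(gap_nt, chain_id, from_xyz, to_xyz, fixed = NULL,
                              max_retries = 500) {
  dAB <- sqrt(sum((to_xyz - from_xyz)^2))
  if ((gap_nt + 1) * SS_STEP < 1.3 * dAB) {
    # taut gap: the strand is stretched nearly straight between its anchors
    frac <- seq_len(gap_nt) / (gap_nt + 1)
    path <- outer(frac, to_xyz - from_xyz) +
      matrix(from_xyz, gap_nt, 3, byrow = TRUE)
  } else {
    path <- bridge_walk(gap_nt, from_xyz, to_xyz, step = SS_STEP, fixed = fixed,
                        max_retries = max_retries)
  }
  topo <- new_topology()
  beads <- list(); coords <- NULL
  seqs <- sample(c("A", "C", "G", "T"), gap_nt, replace = TRUE)
  for (q in seq_len(gap_nt)) {
    s <- path[q, ]
    dirv <- if (q < gap_nt) path[min(q + 1, gap_nt), ] - s else s - path[max(1, q - 1), ]
    nv <- sqrt(sum(dirv^2)); dirv <- if (nv > 0) dirv / nv else c(0, 0, 1)
    perp <- c(-dirv[2], dirv[1], 0)
    np <- sqrt(sum(perp^2)); perp <- if (np > 1e-6) perp / np else c(1, 0, 0)
    sites <- if (q == 1) c("sugar", "base") else c("phosphate", "sugar", "base")
    for (sk in sites) {
      xyz <- switch(sk, sugar = s, base = s + 4.0 * perp,
                    phosphate = s - SS_STEP / 2 * dirv + 1.5 * perp)
      beads[[length(beads) + 1]] <- list(site_kind = sk, name = seqs[q],
                                         nt_index = q, xyz = xyz)
      coords <- rbind(coords, xyz)
    }
  }
  topo$beads <- data.frame(
    index = seq_along(beads), chain_id = chain_id,
    site_kind = vapply(beads, function(b) b$site_kind, ""),
    name = vapply(beads, function(b) b$name, ""),
    charge = ifelse(vapply(beads, function(b) b$site_kind, "") == "phosphate", -0.6, 0),
    radius = BEAD_RADII[vapply(beads, function(b) b$site_kind, "")],
    nt_index = vapply(beads, function(b) b$nt_index, 1L),
    nt_from_junction = NA_integer_, stringsAsFactors = FALSE)
  topo$chains <- data.frame(chain_id = chain_id, molecule_class = "dna_strand",
                            first = 1L, last = length(beads), stringsAsFactors = FALSE)
  topo <- add_strand_local_terms(topo, coords, seq_len(nrow(coords)),
                                 k_angle = SS_KANGLE, with_dihedrals = FALSE)
  rownames(coords) <- NULL
  list(topology = topo, coords = coords)
}

# m-bead bridge from A to B with fixed step length; positions are exact
# multiples of `step` apart along the chain. Retries with fresh noise until
# the end lands within bonding range of B and no clash occurs.
bridge_walk <- function(m, A, B, step, fixed = NULL, excluded = 2.0,
                        max_retries = 500, terminal = FALSE) {
  if (m < 1) stop("bridge requires at least one bead")
  dAB <- sqrt(sum((B - A)^2))
  if (!terminal && (m + 1) * step < dAB)
    stop(sprintf("gap of %d beads cannot bridge %.1f A (max span %.1f A)",
                 m, dAB, (m + 1) * step))
  for (try in seq_len(max_retries)) {
    noise_sd <- step * 0.6 * (1 + try / 20)
    wp <- matrix(NA_real_, m, 3)
    for (q in seq_len(m)) {
      frac <- q / (m + 1)
      wp[q, ] <- A + frac * (B - A) + rnorm(3, 0, noise_sd)
    }
    path <- matrix(NA_real_, m, 3)
    prev <- A
    ok <- TRUE
    for (q in seq_len(m)) {
      dirv <- wp[q, ] - prev
      nv <- sqrt(sum(dirv^2))
      if (nv < 1e-9) { ok <- FALSE; break }
      path[q, ] <- prev + step * dirv / nv
      if (!is.null(fixed) && nrow(fixed)) {
        d2 <- rowSums((fixed - matrix(path[q, ], nrow(fixed), 3, byrow = TRUE))^2)
        if (min(d2) < excluded^2) { ok <- FALSE; break }
      }
      if (q > 1) {
        d2p <- rowSums((path[seq_len(q - 1), , drop = FALSE] -
                          matrix(path[q, ], q - 1, 3, byrow = TRUE))^2)
        if (min(d2p) < excluded^2) { ok <- FALSE; break }
      }
      prev <- path[q, ]
    }
    if (!ok) next
    if (terminal || sqrt(sum((path[m, ] - B)^2)) <= step * 1.6) return(path)
  }
  stop(sprintf("could not place %d-bead bridge after %d retries", m, max_retries))
}

#' Derive a native-contact set from reference coordinates
#'
#' Two beads form a native contact when any mapped heavy-atom pair (or, if no
#' atom map is supplied, the bead pair itself) lies within the cutoff in the
#' reference coordinates. Intra-chain pairs additionally require a sequence
#' separation of at least `min_seq_sep` beads.
#'
#' @param topology A `cg_topology`.
#' @param coords Reference bead coordinates (N x 3).
#' @param heavy_atom_map Optional list (length N) of per-bead heavy-atom
#'   coordinate matrices; `NULL` elements fall back to the bead position.
#' @param cutoff Heavy-atom distance cutoff, A (default 6.5).
#' @param sigma Global scale of the resulting set.
#' @param eps_rule Per-pair strength: a single number or a function(i, j).
#' @param label Label for the resulting `contact_set`.
#' @param between Optional list of two tag names restricting pairs to one
#'   bead from each group (cross-molecular sets).
#' @param min_seq_sep Minimum |i - j| for intra-chain pairs.
#' @return A `contact_set`; `r0` is the bead-bead distance in `coords`.
#' @export
derive_native_contacts <- function(topology, coords, heavy_atom_map = NULL,
                                   cutoff = 6.5, sigma = 1, eps_rule = 0.3,
                                   label = "native", between = NULL,
                                   min_seq_sep = 4) {
  stopifnot(cutoff > 0)
  n <- n_beads(topology)
  chain_of <- rep(NA_character_, n)
  for (q in seq_len(nrow(topology$chains)))
    chain_of[topology$chains$first[q]:topology$chains$last[q]] <-
    topology$chains$chain_id[q]
  if (!is.null(between)) {
    ga <- beads_with_tag(topology, between[[1]])
    gb <- beads_with_tag(topology, between[[2]])
    cand <- expand.grid(i = ga, j = gb)
    cand <- cand[cand$i != cand$j, ]
    sw <- cand$i > cand$j
    tmp <- cand$i[sw]; cand$i[sw] <- cand$j[sw]; cand$j[sw] <- tmp
    cand <- unique(cand)
  } else {
    cand <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    cand <- data.frame(i = cand[, 1], j = cand[, 2])
  }
  same <- chain_of[cand$i] == chain_of[cand$j]
  cand <- cand[!same | abs(cand$i - cand$j) >= min_seq_sep, , drop = FALSE]
  db <- sqrt(rowSums((coords[cand$i, , drop = FALSE] -
                        coords[cand$j, , drop = FALSE])^2))
  if (is.null(heavy_atom_map)) {
    keep <- db < cutoff
  } else {
    # pre-filter by bead distance, then test atom pairs
    pre <- db < cutoff + 15
    keep <- rep(FALSE, nrow(cand))
    for (q in which(pre)) {
      ai <- heavy_atom_map[[cand$i[q]]]
      aj <- heavy_atom_map[[cand$j[q]]]
      if (is.null(ai)) ai <- matrix(coords[cand$i[q], ], 1, 3)
      if (is.null(aj)) aj <- matrix(coords[cand$j[q], ], 1, 3)
      dmin2 <- min(outer(seq_len(nrow(ai)), seq_len(nrow(aj)), Vectorize(function(a, b)
        sum((ai[a, ] - aj[b, ])^2))))
      keep[q] <- dmin2 < cutoff^2
    }
  }
  pairs <- data.frame(i = cand$i[keep], j = cand$j[keep], r0 = db[keep])
  pairs$eps <- if (is.function(eps_rule))
    mapply(eps_rule, pairs$i, pairs$j) else rep(eps_rule, nrow(pairs))
  contact_set(pairs, sigma = sigma, label = label)
}

#' Charge context for context-dependent electrostatics
#'
#' DNA phosphate beads expose two charges selected by the interaction
#' partner's molecule class: a reduced charge for DNA-DNA pairs (counter-ion
#' condensation) and the full charge for protein-DNA pairs (counter-ion
#' release on binding).
#'
#' @param intra_dna_phosphate_charge Phosphate charge seen by DNA partners (e).
#' @param cross_phosphate_charge Phosphate charge seen by protein partners (e).
#' @param overrides Optional data frame (index, charge) of per-bead charges
#'   applied in both contexts (e.g. externally computed surface charges).
#' @return Object of class `charge_context`.
#' @export
charge_context <- function(intra_dna_phosphate_charge = -0.6,
                           cross_phosphate_charge = -1.0,
                           overrides = NULL) {
  structure(list(intra = intra_dna_phosphate_charge,
                 cross = cross_phosphate_charge,
                 overrides = overrides), class = "charge_context")
}

#' Assign per-bead charges (dual-valued for phosphates)
#'
#' Protein beads follow the formal-charge rule (K/R -> +1, D/E -> -1, else 0)
#' in both contexts. Phosphate beads carry the two context-dependent charges
#' of the supplied [charge_context()]. Beads whose tags intersect
#' `neutralize_tags` are zeroed in all contexts.
#'
#' @param topology A `cg_topology`.
#' @param context A [charge_context()].
#' @param neutralize_tags Character vector of tags whose beads are neutralised.
#' @return Data frame with columns `index`, `q_dna_ctx` (charge exposed to DNA
#'   partners) and `q_protein_ctx` (charge exposed to protein partners).
#' @export
assign_charges <- function(topology, context = charge_context(),
                           neutralize_tags = character()) {
  b <- topology$beads
  q_dna <- numeric(nrow(b))
  q_pro <- numeric(nrow(b))
  is_res <- b$site_kind == "residue"
  q_dna[is_res] <- q_pro[is_res] <- residue_formal_charge(b$name[is_res])
  is_p <- b$site_kind == "phosphate"
  q_dna[is_p] <- context$intra
  q_pro[is_p] <- context$cross
  if (!is.null(context$overrides)) {
    ov <- context$overrides
    if (any(ov$index < 1 | ov$index > nrow(b)))
      stop("charge override index out of range")
    q_dna[ov$index] <- q_pro[ov$index] <- ov$charge
  }
  for (tg in neutralize_tags) {
    idx <- beads_with_tag(topology, tg)
    q_dna[idx] <- q_pro[idx] <- 0
  }
  data.frame(index = b$index, q_dna_ctx = q_dna, q_protein_ctx = q_pro)
}

#' Model disordered-span conformations as self-avoiding walks
#'
#' Fills coordinate gaps (rows of NA) with a seeded self-avoiding random walk
#' of fixed 3.8 A steps connecting the flanking anchored beads; terminal
#' spans walk outward from their single anchor. Reproducible for a given seed.
#'
#' @param topology A `cg_topology`.
#' @param fixed_coords N x 3 matrix with NA rows for unresolved beads.
#' @param seed Integer seed.
#' @param max_retries Placement retries before a hard error.
#' @return Completed N x 3 coordinate matrix.
#' @export
model_idr_conformation <- function(topology, fixed_coords, seed = 1,
                                   max_retries = 200) {
  stopifnot(nrow(fixed_coords) == n_beads(topology))
  with_seed(seed, {
    coords <- fixed_coords
    for (ch in seq_len(nrow(topology$chains))) {
      rng <- topology$chains$first[ch]:topology$chains$last[ch]
      miss <- is.na(coords[rng, 1])
      if (!any(miss)) next
      rr <- rle(miss)
      ends <- cumsum(rr$lengths); starts <- ends - rr$lengths + 1
      for (q in which(rr$values)) {
        span <- rng[starts[q]:ends[q]]
        m <- length(span)
        before <- if (starts[q] > 1) rng[starts[q] - 1] else NA
        after <- if (ends[q] < length(rng)) rng[ends[q] + 1] else NA
        fixed <- coords[!is.na(coords[, 1]), , drop = FALSE]
        if (!is.na(before) && !is.na(after)) {
          path <- bridge_walk(m, coords[before, ], coords[after, ], CA_STEP,
                              fixed = fixed, max_retries = max_retries)
        } else if (!is.na(before)) {
          path <- bridge_walk(m, coords[before, ],
                              coords[before, ] + c(0, 0, m * CA_STEP), CA_STEP,
                              fixed = fixed, max_retries = max_retries,
                              terminal = TRUE)
        } else if (!is.na(after)) {
          path <- bridge_walk(m, coords[after, ],
                              coords[after, ] + c(0, 0, m * CA_STEP), CA_STEP,
                              fixed = fixed, max_retries = max_retries,
                              terminal = TRUE)
          path <- path[rev(seq_len(m)), , drop = FALSE]
        } else stop("span has no anchored neighbour and chain is fully unresolved")
        coords[span, ] <- path
      }
    }
    coords
  })
}

# evaluate expr with a temporarily seeded RNG, restoring the caller's state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
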