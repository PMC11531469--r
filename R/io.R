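## Readers and writers: PDB input (via bio3d) and CG-bead PDB output,
## binary DCD trajectories with JSON metadata sidecars, topology and
## configuration JSON, TSV tables and OBJ meshes.

#' Read a PDB structure
#'
#' Parses a PDB file into a flat atom table. Alternate locations are
#' resolved to the highest occupancy, models beyond the first are ignored
#' with a notice, and insertion codes are rejected.
#'
#' @param path Path to a PDB file.
#' @param chains Optional chain selection.
#' @return List of class `pdb_structure` with `atoms` (data frame: chain,
#'   resno, resid, elety, x, y, z, occ).
#' @export
read_pdb <- function(path, chains = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  atom_lines <- grep("^ATOM  |^HETATM", lines)
  for (ln in atom_lines) {
    l <- lines[ln]
    if (nchar(l) < 54 ||
        is.na(suppressWarnings(as.numeric(substr(l, 31, 38)))) ||
        is.na(suppressWarnings(as.numeric(substr(l, 39, 46)))) ||
        is.na(suppressWarnings(as.numeric(substr(l, 47, 54)))))
      stop(sprintf("unparseable ATOM record at line %d of %s", ln, path))
  }
  if (sum(grepl("^MODEL", lines)) > 1)
    message("multiple models in ", path, "; using the first")
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (any(!is.na(at$insert) & at$insert != ""))
    stop("insertion codes are not supported (found in ", path, ")")
  if (!is.null(chains)) at <- at[at$chain %in% chains, , drop = FALSE]
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1
  # resolve altlocs: keep the highest-occupancy record per atom
  key <- paste(at$chain, at$resno, at$elety)
  at <- at[order(key, -at$o), , drop = FALSE]
  at <- at[!duplicated(paste(at$chain, at$resno, at$elety)), , drop = FALSE]
  at <- at[order(at$chain, at$resno), , drop = FALSE]
  structure(list(atoms = data.frame(
    chain = at$chain, resno = at$resno, resid = at$resid, elety = at$elety,
    x = at$x, y = at$y, z = at$z, occ = at$o, stringsAsFactors = FALSE),
    path = path), class = "pdb_structure")
}

#' Heavy-atom map for contact derivation
#'
#' Builds the per-bead list of heavy-atom coordinates used by
#' [derive_native_contacts()], matching beads to the residues of a parsed
#' structure in chain order.
#'
#' @param structure A [read_pdb()] result.
#' @param topology The `cg_topology` built from the same chains.
#' @return List of per-bead coordinate matrices.
#' @export
heavy_atom_map <- function(structure, topology) {
  at <- structure$atoms
  at <- at[!grepl("^H", at$elety), , drop = FALSE]
  out <- vector("list", n_beads(topology))
  for (q in seq_len(nrow(topology$chains))) {
    ch <- topology$chains$chain_id[q]
    rows <- at[at$chain == ch, , drop = FALSE]
    if (!nrow(rows)) next
    resnos <- sort(unique(rows$resno))
    rng <- topology$chains$first[q]:topology$chains$last[q]
    for (w in seq_along(rng)) {
      if (w > length(resnos)) break
      rr <- rows[rows$resno == resnos[w], c("x", "y", "z"), drop = FALSE]
      out[[rng[w]]] <- as.matrix(rr)
    }
  }
  out
}

#' Write coarse-grained beads as a pseudo-atom PDB
#'
#' One pseudo-atom per bead; the bead kind is encoded in the atom-name field
#' (CA for residues, DB/DS/DP for base/sugar/phosphate sites).
#'
#' @param topology A `cg_topology`.
#' @param coords N x 3 coordinates.
#' @param path Output path.
#' @export
write_cg_pdb <- function(topology, coords, path) {
  b <- topology$beads
  kinds <- c(residue = "CA", base = "DB", sugar = "DS", phosphate = "DP")
  chmap <- setNames(rep(c(LETTERS, letters, 0:9),
                        length.out = nrow(topology$chains)),
                    topology$chains$chain_id)
  con <- file(path, "w")
  on.exit(close(con))
  for (q in seq_len(nrow(b))) {
    resno <- if (!is.na(b$nt_index[q])) b$nt_index[q] else {
      ch <- topology$chains[topology$chains$chain_id == b$chain_id[q], ]
      q - ch$first + 1L
    }
    resname <- if (b$site_kind[q] == "residue") {
      m <- names(AA3TO1)[match(b$name[q], AA3TO1)]
      if (is.na(m)) "UNK" else m
    } else paste0("D", b$name[q], " ")
    writeLines(sprintf("ATOM  %5d %-4s%-4s%s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
                       q %% 100000, kinds[[b$site_kind[q]]],
                       substr(resname, 1, 3), chmap[[b$chain_id[q]]],
                       resno %% 10000, coords[q, 1], coords[q, 2], coords[q, 3],
                       1.0, 0.0), con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Write a trajectory as DCD with a JSON metadata sidecar
#'
#' Standard CHARMM-style DCD (single-precision coordinates); run metadata,
#' step ids and energies go to `<path>.json`.
#'
#' @param traj A `cg_trajectory` (non-empty).
#' @param path Output path (conventionally `.dcd`).
#' @export
write_trajectory <- function(traj, path) {
  d <- dim(traj$frames)
  if (is.null(d) || d[1] == 0) stop("cannot write an empty trajectory")
  nf <- d[1]; n <- d[2]
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4)
  wi(84)
  writeChar("CORD", con, nchars = 4, eos = NULL)
  step0 <- if (length(traj$step_ids)) traj$step_ids[1] else 1
  dstep <- if (length(traj$step_ids) > 1) diff(traj$step_ids[1:2]) else 1
  wi(c(nf, step0, dstep, 0, 0, 0, 0, 0, 0))
  writeBin(1, con, size = 4)  # timestep slot (float)
  wi(c(0, 0, 0, 0, 0, 0, 0, 0, 0, 24))
  wi(84)
  title <- sprintf("%-80s", "cgfork trajectory")
  wi(4 + 80)
  wi(1)
  writeChar(title, con, nchars = 80, eos = NULL)
  wi(4 + 80)
  wi(4); wi(n); wi(4)
  for (f in seq_len(nf)) {
    for (k in 1:3) {
      wi(4 * n)
      writeBin(as.numeric(traj$frames[f, , k]), con, size = 4)
      wi(4 * n)
    }
  }
  meta <- list(n_frames = nf, n_beads = n, step_ids = traj$step_ids,
               epot = traj$epot, ekin = traj$ekin,
               params = unclass(traj$params), metadata = traj$metadata,
               package_version = as.character(utils::packageVersion("cgfork")))
  meta$metadata$coords_last <- NULL
  meta$metadata$vels_last <- NULL
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a DCD trajectory written by [write_trajectory()]
#'
#' @param path Path to the `.dcd` file; the `<path>.json` sidecar is loaded
#'   when present.
#' @param n_beads Expected bead count; mismatch is an error.
#' @return A `cg_trajectory`.
#' @export
read_trajectory <- function(path, n_beads = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(k = 1) readBin(con, "integer", n = k, size = 4)
  if (ri() != 84) stop("not a DCD file: ", path)
  magic <- readChar(con, 4, useBytes = TRUE)
  if (magic != "CORD") stop("not a DCD file: ", path)
  icntrl_a <- ri(9)
  invisible(readBin(con, "numeric", n = 1, size = 4))
  invisible(ri(10))
  if (ri() != 84) stop("corrupt DCD header")
  tlen <- ri()
  invisible(ri())  # ntitle
  invisible(readChar(con, tlen - 4, useBytes = TRUE))
  if (ri() != tlen) stop("corrupt DCD title block")
  if (ri() != 4) stop("corrupt DCD natom block")
  n <- ri()
  if (ri() != 4) stop("corrupt DCD natom block")
  if (!is.null(n_beads) && n != n_beads)
    stop(sprintf("bead count mismatch: file has %d, expected %d", n, n_beads))
  nf <- icntrl_a[1]
  frames <- array(NA_real_, c(nf, n, 3))
  for (f in seq_len(nf)) {
    for (k in 1:3) {
      nb <- ri()
      if (length(nb) == 0 || nb != 4 * n)
        stop(sprintf("frame/bead count mismatch reading frame %d", f))
      frames[f, , k] <- readBin(con, "numeric", n = n, size = 4)
      if (ri() != 4 * n) stop("corrupt DCD frame record")
    }
  }
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar,
                                                        simplifyVector = TRUE)
  else list()
  new_trajectory(frames,
                 if (!is.null(meta$step_ids)) meta$step_ids else seq_len(nf),
                 if (!is.null(meta$epot)) meta$epot else numeric(0),
                 if (!is.null(meta$ekin)) meta$ekin else numeric(0),
                 meta$params, if (!is.null(meta$metadata)) meta$metadata else list())
}

#' Serialise a topology to JSON
#'
#' @param topology A `cg_topology`.
#' @param path Output path.
#' @export
write_topology_json <- function(topology, path) {
  obj <- list(
    beads = topology$beads,
    chains = topology$chains,
    bonds = as.data.frame(topology$bonds),
    angles = as.data.frame(topology$angles),
    dihedrals = as.data.frame(topology$dihedrals),
    tags = topology$tags,
    idr_ranges = topology$idr_ranges,
    contacts = lapply(unname(topology$contacts), function(cs)
      list(label = cs$label, sigma = cs$sigma, pairs = cs$pairs)),
    junction_index = topology$junction_index)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' Read a topology from JSON
#'
#' @param path Path written by [write_topology_json()].
#' @return A `cg_topology`.
#' @export
read_topology_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  topo <- new_topology()
  topo$beads <- as.data.frame(obj$beads)
  topo$beads$nt_index <- as.integer(topo$beads$nt_index)
  topo$beads$nt_from_junction <- as.integer(topo$beads$nt_from_junction)
  topo$chains <- as.data.frame(obj$chains)
  as_mat <- function(df, template) {
    m <- as.matrix(as.data.frame(df))
    if (!nrow(m)) return(template)
    colnames(m) <- colnames(template)
    m
  }
  empty <- new_topology()
  topo$bonds <- as_mat(obj$bonds, empty$bonds)
  topo$angles <- as_mat(obj$angles, empty$angles)
  topo$dihedrals <- as_mat(obj$dihedrals, empty$dihedrals)
  topo$tags <- lapply(obj$tags, as.integer)
  topo$idr_ranges <- obj$idr_ranges
  if (length(obj$contacts)) {
    cs_list <- if (is.data.frame(obj$contacts)) split(obj$contacts,
                                                      seq_len(nrow(obj$contacts)))
    else obj$contacts
    for (cs in cs_list)
      topo <- add_contact_set(topo, contact_set(as.data.frame(cs$pairs),
                                                sigma = cs$sigma,
                                                label = cs$label))
  }
  topo$junction_index <- if (is.null(obj$junction_index)) NA_integer_
  else as.integer(obj$junction_index)
  topo
}

#' Write an iso-surface mesh as Wavefront OBJ
#'
#' @param mesh Result of [iso_surface()].
#' @param path Output path.
#' @export
write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(mesh$vertices)) {
    writeLines(sprintf("v %.4f %.4f %.4f", mesh$vertices[, 1],
                       mesh$vertices[, 2], mesh$vertices[, 3]), con)
    writeLines(sprintf("f %d %d %d %d", mesh$faces[, 1], mesh$faces[, 2],
                       mesh$faces[, 3], mesh$faces[, 4]), con)
  }
  invisible(path)
}

CONFIG_KEYS <- c("system", "dynamics", "analysis", "output", "seeds")

#' Read and validate a run configuration
#'
#' JSON configuration with sections `system` (toy spec or fork lengths,
#' tags, charge context, sigma overrides), `dynamics` (Langevin and replica
#' parameters, confinement), `analysis` (cutoffs, classifier thresholds,
#' grid spacing, iso-level), `output` (paths, intervals) and `seeds`.
#' Unknown top-level keys are rejected.
#'
#' @param path Path to a JSON config.
#' @return Named list of validated sections.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  unknown <- setdiff(names(cfg), CONFIG_KEYS)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         " (allowed: ", paste(CONFIG_KEYS, collapse = ", "), ")")
  cfg
}

#' Write the resolved configuration next to run outputs
#'
#' @param cfg Configuration list.
#' @param path Output path.
#' @export
write_config <- function(cfg, path) {
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
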