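# Synthetic octameric-pore fixture generator.
#
# Builds desk-scale topology + trajectory fixtures in which the H-bond
# network is known exactly by construction. Peptides are rigid
# pseudo-helices of CA pseudo-atoms on a ring; each planted edge gets its
# own donor/acceptor surrogate site pair plus dedicated bridging waters,
# laid out in a spatially isolated "lane" so that scheduled presence or
# absence of the edge is the only thing that determines whether the
# geometric H-bond criteria are met. Frames are scheduled geometric
# constructions, not dynamics.

.DEFAULT_SEQ <- "AAAEAAKEAATAAAEAQSWAKAAAAA"

.default_planted_edges <- function(n_peptides = 8) {
  nxt <- function(p) p %% n_peptides + 1
  ss <- data.frame(
    node_a = sprintf("P%d:18", seq_len(n_peptides)),
    node_b = sprintf("P%d:15", nxt(seq_len(n_peptides))),
    n_waters = rep(c(0L, 1L, 2L, 3L), length.out = n_peptides),
    presence = rep(c(1, 0.9, 0.8, 0.6), length.out = n_peptides),
    stringsAsFactors = FALSE)
  intra <- data.frame(
    node_a = sprintf("P%d:4", 1:4), node_b = sprintf("P%d:8", 1:4),
    n_waters = 2L, presence = 0.7, stringsAsFactors = FALSE)
  lip <- data.frame(
    node_a = sprintf("P%d:17", 1:4), node_b = sprintf("L%d", 1:4),
    n_waters = 1L, presence = 0.85, stringsAsFactors = FALSE)
  rbind(ss, intra, lip)
}

.default_lipid_layout <- function() {
  pore <- data.frame(
    lipid_id = 1:8,
    leaflet = c(1, -1, 1, -1, 1, -1, 1, -1),
    dist = c(6, 8, 10, 12, 14, 14.9, 15.1, 18),
    depth = c(8, 6, 0, 0, 3, 0, 0, 0))
  bulk <- data.frame(lipid_id = 9:32,
                     leaflet = rep(c(1, -1), each = 12),
                     dist = 40, depth = 0)
  rbind(pore, bulk)
}

#' Specification of a synthetic pore system
#'
#' Describes an idealized octameric transmembrane pore with planted,
#' fully known H-bond connectivity: which node pairs are connected, with
#' how many bridging waters, and in which fraction of frames. The
#' generator realizes each planted edge with dedicated surrogate
#' donor/acceptor sites and bridging waters placed to satisfy the
#' geometric H-bond criteria exactly when scheduled present and to
#' violate the distance cutoff by at least 0.5 Å when absent.
#'
#' @param n_peptides number of peptides (default 8).
#' @param residues_per_peptide residues per peptide (default 26).
#' @param sequence one-letter sequence of the synthetic peptide; length
#'   must equal `residues_per_peptide`.
#' @param ring_radius pore ring radius (Å, default 20).
#' @param phosphate_plane_z leaflet phosphate plane position (Å, default
#'   19, i.e. planes at ±19).
#' @param planted_edges data.frame with `node_a`, `node_b` (node
#'   references `"P<peptide>:<position>"` or `"L<lipid_id>"`), `n_waters`
#'   (0-3) and `presence` (per-frame presence probability in \[0, 1\]);
#'   an optional `schedule` list column of logical vectors overrides the
#'   probability with an explicit per-frame schedule.
#' @param lipid_layout data.frame with `lipid_id`, `leaflet` (+1/-1),
#'   `dist` (Å, exact minimum distance of the phosphate from the nearest
#'   peptide atom) and `depth` (Å below the leaflet phosphate plane,
#'   toward the bilayer center).
#' @param water_column `"continuous"` (water wire crossing the bilayer),
#'   `"gapped"` (wire with a >= 5 Å gap at the midplane) or `"none"`.
#' @param trp_position probe residue position carrying a CB side-chain
#'   marker (default 19).
#' @param deinserted_peptides peptide ids displaced outward along +z by
#'   `deinsert_shift`, emulating peptides drifting toward an interfacial
#'   state.
#' @param deinsert_shift outward displacement (Å, default 12).
#' @param n_frames number of frames (default 100).
#' @param frame_interval_ps frame spacing (ps, default 10).
#' @param seed RNG seed for presence scheduling.
#' @return An object of class `pore_spec`.
#' @export
pore_spec <- function(n_peptides = 8, residues_per_peptide = 26,
                      sequence = .DEFAULT_SEQ, ring_radius = 20,
                      phosphate_plane_z = 19,
                      planted_edges = .default_planted_edges(n_peptides),
                      lipid_layout = .default_lipid_layout(),
                      water_column = c("continuous", "gapped", "none"),
                      trp_position = 19, deinserted_peptides = integer(),
                      deinsert_shift = 12, n_frames = 100,
                      frame_interval_ps = 10, seed = 1) {
  water_column <- match.arg(water_column)
  if (ring_radius <= 0) stop("ring_radius must be positive")
  if (nchar(sequence) != residues_per_peptide)
    stop("sequence length must equal residues_per_peptide")
  if (nrow(planted_edges) > 99)
    stop("at most 99 planted edges are supported")
  if (any(planted_edges$n_waters < 0 | planted_edges$n_waters > 3))
    stop("planted n_waters must be in 0..3")
  has_sched <- if (is.null(planted_edges$schedule))
    rep(FALSE, nrow(planted_edges))
  else !vapply(planted_edges$schedule, is.null, logical(1))
  p <- planted_edges$presence
  if (any(is.na(p) & !has_sched))
    stop("presence may be NA only for edges with an explicit schedule")
  if (any(!is.na(p) & (p < 0 | p > 1)))
    stop("presence probabilities must be in [0, 1]")
  pair_key <- paste(pmin(planted_edges$node_a, planted_edges$node_b),
                    pmax(planted_edges$node_a, planted_edges$node_b))
  if (anyDuplicated(pair_key))
    stop("planted edges must reference distinct node pairs")
  structure(list(
    n_peptides = n_peptides, residues_per_peptide = residues_per_peptide,
    sequence = toupper(sequence), ring_radius = ring_radius,
    phosphate_plane_z = phosphate_plane_z, planted_edges = planted_edges,
    lipid_layout = lipid_layout, water_column = water_column,
    trp_position = trp_position,
    deinserted_peptides = as.integer(deinserted_peptides),
    deinsert_shift = deinsert_shift, n_frames = as.integer(n_frames),
    frame_interval_ps = frame_interval_ps, seed = as.integer(seed)
  ), class = "pore_spec")
}

#' Realize the per-edge presence schedule
#'
#' Draws, for every planted edge, the per-frame presence indicators from
#' its presence probability (an explicit `schedule` column, when present,
#' is used verbatim). Deterministic given `spec$seed`. The manifest
#' records the realized fractions, not the nominal probabilities.
#'
#' @param spec a [pore_spec].
#' @param seed optional override of `spec$seed`.
#' @return logical matrix, edges x frames.
#' @export
schedule_presence <- function(spec, seed = spec$seed) {
  pe <- spec$planted_edges
  nfr <- spec$n_frames
  m <- matrix(FALSE, nrow(pe), nfr)
  set.seed(seed)
  for (i in seq_len(nrow(pe))) {
    if (!is.null(pe$schedule) && !is.null(pe$schedule[[i]])) {
      s <- pe$schedule[[i]]
      if (length(s) != nfr) stop("explicit schedule must have n_frames entries")
      m[i, ] <- as.logical(s)
    } else if (pe$presence[i] >= 1) {
      m[i, ] <- TRUE
    } else if (pe$presence[i] > 0) {
      m[i, ] <- stats::runif(nfr) < pe$presence[i]
    }
  }
  m
}

# resolve "P3:18" to the topology node key "P3:S18"; lipid refs pass through
.resolve_node <- function(ref, seq_letters) {
  if (startsWith(ref, "L")) return(ref)
  m <- regmatches(ref, regexec("^P([0-9]+):([0-9]+)$", ref))[[1]]
  if (length(m) != 3) stop("bad node reference: ", ref)
  pos <- as.integer(m[3])
  sprintf("P%s:%s%d", m[2], seq_letters[pos], pos)
}

.three_letter <- function() {
  stats::setNames(names(.ONE_LETTER)[!duplicated(.ONE_LETTER)],
                  .ONE_LETTER[!duplicated(.ONE_LETTER)])
}

#' Build a synthetic pore system with known ground truth
#'
#' Constructs the topology, all frames, and a ground-truth manifest
#' recording exactly what an analysis of the system must recover: the
#' planted edge set with realized per-edge occupancies and water counts,
#' the lipid nodes inside the 15 Å shell, the deep-phosphate depths, and
#' the per-frame water-spanning flag.
#'
#' @param spec a [pore_spec].
#' @return list with `topology` (a [pore_topology]), `frames` (a
#'   [pore_frames]), `manifest`, `chemistry_table` (override table for
#'   [assign_donors_acceptors()]) and `class_rules` (for
#'   [load_topology()]).
#' @export
build_pore_system <- function(spec) {
  stopifnot(inherits(spec, "pore_spec"))
  np <- spec$n_peptides
  nres <- spec$residues_per_peptide
  seq_letters <- strsplit(spec$sequence, "")[[1]]
  rise <- 1.5
  plane <- spec$phosphate_plane_z
  R <- spec$ring_radius
  lane_x0 <- 120
  lane_dy <- 20
  shift_absent <- 1.2          # breaks the first link to 4.0 Å (>= 3.5 + 0.5)

  pe <- spec$planted_edges
  ne <- nrow(pe)
  key_a <- vapply(pe$node_a, .resolve_node, "", seq_letters = seq_letters)
  key_b <- vapply(pe$node_b, .resolve_node, "", seq_letters = seq_letters)

  # validate lipid references: must be comfortably inside the 15 Å shell
  lip_refs <- grep("^L", c(pe$node_a, pe$node_b), value = TRUE)
  if (length(lip_refs)) {
    ids <- as.integer(sub("^L", "", lip_refs))
    dists <- spec$lipid_layout$dist[match(ids, spec$lipid_layout$lipid_id)]
    if (anyNA(dists)) stop("planted edge references unknown lipid id")
    if (any(dists > 14.5))
      stop("edge-bearing lipids must lie inside the lipid shell (dist <= 14.5)")
  }
  pep_refs <- grep("^P", c(pe$node_a, pe$node_b), value = TRUE)
  pos_used <- as.integer(sub("^P[0-9]+:", "", pep_refs))
  if (any(pos_used > nres)) stop("planted edge references residue beyond peptide")
  if (any(pos_used == spec$trp_position))
    stop("planted edges may not use the depth-probe residue position")

  atoms <- list(); xyz <- list()
  add <- function(name, el, resno, resname, chain, x, y, z) {
    atoms[[length(atoms) + 1L]] <<- data.frame(
      atom_name = name, element = el, residue_index = resno,
      residue_name = resname, chain_id = chain, stringsAsFactors = FALSE)
    xyz[[length(xyz) + 1L]] <<- c(x, y, z)
  }

  theta <- 2 * pi * (seq_len(np) - 1) / np
  ca_z <- (seq_len(nres) - (nres + 1) / 2) * rise
  z_shift <- ifelse(seq_len(np) %in% spec$deinserted_peptides,
                    spec$deinsert_shift, 0)
  chains <- LETTERS[seq_len(np)]
  resnames <- unname(.three_letter()[seq_letters])

  for (p in seq_len(np)) {
    for (j in seq_len(nres)) {
      add("CA", "C", j, resnames[j], chains[p],
          R * cos(theta[p]), R * sin(theta[p]), ca_z[j] + z_shift[p])
      if (j == spec$trp_position)
        add("CB", "C", j, resnames[j], chains[p],
            (R - 1.5) * cos(theta[p]), (R - 1.5) * sin(theta[p]),
            ca_z[j] + z_shift[p])
    }
  }

  # planted-edge lanes: site atoms + bridging waters; record which atom
  # rows move when the edge is scheduled absent
  n_pep_atoms <- length(atoms)
  movable <- vector("list", ne)
  water_resno <- 0L
  water_rows_of_edge <- vector("list", ne)
  place_site <- function(ref, name, hname, x, y, z, with_h) {
    if (startsWith(ref, "L")) {
      lid <- as.integer(sub("^L", "", ref))
      add(name, "O", lid, "LIP", "L", x, y, z)
    } else {
      m <- regmatches(ref, regexec("^P([0-9]+):([0-9]+)$", ref))[[1]]
      p <- as.integer(m[2]); j <- as.integer(m[3])
      add(name, "O", j, resnames[j], chains[p], x, y, z)
      if (with_h) add(hname, "H", j, resnames[j], chains[p], x + 1.0, y, z)
    }
  }
  chem_rows <- list()
  for (k in seq_len(ne)) {
    ly <- (k - 1) * lane_dy
    nw <- pe$n_waters[k]
    # donor site (always on a peptide for lipid edges: put donor on node_a
    # if it is a peptide, else swap)
    a <- pe$node_a[k]; b <- pe$node_b[k]
    if (startsWith(a, "L")) { tmp <- a; a <- b; b <- tmp }
    if (startsWith(a, "L")) stop("lipid-lipid edges cannot be planted")
    place_site(a, sprintf("OD%d", k), sprintf("HD%d", k), lane_x0, ly, 0, TRUE)
    first_movable <- length(atoms) + 1L
    wrows <- integer()
    for (w in seq_len(nw)) {
      water_resno <- water_resno + 1L
      ox <- lane_x0 + 2.8 * w
      add("O", "O", water_resno, "HOH", "W", ox, ly, 0)
      add("H1", "H", water_resno, "HOH", "W", ox + 1.0, ly, 0)
      add("H2", "H", water_resno, "HOH", "W", ox - 0.3, ly + 0.95, 0)
      wrows <- c(wrows, water_resno)
    }
    water_rows_of_edge[[k]] <- wrows
    place_site(b, sprintf("OA%d", k), NULL, lane_x0 + 2.8 * (nw + 1), ly, 0,
               FALSE)
    movable[[k]] <- first_movable:length(atoms)
    if (startsWith(b, "L"))
      chem_rows[[length(chem_rows) + 1L]] <-
        data.frame(residue_name = "LIP", atom_name = sprintf("OA%d", k),
                   role = "acceptor", stringsAsFactors = FALSE)
  }

  # transmembrane water column on the pore axis
  col_z <- seq(-(plane + 8), plane + 8, by = 2.8)
  if (spec$water_column == "gapped") col_z <- col_z[abs(col_z) > 2.6]
  if (spec$water_column != "none") {
    for (z in col_z) {
      water_resno <- water_resno + 1L
      add("O", "O", water_resno, "HOH", "W", 0, 0, z)
      add("H1", "H", water_resno, "HOH", "W", 0, 0, z + 1.0)
      add("H2", "H", water_resno, "HOH", "W", 0.95, 0, z - 0.3)
    }
  }

  # lipid phosphates at exact planned distances from the nearest peptide
  ll <- spec$lipid_layout
  aligned_pep <- setdiff(seq_len(np), spec$deinserted_peptides)
  if (!length(aligned_pep)) stop("all peptides deinserted; cannot place lipids")
  for (i in seq_len(nrow(ll))) {
    p <- aligned_pep[(i - 1) %% length(aligned_pep) + 1]
    zP <- ll$leaflet[i] * (plane - ll$depth[i])
    dz <- min(abs(zP - ca_z))
    if (ll$dist[i] <= dz)
      stop("lipid ", ll$lipid_id[i], " planned distance smaller than its ",
           "vertical offset from the peptide")
    radial <- R + sqrt(ll$dist[i]^2 - dz^2)
    add("P", "P", ll$lipid_id[i], "LIP", "L",
        radial * cos(theta[p]), radial * sin(theta[p]), zP)
  }

  # a couple of counter-ions, inert in every analysis
  add("SOD", "NA", 1, "SOD", "I", 130, -30, 45)
  add("SOD", "NA", 2, "SOD", "I", -130, 30, -45)

  at <- do.call(rbind, atoms)
  at$atom_id <- seq_len(nrow(at))
  base <- do.call(rbind, xyz)
  class_rules <- c(LIP = "lipid")
  at$molecule_class <- unname(
    c(.default_class_rules(), class_rules)[at$residue_name])
  topo <- pore_topology(at, base)

  # frames: shift the movable block of each absent edge by +shift_absent
  sched <- schedule_presence(spec)
  nfr <- spec$n_frames
  lane_rows <- lapply(movable, function(res_rows) res_rows)
  coords <- vector("list", nfr)
  for (f in seq_len(nfr)) {
    m <- base
    for (k in seq_len(ne)) if (!sched[k, f])
      m[movable[[k]], 1] <- m[movable[[k]], 1] + shift_absent
    coords[[f]] <- m
  }
  box_y <- max(300, 2 * ne * lane_dy)
  frames <- pore_frames(coords, seq_len(nfr) * spec$frame_interval_ps,
                        c(400, box_y, 140))

  chemistry_table <- if (length(chem_rows)) do.call(rbind, chem_rows) else NULL

  occ <- 100 * rowMeans(sched)
  edges_manifest <- data.frame(
    node_a = pmin(key_a, key_b), node_b = pmax(key_a, key_b),
    n_waters = pe$n_waters, occupancy_pct = occ,
    direct_pct = ifelse(pe$n_waters == 0, 100, 0),
    stringsAsFactors = FALSE)
  edges_manifest$water_ids <- water_rows_of_edge
  o <- order(edges_manifest$node_a, edges_manifest$node_b)
  edges_manifest <- edges_manifest[o, , drop = FALSE]
  rownames(edges_manifest) <- NULL

  lip_in_shell <- ll$lipid_id[ll$dist <= 15]
  # expected donor/acceptor census under the default chemistry + override
  n_waters_total <- water_resno
  n_lip_acc <- length(chem_rows)
  manifest <- list(
    edges = edges_manifest,
    schedule = sched,
    lipid_nodes_in_shell = sprintf("L%d", sort(lip_in_shell)),
    lipid_layout = ll,
    water_spans = rep(spec$water_column == "continuous", nfr),
    n_frames = nfr,
    deinserted_peptides = spec$deinserted_peptides,
    expected_donors = ne + n_waters_total,
    expected_acceptors = 2 * ne + n_waters_total + n_lip_acc -
      sum(startsWith(pe$node_a, "L") | startsWith(pe$node_b, "L"))
  )

  list(topology = topo, frames = frames, manifest = manifest,
       chemistry_table = chemistry_table, class_rules = class_rules)
}

#' Write a synthetic system as on-disk fixtures
#'
#' Writes `<prefix>.pdb` (topology with reference coordinates),
#' `<prefix>.traj` (plain-text trajectory readable by
#' [read_trajectory()]), and `<prefix>_chemistry.tsv` (the donor/acceptor
#' override table) so the system can be re-loaded and re-analyzed from
#' files alone.
#'
#' @param system output of [build_pore_system()].
#' @param prefix output path prefix.
#' @return named character vector of the written paths, invisibly.
#' @export
write_fixture <- function(system, prefix) {
  if (!n_frames(system$frames)) stop("refusing to write an empty frame list")
  at <- system$topology$atoms
  pdb_path <- paste0(prefix, ".pdb")
  traj_path <- paste0(prefix, ".traj")
  chem_path <- paste0(prefix, "_chemistry.tsv")
  bio3d::write.pdb(file = pdb_path, xyz = as.vector(t(system$topology$ref_xyz)),
                   resno = at$residue_index, resid = at$residue_name,
                   eleno = at$atom_id, elety = at$atom_name,
                   chain = at$chain_id)
  write_trajectory(system$frames, traj_path)
  chem <- system$chemistry_table %||%
    data.frame(residue_name = character(), atom_name = character(),
               role = character())
  utils::write.table(chem, chem_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(pdb = pdb_path, traj = traj_path, chemistry = chem_path))
}

#' Load a written fixture back into topology and frames
#'
#' @param prefix the prefix used with [write_fixture()].
#' @return list with `topology` (donors/acceptors assigned) and `frames`.
#' @export
load_fixture <- function(prefix) {
  topo <- load_topology(paste0(prefix, ".pdb"), class_rules = c(LIP = "lipid"))
  chem <- utils::read.table(paste0(prefix, "_chemistry.tsv"), header = TRUE,
                            sep = "\t", stringsAsFactors = FALSE)
  if (!nrow(chem)) chem <- NULL
  topo <- assign_donors_acceptors(topo, chem)
  frames <- read_trajectory(paste0(prefix, ".traj"))
  list(topology = topo, frames = frames)
}
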