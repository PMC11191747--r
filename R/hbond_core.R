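#' Geometric hydrogen-bond criteria
#'
#' A hydrogen bond is accepted when the donor-acceptor heavy-atom distance
#' is at most `d_max` and the H-bond angle is at most `angle_max`. Two
#' conventions for the angle are supported, selected by
#' `angle_convention`:
#'
#' * `"H_D_A"` (default): the angle at the donor heavy atom between the
#'   D->H and D->A vectors;
#' * `"DHA_supplement"`: 180 degrees minus the D-H...A angle at the
#'   hydrogen (0 for a perfectly linear bond).
#'
#' Both conventions admit near-linear bonds and are nearly equivalent at
#' the default 60 degree cutoff; neither is asserted as the only correct
#' reading of a "H-bond angle" cutoff, so the choice is exposed.
#'
#' @param d_max heavy-atom donor-acceptor distance cutoff (Å).
#' @param angle_max angle cutoff (degrees).
#' @param angle_convention `"H_D_A"` or `"DHA_supplement"`.
#' @return An object of class `hbond_criteria`.
#' @export
hbond_criteria <- function(d_max = 3.5, angle_max = 60,
                           angle_convention = c("H_D_A", "DHA_supplement")) {
  if (d_max <= 0) stop("d_max must be positive")
  if (angle_max <= 0 || angle_max > 180)
    stop("angle_max must be in (0, 180]")
  structure(list(d_max = d_max, angle_max = angle_max,
                 angle_convention = match.arg(angle_convention)),
            class = "hbond_criteria")
}

#' Assign hydrogen-bond donors and acceptors
#'
#' Default chemistry: every peptide *side-chain* N, O or S bearing at
#' least one covalent hydrogen is a donor; every side-chain N or O is an
#' acceptor; water oxygens are both donor and acceptor; lipid oxygens
#' covalently adjacent to a phosphorus (the phosphate oxygens) are
#' acceptors. Peptide backbone atoms (N, CA, C, O and their hydrogens)
#' are excluded: the networks analyzed here are side-chain networks.
#'
#' `chemistry_table` overrides the defaults per (residue_name, atom_name):
#' a data.frame with columns `residue_name`, `atom_name`, `role` in
#' `"donor"`, `"acceptor"`, `"both"`, `"none"`.
#'
#' @param topology a [pore_topology].
#' @param chemistry_table optional override table (see Details).
#' @return The topology with `donor`/`acceptor` flags filled in.
#' @export
assign_donors_acceptors <- function(topology, chemistry_table = NULL) {
  at <- topology$atoms
  n <- nrow(at)
  is_h <- at$element == "H"
  if (any(is_h & is.na(topology$h_parent)))
    stop("topology has hydrogens without covalent parents")

  has_h <- tabulate(topology$h_parent[is_h], nbins = n) > 0
  backbone <- at$molecule_class == "peptide" &
    at$atom_name %in% c("N", "CA", "C", "O", "OXT", "OT1", "OT2")
  # backbone hydrogens follow their parent
  backbone[is_h] <- backbone[topology$h_parent[is_h]]

  donor <- rep(FALSE, n)
  acceptor <- rep(FALSE, n)

  pep <- at$molecule_class == "peptide" & !backbone & !is_h
  donor[pep & at$element %in% c("N", "O", "S") & has_h] <- TRUE
  acceptor[pep & at$element %in% c("N", "O")] <- TRUE

  wat_o <- at$molecule_class == "water" & at$element == "O"
  donor[wat_o] <- TRUE
  acceptor[wat_o] <- TRUE

  lip_o <- at$molecule_class == "lipid" & at$element == "O"
  if (any(lip_o)) {
    lip_p <- which(at$molecule_class == "lipid" & at$element == "P")
    for (i in which(lip_o)) {
      p_same <- lip_p[topology$residue_id[lip_p] == topology$residue_id[i]]
      if (length(p_same)) {
        d <- sqrt(colSums((t(topology$ref_xyz[p_same, , drop = FALSE]) -
                             topology$ref_xyz[i, ])^2))
        if (min(d) <= 1.9) acceptor[i] <- TRUE
      }
    }
  }

  if (!is.null(chemistry_table)) {
    need <- c("residue_name", "atom_name", "role")
    if (!all(need %in% names(chemistry_table)))
      stop("chemistry_table needs columns residue_name, atom_name, role")
    key <- paste(at$residue_name, at$atom_name)
    tkey <- paste(chemistry_table$residue_name, chemistry_table$atom_name)
    hit <- match(key, tkey)
    idx <- which(!is.na(hit))
    role <- chemistry_table$role[hit[idx]]
    donor[idx] <- role %in% c("donor", "both")
    acceptor[idx] <- role %in% c("acceptor", "both")
  }

  if (any(donor & !has_h)) {
    bad <- which(donor & !has_h)
    warning("dropping ", length(bad),
            " donor(s) with no covalent hydrogen (cannot define an angle)")
    donor[bad] <- FALSE
  }

  topology$donor <- donor
  topology$acceptor <- acceptor
  topology$chemistry_assigned <- TRUE
  topology
}

#' Detect hydrogen bonds in one frame
#'
#' Returns every donor-H-acceptor triple whose heavy-atom distance and
#' H-bond angle satisfy `criteria`. Distances use the minimum-image
#' convention under the frame's orthorhombic box.
#'
#' @param frame a single frame as returned by [get_frame()].
#' @param topology a [pore_topology] with donors/acceptors assigned.
#' @param criteria an [hbond_criteria] object.
#' @return data.frame with columns `donor`, `hydrogen`, `acceptor`
#'   (atom ids), `distance` (Å) and `angle` (degrees).
#' @export
detect_hbonds <- function(frame, topology, criteria = hbond_criteria()) {
  if (!isTRUE(topology$chemistry_assigned))
    stop("run assign_donors_acceptors() first")
  xyz <- frame$xyz
  box <- frame$box
  don <- which(topology$donor)
  acc <- which(topology$acceptor)
  empty <- data.frame(donor = integer(), hydrogen = integer(),
                      acceptor = integer(), distance = numeric(),
                      angle = numeric())
  if (!length(don) || !length(acc)) return(empty)

  dmat <- .pair_dist(xyz[don, , drop = FALSE], xyz[acc, , drop = FALSE], box)
  hit <- which(dmat <= criteria$d_max, arr.ind = TRUE)
  if (!nrow(hit)) return(empty)
  di <- don[hit[, 1]]
  ai <- acc[hit[, 2]]
  keep <- di != ai
  di <- di[keep]; ai <- ai[keep]
  dist <- dmat[hit][keep]
  if (!length(di)) return(empty)

  # expand over the hydrogens attached to each donor
  is_h <- topology$atoms$element == "H"
  h_idx <- which(is_h)
  h_by_parent <- split(h_idx, topology$h_parent[h_idx])
  hl <- h_by_parent[as.character(di)]
  nh <- lengths(hl)
  rep_i <- rep.int(seq_along(di), nh)
  hi <- unlist(hl, use.names = FALSE)
  di2 <- di[rep_i]; ai2 <- ai[rep_i]; dist2 <- dist[rep_i]
  if (!length(hi)) return(empty)

  if (criteria$angle_convention == "H_D_A") {
    v_dh <- .disp(xyz[di2, , drop = FALSE], xyz[hi, , drop = FALSE], box)
    v_da <- .disp(xyz[di2, , drop = FALSE], xyz[ai2, , drop = FALSE], box)
    ang <- .vec_angle(v_dh, v_da)
  } else {
    v_hd <- .disp(xyz[hi, , drop = FALSE], xyz[di2, , drop = FALSE], box)
    v_ha <- .disp(xyz[hi, , drop = FALSE], xyz[ai2, , drop = FALSE], box)
    ang <- 180 - .vec_angle(v_hd, v_ha)
  }
  ok <- ang <= criteria$angle_max
  out <- data.frame(donor = topology$atoms$atom_id[di2[ok]],
                    hydrogen = topology$atoms$atom_id[hi[ok]],
                    acceptor = topology$atoms$atom_id[ai2[ok]],
                    distance = dist2[ok], angle = ang[ok])
  out <- out[order(out$donor, out$acceptor, out$hydrogen), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Residue-level undirected contact edges implied by an atom-level event
# list. Returns a 2-column matrix of residue node keys (self-contacts
# dropped), plus a parallel logical for whether each edge touches a water.
.residue_edges <- function(hbonds, topology) {
  if (!nrow(hbonds)) return(matrix(character(), ncol = 2))
  row_of <- match(hbonds$donor, topology$atoms$atom_id)
  row_ac <- match(hbonds$acceptor, topology$atoms$atom_id)
  a <- topology$node_key[row_of]
  b <- topology$node_key[row_ac]
  keep <- !is.na(a) & !is.na(b) & a != b
  a <- a[keep]; b <- b[keep]
  if (!length(a)) return(matrix(character(), ncol = 2))
  sw <- a > b
  tmp <- a[sw]; a[sw] <- b[sw]; b[sw] <- tmp
  unique(cbind(a, b))
}

# Minimal bridging-water counts between non-water nodes for one frame's
# residue edge set. Returns data.frame(node_a, node_b, n_waters) with
# node_a < node_b. BFS through the water subgraph, at most max_waters
# interior layers.
.bridge_pairs <- function(edges, topology, max_waters) {
  out0 <- data.frame(node_a = character(), node_b = character(),
                     n_waters = integer())
  if (!nrow(edges)) return(out0)
  is_wat_key <- function(k) startsWith(k, "W")
  a <- edges[, 1]; b <- edges[, 2]
  wa <- is_wat_key(a); wb <- is_wat_key(b)

  best <- new.env(hash = TRUE, parent = emptyenv())
  note <- function(x, y, n) {
    key <- if (x < y) paste(x, y) else paste(y, x)
    cur <- best[[key]]
    if (is.null(cur) || n < cur) best[[key]] <- n
  }

  # direct non-water contacts
  dd <- !wa & !wb
  if (any(dd)) mapply(note, a[dd], b[dd], 0L)

  if (max_waters >= 1L) {
    # adjacency lists
    nw_w <- rbind(cbind(a[!wa & wb], b[!wa & wb]),
                  cbind(b[wa & !wb], a[wa & !wb]))      # nonwater, water
    ww <- edges[wa & wb, , drop = FALSE]
    if (nrow(nw_w)) {
      wat_of_nw <- split(nw_w[, 2], nw_w[, 1])
      nw_of_wat <- split(nw_w[, 1], nw_w[, 2])
      w_adj <- if (nrow(ww))
        split(c(ww[, 2], ww[, 1]), c(ww[, 1], ww[, 2])) else list()
      for (u in names(wat_of_nw)) {
        layer <- unique(wat_of_nw[[u]])
        seen <- layer
        depth <- 1L
        while (length(layer) && depth <= max_waters) {
          # non-water nodes adjacent to this layer complete a bridge
          ends <- unlist(nw_of_wat[layer], use.names = FALSE)
          for (v in unique(ends)) if (v != u) note(u, v, depth)
          if (depth == max_waters) break
          nxt <- unique(unlist(w_adj[layer], use.names = FALSE))
          layer <- setdiff(nxt, seen)
          seen <- c(seen, layer)
          depth <- depth + 1L
        }
      }
    }
  }

  keys <- ls(best)
  if (!length(keys)) return(out0)
  parts <- strsplit(keys, " ", fixed = TRUE)
  data.frame(node_a = vapply(parts, `[`, "", 1),
             node_b = vapply(parts, `[`, "", 2),
             n_waters = vapply(keys, function(k) as.integer(best[[k]]),
                               integer(1)),
             row.names = NULL)
}

# Lexicographically smallest minimal water path between two non-water
# nodes, given the frame's residue edge set. Returns integer water ids.
.min_water_path <- function(edges, u, v, n_waters) {
  if (n_waters == 0L) return(integer())
  a <- edges[, 1]; b <- edges[, 2]
  adj <- split(c(b, a), c(a, b))
  wat_id <- function(k) as.integer(sub("^W", "", k))
  waters_adj <- function(k) {
    nb <- unique(adj[[k]] %||% character())
    nb[startsWith(nb, "W")]
  }
  # D[w]: minimal waters in a chain from w to v, inclusive of w
  D <- new.env(hash = TRUE, parent = emptyenv())
  layer <- waters_adj(v)
  d <- 1L
  for (w in layer) D[[w]] <- 1L
  while (length(layer) && d < n_waters) {
    nxt <- setdiff(unique(unlist(lapply(layer, waters_adj))), ls(D))
    d <- d + 1L
    for (w in nxt) D[[w]] <- d
    layer <- nxt
  }
  path <- character(n_waters)
  frontier <- waters_adj(u)
  for (j in seq_len(n_waters)) {
    need <- n_waters - j + 1L
    cand <- frontier[vapply(frontier, function(w)
      identical(D[[w]], need), logical(1))]
    if (!length(cand)) return(integer())  # should not happen for minimal n
    w <- cand[order(wat_id(cand))][1]
    path[j] <- w
    frontier <- waters_adj(w)
  }
  vapply(path, wat_id, integer(1), USE.NAMES = FALSE)
}

#' Water-mediated bridges between non-water nodes in one frame
#'
#' From an atom-level H-bond event list, finds every pair of non-water
#' nodes (peptide side chains, lipid phosphates) connected by a chain of
#' H-bonds whose interior members are exclusively water molecules, with at
#' most `max_waters` waters in the chain. Each pair is reported once with
#' the minimum achievable number of bridging waters; `n_waters = 0` is a
#' direct H-bond. H-bond directionality is ignored. When several minimal
#' paths exist, `water_ids` records the lexicographically smallest
#' water-id sequence (only `n_waters` matters downstream).
#'
#' @param frame a single frame (as from [get_frame()]).
#' @param hbonds event list from [detect_hbonds()] for the same frame.
#' @param topology a [pore_topology].
#' @param max_waters maximum number of interior waters (default 3).
#' @param record_paths set `FALSE` to skip water-path reconstruction.
#' @return data.frame with `node_a`, `node_b`, `n_waters` and (when
#'   `record_paths`) a `water_ids` list column.
#' @export
water_bridges <- function(frame, hbonds, topology, max_waters = 3,
                          record_paths = TRUE) {
  if (max_waters < 0) stop("max_waters must be nonnegative")
  edges <- .residue_edges(hbonds, topology)
  pairs <- .bridge_pairs(edges, topology, as.integer(max_waters))
  pairs <- pairs[order(pairs$node_a, pairs$node_b), , drop = FALSE]
  rownames(pairs) <- NULL
  if (record_paths) {
    pairs$water_ids <- lapply(seq_len(nrow(pairs)), function(i)
      .min_water_path(edges, pairs$node_a[i], pairs$node_b[i],
                      pairs$n_waters[i]))
  }
  pairs
}

#' Per-frame event table over a trajectory window
#'
#' Convenience wrapper producing the tabular per-frame H-bond dump
#' (frame, donor, hydrogen, acceptor, distance, angle).
#'
#' @inheritParams detect_hbonds
#' @param frames a [pore_frames] object.
#' @return data.frame of events across all frames.
#' @export
hbond_events <- function(frames, topology, criteria = hbond_criteria()) {
  out <- lapply(seq_len(n_frames(frames)), function(i) {
    ev <- detect_hbonds(get_frame(frames, i), topology, criteria)
    if (nrow(ev)) cbind(frame = i, ev) else NULL
  })
  do.call(rbind, out) %||%
    data.frame(frame = integer(), donor = integer(), hydrogen = integer(),
               acceptor = integer(), distance = numeric(), angle = numeric())
}
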