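#' Per-frame counts of direct and water-mediated side-chain bridges
#'
#' For each frame of the window, counts the residue pairs of peptide side
#' chains connected directly (`n_waters = 0`) and through 1..`max_waters`
#' bridging waters. Each pair counts once per frame regardless of how many
#' simultaneous atom-level contacts connect it.
#'
#' @param frames a [pore_frames] object.
#' @param topology a [pore_topology] with donors/acceptors assigned.
#' @param criteria an [hbond_criteria].
#' @param max_waters maximum bridging waters (default 3).
#' @return data.frame with `time_ps`, `direct`, `water_bridged`, `total`.
#' @export
bridge_timeseries <- function(frames, topology, criteria = hbond_criteria(),
                              max_waters = 3) {
  if (!inherits(frames, "pore_frames") || !n_frames(frames))
    stop("frames must be a nonempty pore_frames object")
  nfr <- n_frames(frames)
  direct <- integer(nfr)
  watb <- integer(nfr)
  for (i in seq_len(nfr)) {
    fr <- get_frame(frames, i)
    hb <- detect_hbonds(fr, topology, criteria)
    br <- water_bridges(fr, hb, topology, max_waters, record_paths = FALSE)
    sc <- startsWith(br$node_a, "P") & startsWith(br$node_b, "P")
    direct[i] <- sum(sc & br$n_waters == 0)
    watb[i] <- sum(sc & br$n_waters >= 1)
  }
  data.frame(time_ps = frames$times_ps, direct = direct,
             water_bridged = watb, total = direct + watb)
}

# Leaflet phosphate planes from bulk (non-pore-shell) lipids.
# Returns list(upper, lower, midplane, n_upper, n_lower).
.leaflet_planes <- function(frame, topology, bulk_exclude_shell = 15) {
  at <- topology$atoms
  p_idx <- which(at$molecule_class == "lipid" & at$element == "P")
  if (!length(p_idx)) stop("no lipid phosphorus atoms in topology")
  z <- frame$xyz[p_idx, 3]
  mid <- mean(z)
  pep <- which(at$molecule_class == "peptide" & at$element != "H")
  bulk <- rep(TRUE, length(p_idx))
  if (length(pep)) {
    d <- .pair_dist(frame$xyz[p_idx, , drop = FALSE],
                    frame$xyz[pep, , drop = FALSE], frame$box)
    bulk <- apply(d, 1, min) > bulk_exclude_shell
  }
  if (!any(bulk)) bulk <- rep(TRUE, length(p_idx))
  up <- bulk & z > mid
  lo <- bulk & z <= mid
  if (sum(up) < 10 || sum(lo) < 10)
    warning("fewer than 10 bulk lipids in a leaflet; phosphate planes ",
            "may be unstable")
  list(upper = mean(z[up]), lower = mean(z[lo]), midplane = mid,
       n_upper = sum(up), n_lower = sum(lo))
}

#' Phosphate depth profile
#'
#' Computes the mean phosphate plane of each leaflet from bulk lipids
#' (those farther than `bulk_exclude_shell` from any peptide atom) and the
#' signed depth of every lipid phosphate relative to its leaflet plane,
#' positive toward the bilayer center. Phosphates drawn at least
#' `deep_threshold` below their plane are the "deep" phosphates
#' characteristic of a toroidal pore rim.
#'
#' @param frame a single frame (as from [get_frame()]).
#' @param topology a [pore_topology].
#' @param deep_threshold depth (Å) at which a phosphate counts as deep
#'   (default 5).
#' @param bulk_exclude_shell radius (Å) around the peptide excluded from
#'   the plane estimate (default 15).
#' @return list with `leaflet_planes` (upper/lower z in Å),
#'   `per_item_depths` (data.frame `lipid_id`, `leaflet`, `z`, `depth`)
#'   and `deep_count`.
#' @export
phosphate_depth_profile <- function(frame, topology, deep_threshold = 5,
                                    bulk_exclude_shell = 15) {
  planes <- .leaflet_planes(frame, topology, bulk_exclude_shell)
  at <- topology$atoms
  p_idx <- which(at$molecule_class == "lipid" & at$element == "P")
  z <- frame$xyz[p_idx, 3]
  leaflet <- ifelse(z > planes$midplane, "upper", "lower")
  depth <- ifelse(leaflet == "upper", planes$upper - z, z - planes$lower)
  out <- data.frame(lipid_id = topology$lipid_id[p_idx], leaflet = leaflet,
                    z = z, depth = depth)
  list(leaflet_planes = c(upper = planes$upper, lower = planes$lower),
       per_item_depths = out,
       deep_count = sum(depth >= deep_threshold))
}

#' Tryptophan (or other probe residue) insertion depth
#'
#' The membrane insertion of each peptide is read off the side-chain
#' centroid of a probe residue — canonically the single tryptophan at
#' position 19 — as the signed distance from the nearest leaflet
#' phosphate plane, positive toward the bilayer center. Peptides whose
#' probe sits deeper than `inserted_cutoff` are classified `inserted`,
#' otherwise `interfacial` (the state unstable pore formers drift toward
#' as they begin to deinsert).
#'
#' @param frame a single frame.
#' @param topology a [pore_topology].
#' @param residue_position probe residue position (default 19).
#' @param inserted_cutoff classification cutoff in Å (default 3).
#' @param bulk_exclude_shell passed to the leaflet-plane estimate.
#' @return data.frame with `peptide_id`, `depth`, `classification`
#'   (`"inserted"`, `"interfacial"`, or NA when side-chain atoms are
#'   missing for that peptide).
#' @export
trp_insertion_depth <- function(frame, topology, residue_position = 19,
                                inserted_cutoff = 3,
                                bulk_exclude_shell = 15) {
  planes <- .leaflet_planes(frame, topology, bulk_exclude_shell)
  at <- topology$atoms
  backbone <- at$atom_name %in% c("N", "CA", "C", "O", "OXT", "OT1", "OT2")
  out <- data.frame(peptide_id = seq_len(topology$n_peptides),
                    depth = NA_real_, classification = NA_character_,
                    stringsAsFactors = FALSE)
  for (p in seq_len(topology$n_peptides)) {
    idx <- which(topology$peptide_id == p &
                   at$residue_index == residue_position &
                   !backbone & at$element != "H")
    if (!length(idx)) next
    cz <- mean(frame$xyz[idx, 3])
    depth <- min(planes$upper - cz, cz - planes$lower)
    out$depth[p] <- depth
    out$classification[p] <- if (depth > inserted_cutoff) "inserted"
      else "interfacial"
  }
  out
}

#' Transmembrane water connectivity
#'
#' Builds a graph whose vertices are the water oxygens plus two virtual
#' terminals: an upper-bulk terminal linked to every water above the upper
#' phosphate plane and a lower-bulk terminal linked to every water below
#' the lower plane. Waters are linked when their O-O minimum-image
#' distance is at most `link_cutoff`. The bilayer is water-connected when
#' both terminals fall in one connected component — the signature of bulk
#' water having entered the pore and connected across the membrane.
#'
#' @param frame a single frame.
#' @param topology a [pore_topology].
#' @param link_cutoff O-O linking distance (Å), default 3.5.
#' @param bulk_exclude_shell passed to the leaflet-plane estimate.
#' @return list with `spans_bilayer` (logical), `spanning_cluster_size`
#'   (waters in the component containing the terminals when spanning, else
#'   0) and `cluster_count` (number of water clusters).
#' @export
water_connectivity <- function(frame, topology, link_cutoff = 3.5,
                               bulk_exclude_shell = 15) {
  at <- topology$atoms
  w_o <- which(at$molecule_class == "water" & at$element == "O")
  if (!length(w_o))
    return(list(spans_bilayer = FALSE, spanning_cluster_size = 0L,
                cluster_count = 0L))
  planes <- .leaflet_planes(frame, topology, bulk_exclude_shell)
  xyz <- frame$xyz[w_o, , drop = FALSE]
  nw <- length(w_o)
  d <- .pair_dist(xyz, xyz, frame$box)
  adj <- which(d <= link_cutoff & upper.tri(d), arr.ind = TRUE)

  up_t <- nw + 1L
  lo_t <- nw + 2L
  up_links <- which(xyz[, 3] > planes$upper)
  lo_links <- which(xyz[, 3] < planes$lower)
  edges <- rbind(adj,
                 cbind(up_links, rep(up_t, length(up_links))),
                 cbind(lo_links, rep(lo_t, length(lo_links))))
  g <- igraph::make_empty_graph(n = nw + 2L, directed = FALSE)
  if (nrow(edges)) g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)
  spans <- comp$membership[up_t] == comp$membership[lo_t] &&
    length(up_links) > 0 && length(lo_links) > 0
  span_size <- if (spans)
    sum(comp$membership[seq_len(nw)] == comp$membership[up_t]) else 0L
  water_comp <- comp$membership[seq_len(nw)]
  list(spans_bilayer = spans,
       spanning_cluster_size = as.integer(span_size),
       cluster_count = length(unique(water_comp)))
}
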