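#' Select pore-proximal lipid phosphate nodes
#'
#' Lipid phosphate groups enter the H-bond graph only when they sit close
#' to the pore. A lipid is selected when the minimum-image distance from
#' any heavy atom of its phosphate group (the phosphorus plus its
#' covalently bound oxygens) to any peptide heavy atom is at most `shell`
#' in the supplied frame — by convention the final frame of the
#' simulation, so that shell membership is decided once and held fixed for
#' the whole analysis window.
#'
#' @param final_frame a single frame (as from [get_frame()]).
#' @param topology a [pore_topology].
#' @param shell shell radius (Å), default 15.
#' @return data.frame with `node_key`, `lipid_id`, `distance` (Å) for the
#'   selected lipids; zero rows (with a warning) when the topology has no
#'   lipid atoms.
#' @export
select_lipid_nodes <- function(final_frame, topology, shell = 15) {
  at <- topology$atoms
  empty <- data.frame(node_key = character(), lipid_id = integer(),
                      distance = numeric())
  lip <- which(at$molecule_class == "lipid")
  if (!length(lip)) {
    warning("topology contains no lipid atoms; empty lipid node set")
    return(empty)
  }
  # phosphate group: P atoms plus O atoms covalently adjacent to a P
  p_idx <- lip[at$element[lip] == "P"]
  o_idx <- lip[at$element[lip] == "O"]
  grp <- p_idx
  if (length(o_idx) && length(p_idx)) {
    near_p <- vapply(o_idx, function(i) {
      ps <- p_idx[topology$residue_id[p_idx] == topology$residue_id[i]]
      length(ps) && min(sqrt(colSums((t(topology$ref_xyz[ps, , drop = FALSE]) -
                                        topology$ref_xyz[i, ])^2))) <= 1.9
    }, logical(1))
    grp <- c(grp, o_idx[near_p])
  }
  if (!length(grp)) {
    warning("no lipid phosphate atoms found; empty lipid node set")
    return(empty)
  }
  pep <- which(at$molecule_class == "peptide" & at$element != "H")
  if (!length(pep)) stop("topology contains no peptide heavy atoms")
  d <- .pair_dist(final_frame$xyz[grp, , drop = FALSE],
                  final_frame$xyz[pep, , drop = FALSE], final_frame$box)
  min_d <- apply(d, 1, min)
  per_lip <- tapply(min_d, topology$lipid_id[grp], min)
  sel <- as.integer(names(per_lip)[per_lip <= shell])
  data.frame(node_key = sprintf("L%d", sel), lipid_id = sel,
             distance = as.numeric(per_lip[per_lip <= shell]))
}

# side-chain node table: one row per peptide residue with >=1 donor or
# acceptor atom
.side_chain_nodes <- function(topology) {
  at <- topology$atoms
  idx <- which(at$molecule_class == "peptide" &
                 (topology$donor | topology$acceptor))
  if (!length(idx))
    return(data.frame(key = character(), kind = character(),
                      peptide_id = integer(), residue_position = integer(),
                      lipid_id = integer(), label = character()))
  keys <- topology$node_key[idx]
  keep <- !duplicated(keys)
  data.frame(key = keys[keep], kind = "side_chain",
             peptide_id = topology$peptide_id[idx][keep],
             residue_position = at$residue_index[idx][keep],
             lipid_id = NA_integer_, label = keys[keep],
             stringsAsFactors = FALSE)
}

#' Build the occupancy-filtered hydrogen-bond network
#'
#' Runs H-bond detection and water-bridge search on every frame of the
#' analysis window and aggregates the per-frame bridge sets into a graph.
#' Nodes are H-bonding peptide side chains plus the supplied lipid
#' phosphate nodes; an edge's occupancy is the percentage of analyzed
#' frames in which the pair is connected directly or through at most
#' `max_waters` bridging waters. Edges below `min_occupancy_pct` are
#' dropped; lipid-lipid edges and lipid nodes left without a peptide
#' connection are pruned (the graph describes peptide-anchored
#' interactions, not bulk lipid-lipid contacts).
#'
#' @param frames the analysis window, a [pore_frames] object (typically
#'   from [select_window()]).
#' @param topology a [pore_topology] with donors/acceptors assigned.
#' @param criteria an [hbond_criteria].
#' @param max_waters maximum bridging waters per edge (default 3).
#' @param lipid_nodes lipid node set from [select_lipid_nodes()] (a
#'   data.frame with `node_key`, or a character vector of keys).
#' @param min_occupancy_pct occupancy threshold in percent (default 30).
#' @return An object of class `hbond_network` with elements `nodes`,
#'   `edges` (`node_a`, `node_b`, `occupancy_pct`, `mean_waters`,
#'   `direct_pct`), `n_frames_analyzed`, `criteria`, `max_waters`,
#'   `min_occupancy_pct`.
#' @export
build_network <- function(frames, topology, criteria = hbond_criteria(),
                          max_waters = 3, lipid_nodes = NULL,
                          min_occupancy_pct = 30) {
  if (!inherits(frames, "pore_frames") || !n_frames(frames))
    stop("frames must be a nonempty pore_frames object")
  lipid_keys <- if (is.null(lipid_nodes)) character()
    else if (is.character(lipid_nodes)) lipid_nodes else lipid_nodes$node_key

  sc <- .side_chain_nodes(topology)
  lip_ids <- as.integer(sub("^L", "", lipid_keys))
  nodes <- rbind(sc, if (length(lipid_keys))
    data.frame(key = lipid_keys, kind = "lipid_phosphate",
               peptide_id = NA_integer_, residue_position = NA_integer_,
               lipid_id = lip_ids, label = lipid_keys,
               stringsAsFactors = FALSE))
  member <- nodes$key

  nfr <- n_frames(frames)
  per_frame <- vector("list", nfr)
  for (i in seq_len(nfr)) {
    fr <- get_frame(frames, i)
    hb <- detect_hbonds(fr, topology, criteria)
    br <- water_bridges(fr, hb, topology, max_waters, record_paths = FALSE)
    keep <- br$node_a %in% member & br$node_b %in% member
    if (any(keep)) per_frame[[i]] <- br[keep, , drop = FALSE]
  }
  all_pairs <- do.call(rbind, per_frame)

  if (is.null(all_pairs) || !nrow(all_pairs)) {
    edges <- data.frame(node_a = character(), node_b = character(),
                        occupancy_pct = numeric(), mean_waters = numeric(),
                        direct_pct = numeric())
  } else {
    key <- paste(all_pairs$node_a, all_pairs$node_b, sep = "\r")
    cnt <- tapply(all_pairs$n_waters, key, length)
    sw <- tapply(all_pairs$n_waters, key, sum)
    dz <- tapply(all_pairs$n_waters == 0, key, sum)
    parts <- strsplit(names(cnt), "\r", fixed = TRUE)
    edges <- data.frame(
      node_a = vapply(parts, `[`, "", 1),
      node_b = vapply(parts, `[`, "", 2),
      occupancy_pct = 100 * as.numeric(cnt) / nfr,
      mean_waters = as.numeric(sw) / as.numeric(cnt),
      direct_pct = 100 * as.numeric(dz) / as.numeric(cnt),
      row.names = NULL, stringsAsFactors = FALSE)
    edges <- edges[edges$occupancy_pct >= min_occupancy_pct, , drop = FALSE]
  }

  net <- structure(list(
    nodes = nodes, edges = edges, n_frames_analyzed = nfr,
    criteria = criteria, max_waters = max_waters,
    min_occupancy_pct = min_occupancy_pct,
    n_peptides = topology$n_peptides,
    residues_per_peptide = topology$residues_per_peptide
  ), class = "hbond_network")
  .prune_lipids(net)
}

# drop lipid-lipid edges, then lipid nodes with no remaining edge
.prune_lipids <- function(network) {
  e <- network$edges
  nd <- network$nodes
  is_lip <- function(k) k %in% nd$key[nd$kind == "lipid_phosphate"]
  if (nrow(e)) {
    ll <- is_lip(e$node_a) & is_lip(e$node_b)
    e <- e[!ll, , drop = FALSE]
  }
  lip_keys <- nd$key[nd$kind == "lipid_phosphate"]
  touched <- lip_keys %in% c(e$node_a, e$node_b)
  drop_keys <- lip_keys[!touched]
  nd <- nd[!(nd$key %in% drop_keys), , drop = FALSE]
  rownames(e) <- NULL; rownames(nd) <- NULL
  network$edges <- e
  network$nodes <- nd
  network
}

#' @export
print.hbond_network <- function(x, ...) {
  npl <- count_peptide_lipid_edges(x)
  cat("hbond_network:", nrow(x$nodes), "nodes,", nrow(x$edges), "edges",
      sprintf("(occupancy >= %g%%, <= %d waters, %d frames)\n",
              x$min_occupancy_pct, x$max_waters, x$n_frames_analyzed))
  cat("  peptide-lipid edges:", npl,
      " side-chain edges:", nrow(x$edges) - npl, "\n")
  invisible(x)
}

#' Re-filter a network at a different occupancy threshold
#'
#' Retains edges with `occupancy_pct >= threshold_pct` and re-prunes
#' lipid nodes. Raising the threshold never adds edges, so edge sets are
#' nested across thresholds (e.g. 20% vs the display threshold of 30%).
#'
#' @param network an `hbond_network`.
#' @param threshold_pct occupancy threshold in percent, in \[0, 100\].
#' @return A filtered `hbond_network`.
#' @export
occupancy_filter <- function(network, threshold_pct) {
  if (threshold_pct < 0 || threshold_pct > 100)
    stop("threshold_pct must be in [0, 100]")
  network$edges <- network$edges[network$edges$occupancy_pct >= threshold_pct,
                                 , drop = FALSE]
  network$min_occupancy_pct <- max(network$min_occupancy_pct, threshold_pct)
  .prune_lipids(network)
}

#' Per-residue interaction density
#'
#' Counts, for every residue position, the number of network edges
#' incident on that position summed over all peptides: a side-chain to
#' side-chain edge increments both endpoint positions, a side-chain to
#' lipid edge increments the side-chain position. The profile therefore
#' satisfies `sum(counts) == 2 * n_sidechain_edges + n_lipid_edges`.
#'
#' @param network an `hbond_network`.
#' @return data.frame with `residue_position` and `count`.
#' @export
density_profile <- function(network) {
  rpp <- network$residues_per_peptide
  counts <- integer(rpp)
  nd <- network$nodes
  pos_of <- stats::setNames(nd$residue_position, nd$key)
  kind_of <- stats::setNames(nd$kind, nd$key)
  e <- network$edges
  for (i in seq_len(nrow(e))) {
    for (k in c(e$node_a[i], e$node_b[i])) {
      if (identical(kind_of[[k]], "side_chain")) {
        p <- pos_of[[k]]
        counts[p] <- counts[p] + 1L
      }
    }
  }
  data.frame(residue_position = seq_len(rpp), count = counts)
}

#' Count peptide-lipid edges
#'
#' The number of network edges with exactly one lipid-phosphate endpoint —
#' the total count of direct and water-mediated peptide-lipid bridges.
#' Because per-residue incidence is an equally defensible reading of a
#' "lipid interactions" total, `per_residue = TRUE` returns instead the
#' number of (side-chain, lipid) incidences, which for this graph equals
#' the same count (each peptide-lipid edge has exactly one side-chain
#' endpoint); both conventions are exposed for clarity.
#'
#' @param network an `hbond_network`.
#' @param per_residue count side-chain incidences instead of edges.
#' @return integer count.
#' @export
count_peptide_lipid_edges <- function(network, per_residue = FALSE) {
  nd <- network$nodes
  lip <- nd$key[nd$kind == "lipid_phosphate"]
  e <- network$edges
  one_lip <- xor(e$node_a %in% lip, e$node_b %in% lip)
  sum(one_lip)
}

#' Convert a network to an igraph object
#'
#' @param network an `hbond_network`.
#' @return An [igraph::igraph] graph with node `kind`/`label` and edge
#'   `occupancy_pct`/`mean_waters`/`direct_pct` attributes.
#' @export
as_igraph <- function(network) {
  v <- data.frame(name = network$nodes$key, kind = network$nodes$kind,
                  label = network$nodes$label, stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(network$edges, directed = FALSE, vertices = v)
}

#' Export a network to GraphML or a delimited edge table
#'
#' @param network an `hbond_network`.
#' @param path output file path.
#' @param format `"graphml"` (standard GraphML with node and edge
#'   attributes) or `"edge_table"` (tab-delimited `node_a`, `node_b`,
#'   `occupancy_pct`, `mean_waters`, `direct_pct`).
#' @return `path`, invisibly.
#' @export
export_network <- function(network, path,
                           format = c("graphml", "edge_table")) {
  format <- match.arg(format)
  if (format == "graphml") {
    g <- as_igraph(network)
    igraph::write_graph(g, path, format = "graphml")
  } else {
    utils::write.table(network$edges, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Read back an exported edge set
#'
#' @param path file written by [export_network()].
#' @param format the format it was written in.
#' @return data.frame of edges with occupancy attributes.
#' @export
import_network_edges <- function(path, format = c("graphml", "edge_table")) {
  format <- match.arg(format)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    el <- igraph::as_edgelist(g)
    out <- data.frame(node_a = el[, 1], node_b = el[, 2],
                      occupancy_pct = igraph::E(g)$occupancy_pct,
                      mean_waters = igraph::E(g)$mean_waters,
                      direct_pct = igraph::E(g)$direct_pct,
                      stringsAsFactors = FALSE)
  } else {
    out <- utils::read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
  }
  sw <- out$node_a > out$node_b
  tmp <- out$node_a[sw]; out$node_a[sw] <- out$node_b[sw]; out$node_b[sw] <- tmp
  out <- out[order(out$node_a, out$node_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}
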