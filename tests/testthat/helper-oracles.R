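# Independent brute-force oracles and small-system builders used across
# the suite. The oracles deliberately share no code with the package:
# scalar loops, their own minimum-image arithmetic.

.mi1 <- function(d, L) d - L * round(d / L)
.mi3 <- function(v, box) c(.mi1(v[1], box[1]), .mi1(v[2], box[2]),
                           .mi1(v[3], box[3]))
.odist <- function(a, b, box) sqrt(sum(.mi3(a - b, box)^2))
.oangle <- function(u, v) {
  cosang <- sum(u * v) / sqrt(sum(u * u) * sum(v * v))
  acos(min(1, max(-1, cosang))) * 180 / pi
}

# Exhaustive O(n^2) H-bond oracle over all donor/hydrogen/acceptor triples.
oracle_hbonds <- function(frame, topology, criteria) {
  at <- topology$atoms
  xyz <- frame$xyz
  box <- frame$box
  out <- list()
  hs <- which(at$element == "H")
  for (d in which(topology$donor)) {
    myh <- hs[topology$h_parent[hs] == d]
    for (a in which(topology$acceptor)) {
      if (a == d) next
      dist <- .odist(xyz[d, ], xyz[a, ], box)
      if (dist > criteria$d_max) next
      for (h in myh) {
        if (criteria$angle_convention == "H_D_A") {
          ang <- .oangle(.mi3(xyz[h, ] - xyz[d, ], box),
                         .mi3(xyz[a, ] - xyz[d, ], box))
        } else {
          ang <- 180 - .oangle(.mi3(xyz[d, ] - xyz[h, ], box),
                               .mi3(xyz[a, ] - xyz[h, ], box))
        }
        if (ang <= criteria$angle_max)
          out[[length(out) + 1L]] <- data.frame(
            donor = at$atom_id[d], hydrogen = at$atom_id[h],
            acceptor = at$atom_id[a], distance = dist, angle = ang)
      }
    }
  }
  if (!length(out))
    return(data.frame(donor = integer(), hydrogen = integer(),
                      acceptor = integer(), distance = numeric(),
                      angle = numeric()))
  res <- do.call(rbind, out)
  res <- res[order(res$donor, res$acceptor, res$hydrogen), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# Exhaustive simple-path enumeration oracle for water bridges: for every
# pair of non-water nodes, the minimum number of distinct interior waters
# (0..max_waters) over all chains u - w1 - ... - wk - v.
oracle_bridges <- function(hbonds, topology, max_waters) {
  row_d <- match(hbonds$donor, topology$atoms$atom_id)
  row_a <- match(hbonds$acceptor, topology$atoms$atom_id)
  a <- topology$node_key[row_d]
  b <- topology$node_key[row_a]
  keep <- !is.na(a) & !is.na(b) & a != b
  ed <- unique(data.frame(a = a[keep], b = b[keep]))
  adj <- list()
  link <- function(x, y) adj[[x]] <<- unique(c(adj[[x]], y))
  for (i in seq_len(nrow(ed))) { link(ed$a[i], ed$b[i]); link(ed$b[i], ed$a[i]) }
  nodes <- unique(c(ed$a, ed$b))
  nw_nodes <- nodes[!startsWith(nodes, "W")]
  out <- list()
  for (i in seq_along(nw_nodes)) for (j in seq_along(nw_nodes)) {
    if (i >= j) next
    u <- nw_nodes[i]; v <- nw_nodes[j]
    best <- Inf
    if (v %in% (adj[[u]] %||% character())) best <- 0
    enumerate <- function(cur, used) {
      if (length(used) > max_waters || length(used) >= best) return()
      for (nb in adj[[cur]] %||% character()) {
        if (nb == v && length(used) > 0) best <<- min(best, length(used))
        if (startsWith(nb, "W") && !(nb %in% used))
          enumerate(nb, c(used, nb))
      }
    }
    if (best > 0) enumerate(u, character())
    if (is.finite(best))
      out[[length(out) + 1L]] <- data.frame(
        node_a = min(u, v), node_b = max(u, v), n_waters = as.integer(best))
  }
  if (!length(out))
    return(data.frame(node_a = character(), node_b = character(),
                      n_waters = integer()))
  res <- do.call(rbind, out)
  res <- res[order(res$node_a, res$node_b), , drop = FALSE]
  rownames(res) <- NULL
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Random small system: a handful of serine-like side-chain sites on one
# peptide chain plus waters, scattered in a periodic box so that H-bonds
# form by chance. <= 50 atoms, <= 30 waters.
random_small_system <- function(seed, n_sites = 5, n_waters = 12,
                                box = c(11, 11, 11)) {
  set.seed(seed)
  atoms <- list(); xyz <- list()
  add <- function(name, el, resno, resname, chain, p) {
    atoms[[length(atoms) + 1L]] <<- data.frame(
      atom_name = name, element = el, residue_index = resno,
      residue_name = resname, chain_id = chain, stringsAsFactors = FALSE)
    xyz[[length(xyz) + 1L]] <<- p
  }
  runit <- function() {
    v <- stats::rnorm(3)
    v / sqrt(sum(v * v))
  }
  for (i in seq_len(n_sites)) {
    o <- stats::runif(3) * box
    add("OG", "O", i, "SER", "A", o)
    add("HG", "H", i, "SER", "A", o + runit())
  }
  for (w in seq_len(n_waters)) {
    o <- stats::runif(3) * box
    add("O", "O", w, "HOH", "W", o)
    add("H1", "H", w, "HOH", "W", o + runit())
    add("H2", "H", w, "HOH", "W", o + runit())
  }
  at <- do.call(rbind, atoms)
  at$atom_id <- seq_len(nrow(at))
  at$molecule_class <- ifelse(at$residue_name == "HOH", "water", "peptide")
  topo <- assign_donors_acceptors(pore_topology(at, do.call(rbind, xyz)))
  list(topology = topo,
       frame = list(xyz = topo$ref_xyz, box = box, time_ps = 0,
                    frame_index = 1))
}

# Fully assigned topology + frames for a default synthetic pore; cached
# per test file via the options mechanism would be overkill, builds are fast.
built_pore <- function(...) {
  sys <- build_pore_system(pore_spec(...))
  sys$topology <- assign_donors_acceptors(sys$topology, sys$chemistry_table)
  sys
}
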