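# two serine-like sites at a controlled distance/angle, no box wrap
two_site_frame <- function(d_oo, h_offset = c(1, 0, 0)) {
  at <- data.frame(
    atom_name = c("OG", "HG", "OG"), element = c("O", "H", "O"),
    residue_index = c(1, 1, 2), residue_name = "SER",
    chain_id = "A", molecule_class = "peptide",
    stringsAsFactors = FALSE)
  at$atom_id <- 1:3
  xyz <- rbind(c(0, 0, 0), h_offset, c(d_oo, 0, 0))
  topo <- assign_donors_acceptors(pore_topology(at, xyz))
  list(topology = topo,
       frame = list(xyz = xyz, box = c(100, 100, 100), time_ps = 0))
}

test_that("ideal geometry is detected and the distance cutoff is sharp", {
  s <- two_site_frame(2.8)
  hb <- detect_hbonds(s$frame, s$topology)
  # donor 1 -> acceptor 3 at angle 0; the reverse direction has no H
  expect_equal(nrow(hb), 1)
  expect_equal(hb$donor, 1)
  expect_equal(hb$acceptor, 3)
  expect_equal(hb$angle, 0, tolerance = 1e-8)
  expect_equal(hb$distance, 2.8)

  expect_equal(nrow(detect_hbonds(two_site_frame(3.6)$frame,
                                  two_site_frame(3.6)$topology)), 0)
  expect_equal(nrow(detect_hbonds(two_site_frame(3.5)$frame,
                                  two_site_frame(3.5)$topology)), 1)
})

test_that("both angle conventions behave as documented", {
  # H at 50 degrees from the D->A axis: accepted under H_D_A
  h50 <- c(cos(50 * pi / 180), sin(50 * pi / 180), 0)
  s <- two_site_frame(2.8, h_offset = h50)
  hb <- detect_hbonds(s$frame, s$topology, hbond_criteria())
  expect_equal(nrow(hb), 1)
  expect_equal(hb$angle, 50, tolerance = 1e-6)

  h70 <- c(cos(70 * pi / 180), sin(70 * pi / 180), 0)
  s70 <- two_site_frame(2.8, h_offset = h70)
  expect_equal(nrow(detect_hbonds(s70$frame, s70$topology)), 0)

  # supplement convention measures at the hydrogen: a perfectly linear
  # D-H...A geometry scores 0 under both conventions
  s0 <- two_site_frame(2.8)
  hb2 <- detect_hbonds(s0$frame, s0$topology,
                       hbond_criteria(angle_convention = "DHA_supplement"))
  expect_equal(hb2$angle, 0, tolerance = 1e-8)
})

test_that("detection is invariant to atom permutation and rigid translation", {
  for (seed in 1:5) {
    sys <- random_small_system(seed)
    ref <- detect_hbonds(sys$frame, sys$topology)

    shift <- c(3.7, -12.1, 25.4)
    fr2 <- sys$frame
    fr2$xyz <- sweep(fr2$xyz, 2, -shift)
    hb2 <- detect_hbonds(fr2, sys$topology)
    expect_equal(hb2[c("donor", "hydrogen", "acceptor")],
                 ref[c("donor", "hydrogen", "acceptor")])
    expect_equal(hb2$distance, ref$distance, tolerance = 1e-9)

    # permute atoms, keeping ids: the event set (by atom id) is unchanged
    n <- nrow(sys$topology$atoms)
    perm <- sample(n)
    at <- sys$topology$atoms[perm, ]
    topo_p <- assign_donors_acceptors(
      pore_topology(at, sys$topology$ref_xyz[perm, , drop = FALSE]))
    fr_p <- list(xyz = sys$topology$ref_xyz[perm, , drop = FALSE],
                 box = sys$frame$box, time_ps = 0)
    hb_p <- detect_hbonds(fr_p, topo_p)
    expect_equal(hb_p[c("donor", "hydrogen", "acceptor")],
                 ref[c("donor", "hydrogen", "acceptor")])
  }
})

test_that("detection matches the exhaustive pairwise oracle", {
  for (seed in 1:10) {
    sys <- random_small_system(seed)
    for (conv in c("H_D_A", "DHA_supplement")) {
      crit <- hbond_criteria(angle_convention = conv)
      got <- detect_hbonds(sys$frame, sys$topology, crit)
      want <- oracle_hbonds(sys$frame, sys$topology, crit)
      expect_equal(got[c("donor", "hydrogen", "acceptor")],
                   want[c("donor", "hydrogen", "acceptor")])
      expect_equal(got$distance, want$distance, tolerance = 1e-9)
      expect_equal(got$angle, want$angle, tolerance = 1e-6)
    }
  }
})

# hand-built bridge scene: two side chains joined through a water chain
chain_scene <- function(n_waters) {
  atoms <- list(); xyz <- list()
  add <- function(name, el, resno, resname, chain, p) {
    atoms[[length(atoms) + 1L]] <<- data.frame(
      atom_name = name, element = el, residue_index = resno,
      residue_name = resname, chain_id = chain, stringsAsFactors = FALSE)
    xyz[[length(xyz) + 1L]] <<- p
  }
  add("OG", "O", 1, "SER", "A", c(0, 0, 0))
  add("HG", "H", 1, "SER", "A", c(1, 0, 0))
  for (w in seq_len(n_waters)) {
    add("O", "O", w, "HOH", "W", c(2.8 * w, 0, 0))
    add("H1", "H", w, "HOH", "W", c(2.8 * w + 1, 0, 0))
    add("H2", "H", w, "HOH", "W", c(2.8 * w - 0.3, 0.95, 0))
  }
  add("OG", "O", 2, "SER", "A", c(2.8 * (n_waters + 1), 0, 0))
  add("HG", "H", 2, "SER", "A", c(2.8 * (n_waters + 1) + 1, 0, 0))
  at <- do.call(rbind, atoms)
  at$atom_id <- seq_len(nrow(at))
  at$molecule_class <- ifelse(at$residue_name == "HOH", "water", "peptide")
  topo <- assign_donors_acceptors(pore_topology(at, do.call(rbind, xyz)))
  list(topology = topo,
       frame = list(xyz = topo$ref_xyz, box = c(500, 500, 500), time_ps = 0))
}

test_that("water bridges carry the minimal interior water count", {
  s1 <- chain_scene(1)
  hb <- detect_hbonds(s1$frame, s1$topology)
  br <- water_bridges(s1$frame, hb, s1$topology)
  expect_equal(nrow(br), 1)
  expect_equal(br$n_waters, 1L)
  expect_equal(br$water_ids[[1]], 1L)

  # chain through four waters exceeds the three-water limit: no bridge
  s4 <- chain_scene(4)
  hb4 <- detect_hbonds(s4$frame, s4$topology)
  br4 <- water_bridges(s4$frame, hb4, s4$topology, max_waters = 3)
  expect_equal(nrow(br4), 0)
  # ...but it is found when the limit is raised
  br4b <- water_bridges(s4$frame, hb4, s4$topology, max_waters = 4)
  expect_equal(br4b$n_waters, 4L)

  expect_error(water_bridges(s1$frame, hb, s1$topology, max_waters = -1),
               "nonnegative")
})

test_that("max_waters = 0 reduces bridges to the direct contact pairs", {
  for (seed in 1:5) {
    sys <- random_small_system(seed)
    hb <- detect_hbonds(sys$frame, sys$topology)
    br0 <- water_bridges(sys$frame, hb, sys$topology, max_waters = 0)
    want <- oracle_bridges(hb, sys$topology, max_waters = 0)
    expect_equal(br0[c("node_a", "node_b", "n_waters")], want)
    expect_true(all(br0$n_waters == 0))
  }
})

test_that("bridge search agrees with exhaustive simple-path enumeration", {
  for (seed in 1:10) {
    sys <- random_small_system(seed, n_sites = 4, n_waters = 10,
                               box = c(9, 9, 9))
    hb <- detect_hbonds(sys$frame, sys$topology)
    got <- water_bridges(sys$frame, hb, sys$topology, max_waters = 3,
                         record_paths = FALSE)
    want <- oracle_bridges(hb, sys$topology, max_waters = 3)
    expect_equal(got[c("node_a", "node_b", "n_waters")], want)
  }
})

test_that("reported bridges are minimal: removing an interior water hurts", {
  for (seed in 1:5) {
    sys <- random_small_system(seed, n_sites = 3, n_waters = 8,
                               box = c(9, 9, 9))
    hb <- detect_hbonds(sys$frame, sys$topology)
    br <- water_bridges(sys$frame, hb, sys$topology, max_waters = 3)
    wat <- br[br$n_waters > 0, , drop = FALSE]
    for (i in seq_len(nrow(wat))) {
      for (wid in wat$water_ids[[i]]) {
        # drop all events touching that water and re-search
        wkey <- sprintf("W%d", wid)
        row_d <- match(hb$donor, sys$topology$atoms$atom_id)
        row_a <- match(hb$acceptor, sys$topology$atoms$atom_id)
        touches <- sys$topology$node_key[row_d] == wkey |
          sys$topology$node_key[row_a] == wkey
        br2 <- water_bridges(sys$frame, hb[!touches, , drop = FALSE],
                             sys$topology, max_waters = 3,
                             record_paths = FALSE)
        hit <- br2[br2$node_a == wat$node_a[i] & br2$node_b == wat$node_b[i], ]
        expect_true(nrow(hit) == 0 || hit$n_waters >= wat$n_waters[i])
      }
    }
  }
})
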