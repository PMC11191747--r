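#' Construct a topology object from an atom table
#'
#' A topology holds the static description of the simulated system: one row
#' per atom with residue/chain identity and a molecule class, reference
#' coordinates used to attach hydrogens to their covalent heavy-atom
#' parents, and derived per-atom network bookkeeping (node keys for peptide
#' side chains, lipids and waters).
#'
#' @param atoms data.frame with columns `atom_id` (unique integer),
#'   `atom_name`, `element`, `residue_index` (1-based within chain),
#'   `residue_name`, `chain_id`, `molecule_class` (one of `"peptide"`,
#'   `"water"`, `"lipid"`, `"ion"`).
#' @param xyz numeric matrix (n_atoms x 3) of reference coordinates (Å),
#'   aligned to `atoms` row order. Used to infer covalent H attachments and
#'   lipid phosphate-group membership.
#' @param h_parent optional integer vector giving, for each atom, the row
#'   index of the covalent heavy-atom parent (NA for heavy atoms). When
#'   omitted, each hydrogen is attached to the nearest heavy atom of the
#'   same residue within 1.9 Å.
#'
#' @return An object of class `pore_topology`.
#' @export
pore_topology <- function(atoms, xyz, h_parent = NULL) {
  required <- c("atom_id", "atom_name", "element", "residue_index",
                "residue_name", "chain_id", "molecule_class")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols))
    stop("atoms is missing columns: ", paste(missing_cols, collapse = ", "))
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  n <- nrow(atoms)
  if (anyDuplicated(atoms$atom_id))
    stop("atom_id values must be unique")
  classes <- c("peptide", "water", "lipid", "ion")
  bad <- setdiff(unique(atoms$molecule_class), classes)
  if (length(bad))
    stop("unknown molecule_class: ", paste(bad, collapse = ", "))
  xyz <- as.matrix(xyz)
  if (!is.numeric(xyz) || nrow(xyz) != n || ncol(xyz) != 3)
    stop("xyz must be a numeric n_atoms x 3 matrix aligned to atoms")

  res_key <- paste(atoms$chain_id, atoms$residue_index, atoms$residue_name,
                   sep = "|")
  residue_id <- match(res_key, unique(res_key))

  # water sanity: exactly one O and two H per water residue
  w <- atoms$molecule_class == "water"
  if (any(w)) {
    for (rid in unique(residue_id[w])) {
      el <- atoms$element[residue_id == rid]
      if (sum(el == "O") != 1L || sum(el == "H") != 2L)
        stop("water residue ", rid, " must contain exactly one O and two H")
    }
  }

  is_h <- atoms$element == "H"
  if (is.null(h_parent)) {
    h_parent <- rep(NA_integer_, n)
    for (i in which(is_h)) {
      cand <- which(residue_id == residue_id[i] & !is_h)
      if (!length(cand))
        stop("hydrogen atom ", atoms$atom_id[i],
             " has no heavy atom in its residue")
      d <- sqrt(colSums((t(xyz[cand, , drop = FALSE]) - xyz[i, ])^2))
      j <- cand[which.min(d)]
      if (min(d) > 1.9)
        stop("hydrogen atom ", atoms$atom_id[i],
             " has no covalent heavy-atom parent within 1.9 Å")
      h_parent[i] <- j
    }
  } else {
    h_parent <- as.integer(h_parent)
    if (length(h_parent) != n)
      stop("h_parent must have one entry per atom")
    if (any(is_h & is.na(h_parent)))
      stop("every hydrogen must have a covalent heavy-atom parent")
  }

  # network node bookkeeping
  node_key <- rep(NA_character_, n)
  node_kind <- rep(NA_character_, n)
  peptide_id <- rep(NA_integer_, n)
  lipid_id <- rep(NA_integer_, n)
  water_id <- rep(NA_integer_, n)

  pep_chains <- sort(unique(atoms$chain_id[atoms$molecule_class == "peptide"]))
  p <- atoms$molecule_class == "peptide"
  if (any(p)) {
    peptide_id[p] <- match(atoms$chain_id[p], pep_chains)
    node_key[p] <- sprintf("P%d:%s%d", peptide_id[p],
                           .aa_one(atoms$residue_name[p]),
                           atoms$residue_index[p])
    node_kind[p] <- "side_chain"
  }
  l <- atoms$molecule_class == "lipid"
  if (any(l)) {
    lip_res <- unique(residue_id[l])
    lipid_id[l] <- match(residue_id[l], lip_res)
    node_key[l] <- sprintf("L%d", lipid_id[l])
    node_kind[l] <- "lipid"
  }
  if (any(w)) {
    wat_res <- unique(residue_id[w])
    water_id[w] <- match(residue_id[w], wat_res)
    node_key[w] <- sprintf("W%d", water_id[w])
    node_kind[w] <- "water"
  }

  n_peptides <- length(pep_chains)
  residues_per_peptide <- if (n_peptides) {
    per <- vapply(pep_chains, function(ch)
      length(unique(atoms$residue_index[p & atoms$chain_id == ch])), integer(1))
    if (length(unique(per)) > 1L)
      warning("peptide chains have unequal residue counts; using the maximum")
    max(per)
  } else 0L

  structure(list(
    atoms = atoms,
    ref_xyz = xyz,
    h_parent = h_parent,
    residue_id = residue_id,
    node_key = node_key,
    node_kind = node_kind,
    peptide_id = peptide_id,
    lipid_id = lipid_id,
    water_id = water_id,
    n_peptides = n_peptides,
    residues_per_peptide = as.integer(residues_per_peptide),
    donor = rep(FALSE, n),
    acceptor = rep(FALSE, n),
    chemistry_assigned = FALSE
  ), class = "pore_topology")
}

#' @export
print.pore_topology <- function(x, ...) {
  cat("pore_topology:", nrow(x$atoms), "atoms\n")
  cat("  class census:\n")
  print(table(x$atoms$molecule_class))
  cat("  peptides:", x$n_peptides, "x", x$residues_per_peptide, "residues\n")
  if (x$chemistry_assigned)
    cat("  donors:", sum(x$donor), " acceptors:", sum(x$acceptor), "\n")
  invisible(x)
}

# residue-name -> molecule_class defaults (CHARMM/PDB conventions)
.default_class_rules <- function() {
  rules <- c(
    stats::setNames(rep("peptide", length(.ONE_LETTER)), names(.ONE_LETTER)),
    HOH = "water", TIP3 = "water", TIP = "water", WAT = "water",
    SOL = "water", SPC = "water",
    POPC = "lipid", POPE = "lipid", POPG = "lipid", POPS = "lipid",
    DOPC = "lipid", DMPC = "lipid", DPPC = "lipid",
    SOD = "ion", CLA = "ion", POT = "ion", MG = "ion", CAL = "ion",
    ZN = "ion", NA. = "ion", CL = "ion", K = "ion"
  )
  names(rules)[names(rules) == "NA."] <- "NA"
  rules
}

#' Load a topology from a PDB file
#'
#' Reads standard fixed-column ATOM/HETATM records and classifies every
#' residue as peptide, water, lipid or ion. The 20 standard amino acids,
#' common water residue names (HOH, TIP3, ...), common phosphatidylcholine
#' lipids and monatomic ions are classified by default; `class_rules`
#' extends or overrides this mapping.
#'
#' @param path path to a PDB file.
#' @param class_rules named character vector mapping residue names to
#'   molecule classes, e.g. `c(POPC = "lipid")`.
#' @param default_class optional class for residue names covered by no
#'   rule; if `NULL` (default), unknown residue names are an error.
#'
#' @return A [pore_topology] object.
#' @export
load_topology <- function(path, class_rules = NULL, default_class = NULL) {
  if (!file.exists(path)) stop("topology file not found: ", path)
  pdb <- tryCatch(bio3d::read.pdb(path),
                  error = function(e) stop("failed to parse PDB file '", path,
                                           "': ", conditionMessage(e)))
  at <- pdb$atom
  rules <- .default_class_rules()
  if (!is.null(class_rules)) rules[names(class_rules)] <- class_rules

  resnames <- at$resid
  cls <- unname(rules[resnames])
  if (anyNA(cls)) {
    unknown <- sort(unique(resnames[is.na(cls)]))
    if (is.null(default_class))
      stop("unclassifiable residue names: ", paste(unknown, collapse = ", "),
           " (supply class_rules or default_class)")
    cls[is.na(cls)] <- default_class
  }

  element <- at$elesy
  blank <- is.na(element) | element == ""
  element[blank] <- substr(gsub("^[0-9]", "", at$elety[blank]), 1, 1)
  element <- toupper(trimws(element))

  atoms <- data.frame(
    atom_id = at$eleno,
    atom_name = at$elety,
    element = element,
    residue_index = at$resno,
    residue_name = resnames,
    chain_id = ifelse(is.na(at$chain) | at$chain == "", "_", at$chain),
    molecule_class = cls,
    stringsAsFactors = FALSE
  )
  xyz <- cbind(at$x, at$y, at$z)
  pore_topology(atoms, xyz)
}

#' Construct a multi-frame coordinate set
#'
#' @param coords list of numeric n_atoms x 3 matrices (Å), one per frame.
#' @param times_ps numeric vector of frame times (ps), nondecreasing.
#' @param box either a length-3 vector of box edge lengths (Å) shared by
#'   all frames or an n_frames x 3 matrix.
#'
#' @return An object of class `pore_frames`.
#' @export
pore_frames <- function(coords, times_ps, box) {
  if (!is.list(coords) || !length(coords))
    stop("coords must be a nonempty list of coordinate matrices")
  n <- length(coords)
  if (length(times_ps) != n)
    stop("times_ps must have one entry per frame")
  if (is.unsorted(times_ps))
    stop("frame times must be nondecreasing")
  if (is.null(dim(box))) box <- matrix(box, nrow = n, ncol = 3, byrow = TRUE)
  box <- as.matrix(box)
  if (nrow(box) != n || ncol(box) != 3)
    stop("box must be a length-3 vector or an n_frames x 3 matrix")
  if (any(box <= 0)) stop("box lengths must be positive")
  natoms <- nrow(coords[[1]])
  ok <- vapply(coords, function(m) is.numeric(m) && nrow(m) == natoms &&
                 ncol(m) == 3, logical(1))
  if (!all(ok)) stop("all coordinate matrices must be numeric n_atoms x 3")
  structure(list(coords = coords, times_ps = as.numeric(times_ps), box = box),
            class = "pore_frames")
}

#' Number of frames in a `pore_frames` object
#' @param frames a [pore_frames] object.
#' @export
n_frames <- function(frames) length(frames$coords)

#' Extract one frame
#'
#' @param frames a [pore_frames] object.
#' @param i frame index.
#' @return list with `xyz` (n_atoms x 3), `box` (length 3), `time_ps`,
#'   `frame_index`.
#' @export
get_frame <- function(frames, i) {
  list(xyz = frames$coords[[i]], box = frames$box[i, ],
       time_ps = frames$times_ps[i], frame_index = i)
}

#' @export
print.pore_frames <- function(x, ...) {
  n <- n_frames(x)
  cat("pore_frames:", n, "frames,", nrow(x$coords[[1]]), "atoms\n")
  cat(sprintf("  time %g .. %g ps\n", x$times_ps[1], x$times_ps[n]))
  invisible(x)
}

#' Select an equally spaced analysis window from the end of a trajectory
#'
#' Picks the frames used for network analysis: those whose times fall in
#' the half-open interval `(t_end - window, t_end]`, subsampled so that
#' consecutive selected frames are `stride_ps` apart (counting back from
#' the final frame). With this convention a 200 ns window at 10 ps stride
#' contains exactly `200000/10 = 20000` frames.
#'
#' @param x either a numeric vector of frame times (ps) or a
#'   [pore_frames] object.
#' @param window_ns window length in ns, measured back from the last frame.
#' @param stride_ps spacing of the selected frames (ps); must be an integer
#'   multiple of the trajectory's saving interval.
#'
#' @return For a numeric `x`, the integer indices of the selected frames;
#'   for a [pore_frames] object, the subset as a new `pore_frames`.
#' @export
select_window <- function(x, window_ns, stride_ps) {
  times <- if (inherits(x, "pore_frames")) x$times_ps else as.numeric(x)
  if (!length(times)) stop("empty trajectory")
  if (window_ns <= 0 || stride_ps <= 0)
    stop("window_ns and stride_ps must be positive")
  t_end <- times[length(times)]
  dt <- unique(round(diff(times), 9))
  if (length(dt) > 1L)
    stop("frames are not equally spaced; cannot define a saving interval")
  dt <- if (length(dt)) dt else stride_ps
  duration <- t_end - times[1] + dt
  window_ps <- window_ns * 1000
  if (window_ps > duration + 1e-9)
    stop(sprintf("window (%g ns) exceeds trajectory duration (%g ns)",
                 window_ns, duration / 1000))
  ratio <- stride_ps / dt
  if (abs(ratio - round(ratio)) > 1e-9)
    stop(sprintf("stride (%g ps) is not a multiple of the saving interval (%g ps)",
                 stride_ps, dt))
  back <- round((t_end - times) / dt)       # whole saving intervals from end
  k <- round(stride_ps / dt)
  sel <- which(times > t_end - window_ps + 1e-9 & back %% k == 0L)
  if (inherits(x, "pore_frames")) {
    pore_frames(x$coords[sel], x$times_ps[sel], x$box[sel, , drop = FALSE])
  } else sel
}

#' Summarize production-run durations
#'
#' @param durations_ns numeric vector of run lengths (ns).
#' @param labels optional run labels.
#' @return list with `runs` (data.frame of label, duration_ns) and
#'   `total_us`, the total sampling time in microseconds.
#' @export
summarize_trajectories <- function(durations_ns, labels = NULL) {
  if (!length(durations_ns)) stop("no run durations supplied")
  if (any(durations_ns <= 0)) stop("run durations must be positive")
  labels <- labels %||% paste0("run", seq_along(durations_ns))
  list(runs = data.frame(label = labels, duration_ns = durations_ns,
                         stringsAsFactors = FALSE),
       total_us = sum(durations_ns) / 1000)
}

#' Write frames in the plain-text trajectory fixture format
#'
#' A self-describing text format: a two-line header (`PORENET_TRAJECTORY 1`,
#' `natoms N nframes M`), then per frame one
#' `FRAME i time_ps t box bx by bz` line followed by one `x y z` line per
#' atom. All numbers are written with six decimals so that
#' write/read/write round-trips are byte-identical.
#'
#' @param frames a [pore_frames] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(frames, path) {
  if (!inherits(frames, "pore_frames")) stop("frames must be a pore_frames object")
  if (!n_frames(frames)) stop("refusing to write an empty frame list")
  con <- file(path, open = "wt")
  on.exit(close(con))
  natoms <- nrow(frames$coords[[1]])
  writeLines(c("PORENET_TRAJECTORY 1",
               sprintf("natoms %d nframes %d", natoms, n_frames(frames))), con)
  for (i in seq_len(n_frames(frames))) {
    writeLines(sprintf("FRAME %d time_ps %.6f box %.6f %.6f %.6f", i,
                       frames$times_ps[i], frames$box[i, 1], frames$box[i, 2],
                       frames$box[i, 3]), con)
    m <- frames$coords[[i]]
    writeLines(sprintf("%.6f %.6f %.6f", m[, 1], m[, 2], m[, 3]), con)
  }
  invisible(path)
}

#' Read a plain-text trajectory fixture
#'
#' @param path file written by [write_trajectory()].
#' @return A [pore_frames] object.
#' @export
read_trajectory <- function(path) {
  if (!file.exists(path)) stop("trajectory file not found: ", path)
  lines <- readLines(path)
  if (!length(lines) || !startsWith(lines[1], "PORENET_TRAJECTORY"))
    stop("not a porenet trajectory file (line 1): ", path)
  hdr <- strsplit(lines[2], "\\s+")[[1]]
  natoms <- as.integer(hdr[2]); nfr <- as.integer(hdr[4])
  if (is.na(natoms) || is.na(nfr))
    stop("malformed trajectory header (line 2): ", path)
  coords <- vector("list", nfr)
  times <- numeric(nfr)
  box <- matrix(0, nfr, 3)
  pos <- 3L
  for (i in seq_len(nfr)) {
    f <- strsplit(lines[pos], "\\s+")[[1]]
    if (f[1] != "FRAME")
      stop("expected FRAME record at line ", pos, " of ", path)
    times[i] <- as.numeric(f[4])
    box[i, ] <- as.numeric(f[6:8])
    block <- lines[(pos + 1L):(pos + natoms)]
    m <- matrix(scan(text = block, quiet = TRUE), ncol = 3, byrow = TRUE)
    coords[[i]] <- m
    pos <- pos + natoms + 1L
  }
  pore_frames(coords, times, box)
}

#' Read a binary DCD trajectory into the frame-stream contract
#'
#' Thin adapter over [bio3d::read.dcd()] so that binary trajectories can
#' feed the same analysis chain as the text fixture format. DCD files do
#' not carry absolute times, so the saving interval must be supplied;
#' unit-cell records are used for the box when present, otherwise `box`
#' is required.
#'
#' @param path DCD file.
#' @param frame_interval_ps saving interval (ps).
#' @param box optional length-3 box edge lengths (Å) when the file lacks
#'   unit-cell records.
#' @return A [pore_frames] object.
#' @export
read_dcd_trajectory <- function(path, frame_interval_ps, box = NULL) {
  if (!file.exists(path)) stop("trajectory file not found: ", path)
  xyz <- bio3d::read.dcd(path, verbose = FALSE)
  nfr <- nrow(xyz)
  coords <- lapply(seq_len(nfr), function(i)
    matrix(xyz[i, ], ncol = 3, byrow = TRUE))
  if (is.null(box)) {
    cell <- tryCatch(bio3d::read.dcd(path, cell = TRUE, verbose = FALSE),
                     error = function(e) NULL)
    if (is.matrix(cell) && ncol(cell) >= 3 && nrow(cell) == nfr) {
      box <- cell[, 1:3, drop = FALSE]
    } else stop("DCD has no usable unit-cell records; supply box explicitly")
  }
  pore_frames(coords, seq_len(nfr) * frame_interval_ps, box)
}

#' Trajectory metadata summary
#'
#' Frame count, duration, saving interval and per-class atom census —
#' the quick sanity check one runs before any analysis.
#'
#' @param topology a [pore_topology].
#' @param frames a [pore_frames].
#' @return list with `n_frames`, `duration_ns`, `interval_ps`, `census`.
#' @export
trajectory_info <- function(topology, frames) {
  n <- n_frames(frames)
  dt <- if (n > 1) diff(frames$times_ps[1:2]) else NA_real_
  list(
    n_frames = n,
    duration_ns = (frames$times_ps[n] - frames$times_ps[1] +
                     (if (is.na(dt)) 0 else dt)) / 1000,
    interval_ps = dt,
    census = table(topology$atoms$molecule_class)
  )
}
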