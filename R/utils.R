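# Internal geometry and bookkeeping helpers.

# Minimum-image displacement components under an orthorhombic box.
# dx: numeric vector/matrix of raw coordinate differences; box_len: scalar.
.min_image <- function(dx, box_len) {
  if (is.null(box_len) || !is.finite(box_len) || box_len <= 0) return(dx)
  dx - box_len * round(dx / box_len)
}

# Pairwise minimum-image distance matrix between two coordinate matrices
# (n x 3 and m x 3), box a length-3 vector of box edge lengths.
.pair_dist <- function(a, b, box) {
  dx <- .min_image(outer(a[, 1], b[, 1], "-"), box[1])
  dy <- .min_image(outer(a[, 2], b[, 2], "-"), box[2])
  dz <- .min_image(outer(a[, 3], b[, 3], "-"), box[3])
  sqrt(dx * dx + dy * dy + dz * dz)
}

# Minimum-image displacement vectors from rows of `from` to rows of `to`
# (both n x 3, paired row-wise).
.disp <- function(from, to, box) {
  d <- to - from
  d[, 1] <- .min_image(d[, 1], box[1])
  d[, 2] <- .min_image(d[, 2], box[2])
  d[, 3] <- .min_image(d[, 3], box[3])
  d
}

# Angle in degrees between paired row vectors u and v (n x 3).
.vec_angle <- function(u, v) {
  dot <- rowSums(u * v)
  nu <- sqrt(rowSums(u * u))
  nv <- sqrt(rowSums(v * v))
  cosang <- pmin(1, pmax(-1, dot / (nu * nv)))
  acos(cosang) * 180 / pi
}

.ONE_LETTER <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", HSD = "H", HSE = "H", HSP = "H",
  ILE = "I", LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V"
)

.aa_one <- function(resname) {
  out <- .ONE_LETTER[resname]
  out[is.na(out)] <- substr(resname[is.na(out)], 1, 1)
  unname(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
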