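.AA_CODES <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

.check_sequence <- function(sequence) {
  s <- strsplit(toupper(sequence), "")[[1]]
  bad <- setdiff(unique(s), .AA_CODES)
  if (length(bad))
    stop("nonstandard amino-acid letter(s): ", paste(bad, collapse = ", "))
  s
}

#' Net charge of a peptide at neutral pH
#'
#' Counts +1 for each Lys/Arg, -1 for each Asp/Glu, `his_charge` for each
#' His (0 by default: His is treated as neutral at pH 7), plus terminal
#' contributions: a free N-terminal amine adds +1, a free C-terminal
#' carboxylate adds -1, while an amidated (or otherwise neutralized)
#' C-terminus adds 0. The defaults (`n_term = "amine"`,
#' `c_term = "amidated"`) match peptides synthesized with a neutral
#' C-terminus, as modeled in the pore simulations.
#'
#' @param sequence one-letter amino-acid string.
#' @param n_term `"amine"` (+1) or `"neutral"` (0).
#' @param c_term `"amidated"` (0) or `"carboxylate"` (-1).
#' @param his_charge charge assigned per histidine (default 0).
#' @return integer net charge.
#' @export
net_charge <- function(sequence, n_term = c("amine", "neutral"),
                       c_term = c("amidated", "carboxylate"),
                       his_charge = 0) {
  n_term <- match.arg(n_term)
  c_term <- match.arg(c_term)
  s <- .check_sequence(sequence)
  charge <- sum(s %in% c("K", "R")) - sum(s %in% c("D", "E")) +
    his_charge * sum(s == "H") +
    (n_term == "amine") - (c_term == "carboxylate")
  charge
}

.AA_CLASS <- c(
  D = "acidic", E = "acidic", K = "basic", R = "basic", H = "basic",
  S = "polar", T = "polar", N = "polar", Q = "polar", Y = "polar",
  C = "polar", W = "polar", G = "special", P = "special"
)

#' Helical-wheel angles
#'
#' Idealized alpha-helical projection: residue i sits at
#' `(i - 1) * rotation_per_residue` degrees (mod 360) around the helix
#' axis, independent of residue identity. Residues at i+3 / i+4 spacings
#' land 300 and 40 degrees apart, which is why polar residues at such
#' spacings cluster on one helix face.
#'
#' @param sequence one-letter amino-acid string.
#' @param rotation_per_residue degrees per residue (default 100, the
#'   canonical alpha-helix value).
#' @return data.frame with `position`, `residue`, `angle` (degrees in
#'   \[0, 360)) and `class` (acidic/basic/polar/special/nonpolar).
#' @export
helical_wheel <- function(sequence, rotation_per_residue = 100) {
  s <- .check_sequence(sequence)
  n <- length(s)
  angle <- ((seq_len(n) - 1) * rotation_per_residue) %% 360
  cls <- unname(.AA_CLASS[s])
  cls[is.na(cls)] <- "nonpolar"
  data.frame(position = seq_len(n), residue = s, angle = angle, class = cls,
             stringsAsFactors = FALSE)
}

# Kyte-Doolittle hydropathy (positive = hydrophobic) and the Eisenberg
# consensus scale. "E_protonated" entries are used when glutamates are
# assumed protonated: a protonated carboxyl is roughly as polar as the
# corresponding amide, so the Gln value is reused.
.HYDROPATHY_SCALES <- list(
  kyte_doolittle = c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5,
                     Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I = 4.5,
                     L = 3.8, K = -3.9, M = 1.9, F = 2.8, P = -1.6,
                     S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2,
                     E_protonated = -0.5),
  eisenberg = c(A = 0.62, R = -2.53, N = -0.78, D = -0.90, C = 0.29,
                Q = -0.85, E = -0.74, G = 0.48, H = -0.40, I = 1.38,
                L = 1.06, K = -1.50, M = 0.64, F = 1.19, P = 0.12,
                S = -0.18, T = -0.05, W = 0.81, Y = 0.26, V = 1.08,
                E_protonated = -0.85)
)

#' Available hydropathy scale names
#' @return character vector.
#' @export
hydropathy_scales <- function() names(.HYDROPATHY_SCALES)

#' Sliding-window hydropathy profile
#'
#' Centered moving average of per-residue hydropathy values. Window ends
#' are truncated (no padding): the profile covers center positions
#' `(window+1)/2 .. n-(window-1)/2`. With `protonate_E = TRUE` glutamates
#' are scored as protonated (uncharged) side chains — the most generous
#' assumption when asking whether a polar sequence could still cross a
#' membrane as a hydrophobic helix.
#'
#' @param sequence one-letter amino-acid string.
#' @param scale a scale name from [hydropathy_scales()] or a named
#'   numeric vector of per-residue values.
#' @param window odd window length, at most the sequence length.
#' @param protonate_E score E as protonated (default FALSE).
#' @return data.frame with `center` (residue position) and `score`.
#' @export
hydropathy_profile <- function(sequence, scale = "kyte_doolittle",
                               window = 19, protonate_E = FALSE) {
  s <- .check_sequence(sequence)
  n <- length(s)
  if (window %% 2 != 1) stop("window must be odd")
  if (window > n) stop("window exceeds sequence length")
  if (is.character(scale)) {
    if (!scale %in% names(.HYDROPATHY_SCALES))
      stop("unknown hydropathy scale '", scale, "'; see hydropathy_scales()")
    sc <- .HYDROPATHY_SCALES[[scale]]
  } else sc <- scale
  if (protonate_E && "E_protonated" %in% names(sc)) sc["E"] <- sc["E_protonated"]
  vals <- unname(sc[s])
  if (anyNA(vals)) stop("scale lacks values for some residues")
  half <- (window - 1) / 2
  centers <- (half + 1):(n - half)
  score <- vapply(centers, function(c0) mean(vals[(c0 - half):(c0 + half)]),
                  numeric(1))
  data.frame(center = centers, score = score)
}

#' Read peptide sequences from a FASTA file
#'
#' @param path FASTA file.
#' @return named character vector of one-letter sequences.
#' @export
read_peptides <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop("reading FASTA requires the Biostrings package")
  aa <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(aa), names(aa))
}
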