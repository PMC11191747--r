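#' Fractional leakage from control-normalized fluorescence
#'
#' Normalizes a fluorescence reading between the no-peptide negative
#' control and the detergent-lysed 100%-leakage positive control:
#' `(F_sample - F_negative) / (F_positive - F_negative)`. The same
#' formula serves dequenching readouts (ANTS/DPX: fluorescence rises with
#' leakage) and donor-quenching readouts (dextran-release FRET:
#' fluorescence falls), because the positive control carries the
#' direction. Values are clipped to \[0, 1\]; clipping is reported via
#' the `"clipped"` attribute. The fraction is invariant to a common gain
#' applied to all three inputs.
#'
#' @param F_sample sample fluorescence (vectorized).
#' @param F_negative no-peptide control.
#' @param F_positive 100%-leakage control.
#' @return numeric fraction(s) in \[0, 1\] with attribute `clipped`.
#' @export
fractional_leakage <- function(F_sample, F_negative, F_positive) {
  if (any(F_positive == F_negative))
    stop("degenerate controls: F_positive equals F_negative")
  frac <- (F_sample - F_negative) / (F_positive - F_negative)
  clipped <- frac < 0 | frac > 1
  frac <- pmin(1, pmax(0, frac))
  attr(frac, "clipped") <- clipped
  frac
}

#' Lipid-exchange fraction from NBD fluorescence
#'
#' Baseline-subtracted ratio of measured NBD fluorescence to the
#' fully-exchanged positive control, reported as a percentage:
#' `100 * (NBD_measured - NBD_negative) / (NBD_positive - NBD_negative)`.
#'
#' @param NBD_measured measured NBD fluorescence (vectorized).
#' @param NBD_positive positive (fully exchanged) control.
#' @param NBD_negative no-peptide control (default 0, i.e. a plain ratio
#'   to the positive control).
#' @return percentage(s).
#' @export
lipid_exchange_fraction <- function(NBD_measured, NBD_positive,
                                    NBD_negative = 0) {
  if (any(NBD_positive <= NBD_negative))
    stop("positive control must exceed the negative control")
  100 * (NBD_measured - NBD_negative) / (NBD_positive - NBD_negative)
}

#' Mole-fraction partition-coefficient model
#'
#' Fluorescence fold increase as a function of lipid concentration:
#' `I([L]) = 1 + (Imax - 1) * Kp * [L] / ([W] + Kp * [L])`, where `Kp` is
#' the mole-fraction partition coefficient, `Imax` the fold increase at
#' full binding and `[W] = 55.3 M` the molar concentration of water.
#'
#' @param L lipid concentrations (M).
#' @param Kp mole-fraction partition coefficient.
#' @param Imax saturating fold increase.
#' @param water_molarity molar concentration of water (default 55.3).
#' @return predicted fold increase.
#' @export
partition_model <- function(L, Kp, Imax, water_molarity = 55.3) {
  1 + (Imax - 1) * Kp * L / (water_molarity + Kp * L)
}

#' Fit the mole-fraction partition coefficient
#'
#' Least-squares fit of [partition_model()] to a tryptophan-fluorescence
#' binding series. When a free-tryptophan scattering series is supplied
#' it is subtracted from the raw fluorescence before computing the fold
#' increase, correcting for lipid scattering.
#'
#' @param L lipid concentrations (M); at least 4 values spanning at least
#'   one order of magnitude.
#' @param I fluorescence fold increase at each `L` (relative to no
#'   lipid). Alternatively supply raw `F_sample` (+ optional baseline).
#' @param F_sample raw fluorescence, used with `F_no_lipid` when `I` is
#'   not given.
#' @param F_no_lipid raw fluorescence without lipid.
#' @param F_scatter optional free-tryptophan scattering series aligned to
#'   `L`, subtracted from `F_sample`.
#' @param water_molarity molar concentration of water (default 55.3).
#' @param start optional named list of starting values (`Kp`, `Imax`).
#' @return list with `Kp`, `Imax`, `fitted`, `residuals` and the
#'   underlying `fit` object.
#' @export
fit_partition_coefficient <- function(L, I = NULL, F_sample = NULL,
                                      F_no_lipid = NULL, F_scatter = NULL,
                                      water_molarity = 55.3, start = NULL) {
  L <- as.numeric(L)
  if (length(L) < 4) stop("need at least 4 lipid concentrations")
  if (diff(range(log10(L[L > 0]))) < 1)
    stop("lipid concentrations should span at least one order of magnitude")
  if (is.null(I)) {
    if (is.null(F_sample) || is.null(F_no_lipid))
      stop("supply either I or F_sample together with F_no_lipid")
    corr <- F_sample
    if (!is.null(F_scatter)) corr <- corr - F_scatter
    I <- corr / F_no_lipid
  }
  if (any(I < 0)) stop("fold increase must be nonnegative")
  if (is.null(start)) {
    Imax0 <- max(I)
    half <- (Imax0 + 1) / 2
    Lh <- L[which.min(abs(I - half))]
    Kp0 <- if (Imax0 > 1 && Lh > 0) water_molarity / Lh else 1
    start <- list(Kp = Kp0, Imax = max(Imax0, 1.01))
  }
  dat <- data.frame(L = L, I = I)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      I ~ 1 + (Imax - 1) * Kp * L / (water_molarity + Kp * L),
      data = dat, start = start, lower = c(Kp = 0, Imax = 1),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("partition fit failed to converge: ",
                             conditionMessage(e)))
  co <- stats::coef(fit)
  list(Kp = unname(co["Kp"]), Imax = unname(co["Imax"]),
       fitted = stats::fitted(fit), residuals = stats::residuals(fit),
       fit = fit)
}

#' Summarize assay replicates as mean and standard error
#'
#' @param table data.frame with at least `peptide_name`, `P_to_L_ratio`
#'   and a `value` column.
#' @param value name of the value column (default `"value"`).
#' @return data.frame with per-(peptide, ratio) `mean`, `se`, `n`.
#' @export
summarize_replicates <- function(table, value = "value") {
  if (!all(c("peptide_name", "P_to_L_ratio", value) %in% names(table)))
    stop("table needs peptide_name, P_to_L_ratio and '", value, "' columns")
  key <- paste(table$peptide_name, table$P_to_L_ratio, sep = "\r")
  agg <- lapply(split(table[[value]], key), function(v)
    c(mean = mean(v), se = stats::sd(v) / sqrt(length(v)), n = length(v)))
  ids <- do.call(rbind, strsplit(names(agg), "\r", fixed = TRUE))
  out <- data.frame(peptide_name = ids[, 1],
                    P_to_L_ratio = as.numeric(ids[, 2]),
                    do.call(rbind, agg), row.names = NULL,
                    stringsAsFactors = FALSE)
  out[order(out$peptide_name, out$P_to_L_ratio), , drop = FALSE]
}
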