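#' CSP parameters
#'
#' @param alpha_n 15N scaling factor of the weighted CSP metric,
#'   dimensionless, in (0, 1]. Default 0.14, the widely used amide-nitrogen
#'   weight.
#' @param window smoothing window in residues (odd, >= 1).
#' @return list of class `csp_params`.
#' @export
csp_params <- function(alpha_n = 0.14, window = 3L) {
  if (!is.numeric(alpha_n) || alpha_n <= 0 || alpha_n > 1) {
    stop("alpha_n must lie in (0, 1]")
  }
  window <- as.integer(window)
  if (window < 1 || window %% 2 == 0) stop("window must be an odd integer >= 1")
  structure(list(alpha_n = alpha_n, window = window), class = "csp_params")
}

#' Weighted chemical-shift perturbation between two titration points
#'
#' For every residue assigned in both spectra the compound perturbation is
#' \deqn{\Delta\delta = \sqrt{\Delta\delta_H^2 + (\alpha_N \Delta\delta_N)^2}}
#' with \eqn{\Delta\delta_H, \Delta\delta_N} the 1H and 15N shift changes
#' (bound minus free). Residues present in only one list, or lacking amide
#' shifts in either (e.g. prolines), are flagged missing.
#'
#' @param free peak list of the reference (free) state.
#' @param bound peak list of the ligand-bound state.
#' @param params a [csp_params()].
#' @return a [residue_profile()] named `"csp"`, in ppm.
#' @export
compute_csp <- function(free, bound, params = csp_params()) {
  stopifnot(inherits(free, "peak_list"), inherits(bound, "peak_list"))
  f <- free$entries
  b <- bound$entries
  shared <- intersect(f$residue_index, b$residue_index)
  if (length(shared) == 0) stop("free and bound share no residue indices")
  idx <- f$residue_index
  fi <- match(idx, f$residue_index)
  bi <- match(idx, b$residue_index)
  dh <- b$shift_h[bi] - f$shift_h[fi]
  dn <- b$shift_n[bi] - f$shift_n[fi]
  val <- sqrt(dh^2 + (params$alpha_n * dn)^2)
  flag <- ifelse(is.na(val), "missing", "ok")
  residue_profile("csp", idx, val, flag = flag,
                  residue_code = f$residue_code[fi],
                  params = list(alpha_n = params$alpha_n,
                                free = free$label, bound = bound$label,
                                molar_ratio = bound$molar_ratio))
}

#' Intensity ratio I/I0 between bound and free spectra
#'
#' Per-residue ratio of bound-state over free-state peak intensity. Values
#' below 1 report exchange broadening and/or the slower tumbling of the
#' complex. A residue observed free but absent from the bound list is
#' reported as ratio 0 with flag `"broadened_out"` (broadened beyond
#' detection); a residue with free intensity 0 is flagged `"invalid"`
#' rather than divided.
#'
#' @param free,bound peak lists; intensities must be present in both for at
#'   least one residue.
#' @return a [residue_profile()] named `"intensity_ratio"`, dimensionless.
#' @export
compute_intensity_ratio <- function(free, bound) {
  stopifnot(inherits(free, "peak_list"), inherits(bound, "peak_list"))
  f <- free$entries
  b <- bound$entries
  f <- f[!is.na(f$intensity), ]
  if (nrow(f) == 0) stop("free peak list carries no intensities")
  bi <- match(f$residue_index, b$residue_index)
  ib <- b$intensity[bi]
  val <- numeric(nrow(f))
  flag <- character(nrow(f))
  for (k in seq_len(nrow(f))) {
    if (f$intensity[k] == 0) {
      val[k] <- NA_real_
      flag[k] <- "invalid"
    } else if (is.na(bi[k])) {
      val[k] <- 0
      flag[k] <- "broadened_out"
    } else if (is.na(ib[k])) {
      val[k] <- NA_real_
      flag[k] <- "missing"
    } else {
      val[k] <- ib[k] / f$intensity[k]
      flag[k] <- "ok"
    }
  }
  if (!any(flag == "ok")) stop("no residue has intensities in both spectra")
  residue_profile("intensity_ratio", f$residue_index, val, flag = flag,
                  residue_code = f$residue_code,
                  params = list(free = free$label, bound = bound$label,
                                molar_ratio = bound$molar_ratio))
}

#' Sliding-window average of a per-residue track
#'
#' Centered moving average over residue *index* (not array position): a gap
#' in the numbering breaks the window, chain ends use the truncated window,
#' and missing values are excluded from both the sum and the divisor.
#' Broadened-out residues contribute their value 0. Rows flagged
#' missing/invalid stay missing.
#'
#' @param track a [residue_profile()].
#' @param window odd integer >= 1; 1 returns the track unchanged (apart
#'   from recorded params).
#' @return smoothed [residue_profile()].
#' @export
smooth_track <- function(track, window = 3L) {
  stopifnot(inherits(track, "residue_profile"))
  window <- as.integer(window)
  if (window < 1 || window %% 2 == 0) stop("window must be an odd integer >= 1")
  d <- track$data
  half <- (window - 1L) %/% 2L
  present <- d$residue_index
  usable <- profile_observed(track)
  out <- d$value
  for (k in seq_len(nrow(d))) {
    if (!usable[k]) next
    i <- present[k]
    # contiguity: extend while consecutive indices exist in the track
    lo <- i
    while (i - lo < half && (lo - 1L) %in% present) lo <- lo - 1L
    hi <- i
    while (hi - i < half && (hi + 1L) %in% present) hi <- hi + 1L
    sel <- which(present >= lo & present <= hi & usable)
    out[k] <- mean(d$value[sel])
  }
  residue_profile(track$name, d$residue_index, out, flag = d$flag,
                  residue_code = d$residue_code,
                  params = c(track$params, list(smooth_window = window)))
}
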