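#' Extract per-residue peak trajectories from a titration series
#'
#' One trajectory per residue observed in the free spectrum, following its
#' amide peak across titration points in molar-ratio order. Points where
#' the residue is unassigned (e.g. broadened beyond detection) are kept as
#' missing rows so the position in the titration is preserved.
#'
#' @param series a [titration_series()].
#' @return list of `peak_trajectory` objects, each with fields
#'   `residue_index`, `residue_code`, `points` (tibble: `molar_ratio`,
#'   `shift_h`, `shift_n`, `intensity`) and `n_observed`.
#' @export
extract_trajectories <- function(series) {
  stopifnot(inherits(series, "titration_series"))
  free <- series$points[[1]]$entries
  free <- free[!is.na(free$shift_h) & !is.na(free$shift_n), ]
  lapply(seq_len(nrow(free)), function(k) {
    idx <- free$residue_index[k]
    pts <- lapply(series$points, function(p) {
      m <- match(idx, p$entries$residue_index)
      tibble(molar_ratio = p$molar_ratio,
             shift_h = if (is.na(m)) NA_real_ else p$entries$shift_h[m],
             shift_n = if (is.na(m)) NA_real_ else p$entries$shift_n[m],
             intensity = if (is.na(m)) NA_real_ else p$entries$intensity[m])
    })
    pts <- bind_rows(pts)
    structure(list(residue_index = idx,
                   residue_code = free$residue_code[k],
                   points = pts,
                   n_observed = sum(!is.na(pts$shift_h) & !is.na(pts$shift_n))),
              class = "peak_trajectory")
  })
}

# total-least-squares principal axis in the scaled (dH, alpha_n*dN) plane;
# returns max perpendicular distance of the points from the line
tls_max_deviation <- function(x, y) {
  cx <- x - mean(x)
  cy <- y - mean(y)
  M <- cbind(cx, cy)
  s <- svd(M)
  if (length(s$d) < 2 || s$d[1] == 0) return(0)
  perp <- abs(M %*% s$v[, 2])
  max(perp)
}

#' Classify one peak trajectory as linear or non-linear
#'
#' In a two-state fast-exchange titration the observed peak moves along
#' the straight line between the free and bound positions, so deviation
#' from linearity flags intermediate states or additional binding sites.
#' Shifts are placed in the compound plane (dH, alpha_n * dN) so distances
#' match the CSP metric, the principal axis is fitted by total least
#' squares, and `max_deviation` is the largest perpendicular distance of
#' an observed point from that line.
#'
#' Labels: `insufficient` when fewer than 3 points are observed (a line
#' always fits two); `broadened_out` when the final titration point is
#' missing (the geometry of the remaining points is still reported);
#' otherwise `nonlinear` when `max_deviation > dev_factor * noise_sd` and
#' the total path length exceeds `4 * noise_sd` (the gate keeps noise-only
#' trajectories of unperturbed residues from being called non-linear),
#' else `linear`.
#'
#' @param traj a `peak_trajectory` from [extract_trajectories()].
#' @param noise_sd shift-noise standard deviation in ppm (> 0).
#' @param dev_factor deviation multiplier for the non-linearity call.
#' @param alpha_n 15N weight of the compound plane.
#' @return tibble row: `residue_index`, `label`, `max_deviation`,
#'   `path_length`, `n_observed`.
#' @export
classify_trajectory <- function(traj, noise_sd, dev_factor = 3,
                                alpha_n = 0.14) {
  stopifnot(inherits(traj, "peak_trajectory"), noise_sd > 0)
  pts <- traj$points
  obs <- !is.na(pts$shift_h) & !is.na(pts$shift_n)
  n_obs <- sum(obs)
  row <- function(label, maxdev, path) {
    tibble(residue_index = traj$residue_index, label = label,
           max_deviation = maxdev, path_length = path, n_observed = n_obs)
  }
  if (n_obs < 3) return(row("insufficient", NA_real_, NA_real_))
  x <- pts$shift_h[obs]
  y <- alpha_n * pts$shift_n[obs]
  maxdev <- tls_max_deviation(x, y)
  path <- sum(sqrt(diff(x)^2 + diff(y)^2))
  if (!obs[length(obs)]) return(row("broadened_out", maxdev, path))
  lab <- if (maxdev > dev_factor * noise_sd && path > 4 * noise_sd)
    "nonlinear" else "linear"
  row(lab, maxdev, path)
}

#' Classify every trajectory of a series
#'
#' @param series a [titration_series()].
#' @inheritParams classify_trajectory
#' @return tibble of per-residue calls, sorted by residue index.
#' @export
classify_trajectories <- function(series, noise_sd, dev_factor = 3,
                                  alpha_n = 0.14) {
  calls <- lapply(extract_trajectories(series), classify_trajectory,
                  noise_sd = noise_sd, dev_factor = dev_factor,
                  alpha_n = alpha_n)
  arrange(bind_rows(calls), .data$residue_index)
}
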