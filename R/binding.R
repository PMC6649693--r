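#' Binding / exchange model parameters
#'
#' Parameters of the two-state (optionally two-site) fast-exchange forward
#' model used by the synthetic generator. Concentrations share one unit
#' (conventionally uM); the titrations modelled here are near-
#' stoichiometric, so ligand depletion is always treated exactly via the
#' quadratic mass balance, never the ligand-excess approximation.
#'
#' @param kd1 dissociation constant of the primary site.
#' @param kd2 dissociation constant of an optional weak secondary site
#'   (`NA` to disable). Non-cooperative: its occupancy is computed against
#'   the same ligand pool and its shift contribution is additive.
#' @param p_total labelled-protein concentration.
#' @param ratios ligand:protein molar ratios of the titration points
#'   (0 = free state).
#' @param r2_free,r2_bound transverse relaxation rates (s^-1) of the free
#'   protein and the complex; their difference models the intensity loss
#'   from slower tumbling of the bound state.
#' @param kex exchange rate (s^-1) entering the fast-exchange broadening
#'   term Rex = f(1-f) * dw^2 / kex applied to contact residues.
#' @param t_relax effective signal-decay time (s) converting a rate excess
#'   into a relative intensity, I/I0 = exp(-dR2 * t_relax).
#' @param field_mhz 1H spectrometer frequency used to convert ppm shift
#'   differences to rad/s.
#' @return list of class `binding_params`.
#' @export
binding_params <- function(kd1 = 5, kd2 = NA_real_, p_total = 50,
                           ratios = c(0, 0.5, 1, 2),
                           r2_free = 20, r2_bound = 30, kex = 2000,
                           t_relax = 0.05, field_mhz = 800) {
  stopifnot(kd1 > 0, is.na(kd2) || kd2 > 0, p_total > 0, all(ratios >= 0),
            kex > 0, r2_free >= 0, r2_bound >= r2_free, t_relax > 0,
            field_mhz > 0)
  structure(list(kd1 = kd1, kd2 = kd2, p_total = p_total,
                 ratios = sort(ratios), r2_free = r2_free,
                 r2_bound = r2_bound, kex = kex, t_relax = t_relax,
                 field_mhz = field_mhz),
            class = "binding_params")
}

#' Fraction of protein bound under ligand depletion
#'
#' Exact single-site mass balance: with total protein P, total ligand L
#' and dissociation constant Kd,
#' \deqn{f = \frac{(P+L+K_d) - \sqrt{(P+L+K_d)^2 - 4PL}}{2P}.}
#' At Kd = 0 the stoichiometric limit f = min(L/P, 1) is returned exactly.
#' Vectorised over `l_total`.
#'
#' @param p_total total protein concentration (> 0).
#' @param l_total total ligand concentration(s) (>= 0).
#' @param kd dissociation constant (>= 0), same units.
#' @return bound fraction(s) in \[0, 1\].
#' @export
fraction_bound <- function(p_total, l_total, kd) {
  if (!is.numeric(p_total) || p_total <= 0) stop("p_total must be > 0")
  if (any(l_total < 0)) stop("l_total must be >= 0")
  if (length(kd) != 1 || kd < 0) stop("kd must be a single value >= 0")
  if (kd == 0) return(pmin(l_total / p_total, 1))
  s <- p_total + l_total + kd
  disc <- pmax(s^2 - 4 * p_total * l_total, 0)
  f <- (s - sqrt(disc)) / (2 * p_total)
  pmin(pmax(f, 0), 1)
}

# compound shift difference in rad/s at the declared field
delta_omega <- function(ddh, ddn, field_mhz) {
  nu_h <- field_mhz          # Hz per ppm for 1H
  nu_n <- field_mhz * 0.10137  # 15N/1H gyromagnetic ratio
  2 * pi * sqrt((ddh * nu_h)^2 + (ddn * nu_n)^2)
}

#' Observed peak position and intensity under fast exchange
#'
#' Population-weighted averaging: the observed shift is the free position
#' displaced by the bound fraction times the full-saturation shift change,
#' and the peak intensity decays with the excess transverse relaxation
#' \deqn{\Delta R_2 = f_{tot}(R_{2,bound}-R_{2,free}) +
#'   [contact]\, f(1-f)\,\Delta\omega^2 / k_{ex},}
#' the second term being the fast-exchange broadening that is maximal at
#' half saturation and vanishes at the endpoints.
#'
#' @param resp per-residue response: list/row with `ddh`, `ddn` (ppm shift
#'   changes at saturation of site 1), optional `ddh2`, `ddn2` (site 2)
#'   and logical `contact` (exchange broadening applies).
#' @param f bound fraction of site 1 in \[0, 1\].
#' @param free_h,free_n free-state shifts (ppm).
#' @param model a [binding_params()].
#' @param f2 bound fraction of the optional second site.
#' @return list with `shift_h`, `shift_n` (ppm) and `rel_intensity`
#'   (I/I0 relative to the free state).
#' @export
observed_peak <- function(resp, f, free_h, free_n, model = binding_params(),
                          f2 = 0) {
  stopifnot(f >= 0, f <= 1, f2 >= 0, f2 <= 1)
  ddh2 <- if (!is.null(resp$ddh2)) resp$ddh2 else 0
  ddn2 <- if (!is.null(resp$ddn2)) resp$ddn2 else 0
  contact <- isTRUE(resp$contact)
  shift_h <- free_h + f * resp$ddh + f2 * ddh2
  shift_n <- free_n + f * resp$ddn + f2 * ddn2
  f_tot <- min(f + f2, 1)
  dr2 <- f_tot * (model$r2_bound - model$r2_free)
  if (contact) {
    dw <- delta_omega(resp$ddh, resp$ddn, model$field_mhz)
    dr2 <- dr2 + f * (1 - f) * dw^2 / model$kex
  }
  list(shift_h = shift_h, shift_n = shift_n,
       rel_intensity = exp(-dr2 * model$t_relax))
}

#' Fit a global dissociation constant to CSP titration curves
#'
#' Least-squares fit of \eqn{\Delta\delta(i, L) = \Delta\delta_{max}(i)
#' \cdot f(P, L, K_d)} with one global Kd shared by all responsive
#' residues and per-residue saturation amplitudes. The amplitudes are
#' profiled out analytically (linear in the model), leaving a 1-D search
#' over log Kd.
#'
#' @param csp_curves numeric matrix of CSPs (ppm), rows = residues,
#'   columns = titration points (may contain `NA`).
#' @param l_total total ligand concentration per column.
#' @param p_total total protein concentration.
#' @param min_response residues whose largest CSP is below this (ppm) are
#'   excluded as non-responsive; if none remain the fit errors.
#' @return list: `kd` (estimate), `dd_max` (per-residue amplitudes, ppm),
#'   `rss`, `n_residues`.
#' @export
fit_kd <- function(csp_curves, l_total, p_total, min_response = 0.02) {
  csp_curves <- as.matrix(csp_curves)
  stopifnot(ncol(csp_curves) == length(l_total), p_total > 0)
  if (length(l_total) < 3) stop("need at least 3 titration points")
  resp <- apply(csp_curves, 1, function(r) max(r, na.rm = TRUE)) > min_response
  if (!any(resp)) stop("no responsive residues: all curves flat")
  y <- csp_curves[resp, , drop = FALSE]
  rss_at <- function(log_kd) {
    f <- fraction_bound(p_total, l_total, exp(log_kd))
    tot <- 0
    for (i in seq_len(nrow(y))) {
      obs <- !is.na(y[i, ])
      a <- sum(f[obs] * y[i, obs]) / sum(f[obs]^2)
      tot <- tot + sum((y[i, obs] - a * f[obs])^2)
    }
    tot
  }
  span <- log(c(1e-4, 1e4) * p_total)
  opt <- optimize(rss_at, interval = span, tol = 1e-10)
  kd <- exp(opt$minimum)
  f <- fraction_bound(p_total, l_total, kd)
  dd_max <- apply(y, 1, function(r) {
    obs <- !is.na(r)
    sum(f[obs] * r[obs]) / sum(f[obs]^2)
  })
  list(kd = kd, dd_max = dd_max, rss = opt$objective, n_residues = nrow(y))
}
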