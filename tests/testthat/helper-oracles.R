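# Independent oracles used to cross-check the implementation.

# equilibrium solver by bisection on free ligand: Lf + P*Lf/(Kd+Lf) = L
fraction_bound_bisect <- function(p_total, l_total, kd) {
  if (l_total == 0) return(0)
  g <- function(lf) lf + p_total * lf / (kd + lf) - l_total
  lo <- 0
  hi <- l_total
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (g(mid) > 0) hi <- mid else lo <- mid
  }
  lf <- (lo + hi) / 2
  lf / (kd + lf)
}

# exhaustive line-angle scan for the total-least-squares principal axis:
# minimises the sum of squared perpendicular distances over the line angle
# (line through the centroid), then reports the max perpendicular distance
tls_maxdev_scan <- function(x, y, n_angles = 1e4) {
  cx <- x - mean(x)
  cy <- y - mean(y)
  ssq <- function(theta) {
    perp <- -cx * sin(theta) + cy * cos(theta)
    sum(perp^2)
  }
  thetas <- seq(0, pi, length.out = n_angles)
  vals <- vapply(thetas, ssq, 0)
  k <- which.min(vals)
  span <- c(thetas[max(1, k - 2)], thetas[min(n_angles, k + 2)])
  best <- stats::optimize(ssq, interval = span, tol = 1e-14)$minimum
  max(abs(-cx * sin(best) + cy * cos(best)))
}

# small assigned peak list straight from vectors
mk_peaklist <- function(idx, code, h, n, intensity = NA_real_,
                        label = "free", ratio = 0) {
  peak_list(tibble::tibble(residue_index = idx, residue_code = code,
                           shift_h = h, shift_n = n, intensity = intensity),
            label = label, molar_ratio = ratio)
}

# noiseless single-site configuration used by several tests
noiseless_config <- function(...) {
  sim_config(noise_shift_sd = 0, noise_ca_sd = 0, noise_intensity_cv = 0, ...)
}

# configuration for the trajectory-discrimination experiment: every amide
# residue responds to the strong site; kex high enough that no peak
# broadens out mid-titration; optional weak second site on all residues
discrimination_config <- function(two_site = FALSE, noise = 0.001) {
  seq <- cspmap:::DEFAULT_SEQUENCE
  chars <- strsplit(seq, "")[[1]]
  amide <- which(chars != "P")
  model <- binding_params(kd1 = 5, kd2 = if (two_site) 100 else NA_real_,
                          kex = 1e5)
  ts <- NULL
  if (two_site) {
    # second-site vector deliberately non-parallel to typical site-1
    # directions (negative 1H, positive scaled 15N component)
    ts <- tibble::tibble(residue = amide, ddh2 = -0.10, ddn2 = 0.11 / 0.14)
  }
  sim_config(sequence = seq,
             patches = tibble::tibble(start = 1L, end = nchar(seq),
                                      dd_max = 0.2),
             model = model, two_site = ts,
             helix_segment = NULL, strand_segment = NULL,
             noise_shift_sd = noise)
}
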