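# typical backbone amide shifts per residue type (ppm), used as free-state
# peak positions before seeded jitter; prolines have no amide peak
AMIDE_TABLE <- list(
  A = c(8.19, 123.2), C = c(8.32, 118.8), D = c(8.30, 120.4),
  E = c(8.33, 120.6), F = c(8.11, 120.7), G = c(8.33, 109.5),
  H = c(8.25, 119.1), I = c(8.00, 121.4), K = c(8.18, 121.3),
  L = c(8.06, 121.8), M = c(8.22, 120.1), N = c(8.32, 118.9),
  Q = c(8.28, 119.8), R = c(8.23, 120.8), S = c(8.27, 115.8),
  T = c(8.15, 114.3), V = c(8.03, 120.8), W = c(7.97, 121.5),
  Y = c(8.05, 120.5))

# 191-residue demo construct: a chromodomain-sized folded N-terminus
# followed by a long low-complexity stretch, proline-free inside the
# default planted patches so every patch residue has an amide probe
DEFAULT_SEQUENCE <- paste0(
  "ADDDFRLGRKTKVYVQVVGGVVALGNKYQLIVVIGPGVWNKRVDEIRIGPLVTIAIIPAQ",
  "FLVLGTVILKAFLNLKELVRYIAKGFSVAFAYAAAIVLVPLKVGAEAASLTAMAGYMVAN",
  "PYWMIVGIIVHRASYIYDRFICEIERPKCDSGLQGCDWEKSDSGLRSLNEADTSEASKAV",
  "IEDLHLQRVPR")

#' Simulation configuration for a synthetic titration
#'
#' Defines the study conditions the generator emulates: a 191-residue
#' construct titrated with an unlabelled ligand at molar ratios
#' 0/0.5/1/2 from 50 uM labelled protein, with contiguous contact patches
#' whose residues shift (and exchange-broaden) on binding, optional
#' weak-second-site curvature, induced helix/strand segments in the
#' Calpha shifts, Gaussian shift noise and multiplicative intensity
#' noise, and a detection floor below which peaks vanish from the list.
#'
#' @param sequence one-letter construct sequence.
#' @param patches tibble/data.frame with columns `start`, `end`,
#'   `dd_max` (compound CSP at saturation, ppm) — the planted contact
#'   patches.
#' @param model a [binding_params()].
#' @param two_site tibble with columns `residue`, `ddh2`, `ddn2` (ppm) of
#'   residues that also feel the weak second site (requires `model$kd2`),
#'   or `NULL`.
#' @param helix_segment,strand_segment integer ranges of induced
#'   secondary structure in the Calpha shifts, or `NULL`.
#' @param helix_amp,strand_amp secondary-shift amplitudes (ppm).
#' @param noise_shift_sd Gaussian noise sd added to every 1H and 15N
#'   shift (ppm).
#' @param noise_ca_sd Gaussian noise sd of the Calpha shifts (ppm).
#' @param noise_intensity_cv coefficient of variation of multiplicative
#'   (lognormal) intensity noise.
#' @param detection_floor relative intensity below which a peak is
#'   dropped from the list ("broadened beyond detection").
#' @param alpha_n 15N weight used to decompose planted compound CSPs into
#'   1H/15N components.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(sequence = DEFAULT_SEQUENCE,
                       patches = tibble(
                         start = c(25L, 40L, 113L, 164L),
                         end = c(28L, 42L, 117L, 170L),
                         dd_max = c(0.20, 0.45, 0.25, 0.18)),
                       model = binding_params(),
                       two_site = NULL,
                       helix_segment = 164:174, strand_segment = 113:117,
                       helix_amp = 2.5, strand_amp = -2.0,
                       noise_shift_sd = 0.003, noise_ca_sd = 0.1,
                       noise_intensity_cv = 0.1,
                       detection_floor = 0.05, alpha_n = 0.14) {
  stopifnot(inherits(model, "binding_params"),
            detection_floor > 0, detection_floor < 1,
            noise_shift_sd >= 0, noise_intensity_cv >= 0, noise_ca_sd >= 0)
  patches <- as_tibble(patches)
  n <- nchar(sequence)
  if (nrow(patches) > 0 &&
      (any(patches$start < 1) || any(patches$end > n) ||
       any(patches$start > patches$end))) {
    stop("planted patch outside the sequence")
  }
  if (!is.null(two_site) && is.na(model$kd2)) {
    stop("two_site residues require model$kd2")
  }
  structure(list(sequence = sequence, patches = patches, model = model,
                 two_site = if (is.null(two_site)) NULL else as_tibble(two_site),
                 helix_segment = helix_segment,
                 strand_segment = strand_segment,
                 helix_amp = helix_amp, strand_amp = strand_amp,
                 noise_shift_sd = noise_shift_sd, noise_ca_sd = noise_ca_sd,
                 noise_intensity_cv = noise_intensity_cv,
                 detection_floor = detection_floor, alpha_n = alpha_n),
            class = "sim_config")
}

#' Generate a synthetic titration dataset with its answer key
#'
#' Free-state amide positions are drawn per residue from residue-type
#' typical shifts with seeded jitter (+-0.3 ppm 1H, +-2 ppm 15N). For each
#' molar ratio the bound fraction follows the exact depletion mass
#' balance ([fraction_bound()]); each peak is placed and attenuated by
#' [observed_peak()], then Gaussian shift noise and lognormal intensity
#' noise are added. Peaks whose model relative intensity falls below the
#' detection floor are dropped from that peak list and recorded in the
#' ground truth. Prolines are omitted from every amide peak list. A
#' Calpha shift table (random coil + planted helix/strand segments +
#' noise) accompanies the series.
#'
#' Identical `config` and `seed` give byte-identical output.
#'
#' @param config a [sim_config()].
#' @param seed integer RNG seed.
#' @return list: `series` ([titration_series()]), `ca_shifts`
#'   ([peak_list()] with Calpha values), `ground_truth` (class
#'   `synthetic_ground_truth`).
#' @export
generate_titration <- function(config = sim_config(), seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  withr::local_seed(as.integer(seed))
  seq_chars <- strsplit(config$sequence, "")[[1]]
  n <- length(seq_chars)
  model <- config$model
  idx_all <- seq_len(n)
  amide_idx <- idx_all[seq_chars != "P"]

  # per-residue responses
  responses <- tibble(residue_index = amide_idx,
                      ddh = 0, ddn = 0, dd_max = 0,
                      ddh2 = 0, ddn2 = 0, contact = FALSE)
  for (p in seq_len(nrow(config$patches))) {
    span <- config$patches$start[p]:config$patches$end[p]
    for (i in span) {
      k <- match(i, responses$residue_index)
      if (is.na(k)) next
      phi <- runif(1, 0.15, pi / 2 - 0.15)
      ddm <- config$patches$dd_max[p]
      responses$ddh[k] <- ddm * cos(phi)
      responses$ddn[k] <- ddm * sin(phi) / config$alpha_n
      responses$dd_max[k] <- ddm
      responses$contact[k] <- TRUE
    }
  }
  if (!is.null(config$two_site)) {
    for (r in seq_len(nrow(config$two_site))) {
      k <- match(config$two_site$residue[r], responses$residue_index)
      if (is.na(k)) next
      responses$ddh2[k] <- config$two_site$ddh2[r]
      responses$ddn2[k] <- config$two_site$ddn2[r]
    }
  }

  # free-state positions and reference intensities
  base_h <- base_n <- numeric(length(amide_idx))
  for (k in seq_along(amide_idx)) {
    ref <- AMIDE_TABLE[[seq_chars[amide_idx[k]]]]
    base_h[k] <- ref[1] + runif(1, -0.3, 0.3)
    base_n[k] <- ref[2] + runif(1, -2, 2)
  }
  base_i <- 1e6 * exp(rnorm(length(amide_idx), 0, 0.15))

  ratios <- model$ratios
  points <- vector("list", length(ratios))
  dropped <- vector("list", length(ratios))
  names(dropped) <- as.character(ratios)
  for (j in seq_along(ratios)) {
    l_total <- ratios[j] * model$p_total
    f1 <- fraction_bound(model$p_total, l_total, model$kd1)
    f2 <- if (is.na(model$kd2)) 0 else
      fraction_bound(model$p_total, l_total, model$kd2)
    sh <- sn <- inten <- numeric(length(amide_idx))
    keep <- logical(length(amide_idx))
    for (k in seq_along(amide_idx)) {
      obs <- observed_peak(as.list(responses[k, ]), f1, base_h[k], base_n[k],
                           model = model, f2 = f2)
      sh[k] <- obs$shift_h + rnorm(1, 0, config$noise_shift_sd)
      sn[k] <- obs$shift_n + rnorm(1, 0, config$noise_shift_sd)
      inten[k] <- base_i[k] * obs$rel_intensity *
        exp(rnorm(1, 0, config$noise_intensity_cv))
      keep[k] <- obs$rel_intensity >= config$detection_floor
    }
    dropped[[j]] <- amide_idx[!keep]
    lab <- if (ratios[j] == 0) "free" else sprintf("1:%g", ratios[j])
    points[[j]] <- peak_list(
      tibble(residue_index = amide_idx[keep],
             residue_code = seq_chars[amide_idx[keep]],
             shift_h = sh[keep], shift_n = sn[keep],
             intensity = inten[keep]),
      label = lab, molar_ratio = ratios[j])
  }
  series <- titration_series(config$sequence, points)

  # Calpha table of the bound state
  rc <- random_coil_ca()
  ca <- unname(rc[seq_chars]) + rnorm(n, 0, config$noise_ca_sd)
  if (!is.null(config$helix_segment)) {
    ca[config$helix_segment] <- ca[config$helix_segment] + config$helix_amp
  }
  if (!is.null(config$strand_segment)) {
    ca[config$strand_segment] <- ca[config$strand_segment] + config$strand_amp
  }
  ca_shifts <- peak_list(
    tibble(residue_index = idx_all, residue_code = seq_chars,
           shift_h = NA_real_, shift_n = NA_real_, intensity = NA_real_,
           shift_ca = ca),
    label = "bound_ca", molar_ratio = max(ratios))

  gt <- structure(list(
    seed = as.integer(seed), sequence = config$sequence,
    patches = config$patches, responses = responses,
    kd1 = model$kd1, kd2 = model$kd2, p_total = model$p_total,
    ratios = ratios,
    contact_residues = responses$residue_index[responses$contact],
    two_site_residues = if (is.null(config$two_site)) integer(0) else
      as.integer(config$two_site$residue),
    helix_segment = config$helix_segment,
    strand_segment = config$strand_segment,
    noise_shift_sd = config$noise_shift_sd,
    noise_intensity_cv = config$noise_intensity_cv,
    detection_floor = config$detection_floor,
    dropped_by_ratio = dropped,
    broadened_out = dropped[[length(dropped)]]), class = "synthetic_ground_truth")
  list(series = series, ca_shifts = ca_shifts, ground_truth = gt)
}

#' Write a generated dataset to disk
#'
#' Emits one Sparky-style peak list per titration point, the Calpha table
#' and ground truth as TSV, and a YAML manifest listing (ratio, file)
#' pairs — the on-disk form consumed by [run_analysis()].
#'
#' @param sim result of [generate_titration()].
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
write_titration <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  entries <- list()
  for (p in sim$series$points) {
    fn <- if (p$molar_ratio == 0) "free.list" else
      sprintf("r%g.list", p$molar_ratio)
    write_peaklist(p, file.path(dir, fn))
    entries[[length(entries) + 1L]] <-
      list(ratio = p$molar_ratio, path = fn, label = p$label)
  }
  ca <- sim$ca_shifts$entries
  lines <- c("residue_index\tresidue_code\tshift_ca_ppm",
             sprintf("%d\t%s\t%.5f", ca$residue_index, ca$residue_code,
                     ca$shift_ca))
  writeLines(lines, file.path(dir, "ca_shifts.tsv"))
  gt <- sim$ground_truth
  gt_tab <- gt$responses
  gt_lines <- c("residue_index\tddh\tddn\tdd_max\tddh2\tddn2\tcontact",
                sprintf("%d\t%.6f\t%.6f\t%.6f\t%.6f\t%.6f\t%d",
                        gt_tab$residue_index, gt_tab$ddh, gt_tab$ddn,
                        gt_tab$dd_max, gt_tab$ddh2, gt_tab$ddn2,
                        as.integer(gt_tab$contact)))
  writeLines(gt_lines, file.path(dir, "ground_truth.tsv"))
  writeLines(c(sprintf(">synthetic_construct length=%d", nchar(gt$sequence)),
               gt$sequence), file.path(dir, "sequence.fasta"))
  manifest <- list(sequence = "sequence.fasta", ca_shifts = "ca_shifts.tsv",
                   points = entries)
  mf <- file.path(dir, "series.yaml")
  yaml::write_yaml(manifest, mf)
  invisible(mf)
}

jaccard_span <- function(a_start, a_end, b_start, b_end) {
  a <- seq.int(a_start, a_end)
  b <- seq.int(b_start, b_end)
  length(intersect(a, b)) / length(union(a, b))
}

#' Score detected patches and structure calls against the answer key
#'
#' @param gt ground truth from [generate_titration()].
#' @param detected patch tibble from [detect_patches()].
#' @param sse optional tibble from [call_sse()].
#' @param broadened_detected optional integer vector of residues the
#'   intensity-ratio track flagged `broadened_out`.
#' @return list: `patch_jaccard` (best Jaccard per planted patch),
#'   `sensitivity` (planted patches overlapped by any detected),
#'   `precision`, `n_false` (detected patches overlapping nothing
#'   planted), `sse_recovered` (per planted segment: matching type and
#'   >= 50% overlap), `broadened_recall`.
#' @export
answer_key_report <- function(gt, detected, sse = NULL,
                              broadened_detected = NULL) {
  planted <- gt$patches
  np <- nrow(planted)
  jac <- numeric(np)
  hit <- logical(np)
  for (i in seq_len(np)) {
    if (nrow(detected) > 0) {
      js <- vapply(seq_len(nrow(detected)), function(j)
        jaccard_span(planted$start[i], planted$end[i],
                     detected$start_index[j], detected$end_index[j]), 0)
      jac[i] <- max(js)
      hit[i] <- any(js > 0)
    }
  }
  false_det <- 0L
  if (nrow(detected) > 0) {
    for (j in seq_len(nrow(detected))) {
      ovl <- any(vapply(seq_len(np), function(i)
        jaccard_span(planted$start[i], planted$end[i],
                     detected$start_index[j], detected$end_index[j]) > 0,
        TRUE))
      if (np == 0 || !ovl) false_det <- false_det + 1L
    }
  }
  sse_rec <- NULL
  if (!is.null(sse)) {
    segs <- list()
    if (!is.null(gt$helix_segment))
      segs$helix <- range(gt$helix_segment)
    if (!is.null(gt$strand_segment))
      segs$strand <- range(gt$strand_segment)
    sse_rec <- vapply(names(segs), function(ty) {
      seg <- segs[[ty]]
      cand <- sse[sse$sse_type == ty, , drop = FALSE]
      if (nrow(cand) == 0) return(FALSE)
      any(vapply(seq_len(nrow(cand)), function(j) {
        ov <- length(intersect(seq.int(seg[1], seg[2]),
                               seq.int(cand$start_index[j], cand$end_index[j])))
        ov >= 0.5 * (seg[2] - seg[1] + 1)
      }, TRUE))
    }, TRUE)
  }
  broad_recall <- NA_real_
  if (!is.null(broadened_detected)) {
    truth <- gt$broadened_out
    broad_recall <- if (length(truth) == 0) NA_real_ else
      length(intersect(broadened_detected, truth)) / length(truth)
  }
  list(patch_jaccard = jac,
       sensitivity = if (np == 0) NA_real_ else mean(hit),
       precision = if (nrow(detected) == 0) NA_real_ else
         1 - false_det / nrow(detected),
       n_false = false_det,
       sse_recovered = sse_rec,
       broadened_recall = broad_recall)
}
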