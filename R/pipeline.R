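#' Run the full titration analysis in memory
#'
#' For every bound titration point computes the CSP track and the
#' (optionally smoothed) intensity-ratio track; detects binding patches
#' on the bound point with the highest molar ratio (the
#' strongest-perturbation condition) using CSP and broadening together;
#' classifies every residue's peak trajectory; and, when a Calpha table
#' is supplied, computes the secondary-shift track and
#' secondary-structure calls. All applied parameters, including
#' defaults, are recorded in the returned `run_report`.
#'
#' @param series a [titration_series()].
#' @param ca_shifts optional [peak_list()] with Calpha values.
#' @param csp a [csp_params()].
#' @param patch a [patch_params()].
#' @param noise_sd trajectory shift-noise sd (ppm).
#' @param dev_factor trajectory non-linearity multiplier.
#' @param helix_cut,strand_cut secondary-shift cutoffs (ppm).
#' @param smooth_intensity smooth the I/I0 tracks with the CSP window
#'   (the CSP tracks themselves are left unsmoothed by default).
#' @param smooth_csp also smooth the CSP tracks.
#' @return list of class `titration_analysis`: `csp` and `ratio` (lists of
#'   [residue_profile()] keyed by point label), `patches`, `patch_point`,
#'   `trajectories`, `secondary_shift`, `sse`, `run_report`.
#' @export
analyze_titration <- function(series, ca_shifts = NULL,
                              csp = csp_params(), patch = patch_params(),
                              noise_sd = 0.003, dev_factor = 3,
                              helix_cut = 0.7, strand_cut = -0.7,
                              smooth_intensity = TRUE, smooth_csp = FALSE) {
  stopifnot(inherits(series, "titration_series"))
  if (length(series$points) < 2) {
    stop("series needs a free point and at least one bound point")
  }
  free <- series$points[[1]]
  bound <- series$points[-1]
  csp_tracks <- list()
  ratio_tracks <- list()
  for (p in bound) {
    ct <- compute_csp(free, p, csp)
    if (smooth_csp) ct <- smooth_track(ct, csp$window)
    rt <- compute_intensity_ratio(free, p)
    if (smooth_intensity) rt <- smooth_track(rt, csp$window)
    csp_tracks[[p$label]] <- ct
    ratio_tracks[[p$label]] <- rt
  }
  top <- length(bound)
  patches <- detect_patches(csp_tracks[[top]], ratio_tracks[[top]], patch)
  traj <- classify_trajectories(series, noise_sd = noise_sd,
                                dev_factor = dev_factor,
                                alpha_n = csp$alpha_n)
  sec <- NULL
  sse <- NULL
  rc_name <- NULL
  if (!is.null(ca_shifts)) {
    rc <- random_coil_ca()
    rc_name <- attr(rc, "reference")
    sec <- secondary_shift_track(ca_shifts, series$sequence, rc)
    sse <- call_sse(sec, helix_cut = helix_cut, strand_cut = strand_cut,
                    smooth_window = csp$window)
  }
  report <- list(
    n_points = length(series$points),
    ratios = vapply(series$points, function(p) p$molar_ratio, 0),
    patch_point = bound[[top]]$label,
    alpha_n = csp$alpha_n, window = csp$window,
    smooth_intensity = smooth_intensity, smooth_csp = smooth_csp,
    csp_threshold_mode = patch$csp_threshold_mode,
    csp_threshold = attr(patches, "csp_threshold"),
    sd_mult = patch$sd_mult, trim = patch$trim,
    ratio_cutoff = patch$ratio_cutoff,
    min_len = patch$min_len, max_gap = patch$max_gap,
    noise_sd = noise_sd, dev_factor = dev_factor,
    helix_cut = helix_cut, strand_cut = strand_cut,
    rc_reference = rc_name,
    package_version = as.character(utils::packageVersion("cspmap")))
  structure(list(csp = csp_tracks, ratio = ratio_tracks,
                 patches = patches, patch_point = bound[[top]]$label,
                 trajectories = traj, secondary_shift = sec, sse = sse,
                 run_report = report),
            class = "titration_analysis")
}

#' File-based end-to-end analysis of a titration series
#'
#' Reads a YAML manifest (as written by [write_titration()]) listing the
#' sequence FASTA, the per-ratio peak lists and optionally a Calpha
#' table, runs [analyze_titration()], and writes per-point `csp_*.tsv`
#' and `ratio_*.tsv`, `patches.tsv`, `trajectories.tsv`, optional
#' `secondary_shift.tsv`/`sse.tsv`, a `run_report.yaml` with every
#' applied parameter, and optional per-residue profile plots. Any stage
#' error aborts the run with the stage name and removes partial outputs.
#'
#' @param manifest path to the series YAML manifest.
#' @param outdir output directory.
#' @param plots also write profile plots (PDF).
#' @param ... passed to [analyze_titration()].
#' @return the `titration_analysis`, invisibly.
#' @export
run_analysis <- function(manifest, outdir, plots = FALSE, ...) {
  if (!file.exists(manifest)) stop("manifest not found: ", manifest)
  base <- dirname(manifest)
  mf <- yaml::read_yaml(manifest)
  if (is.null(mf$points) || length(mf$points) < 2) {
    stop("stage input: manifest must list a free and at least one bound point")
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      unlink(outdir, recursive = TRUE)
      stop("stage ", name, ": ", conditionMessage(e), call. = FALSE)
    })
  }
  sequence <- stage("read_sequence",
                    read_fasta_sequence(file.path(base, mf$sequence)))
  points <- stage("read_peaklists", lapply(mf$points, function(p) {
    read_peaklist(file.path(base, p$path), format = "sparky",
                  label = if (is.null(p$label)) basename(p$path) else p$label,
                  molar_ratio = p$ratio)
  }))
  series <- stage("assemble_series", titration_series(sequence, points))
  ca <- NULL
  if (!is.null(mf$ca_shifts)) {
    ca <- stage("read_ca_shifts", {
      tab <- utils::read.delim(file.path(base, mf$ca_shifts))
      peak_list(tibble(residue_index = tab$residue_index,
                       residue_code = tab$residue_code,
                       shift_h = NA_real_, shift_n = NA_real_,
                       shift_ca = tab$shift_ca_ppm),
                label = "ca", molar_ratio = 0)
    })
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  res <- stage("analyze", analyze_titration(series, ca_shifts = ca, ...))
  stage("write_outputs", {
    safe <- function(lab) gsub("[^A-Za-z0-9._-]", "_", lab)
    for (lab in names(res$csp)) {
      write_profile(res$csp[[lab]],
                    file.path(outdir, sprintf("csp_%s.tsv", safe(lab))))
      write_profile(res$ratio[[lab]],
                    file.path(outdir, sprintf("ratio_%s.tsv", safe(lab))))
    }
    write_tsv_table(res$patches, file.path(outdir, "patches.tsv"))
    write_tsv_table(res$trajectories, file.path(outdir, "trajectories.tsv"))
    if (!is.null(res$secondary_shift)) {
      write_profile(res$secondary_shift,
                    file.path(outdir, "secondary_shift.tsv"))
      write_tsv_table(res$sse, file.path(outdir, "sse.tsv"))
    }
    yaml::write_yaml(res$run_report, file.path(outdir, "run_report.yaml"))
  })
  if (plots) {
    stage("plots", {
      top <- length(res$csp)
      pdf_path <- file.path(outdir, "profiles.pdf")
      grDevices::pdf(pdf_path, width = 9, height = 4)
      on.exit(grDevices::dev.off(), add = TRUE)
      print(plot_profile(res$csp[[top]], patches = res$patches))
      print(plot_profile(res$ratio[[top]]))
      if (!is.null(res$secondary_shift)) print(plot_profile(res$secondary_shift))
    })
  }
  invisible(res)
}

# deterministic TSV writer for result tables (fixed formatting, LF endings)
write_tsv_table <- function(tab, path) {
  fmt_col <- function(x) {
    if (is.numeric(x) && !is.integer(x)) {
      ifelse(is.na(x), "NA", sprintf("%.10g", x))
    } else {
      as.character(x)
    }
  }
  cols <- lapply(tab, fmt_col)
  lines <- c(paste(names(tab), collapse = "\t"),
             if (nrow(tab) > 0) do.call(paste, c(cols, sep = "\t")))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Plot a per-residue profile track
#'
#' Bar plot of the track against residue index; broadened-out residues
#' are marked at zero in a distinct colour, and detected patches can be
#' shaded.
#'
#' @param track a [residue_profile()].
#' @param patches optional patch tibble from [detect_patches()].
#' @return a ggplot object.
#' @export
plot_profile <- function(track, patches = NULL) {
  d <- track$data
  d$status <- ifelse(d$flag == "broadened_out", "broadened out",
                     ifelse(d$flag == "ok", "observed", "missing"))
  g <- ggplot2::ggplot(d[d$flag %in% c("ok", "broadened_out"), ],
                       ggplot2::aes(x = .data$residue_index, y = .data$value,
                                    fill = .data$status)) +
    ggplot2::geom_col(width = 0.8) +
    ggplot2::scale_fill_manual(values = c(`observed` = "#2166ac",
                                          `broadened out` = "#b2182b")) +
    ggplot2::labs(x = "residue", y = track$name, title = track$name) +
    ggplot2::theme_minimal()
  if (!is.null(patches) && nrow(patches) > 0) {
    g <- g + ggplot2::annotate("rect",
                               xmin = patches$start_index - 0.5,
                               xmax = patches$end_index + 0.5,
                               ymin = -Inf, ymax = Inf,
                               alpha = 0.15, fill = "#fdae61")
  }
  g
}
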