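#' Patch-detection parameters
#'
#' A residue is significant if its CSP exceeds a threshold, or its I/I0
#' falls below `ratio_cutoff`, or it is broadened beyond detection. The
#' CSP threshold is either `fixed` (use `csp_fixed_cutoff`) or
#' `mean_plus_sd`: trimmed mean of the CSP track plus `sd_mult` standard
#' deviations of the trimmed values. Trimming (10% of each tail) keeps the
#' binding patch itself from inflating the baseline, but also shrinks the
#' apparent noise scale, so the default multiplier of 3 corresponds to
#' roughly two untrimmed standard deviations — low enough to keep real
#' contact residues, high enough that run merging does not manufacture
#' patches from noise.
#'
#' Runs of significant residues separated by gaps of at most `max_gap`
#' non-significant residues are merged; merged runs spanning fewer than
#' `min_len` residues, or containing fewer than `min_len` significant
#' residues, are discarded (two noise exceedances straddling a gap never
#' qualify on their own).
#'
#' @param csp_threshold_mode `"mean_plus_sd"` or `"fixed"`.
#' @param csp_fixed_cutoff CSP cutoff in ppm when mode is `"fixed"`.
#' @param sd_mult standard-deviation multiplier for `"mean_plus_sd"`.
#' @param trim tail fraction trimmed from each side of the CSP
#'   distribution before the mean/sd are taken.
#' @param ratio_cutoff I/I0 below which a residue is significant.
#' @param min_len minimum patch span in residues.
#' @param max_gap maximum internal gap merged into a patch.
#' @return list of class `patch_params`.
#' @export
patch_params <- function(csp_threshold_mode = c("mean_plus_sd", "fixed"),
                         csp_fixed_cutoff = 0.05, sd_mult = 3, trim = 0.1,
                         ratio_cutoff = 0.3, min_len = 3L, max_gap = 1L) {
  csp_threshold_mode <- match.arg(csp_threshold_mode)
  stopifnot(csp_fixed_cutoff > 0, ratio_cutoff > 0, sd_mult > 0,
            trim >= 0, trim < 0.5)
  min_len <- as.integer(min_len)
  max_gap <- as.integer(max_gap)
  if (min_len < 1) stop("min_len must be >= 1")
  if (max_gap < 0) stop("max_gap must be >= 0")
  structure(list(csp_threshold_mode = csp_threshold_mode,
                 csp_fixed_cutoff = csp_fixed_cutoff, sd_mult = sd_mult,
                 trim = trim, ratio_cutoff = ratio_cutoff,
                 min_len = min_len, max_gap = max_gap),
            class = "patch_params")
}

#' CSP significance threshold for a track
#'
#' @param csp a [residue_profile()] of CSP values.
#' @param params a [patch_params()].
#' @return threshold in ppm.
#' @export
csp_threshold <- function(csp, params = patch_params()) {
  if (params$csp_threshold_mode == "fixed") return(params$csp_fixed_cutoff)
  v <- csp$data$value[csp$data$flag == "ok"]
  v <- v[is.finite(v)]
  if (length(v) < 3) return(params$csp_fixed_cutoff)
  v <- sort(v)
  k <- floor(params$trim * length(v))
  if (k > 0) v <- v[(k + 1):(length(v) - k)]
  mean(v) + params$sd_mult * sd(v)
}

#' Detect contiguous binding patches
#'
#' Calls contiguous runs of significant residues from a CSP track and,
#' optionally, an intensity-ratio track (residues flagged
#' `broadened_out` are always significant: their peaks vanished on
#' binding). Runs with internal gaps of at most `max_gap` are merged and
#' runs spanning fewer than `min_len` residues are dropped. If every value
#' is missing an empty result is returned with a warning.
#'
#' @param csp [residue_profile()] of CSPs (ppm).
#' @param ratio optional [residue_profile()] of I/I0 values aligned on the
#'   same residue index space, or `NULL`.
#' @param params a [patch_params()].
#' @return tibble with one row per patch: `start_index`, `end_index`,
#'   `length`, `tracks`, `peak_value` (largest CSP inside), `mean_value`
#'   (mean CSP inside), `n_missing` (broadened-out residues inside),
#'   sorted by `start_index`. The CSP threshold used is attached as
#'   attribute `csp_threshold`.
#' @export
detect_patches <- function(csp, ratio = NULL, params = patch_params()) {
  stopifnot(inherits(csp, "residue_profile"))
  if (!is.null(ratio)) stopifnot(inherits(ratio, "residue_profile"))
  thr <- csp_threshold(csp, params)
  d <- csp$data
  sig_csp <- d$flag == "ok" & d$value > thr
  idx <- d$residue_index
  sig_ratio <- rep(FALSE, length(idx))
  broad <- rep(FALSE, length(idx))
  if (!is.null(ratio)) {
    m <- match(idx, ratio$data$residue_index)
    rflag <- ratio$data$flag[m]
    rval <- ratio$data$value[m]
    broad <- !is.na(rflag) & rflag == "broadened_out"
    sig_ratio <- (!is.na(rflag) & rflag == "ok" & rval < params$ratio_cutoff) | broad
    extra <- setdiff(ratio$data$residue_index[ratio$data$flag == "broadened_out"], idx)
  } else {
    extra <- integer(0)
  }
  sig_idx <- sort(unique(c(idx[sig_csp | sig_ratio], extra)))
  if (all(!sig_csp) && all(!sig_ratio) && length(extra) == 0 &&
      !any(d$flag == "ok")) {
    warning("detect_patches: all values missing; returning no patches")
  }
  empty <- tibble(start_index = integer(0), end_index = integer(0),
                  length = integer(0), tracks = character(0),
                  peak_value = numeric(0), mean_value = numeric(0),
                  n_missing = integer(0))
  attr(empty, "csp_threshold") <- thr
  if (length(sig_idx) == 0) return(empty)

  grp <- cumsum(c(1L, diff(sig_idx) > params$max_gap + 1L))
  out <- list()
  for (g in unique(grp)) {
    members <- sig_idx[grp == g]
    start <- min(members)
    end <- max(members)
    if (end - start + 1L < params$min_len) next
    if (length(members) < params$min_len) next
    inside <- idx >= start & idx <= end
    csp_ok <- inside & d$flag == "ok"
    trig <- c(if (any(sig_csp[inside])) "csp",
              if (any(sig_ratio & inside) || any(extra >= start & extra <= end))
                "intensity_ratio")
    out[[length(out) + 1L]] <- tibble(
      start_index = start, end_index = end,
      length = end - start + 1L,
      tracks = paste(trig, collapse = "+"),
      peak_value = if (any(csp_ok)) max(d$value[csp_ok]) else NA_real_,
      mean_value = if (any(csp_ok)) mean(d$value[csp_ok]) else NA_real_,
      n_missing = sum(broad[inside]) + sum(extra >= start & extra <= end))
  }
  res <- if (length(out) == 0) empty else arrange(bind_rows(out), .data$start_index)
  attr(res, "csp_threshold") <- thr
  res
}

#' Compare two patch sets
#'
#' Classifies patches from two conditions (e.g. methylated versus
#' unmodified nucleosome) as shared (any residue overlap), a-only or
#' b-only, reporting overlap residue counts. Losing a patch in condition b
#' marks a contact that depends on the feature distinguishing the
#' conditions.
#'
#' @param a,b patch tibbles from [detect_patches()] over the same sequence
#'   space.
#' @return tibble with columns `set` (`"a"`/`"b"`), `start_index`,
#'   `end_index`, `status` (`shared`/`a_only`/`b_only`), `overlap_residues`.
#' @export
compare_patch_sets <- function(a, b) {
  span <- function(p) seq.int(p$start_index, p$end_index)
  classify <- function(x, other, own, other_lab) {
    if (nrow(x) == 0) return(NULL)
    rows <- lapply(seq_len(nrow(x)), function(i) {
      ov <- 0L
      if (nrow(other) > 0) {
        for (j in seq_len(nrow(other))) {
          ov <- ov + length(intersect(span(x[i, ]), span(other[j, ])))
        }
      }
      tibble(set = own, start_index = x$start_index[i],
             end_index = x$end_index[i],
             status = if (ov > 0) "shared" else paste0(own, "_only"),
             overlap_residues = ov)
    })
    bind_rows(rows)
  }
  bind_rows(classify(a, b, "a"), classify(b, a, "b"))
}
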