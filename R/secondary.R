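#' Random-coil Calpha reference shifts
#'
#' The packaged default is the Wishart et al. (1995) random-coil Calpha
#' set (ppm), the zero point against which measured Calpha shifts are
#' compared: positive secondary shifts indicate alpha-helix, negative
#' beta-strand.
#'
#' @param path optional TSV override with columns `residue_code`,
#'   `shift_ca_ppm` covering all 20 amino acids.
#' @return named numeric vector over the one-letter codes, with attribute
#'   `reference` naming the set.
#' @export
random_coil_ca <- function(path = NULL) {
  if (is.null(path)) {
    rc <- c(A = 52.5, C = 58.2, D = 54.2, E = 56.6, F = 57.7,
            G = 45.1, H = 55.0, I = 61.1, K = 56.2, L = 55.1,
            M = 55.4, N = 52.8, P = 63.3, Q = 55.7, R = 56.0,
            S = 58.3, T = 61.8, V = 62.2, W = 57.5, Y = 57.9)
    attr(rc, "reference") <- "wishart1995"
    return(rc)
  }
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("residue_code", "shift_ca_ppm") %in% names(tab))) {
    stop("random-coil table needs columns residue_code, shift_ca_ppm")
  }
  rc <- setNames(as.numeric(tab$shift_ca_ppm), tab$residue_code)
  miss <- setdiff(AA1, names(rc))
  if (length(miss) > 0) stop("random-coil table lacks amino acid(s): ",
                             paste(miss, collapse = ", "))
  if (any(rc < 40 | rc > 70)) stop("random-coil Calpha values outside 40-70 ppm")
  attr(rc, "reference") <- basename(path)
  rc
}

#' Calpha secondary chemical shifts
#'
#' Per-residue difference between the measured Calpha shift and the
#' residue-type random-coil value,
#' \eqn{\Delta\delta_{C\alpha}(i) = \delta_{C\alpha}(i) - RC(aa_i)}.
#' Residues without a Calpha assignment are flagged missing.
#'
#' @param ca_shifts a [peak_list()] whose `shift_ca` column carries the
#'   measured values.
#' @param sequence one-letter sequence covering every assigned index.
#' @param rc random-coil table from [random_coil_ca()].
#' @return a [residue_profile()] named `"secondary_shift"`, in ppm.
#' @export
secondary_shift_track <- function(ca_shifts, sequence, rc = random_coil_ca()) {
  stopifnot(inherits(ca_shifts, "peak_list"))
  e <- ca_shifts$entries
  seq_chars <- strsplit(sequence, "")[[1]]
  if (any(e$residue_index > length(seq_chars))) {
    stop("Calpha table has indices beyond the sequence")
  }
  codes <- seq_chars[e$residue_index]
  unknown <- setdiff(unique(codes), names(rc))
  if (length(unknown) > 0) {
    stop("residue code(s) absent from random-coil table: ",
         paste(unknown, collapse = ", "))
  }
  if (all(is.na(e$shift_ca))) stop("no Calpha shifts present")
  val <- e$shift_ca - unname(rc[codes])
  residue_profile("secondary_shift", e$residue_index, val,
                  residue_code = codes,
                  params = list(rc_reference = attr(rc, "reference")))
}

#' Call secondary-structure segments from a secondary-shift track
#'
#' The track is smoothed ([smooth_track()]) and runs of consecutive
#' residues above `helix_cut` (length >= 4) are called helix, runs below
#' `strand_cut` (length >= 3) strand — the conventional consensus
#' chemical-shift sign rule (positive Calpha secondary shift: helix;
#' negative: strand). Runs must be contiguous in residue numbering.
#'
#' @param track a [residue_profile()] of Calpha secondary shifts.
#' @param helix_cut positive cutoff in ppm.
#' @param strand_cut negative cutoff in ppm.
#' @param smooth_window odd window for pre-smoothing (1 = none).
#' @param min_len_helix,min_len_strand minimum run lengths.
#' @return tibble: `start_index`, `end_index`, `sse_type`
#'   (`helix`/`strand`), `mean_secondary_shift`, sorted and
#'   non-overlapping.
#' @export
call_sse <- function(track, helix_cut = 0.7, strand_cut = -0.7,
                     smooth_window = 3L, min_len_helix = 4L,
                     min_len_strand = 3L) {
  stopifnot(inherits(track, "residue_profile"))
  if (!(helix_cut > 0) || !(strand_cut < 0)) {
    stop("require helix_cut > 0 > strand_cut")
  }
  sm <- smooth_track(track, smooth_window)
  d <- sm$data
  ok <- profile_observed(sm)
  runs_of <- function(sel, min_len, type) {
    idx <- d$residue_index[sel & ok]
    if (length(idx) == 0) return(NULL)
    idx <- sort(idx)
    grp <- cumsum(c(1L, diff(idx) > 1L))
    out <- lapply(unique(grp), function(g) {
      mem <- idx[grp == g]
      if (length(mem) < min_len) return(NULL)
      inside <- d$residue_index %in% mem
      tibble(start_index = min(mem), end_index = max(mem), sse_type = type,
             mean_secondary_shift = mean(d$value[inside & ok]))
    })
    bind_rows(out)
  }
  res <- bind_rows(
    runs_of(!is.na(d$value) & d$value > helix_cut, min_len_helix, "helix"),
    runs_of(!is.na(d$value) & d$value < strand_cut, min_len_strand, "strand"))
  if (nrow(res) == 0) {
    return(tibble(start_index = integer(0), end_index = integer(0),
                  sse_type = character(0), mean_secondary_shift = numeric(0)))
  }
  arrange(res, .data$start_index)
}
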