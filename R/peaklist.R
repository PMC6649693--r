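#' cspmap: mapping binding surfaces from NMR titration data
#'
#' Tools for analysing assigned 2D 1H-15N HSQC titration series: weighted
#' chemical-shift perturbations, intensity-ratio broadening profiles,
#' contiguous binding-patch detection, peak-trajectory linearity
#' classification, and Calpha secondary-chemical-shift secondary-structure
#' calls, together with a seeded synthetic titration generator and a
#' two-state fast-exchange forward model used to validate every stage.
#'
#' @importFrom dplyr arrange bind_rows filter left_join mutate group_by
#'   summarise ungroup
#' @importFrom tibble tibble as_tibble
#' @importFrom rlang .data
#' @importFrom stats sd optimize rnorm runif setNames
#' @importFrom utils head tail
#' @keywords internal
"_PACKAGE"

AA1 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
         "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

AA3TO1 <- c(ALA = "A", CYS = "C", ASP = "D", GLU = "E", PHE = "F",
            GLY = "G", HIS = "H", ILE = "I", LYS = "K", LEU = "L",
            MET = "M", ASN = "N", PRO = "P", GLN = "Q", ARG = "R",
            SER = "S", THR = "T", VAL = "V", TRP = "W", TYR = "Y")

#' Construct an assigned peak list
#'
#' A peak list holds one titration point: per-residue assigned amide shifts
#' (1H, 15N in ppm), optional peak intensity, and optional Calpha shift.
#' Entries are stored canonically sorted by residue index.
#'
#' @param entries data frame with columns `residue_index`, `residue_code`,
#'   `shift_h`, `shift_n` and optionally `intensity`, `shift_ca`. Missing
#'   values are `NA`: prolines, having no amide proton, must carry `NA`
#'   amide shifts.
#' @param label free-text label for the titration point (e.g. "free",
#'   "1:2").
#' @param molar_ratio ligand:protein molar ratio, 0 for the free state.
#' @return object of class `peak_list`.
#' @export
peak_list <- function(entries, label = "free", molar_ratio = 0) {
  entries <- as_tibble(entries)
  for (col in c("intensity", "shift_ca")) {
    if (!col %in% names(entries)) entries[[col]] <- NA_real_
  }
  need <- c("residue_index", "residue_code", "shift_h", "shift_n")
  miss <- setdiff(need, names(entries))
  if (length(miss) > 0) {
    stop("peak list entries lack column(s): ", paste(miss, collapse = ", "))
  }
  entries <- entries[, c(need, "intensity", "shift_ca")]
  entries$residue_index <- as.integer(entries$residue_index)
  for (col in c("shift_h", "shift_n", "intensity", "shift_ca")) {
    entries[[col]] <- as.numeric(entries[[col]])
  }
  if (nrow(entries) == 0) stop("peak list must contain at least one entry")
  if (any(entries$residue_index < 1, na.rm = TRUE)) {
    stop("residue indices must be positive (1-based)")
  }
  dup <- entries$residue_index[duplicated(entries$residue_index)]
  if (length(dup) > 0) {
    stop("duplicate residue index in peak list: ",
         paste(unique(dup), collapse = ", "))
  }
  bad <- !is.na(entries$intensity) & entries$intensity < 0
  if (any(bad)) stop("negative intensity at residue ",
                     paste(entries$residue_index[bad], collapse = ", "))
  for (col in c("shift_h", "shift_n", "shift_ca")) {
    nf <- !is.na(entries[[col]]) & !is.finite(entries[[col]])
    if (any(nf)) stop("non-finite ", col, " at residue ",
                      paste(entries$residue_index[nf], collapse = ", "))
  }
  if (!is.numeric(molar_ratio) || length(molar_ratio) != 1 || molar_ratio < 0) {
    stop("molar_ratio must be a single non-negative number")
  }
  entries <- arrange(entries, .data$residue_index)
  structure(list(label = as.character(label),
                 molar_ratio = as.numeric(molar_ratio),
                 entries = entries),
            class = "peak_list")
}

#' @export
print.peak_list <- function(x, ...) {
  cat(sprintf("<peak_list> '%s' (ratio %.3g): %d residues\n",
              x$label, x$molar_ratio, nrow(x$entries)))
  print(head(x$entries, 5))
  invisible(x)
}

#' Assemble a titration series
#'
#' Orders peak lists by molar ratio and checks them against the protein
#' sequence. The first point must be the free state (ratio 0); every
#' residue index must fall inside the sequence and carry the matching
#' one-letter code.
#'
#' @param sequence one-letter amino-acid string of the construct.
#' @param points list of [peak_list()] objects (any order; sorted here).
#' @return object of class `titration_series`.
#' @export
titration_series <- function(sequence, points) {
  stopifnot(is.character(sequence), length(sequence) == 1, nchar(sequence) > 0)
  if (length(points) < 1 || !all(vapply(points, inherits, TRUE, "peak_list"))) {
    stop("points must be a non-empty list of peak_list objects")
  }
  ratios <- vapply(points, function(p) p$molar_ratio, 0)
  points <- points[order(ratios)]
  ratios <- sort(ratios)
  if (ratios[1] != 0) {
    stop("the first titration point must be the free state (molar ratio 0)")
  }
  seq_chars <- strsplit(sequence, "")[[1]]
  for (p in points) {
    idx <- p$entries$residue_index
    if (any(idx > length(seq_chars))) {
      stop("peak list '", p$label, "' has residue indices beyond the sequence")
    }
    mism <- p$entries$residue_code != seq_chars[idx]
    if (any(mism)) {
      stop("peak list '", p$label, "' residue code mismatch at index ",
           paste(idx[mism], collapse = ", "))
    }
  }
  structure(list(sequence = sequence, points = points),
            class = "titration_series")
}

#' @export
print.titration_series <- function(x, ...) {
  cat(sprintf("<titration_series> %d residues, %d points (ratios: %s)\n",
              nchar(x$sequence), length(x$points),
              paste(vapply(x$points, function(p) format(p$molar_ratio), ""),
                    collapse = ", ")))
  invisible(x)
}

#' Per-residue profile track
#'
#' A named per-residue numeric track (CSP, I/I0, secondary shift, ...) with
#' an explicit missing-data flag, so residues broadened beyond detection are
#' never confused with unperturbed ones.
#'
#' @param name track name.
#' @param residue_index integer vector of residue positions.
#' @param value numeric values (`NA` where missing).
#' @param flag per-residue status: `"ok"`, `"missing"`, `"broadened_out"`
#'   or `"invalid"`. `broadened_out` rows carry value 0, not `NA`.
#' @param residue_code optional one-letter codes.
#' @param params named list recording the parameters that produced the track.
#' @return object of class `residue_profile`.
#' @export
residue_profile <- function(name, residue_index, value,
                            flag = NULL, residue_code = NA_character_,
                            params = list()) {
  n <- length(residue_index)
  if (is.null(flag)) flag <- ifelse(is.na(value), "missing", "ok")
  stopifnot(length(value) == n, length(flag) == n)
  ok <- flag %in% c("ok", "broadened_out")
  if (any(ok & !is.finite(value))) {
    stop("non-finite value in rows not flagged missing")
  }
  data <- tibble(residue_index = as.integer(residue_index),
                 residue_code = rep_len(as.character(residue_code), n),
                 value = as.numeric(value),
                 flag = as.character(flag))
  data <- arrange(data, .data$residue_index)
  structure(list(name = as.character(name), data = data, params = params),
            class = "residue_profile")
}

#' @export
print.residue_profile <- function(x, ...) {
  cat(sprintf("<residue_profile> '%s': %d residues (%d ok, %d missing/invalid, %d broadened_out)\n",
              x$name, nrow(x$data), sum(x$data$flag == "ok"),
              sum(x$data$flag %in% c("missing", "invalid")),
              sum(x$data$flag == "broadened_out")))
  invisible(x)
}

# values usable as numbers: observed ("ok") plus broadened-out zeros
profile_observed <- function(profile) {
  profile$data$flag %in% c("ok", "broadened_out")
}
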