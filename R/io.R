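#' Read an assigned peak list from disk
#'
#' Two dialects are supported. `sparky`: whitespace-delimited lines whose
#' first token is an assignment of the form `<Res1><Index><Atom1>-<Atom2>`
#' (e.g. `K113N-H`), followed by the two shifts in the atom order of the
#' label and an optional intensity column. `tsv`: tab-separated with header
#' columns `residue_index`, `residue_code`, `shift_h_ppm`, `shift_n_ppm`
#' and optionally `intensity`, `shift_ca_ppm`.
#'
#' Rows whose assignment label cannot be parsed are skipped with a warning
#' that reports how many were dropped; a duplicated residue index is an
#' error naming the residue.
#'
#' @param path file to read.
#' @param format `"sparky"` or `"tsv"`.
#' @param label,molar_ratio metadata attached to the returned [peak_list()].
#' @return a [peak_list()].
#' @export
read_peaklist <- function(path, format = c("sparky", "tsv"),
                          label = "free", molar_ratio = 0) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tsv") {
    tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                             check.names = FALSE)
    if (nrow(tab) == 0) stop("empty peak list file: ", path)
    need <- c("residue_index", "residue_code", "shift_h_ppm", "shift_n_ppm")
    miss <- setdiff(need, names(tab))
    if (length(miss) > 0) stop("TSV peak list lacks column(s): ",
                               paste(miss, collapse = ", "))
    entries <- tibble(
      residue_index = tab$residue_index,
      residue_code = tab$residue_code,
      shift_h = tab$shift_h_ppm,
      shift_n = tab$shift_n_ppm,
      intensity = if ("intensity" %in% names(tab)) tab$intensity else NA_real_,
      shift_ca = if ("shift_ca_ppm" %in% names(tab)) tab$shift_ca_ppm else NA_real_)
    return(peak_list(entries, label = label, molar_ratio = molar_ratio))
  }

  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  lines <- lines[!grepl("^(Assignment|#)", lines, ignore.case = TRUE)]
  if (length(lines) == 0) stop("empty peak list file: ", path)
  pat <- "^([A-Za-z])([0-9]+)([A-Za-z][A-Za-z0-9']*)-([A-Za-z][A-Za-z0-9']*)$"
  rows <- list()
  skipped <- 0L
  for (ln in lines) {
    tok <- strsplit(ln, "[[:space:]]+")[[1]]
    m <- regmatches(tok[1], regexec(pat, tok[1]))[[1]]
    if (length(m) != 5 || length(tok) < 3) {
      skipped <- skipped + 1L
      next
    }
    w <- suppressWarnings(as.numeric(tok[2:3]))
    inten <- if (length(tok) >= 4) suppressWarnings(as.numeric(tok[4])) else NA_real_
    if (any(is.na(w))) {
      skipped <- skipped + 1L
      next
    }
    atoms <- toupper(c(m[4], m[5]))
    sh <- c(NA_real_, NA_real_)  # (H, N)
    for (k in 1:2) {
      if (startsWith(atoms[k], "H")) sh[1] <- w[k]
      if (startsWith(atoms[k], "N")) sh[2] <- w[k]
    }
    if (any(is.na(sh))) {
      skipped <- skipped + 1L
      next
    }
    rows[[length(rows) + 1L]] <- tibble(
      residue_index = as.integer(m[3]),
      residue_code = toupper(m[2]),
      shift_h = sh[1], shift_n = sh[2], intensity = inten)
  }
  if (skipped > 0) {
    warning(sprintf("read_peaklist: skipped %d unparseable line(s) in %s",
                    skipped, path))
  }
  if (length(rows) == 0) stop("no parseable peaks in ", path)
  peak_list(bind_rows(rows), label = label, molar_ratio = molar_ratio)
}

#' Write a peak list in Sparky-style format
#'
#' @param pl a [peak_list()].
#' @param path output file.
#' @param digits decimal places for shifts.
#' @export
write_peaklist <- function(pl, path, digits = 5) {
  e <- pl$entries
  keep <- !is.na(e$shift_h) & !is.na(e$shift_n)
  e <- e[keep, ]
  lab <- sprintf("%s%d%s", e$residue_code, e$residue_index, "N-H")
  inten <- ifelse(is.na(e$intensity), "", sprintf("%.6e", e$intensity))
  lines <- sprintf("%-12s %10.*f %10.*f %s", lab, digits, e$shift_n,
                   digits, e$shift_h, inten)
  writeLines(c("Assignment         w1         w2   Height", trimws(lines, "right")),
             path)
  invisible(path)
}

#' Read an NMR-STAR v3 chemical-shift loop
#'
#' Minimal reader for the `Atom_chem_shift` loop of an NMR-STAR v3 file
#' (the format of BMRB depositions). H, N and CA rows are mapped onto the
#' amide/Calpha fields of one peak list; residues lacking H or N keep
#' missing amide shifts.
#'
#' @param path NMR-STAR file.
#' @param label,molar_ratio metadata for the returned [peak_list()].
#' @return a [peak_list()].
#' @export
read_shift_table_nmrstar <- function(path, label = "nmrstar", molar_ratio = 0) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  i <- 1L
  tags <- character()
  data_rows <- list()
  n <- length(lines)
  found <- FALSE
  while (i <= n) {
    if (lines[i] == "loop_") {
      j <- i + 1L
      tags <- character()
      while (j <= n && startsWith(lines[j], "_")) {
        tags <- c(tags, lines[j])
        j <- j + 1L
      }
      if (any(grepl("^_Atom_chem_shift\\.", tags))) {
        found <- TRUE
        rows <- list()
        while (j <= n && lines[j] != "stop_") {
          if (nzchar(lines[j]) && !startsWith(lines[j], "#")) {
            rows[[length(rows) + 1L]] <- strsplit(lines[j], "[[:space:]]+")[[1]]
          }
          j <- j + 1L
        }
        if (j > n) stop("malformed NMR-STAR: Atom_chem_shift loop lacks stop_")
        data_rows <- rows
        break
      }
      i <- j
    } else {
      i <- i + 1L
    }
  }
  if (!found) stop("no Atom_chem_shift loop found in ", path)
  if (length(data_rows) == 0) stop("Atom_chem_shift loop is empty in ", path)
  tagnames <- sub("^_Atom_chem_shift\\.", "", tags)
  col <- function(nm) {
    k <- match(nm, tagnames)
    if (is.na(k)) stop("Atom_chem_shift loop lacks tag ", nm)
    k
  }
  bad <- vapply(data_rows, length, 0L) != length(tags)
  if (any(bad)) stop("malformed NMR-STAR: row width does not match tag count")
  seq_col <- col("Seq_ID")
  comp_col <- col("Comp_ID")
  atom_col <- col("Atom_ID")
  val_col <- col("Val")
  idx <- as.integer(vapply(data_rows, `[`, "", seq_col))
  comp <- toupper(vapply(data_rows, `[`, "", comp_col))
  atom <- toupper(vapply(data_rows, `[`, "", atom_col))
  val <- as.numeric(vapply(data_rows, `[`, "", val_col))
  code <- unname(AA3TO1[comp])
  keep <- atom %in% c("H", "N", "CA") & !is.na(code)
  df <- tibble(residue_index = idx[keep], residue_code = code[keep],
               atom = atom[keep], val = val[keep])
  if (nrow(df) == 0) stop("no H/N/CA shifts in Atom_chem_shift loop")
  wide <- df |>
    group_by(.data$residue_index, .data$residue_code) |>
    summarise(shift_h = if (any(.data$atom == "H")) .data$val[.data$atom == "H"][1] else NA_real_,
              shift_n = if (any(.data$atom == "N")) .data$val[.data$atom == "N"][1] else NA_real_,
              shift_ca = if (any(.data$atom == "CA")) .data$val[.data$atom == "CA"][1] else NA_real_,
              .groups = "drop")
  peak_list(wide, label = label, molar_ratio = molar_ratio)
}

#' Read a protein sequence from FASTA
#'
#' Uses Biostrings when installed, otherwise a plain-text fallback. Only
#' the first record is returned.
#'
#' @param path FASTA file.
#' @return one-letter amino-acid string.
#' @export
read_fasta_sequence <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    ss <- Biostrings::readAAStringSet(path)
    if (length(ss) == 0) stop("no sequences in ", path)
    return(as.character(ss[[1]]))
  }
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0 || !startsWith(lines[1], ">")) {
    stop("not a FASTA file: ", path)
  }
  body <- lines[-1]
  stop_at <- which(startsWith(body, ">"))
  if (length(stop_at) > 0) body <- body[seq_len(stop_at[1] - 1)]
  toupper(gsub("[^A-Za-z]", "", paste(body, collapse = "")))
}

#' Write a per-residue profile as TSV
#'
#' Columns: `residue_index`, `residue_code`, `value`, `flag`. Values are
#' written with 17 significant digits so that [read_profile()] round-trips
#' them bit-exactly.
#'
#' @param track a [residue_profile()].
#' @param path output file.
#' @export
write_profile <- function(track, path) {
  stopifnot(inherits(track, "residue_profile"))
  d <- track$data
  val <- ifelse(is.na(d$value), "NA", sprintf("%.17g", d$value))
  lines <- c("residue_index\tresidue_code\tvalue\tflag",
             sprintf("%d\t%s\t%s\t%s", d$residue_index, d$residue_code,
                     val, d$flag))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read a per-residue profile written by [write_profile()]
#'
#' @param path TSV file.
#' @param name track name (defaults to the file name without extension).
#' @return a [residue_profile()].
#' @export
read_profile <- function(path, name = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           na.strings = "NA", colClasses = c(
                             residue_index = "integer",
                             residue_code = "character",
                             value = "numeric", flag = "character"))
  residue_profile(name, tab$residue_index, tab$value,
                  flag = tab$flag, residue_code = tab$residue_code)
}
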