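test_that("sparky dialect maps assignment tokens onto residue fields", {
  f <- withr::local_tempfile(fileext = ".list")
  writeLines(c("Assignment    w1      w2    Height",
               "K113N-H  122.41  8.35  1.0e6",
               "G22N-H   109.77  8.41  8.5e5",
               "???-?     101.0   8.0   1e5",
               "T40N-H   114.02  8.12"),
             f)
  expect_warning(pl <- read_peaklist(f, "sparky"), "skipped 1")
  e <- pl$entries
  expect_equal(nrow(e), 3)
  k113 <- e[e$residue_index == 113, ]
  expect_equal(k113$residue_code, "K")
  expect_equal(k113$shift_n, 122.41)
  expect_equal(k113$shift_h, 8.35)
  expect_equal(k113$intensity, 1.0e6)
  # intensity column optional
  expect_true(is.na(e$intensity[e$residue_index == 40]))
})

test_that("peak list invariants: duplicates named, empties rejected", {
  f <- withr::local_tempfile(fileext = ".list")
  writeLines(c("T40N-H 114.0 8.1 1e5", "T40N-H 114.1 8.2 1e5"), f)
  expect_error(read_peaklist(f, "sparky"), "40")
  writeLines(character(0), f)
  expect_error(read_peaklist(f, "sparky"), "empty")
  expect_error(mk_peaklist(1L, "A", 8.1, 120, intensity = -1), "negative")
  expect_error(peak_list(tibble::tibble(residue_index = integer(0),
                                        residue_code = character(0),
                                        shift_h = numeric(0),
                                        shift_n = numeric(0))),
               "at least one")
})

test_that("TSV dialect round-trips a three-residue list", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("residue_index\tresidue_code\tshift_h_ppm\tshift_n_ppm\tintensity",
               "5\tA\t8.10\t123.4\t1e6",
               "6\tG\t8.35\t109.2\t2e6",
               "8\tL\t8.01\t121.9\t1.5e6"), f)
  pl <- read_peaklist(f, "tsv")
  expect_equal(nrow(pl$entries), 3)
  expect_equal(pl$entries$residue_index, c(5L, 6L, 8L))
  expect_equal(pl$entries$shift_h[2], 8.35)
})

test_that("NMR-STAR chemical-shift loop reader maps H/N/CA rows", {
  star <- withr::local_tempfile(fileext = ".str")
  writeLines(c("data_synthetic_fixture", "save_assigned_shifts", "loop_",
               "_Atom_chem_shift.ID", "_Atom_chem_shift.Seq_ID",
               "_Atom_chem_shift.Comp_ID", "_Atom_chem_shift.Atom_ID",
               "_Atom_chem_shift.Val",
               "1 12 LYS H 8.35", "2 12 LYS N 122.41", "3 12 LYS CA 56.9",
               "4 13 ALA CA 52.7",
               "stop_", "save_"), star)
  pl <- read_shift_table_nmrstar(star)
  e <- pl$entries
  expect_equal(nrow(e), 2)
  r12 <- e[e$residue_index == 12, ]
  expect_equal(r12$residue_code, "K")
  expect_equal(r12$shift_h, 8.35)
  expect_equal(r12$shift_n, 122.41)
  expect_equal(r12$shift_ca, 56.9)
  # CA-only residue keeps missing amide shifts
  r13 <- e[e$residue_index == 13, ]
  expect_true(is.na(r13$shift_h) && is.na(r13$shift_n))
  expect_equal(r13$shift_ca, 52.7)
})

test_that("NMR-STAR reader rejects files without a usable loop", {
  f <- withr::local_tempfile(fileext = ".str")
  writeLines(c("data_x", "loop_", "_Other.Tag", "1", "stop_"), f)
  expect_error(read_shift_table_nmrstar(f), "Atom_chem_shift")
  writeLines(c("data_x", "loop_", "_Atom_chem_shift.Seq_ID",
               "_Atom_chem_shift.Comp_ID", "_Atom_chem_shift.Atom_ID",
               "_Atom_chem_shift.Val", "1 ALA CA"), f)
  expect_error(read_shift_table_nmrstar(f))
})

test_that("profile TSV round-trips bit-exactly, with missing rows flagged", {
  set.seed(11)
  val <- rnorm(10) * exp(rnorm(10, 0, 4))
  flag <- rep("ok", 10)
  val[c(3, 7)] <- NA
  flag[c(3, 7)] <- "missing"
  val[5] <- 0
  flag[5] <- "broadened_out"
  tr <- residue_profile("csp", 1:10, val, flag = flag,
                        residue_code = strsplit("ACDEFGHIKL", "")[[1]])
  f <- withr::local_tempfile(fileext = ".tsv")
  write_profile(tr, f)
  back <- read_profile(f, name = "csp")
  expect_identical(back$data$value, tr$data$value)
  expect_identical(back$data$flag, tr$data$flag)
  expect_identical(back$data$residue_index, tr$data$residue_index)
  expect_equal(sum(back$data$flag == "missing"), 2)
})

test_that("empty profile writes a header-only file", {
  tr <- residue_profile("csp", integer(0), numeric(0))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_profile(tr, f)
  expect_equal(readLines(f), "residue_index\tresidue_code\tvalue\tflag")
  expect_equal(nrow(read_profile(f)$data), 0)
})

test_that("prolines never appear in amide-based tracks", {
  sim <- generate_titration(sim_config(), seed = 3)
  pro <- which(strsplit(sim$ground_truth$sequence, "")[[1]] == "P")
  for (p in sim$series$points) {
    expect_length(intersect(p$entries$residue_index, pro), 0)
  }
  csp <- compute_csp(sim$series$points[[1]], sim$series$points[[4]])
  expect_length(intersect(csp$data$residue_index, pro), 0)
})

test_that("readers never invent residues and FASTA reading works", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">demo", "ACDEFGHIKL", "MNPQRSTVWY"), fa)
  expect_equal(read_fasta_sequence(fa), "ACDEFGHIKLMNPQRSTVWY")
  f <- withr::local_tempfile(fileext = ".list")
  writeLines(c("K3N-H 122.4 8.3 1e6", "A5N-H 123.0 8.2 1e6"), f)
  pl <- read_peaklist(f, "sparky")
  expect_true(all(pl$entries$residue_index %in% c(3L, 5L)))
})
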