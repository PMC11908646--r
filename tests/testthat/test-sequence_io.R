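test_that("read_fasta parses records, normalizes case and strips stops", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">p1 some description", "mck", ">p2", "ACDE*", "FG"), fa)
  rec <- read_fasta(fa)
  expect_equal(rec$id, c("p1", "p2"))
  expect_equal(rec$sequence, c("MCK", "ACDEFG"))
})

test_that("read_fasta handles empty files and rejects bad records", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(0), fa)
  expect_equal(nrow(read_fasta(fa)), 0L)

  writeLines(c(">ok", "ACD", ">empty_rec", ""), fa)
  expect_error(read_fasta(fa), "empty_rec")

  writeLines(c(">badchar", "AC1D"), fa)
  expect_error(read_fasta(fa), "badchar")
})

test_that("fasta and site tables round-trip through write/read", {
  dir <- withr::local_tempdir()
  prot <- tibble::tibble(id = c("a", "b"), sequence = c("MCK", "CCAC"))
  write_fasta(prot, file.path(dir, "p.fasta"))
  expect_equal(read_fasta(file.path(dir, "p.fasta")), prot)

  sites <- tibble::tibble(protein_id = c("a", "b"), position = c(2L, 1L),
                          label = c(1L, 0L))
  write_site_table(sites, file.path(dir, "s.tsv"))
  expect_equal(read_site_table(file.path(dir, "s.tsv")), sites)
})

test_that("extract_windows pads termini and validates sites", {
  prot <- tibble::tibble(id = "p1", sequence = "ACDEFG")
  w <- extract_windows(prot,
                       tibble::tibble(protein_id = "p1", position = 2L,
                                      label = 1L), k = 3)
  expect_equal(w$window, "--ACDEF")  # pad prefix of length 2
  expect_equal(nchar(w$window), 7L)

  # interior site: no pads
  prot2 <- tibble::tibble(id = "p2", sequence = "AAACAAA")
  w2 <- extract_windows(prot2,
                        tibble::tibble(protein_id = "p2", position = 4L,
                                       label = 0L), k = 3)
  expect_equal(w2$window, "AAACAAA")
  expect_false(grepl("-", w2$window))

  # one window per site row
  sites <- tibble::tibble(protein_id = "p2", position = c(4L, 4L),
                          label = c(1L, 0L))
  expect_equal(nrow(extract_windows(prot2, sites, k = 2)), 2L)

  expect_error(
    extract_windows(prot, tibble::tibble(protein_id = "p1", position = 1L,
                                         label = 1L), k = 3),
    "not a cysteine")
  expect_error(
    extract_windows(prot, tibble::tibble(protein_id = "p1", position = 99L,
                                         label = 1L), k = 3),
    "out of range")
  expect_error(
    extract_windows(prot, tibble::tibble(protein_id = "nope", position = 2L,
                                         label = 1L), k = 3),
    "unknown protein")
})

test_that("segment_window splits around the shared central cysteine", {
  seg <- segment_window("ABCDE")
  expect_equal(seg$left, "ABC")
  expect_equal(seg$right, "CDE")
  expect_equal(seg$full, "ABCDE")

  seg2 <- segment_window("--C--")
  expect_equal(seg2$left, "--C")
  expect_equal(seg2$right, "C--")

  expect_error(segment_window("ABCD"), "odd")
  expect_error(segment_window("ABADE"), "cysteine")
})

test_that("left + right minus shared center reconstructs the full window", {
  d <- generate_synth(synth_config(n_pos = 10, n_neg = 10, k = 7), seed = 3)
  seg <- segment_window(d)
  rebuilt <- paste0(seg$left, substr(seg$right, 2L, nchar(seg$right)))
  expect_equal(rebuilt, seg$full)
  expect_equal(nchar(seg$left) + nchar(seg$right) - 1L, nchar(seg$full))
})

test_that("apply_direction reverses exactly the parts its code marks", {
  seg <- tibble::tibble(left = "ABC", right = "CDE", full = "ABCDE")
  lll <- apply_direction(seg, "LLL")
  expect_equal(lll[, c("left", "right", "full")],
               seg[, c("left", "right", "full")])

  rll <- apply_direction(seg, "RLL")
  expect_equal(rll$left, "CBA")
  expect_equal(rll$right, "CDE")
  expect_equal(rll$full, "ABCDE")

  rrr <- apply_direction(seg, "RRR")
  expect_equal(rrr$left, "CBA")
  expect_equal(rrr$right, "EDC")
  expect_equal(rrr$full, "EDCBA")

  expect_error(apply_direction(seg, "RLX"), "direction code")
  expect_error(apply_direction(seg, "RL"), "direction code")
})

test_that("applying any direction code twice is the identity", {
  d <- generate_synth(synth_config(n_pos = 5, n_neg = 5, k = 4), seed = 9)
  seg <- segment_window(d)
  for (code in direction_codes()) {
    twice <- apply_direction(apply_direction(seg, code), code)
    expect_equal(twice[, c("left", "right", "full")],
                 seg[, c("left", "right", "full")],
                 info = code)
  }
})

test_that("windows export as a four-column TSV", {
  d <- generate_synth(synth_config(n_pos = 3, n_neg = 3, k = 3), seed = 1)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_windows(d, path)
  back <- utils::read.delim(path, stringsAsFactors = FALSE)
  expect_equal(names(back), c("protein_id", "position", "window", "label"))
  expect_equal(back$window, d$window)
})
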