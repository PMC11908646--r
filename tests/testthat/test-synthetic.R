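test_that("generated windows satisfy the window invariants", {
  cfg <- synth_config(n_pos = 30, n_neg = 60, k = 7)
  d <- generate_synth(cfg, seed = 5)
  expect_equal(nrow(d), 90L)
  expect_true(all(nchar(d$window) == 15L))
  expect_true(all(substr(d$window, 8L, 8L) == "C"))
  expect_true(all(d$position == 8L))
  # regenerating with the same seed reproduces everything
  expect_identical(generate_synth(cfg, seed = 5), d)
  expect_false(identical(generate_synth(cfg, seed = 6)$window, d$window))
})

test_that("noise planting flips exactly the configured number of positives", {
  d0 <- generate_synth(synth_config(n_pos = 40, n_neg = 40, k = 5,
                                    noise_rate = 0), seed = 2)
  expect_false(any(d0$mislabeled))
  expect_equal(d0$label, d0$true_label)

  d <- generate_synth(synth_config(n_pos = 40, n_neg = 40, k = 5,
                                   noise_rate = 0.1), seed = 2)
  expect_equal(sum(d$mislabeled), round(0.1 * 40))
  expect_true(all(d$true_label[d$mislabeled] == 1L))
  expect_true(all(d$label[d$mislabeled] == 0L))
  # noise is only ever planted into the negative pool
  expect_true(all(d$label <= d$true_label))
})

test_that("the positive model's enrichment decays monotonically outward", {
  cfg <- synth_config(n_pos = 10, n_neg = 10, k = 6,
                      enrichment = c(A = 1.5), decay = 0.3)
  tab <- synth_prob_table(cfg)
  pa <- tab[, "A"]
  up <- pa[as.character(1:6)]
  expect_true(all(diff(up) < 0))
  dn <- pa[as.character(-(1:6))]
  expect_true(all(diff(dn) < 0))
  expect_equal(tab["0", "C"], 1)
  expect_equal(unname(rowSums(tab)), rep(1, 13))
})

test_that("zero enrichment makes positives compositionally like background", {
  d <- generate_synth(synth_config(n_pos = 800, n_neg = 800, k = 7,
                                   enrichment = c(A = 0, K = 0, R = 0, V = 0)),
                      seed = 7)
  flank <- function(w) paste0(substr(w, 1, 7), substr(w, 9, 15))
  count_of <- function(w) table(factor(strsplit(paste(flank(w), collapse = ""),
                                                "")[[1]],
                                levels = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]))
  tab <- rbind(count_of(d$window[d$true_label == 1]),
               count_of(d$window[d$true_label == 0]))
  p <- suppressWarnings(stats::chisq.test(tab))$p.value
  expect_gt(p, 0.001)
})

test_that("default enrichment lifts A/K/R/V near the center by the set log-odds", {
  boost <- 1
  cfg <- synth_config(n_pos = 10000, n_neg = 10000, k = 5,
                      enrichment = c(A = boost, K = boost, R = boost,
                                     V = boost), decay = 0.15)
  d <- generate_synth(cfg, seed = 13)
  pos_w <- d$window[d$true_label == 1]
  neg_w <- d$window[d$true_label == 0]
  freq_at <- function(w, offset) {
    ch <- substr(w, 6 + offset, 6 + offset)
    mean(ch %in% c("A", "K", "R", "V"))
  }
  for (offset in c(-2L, 1L, 3L)) {
    f_pos <- freq_at(pos_w, offset)
    f_neg <- freq_at(neg_w, offset)
    # expected positive-class frequency from the exact sampling table
    expected <- sum(synth_prob_table(cfg)[as.character(offset),
                                          c("A", "K", "R", "V")])
    expect_equal(f_pos, expected, tolerance = 0.05)
    expect_gt(f_pos, f_neg)
  }
})

test_that("synthetic sets round-trip through the FASTA + TSV interfaces", {
  d <- generate_synth(synth_config(n_pos = 5, n_neg = 5, k = 4), seed = 3)
  dir <- withr::local_tempdir()
  write_synth(d, dir)
  prot <- read_fasta(file.path(dir, "proteins.fasta"))
  sites <- read_site_table(file.path(dir, "sites.tsv"))
  rebuilt <- extract_windows(prot, sites, k = 4)
  expect_equal(rebuilt$window, d$window)
  expect_equal(rebuilt$label, d$label)
})
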