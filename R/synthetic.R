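#' Configuration for the synthetic planted-motif generator
#'
#' The generator emits Cys-centered windows mimicking the compositional
#' structure seen around real S-sulfhydration sites: selected residues
#' (by default alanine, lysine, arginine and valine) are enriched near the
#' central cysteine in positive windows, with the enrichment decaying
#' toward the window edges; negative windows are drawn from background
#' residue frequencies. A configurable fraction of positives is emitted
#' with label 0, emulating the experimentally unverifiable negative pool.
#'
#' @param n_pos,n_neg Numbers of positive-model and background windows.
#'   Defaults keep the roughly 1:6.2 positive:negative imbalance typical
#'   of curated S-sulfhydration data.
#' @param k Window radius (window length `2k + 1`).
#' @param enrichment Named numeric vector of log-odds boosts applied to
#'   the named residues at the positions nearest the center of positive
#'   windows.
#' @param decay Exponential decay rate of the enrichment with distance
#'   from the center (per residue position); must be positive.
#' @param noise_rate Fraction of positives relabeled as negatives
#'   (`label = 0` with the `mislabeled` flag set). In `[0, 1)`.
#' @param background Length-20 probability vector over the amino acids in
#'   [aa_vocab()] order, or `"uniform"`.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_pos = 500L, n_neg = 3100L, k = 15L,
                         enrichment = c(A = 2, K = 2, R = 2, V = 2),
                         decay = 0.15, noise_rate = 0,
                         background = "uniform") {
  stopifnot(n_pos >= 1L, n_neg >= 1L, k >= 1L, decay > 0,
            noise_rate >= 0, noise_rate < 1)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  if (identical(background, "uniform")) {
    background <- stats::setNames(rep(1 / 20, 20), aas)
  }
  stopifnot(length(background) == 20L, abs(sum(background) - 1) < 1e-8)
  if (!all(names(enrichment) %in% aas)) {
    stop("enrichment names must be amino-acid letters", call. = FALSE)
  }
  structure(list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
                 k = as.integer(k), enrichment = enrichment, decay = decay,
                 noise_rate = noise_rate, background = background),
            class = "synth_config")
}

#' Per-position residue probabilities of the positive model
#'
#' Returns the exact sampling distribution used for positive windows: a
#' `(2k + 1) x 20` matrix of residue probabilities per window position
#' (the center row is degenerate at `C`). At distance `d >= 1` from the
#' center, enriched residues receive a log-odds boost
#' `enrichment * exp(-decay * (d - 1))`, so the boost is maximal adjacent
#' to the cysteine and decays monotonically outward.
#'
#' @param config A [synth_config()].
#' @return Numeric matrix, rows = window positions `-k .. +k`,
#'   columns = amino acids; each row sums to 1.
#' @export
synth_prob_table <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  k <- config$k
  aas <- names(config$background)
  tab <- matrix(0, nrow = 2L * k + 1L, ncol = 20L,
                dimnames = list(as.character(-k:k), aas))
  logbg <- log(config$background)
  for (d in -k:k) {
    if (d == 0L) {
      tab[as.character(d), "C"] <- 1
      next
    }
    boost <- stats::setNames(rep(0, 20), aas)
    boost[names(config$enrichment)] <-
      config$enrichment * exp(-config$decay * (abs(d) - 1L))
    logits <- logbg + boost
    p <- exp(logits - max(logits))
    tab[as.character(d), ] <- p / sum(p)
  }
  tab
}

sample_residues <- function(n, probs, aas) {
  aas[sample.int(length(aas), n, replace = TRUE, prob = probs)]
}

#' Generate a synthetic labeled window set
#'
#' Draws `n_pos` windows from the enriched positional model and `n_neg`
#' from the background, all centered on `C`. Exactly
#' `round(noise_rate * n_pos)` positives are emitted with `label = 0`
#' (their `mislabeled` flag is `TRUE`), emulating true modification sites
#' hidden in the negative pool. Each window is reported as its own
#' protein, so the output is directly consumable by [segment_window()]
#' and friends, or writable with [write_synth()] in the formats
#' [read_fasta()] and [read_site_table()] read.
#'
#' @param config A [synth_config()].
#' @param seed Integer seed; generation is fully reproducible.
#' @return A tibble with columns `protein_id`, `position`, `window`,
#'   `label` (possibly noisy), `true_label`, and `mislabeled`; the config
#'   is attached as attribute `"config"`.
#' @examples
#' d <- generate_synth(synth_config(n_pos = 5, n_neg = 10, k = 3), seed = 1)
#' d$window
#' @export
generate_synth <- function(config, seed = 1L) {
  stopifnot(inherits(config, "synth_config"))
  local_seed(seed)
  k <- config$k
  L <- 2L * k + 1L
  aas <- names(config$background)
  tab <- synth_prob_table(config)

  draw_windows <- function(n, pos_model) {
    mat <- matrix("", nrow = n, ncol = L)
    for (j in seq_len(L)) {
      d <- j - k - 1L
      if (d == 0L) {
        mat[, j] <- "C"
      } else if (pos_model) {
        mat[, j] <- sample_residues(n, tab[as.character(d), ], aas)
      } else {
        mat[, j] <- sample_residues(n, config$background, aas)
      }
    }
    apply(mat, 1L, paste, collapse = "")
  }

  win_pos <- draw_windows(config$n_pos, TRUE)
  win_neg <- draw_windows(config$n_neg, FALSE)

  n_noise <- round(config$noise_rate * config$n_pos)
  noisy_idx <- if (n_noise > 0) sample.int(config$n_pos, n_noise) else integer(0)
  label_pos <- rep(1L, config$n_pos)
  label_pos[noisy_idx] <- 0L

  n <- config$n_pos + config$n_neg
  out <- tibble::tibble(
    protein_id = sprintf("synth%05d", seq_len(n)),
    position = rep(k + 1L, n),
    window = c(win_pos, win_neg),
    label = c(label_pos, rep(0L, config$n_neg)),
    true_label = c(rep(1L, config$n_pos), rep(0L, config$n_neg)),
    mislabeled = c(label_pos != 1L, rep(FALSE, config$n_neg))
  )
  attr(out, "config") <- config
  out
}

#' Write a synthetic window set as FASTA + site table + truth table
#'
#' Produces `proteins.fasta` and `sites.tsv` in exactly the formats
#' [read_fasta()] and [read_site_table()] consume, plus `truth.tsv`
#' holding the noise indicator for evaluating the confident-learning
#' filter.
#'
#' @param data Output of [generate_synth()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_synth <- function(data, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_fasta(tibble::tibble(id = data$protein_id, sequence = data$window),
              file.path(dir, "proteins.fasta"))
  write_site_table(data, file.path(dir, "sites.tsv"))
  utils::write.table(
    data[, c("protein_id", "true_label", "mislabeled")],
    file.path(dir, "truth.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
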