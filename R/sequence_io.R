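#' Read protein sequences from a FASTA file
#'
#' Sequences are upper-cased and trailing/internal `*` stop symbols are
#' stripped. Every sequence must be non-empty and drawn from the 20
#' amino-acid letters plus `X` (unknown).
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id` (first whitespace-delimited word of
#'   the header) and `sequence`.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1", "MCKA"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("malformed FASTA file '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(set) == 0L) {
    return(tibble::tibble(id = character(0), sequence = character(0)))
  }
  ids <- vapply(strsplit(names(set), "\\s+"), `[[`, character(1), 1L)
  seqs <- toupper(gsub("\\*", "", as.character(set)))
  empty <- !nzchar(seqs)
  if (any(empty)) {
    stop("empty sequence for FASTA record(s): ",
         paste(ids[empty], collapse = ", "), call. = FALSE)
  }
  bad <- grepl("[^ACDEFGHIKLMNPQRSTVWYX]", seqs)
  if (any(bad)) {
    stop("non amino-acid characters in record(s): ",
         paste(ids[bad], collapse = ", "), call. = FALSE)
  }
  tibble::tibble(id = unname(ids), sequence = unname(seqs))
}

#' Write protein sequences to a FASTA file
#'
#' @param proteins Tibble with columns `id` and `sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path) {
  lines <- as.vector(rbind(paste0(">", proteins$id), proteins$sequence))
  writeLines(lines, path)
  invisible(path)
}

#' Read a site-annotation table
#'
#' Site tables are tab-separated with header columns `protein_id`,
#' `position` (1-based cysteine position) and `label` (1 = S-sulfhydration,
#' 0 = nonsulfhydration).
#'
#' @param path Path to a TSV file.
#' @return A tibble with columns `protein_id` (character), `position`
#'   (integer) and `label` (integer).
#' @export
read_site_table <- function(path) {
  stopifnot(file.exists(path))
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "position", "label")
  if (!all(need %in% names(df))) {
    stop("site table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (!all(df$label %in% c(0L, 1L))) {
    stop("site labels must be 0 or 1", call. = FALSE)
  }
  tibble::tibble(protein_id = as.character(df$protein_id),
                 position = as.integer(df$position),
                 label = as.integer(df$label))
}

#' @rdname read_site_table
#' @param sites Tibble with columns `protein_id`, `position`, `label`.
#' @export
write_site_table <- function(sites, path) {
  utils::write.table(sites[, c("protein_id", "position", "label")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Extract Cys-centered windows around annotated sites
#'
#' For every annotated site, extracts the residues at positions
#' `-k .. +k` around the central cysteine (default `k = 15`, the
#' 31-residue window). Positions falling outside the protein are filled
#' with the pad symbol `-`, so every window has length `2k + 1`.
#'
#' @param proteins Tibble with columns `id`, `sequence` (see [read_fasta()]).
#' @param sites Tibble with columns `protein_id`, `position` (1-based),
#'   `label`.
#' @param k Window radius; the window length is `2k + 1`.
#' @return A tibble with columns `protein_id`, `position`, `window`,
#'   `label`, one row per site in site-table order.
#' @examples
#' prot <- tibble::tibble(id = "p1", sequence = "ACDEFG")
#' sites <- tibble::tibble(protein_id = "p1", position = 2L, label = 1L)
#' extract_windows(prot, sites, k = 3)
#' @export
extract_windows <- function(proteins, sites, k = 15L) {
  stopifnot(k >= 1L)
  k <- as.integer(k)
  seq_of <- stats::setNames(proteins$sequence, proteins$id)
  missing <- setdiff(unique(sites$protein_id), names(seq_of))
  if (length(missing) > 0L) {
    stop("site table references unknown protein(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  windows <- character(nrow(sites))
  for (i in seq_len(nrow(sites))) {
    s <- seq_of[[sites$protein_id[i]]]
    pos <- sites$position[i]
    n <- nchar(s)
    if (pos < 1L || pos > n) {
      stop("site position ", pos, " out of range for protein '",
           sites$protein_id[i], "' (length ", n, ")", call. = FALSE)
    }
    if (substr(s, pos, pos) != "C") {
      stop("site position ", pos, " in protein '", sites$protein_id[i],
           "' is '", substr(s, pos, pos), "', not a cysteine", call. = FALSE)
    }
    lo <- pos - k
    hi <- pos + k
    core <- substr(s, max(lo, 1L), min(hi, n))
    pre <- strrep("-", max(0L, 1L - lo))
    suf <- strrep("-", max(0L, hi - n))
    windows[i] <- paste0(pre, core, suf)
  }
  tibble::tibble(protein_id = sites$protein_id,
                 position = sites$position,
                 window = windows,
                 label = sites$label)
}

#' Split a window into left, right and full parts
#'
#' Both halves include the central cysteine: the left part covers positions
#' `-k .. 0` and the right part positions `0 .. +k` (each of length
#' `k + 1`), so the modified residue anchors every branch;
#' `left + right[-1]` reconstructs the full window.
#'
#' @param windows Tibble with a `window` column (see [extract_windows()]),
#'   or a character vector of windows.
#' @return The input tibble with added character columns `left`, `right`
#'   and `full` (a character-input call returns a tibble with just those
#'   columns).
#' @examples
#' segment_window("ABCDE")  # k = 2: left "ABC", right "CDE"
#' @export
segment_window <- function(windows) {
  if (is.character(windows)) {
    windows <- tibble::tibble(window = windows)
  }
  w <- windows$window
  len <- nchar(w)
  if (length(unique(len)) > 1L) {
    stop("all windows must share one length", call. = FALSE)
  }
  L <- len[1]
  if (L %% 2L == 0L) stop("window length must be odd (2k + 1)", call. = FALSE)
  k <- (L - 1L) %/% 2L
  centers <- substr(w, k + 1L, k + 1L)
  if (!all(centers == "C")) {
    stop("window center must be a cysteine", call. = FALSE)
  }
  dplyr::mutate(windows,
                left = substr(.data$window, 1L, k + 1L),
                right = substr(.data$window, k + 1L, L),
                full = .data$window)
}

#' The eight reading-orientation codes
#'
#' A direction code is a 3-letter string over `{L, R}` giving the reading
#' orientation of the left half, the right half, and the full window:
#' `L` reads a part as-is (left to right) and `R` reverses it. `RLL`
#' (left half read right-to-left, i.e. outward-in toward the cysteine) is
#' the default orientation used by the classifier.
#'
#' @return Character vector of the 8 valid codes.
#' @export
direction_codes <- function() {
  c("LLL", "LRL", "LLR", "LRR", "RRR", "RLR", "RRL", "RLL")
}

assert_direction_code <- function(code) {
  if (!(is.character(code) && length(code) == 1L &&
        grepl("^[LR]{3}$", code))) {
    stop("direction code must be 3 characters over {L, R}, got: ",
         paste(format(code), collapse = ","), call. = FALSE)
  }
  invisible(code)
}

str_rev <- function(x) {
  vapply(strsplit(x, ""), function(ch) paste(rev(ch), collapse = ""),
         character(1))
}

#' Apply a direction code to segmented windows
#'
#' For each of the three parts (`left`, `right`, `full`), the
#' corresponding letter of the code leaves the string as-is (`L`) or
#' reverses it (`R`). Applying `R` twice restores the original, so the
#' operation is an involution per part.
#'
#' @param segments Tibble with columns `left`, `right`, `full`
#'   (see [segment_window()]).
#' @param code A 3-character direction code; see [direction_codes()].
#' @return The tibble with the three part columns oriented and a `code`
#'   column recording the applied code.
#' @examples
#' seg <- segment_window("ABCDE")
#' apply_direction(seg, "RLL")
#' @export
apply_direction <- function(segments, code = "RLL") {
  assert_direction_code(code)
  stopifnot(all(c("left", "right", "full") %in% names(segments)))
  letters3 <- strsplit(code, "")[[1]]
  parts <- c("left", "right", "full")
  out <- segments
  for (j in 1:3) {
    if (letters3[j] == "R") out[[parts[j]]] <- str_rev(out[[parts[j]]])
  }
  out$code <- code
  out
}

#' Write extracted windows as TSV
#'
#' @param windows Tibble with columns `protein_id`, `position`, `window`,
#'   `label`.
#' @param path Output path.
#' @export
write_windows <- function(windows, path) {
  utils::write.table(windows[, c("protein_id", "position", "window", "label")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
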