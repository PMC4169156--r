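# Predicted binding-specificity change between reference and variant
# fingers: position frequency matrices and the summed Kullback-Leibler
# distance.

#' Read a position frequency matrix
#'
#' Accepts either a TSV with four labelled rows (A, C, G, T; optional
#' header of position names) or JASPAR-style text (optional `>` header
#' line, rows like `A [ 12 0 3 ]`). Counts are normalized to per-column
#' frequencies.
#'
#' @param path file path.
#' @return numeric matrix, rows A/C/G/T, columns positions, every column
#'   summing to 1.
#' @export
read_pfm <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, ">") & !startsWith(lines, "#")]
  if (length(lines) == 0L) abort(sprintf("empty PFM file: %s", path))
  rows <- list()
  for (ln in lines) {
    ln <- gsub("\\[|\\]", " ", ln)
    toks <- strsplit(ln, "[\t ]+")[[1]]
    toks <- toks[nzchar(toks)]
    base <- toupper(toks[1])
    if (!base %in% c("A", "C", "G", "T")) next  # e.g. a header of position names
    vals <- suppressWarnings(as.numeric(toks[-1]))
    if (any(is.na(vals))) abort(sprintf("non-numeric PFM entries in row %s: %s", base, path))
    rows[[base]] <- vals
  }
  missing_rows <- setdiff(c("A", "C", "G", "T"), names(rows))
  if (length(missing_rows)) {
    abort(sprintf("PFM %s is missing base row(s): %s", path,
                  paste(missing_rows, collapse = ", ")))
  }
  widths <- lengths(rows)
  if (length(unique(widths)) != 1L) abort(sprintf("ragged PFM rows in %s", path))
  m <- rbind(A = rows$A, C = rows$C, G = rows$G, T = rows$T)
  as_pfm(m, where = path)
}

#' Validate and column-normalize a PFM matrix
#'
#' @param m 4-row numeric matrix (rows A/C/G/T in order, or named).
#' @param where label used in error messages.
#' @return normalized matrix with rows A/C/G/T.
#' @export
as_pfm <- function(m, where = "PFM") {
  if (!is.matrix(m) || nrow(m) != 4L) abort(sprintf("%s must be a 4-row matrix", where))
  if (!is.null(rownames(m))) m <- m[c("A", "C", "G", "T"), , drop = FALSE]
  rownames(m) <- c("A", "C", "G", "T")
  if (any(m < 0)) abort(sprintf("negative entry in %s", where))
  cs <- colSums(m)
  if (any(cs == 0)) abort(sprintf("all-zero column in %s", where))
  sweep(m, 2L, cs, "/")
}

#' Kullback-Leibler distance between two PFMs
#'
#' Computes `D(R||S) = sum_i R_i * ln(R_i / S_i)` over every cell of the
#' matrices (natural log, all columns summed). Because observed PFMs
#' contain zeros, a global pseudocount is added to every cell of both
#' matrices and columns are renormalized before the divergence is taken.
#'
#' @param r,s PFM matrices (or file paths), equal width, columns compared
#'   in the given order.
#' @param pseudocount value added to every cell, default `1e-6`.
#' @return the forward divergence, a non-negative scalar.
#' @export
kl_distance <- function(r, s, pseudocount = 1e-6) {
  r <- .pfm_arg(r)
  s <- .pfm_arg(s)
  if (ncol(r) != ncol(s)) abort("PFM width mismatch")
  if (pseudocount <= 0) abort("pseudocount must be positive")
  r <- as_pfm(r + pseudocount)
  s <- as_pfm(s + pseudocount)
  sum(r * log(r / s))
}

.pfm_arg <- function(x) {
  if (is.character(x) && length(x) == 1L) return(read_pfm(x))
  as_pfm(x)
}

#' Summed Kullback-Leibler distance between reference and variant PFMs
#'
#' The forward divergence D(R||S) and its reciprocal D(S||R) are added to
#' give a symmetric measure of predicted binding-specificity change; a
#' summed distance above the threshold (default 2.5) marks a dramatic
#' specificity shift.
#'
#' @inheritParams kl_distance
#' @param threshold dramatic-shift cutoff on the summed distance.
#' @return one-row tibble: `forward`, `reverse`, `summed`, `is_dramatic`,
#'   `pseudocount`.
#' @export
summed_kl <- function(r, s, pseudocount = 1e-6, threshold = 2.5) {
  fwd <- kl_distance(r, s, pseudocount)
  rev <- kl_distance(s, r, pseudocount)
  tibble(
    forward = fwd,
    reverse = rev,
    summed = fwd + rev,
    is_dramatic = classify_shift(fwd + rev, threshold),
    pseudocount = pseudocount
  )
}

#' Classify a summed KL distance as a dramatic specificity shift
#'
#' @param summed numeric vector of summed KL distances.
#' @param threshold cutoff, default 2.5; the comparison is strict
#'   (`summed > threshold`).
#' @return logical vector (NA propagates, mirroring fingers for which no
#'   PFM prediction exists).
#' @export
classify_shift <- function(summed, threshold = 2.5) {
  if (threshold < 0) abort("threshold must be non-negative")
  summed > threshold
}

#' Summed KL distances for a manifest of PFM pairs
#'
#' @param manifest tibble with `pair_id`, `ref_path`, `snp_path` and
#'   optionally `maf` (paths may instead be list-columns of matrices named
#'   `ref`, `snp`). Pairs with a missing/unreadable PFM yield NA distances
#'   with a warning, mirroring predictor failures on real fingers.
#' @inheritParams summed_kl
#' @return tibble: `pair_id`, `forward`, `reverse`, `summed`,
#'   `is_dramatic`, and `maf` when present.
#' @export
kl_pairs <- function(manifest, pseudocount = 1e-6, threshold = 2.5) {
  get_one <- function(i) {
    pull_m <- function(col_m, col_p) {
      if (col_m %in% names(manifest)) return(manifest[[col_m]][[i]])
      p <- manifest[[col_p]][i]
      if (is.na(p) || !file.exists(p)) return(NULL)
      read_pfm(p)
    }
    r <- pull_m("ref", "ref_path")
    s <- pull_m("snp", "snp_path")
    if (is.null(r) || is.null(s)) {
      warn(sprintf("PFM missing for pair %s; distances set to NA", manifest$pair_id[i]))
      return(tibble(forward = NA_real_, reverse = NA_real_, summed = NA_real_,
                    is_dramatic = NA, pseudocount = pseudocount))
    }
    summed_kl(r, s, pseudocount, threshold)
  }
  res <- purrr::map(seq_len(nrow(manifest)), get_one) %>% bind_rows()
  out <- bind_cols(manifest["pair_id"], res %>% select(-"pseudocount"))
  if ("maf" %in% names(manifest)) out$maf <- manifest$maf
  out
}
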