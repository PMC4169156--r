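# C2H2 zinc finger detection: pattern matcher, helix position map,
# TGEKP linker scoring and array assembly.

.check_protein <- function(sequence) {
  if (is.na(sequence) || !is.character(sequence)) {
    abort("protein sequence must be a character string")
  }
  if (nchar(sequence) > 0L && grepl("[^A-Z]", sequence)) {
    abort("protein sequence contains non-amino-acid characters (uppercase letters only, X allowed)")
  }
  invisible(sequence)
}

# All candidate gap triples at a fixed start, shortest total span first,
# then lexicographically smallest gaps.
.finger_at <- function(chars, i, c_gap, ch_gap, h_gap) {
  n <- length(chars)
  best <- NULL
  for (g1 in seq(c_gap[1], c_gap[2])) {
    cys2 <- i + g1 + 1L
    if (cys2 > n || chars[cys2] != "C") next
    for (g2 in seq(ch_gap[1], ch_gap[2])) {
      his1 <- cys2 + g2 + 1L
      if (his1 > n || chars[his1] != "H") next
      for (g3 in seq(h_gap[1], h_gap[2])) {
        his2 <- his1 + g3 + 1L
        if (his2 > n || chars[his2] != "H") next
        cand <- c(cys1 = i, cys2 = cys2, his1 = his1, his2 = his2)
        if (is.null(best) ||
            (his2 - i) < (best["his2"] - best["cys1"]) ||
            ((his2 - i) == (best["his2"] - best["cys1"]) &&
             (cys2 < best["cys2"] || (cys2 == best["cys2"] && his1 < best["his1"])))) {
          best <- cand
        }
      }
    }
  }
  best
}

#' Find C2H2 zinc finger repeats in a protein sequence
#'
#' Matches the canonical C2H2 pattern `C-x(2,4)-C-x(11,14)-H-x(3,5)-H`
#' left to right. Matches are non-overlapping and greedy: the leftmost
#' possible start wins, and at a given start the candidate with the
#' shortest total span is taken (ties broken by the smallest gaps, in
#' order). `X` and other ambiguity codes never match the conserved
#' cysteines/histidines.
#'
#' @param sequence protein sequence (uppercase single-letter amino acids).
#' @param protein_id identifier copied into the output.
#' @param c_gap,ch_gap,h_gap integer length-2 vectors giving the allowed
#'   number of residues between Cys1-Cys2, Cys2-His1 and His1-His2.
#' @return a tibble with one row per finger: `protein_id`, `finger`
#'   (1-based index along the protein), `start`, `end` (1-based inclusive,
#'   from the first Cys to the second His), and the conserved-residue
#'   positions `cys1_pos`, `cys2_pos`, `his1_pos`, `his2_pos`.
#' @examples
#' find_fingers("YACPVESCDRRFSRSDELTRHIRIHT")
#' @export
find_fingers <- function(sequence, protein_id = NA_character_,
                         c_gap = c(2L, 4L), ch_gap = c(11L, 14L),
                         h_gap = c(3L, 5L)) {
  .check_protein(sequence)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(chars)
  hits <- list()
  i <- 1L
  while (i <= n) {
    if (chars[i] == "C") {
      m <- .finger_at(chars, i, c_gap, ch_gap, h_gap)
      if (!is.null(m)) {
        hits[[length(hits) + 1L]] <- m
        i <- m[["his2"]] + 1L
        next
      }
    }
    i <- i + 1L
  }
  if (length(hits) == 0L) {
    return(tibble(protein_id = character(), finger = integer(),
                  start = integer(), end = integer(),
                  cys1_pos = integer(), cys2_pos = integer(),
                  his1_pos = integer(), his2_pos = integer()))
  }
  m <- do.call(rbind, hits)
  tibble(
    protein_id = protein_id,
    finger = seq_len(nrow(m)),
    start = as.integer(m[, "cys1"]),
    end = as.integer(m[, "his2"]),
    cys1_pos = as.integer(m[, "cys1"]),
    cys2_pos = as.integer(m[, "cys2"]),
    his1_pos = as.integer(m[, "his1"]),
    his2_pos = as.integer(m[, "his2"])
  )
}

#' Scan a set of proteins for zinc fingers
#'
#' @param seqs named character vector of protein sequences, or the path of
#'   a FASTA file.
#' @inheritParams find_fingers
#' @return tibble of fingers across all proteins (see [find_fingers()]).
#' @export
scan_fingers <- function(seqs, c_gap = c(2L, 4L), ch_gap = c(11L, 14L),
                         h_gap = c(3L, 5L)) {
  seqs <- .as_protein_set(seqs)
  purrr::imap(seqs, function(s, id) {
    find_fingers(s, protein_id = id, c_gap = c_gap, ch_gap = ch_gap, h_gap = h_gap)
  }) %>% bind_rows()
}

.as_protein_set <- function(seqs) {
  if (is.character(seqs) && length(seqs) == 1L && file.exists(seqs)) {
    x <- Biostrings::readAAStringSet(seqs)
    seqs <- setNames(as.character(x), sub("\\s.*$", "", names(x)))
  }
  if (is.null(names(seqs)) || any(names(seqs) == "")) {
    abort("protein sequences must be named (or given as a FASTA path)")
  }
  seqs
}

#' Map recognition-helix positions of detected fingers
#'
#' Position numbering starts at the first residue of the recognition
#' alpha-helix, anchored to the first conserved histidine: position 1 is
#' `his1_pos - 6`, so -2, -1, 1, 2, 3, 5, 6 sit at offsets -8, -7, -6,
#' -5, -4, -2, -1 from his1. C2 (beta-turn) is the residue two after the
#' first conserved cysteine. Positions -1, 2, 3 and 6 contact DNA bases;
#' C2, -2, 1 and 5 face away from the DNA.
#'
#' @param fingers tibble as returned by [find_fingers()]/[scan_fingers()].
#' @param seqs named character vector of protein sequences (or FASTA path);
#'   may also be a single unnamed sequence when `fingers` covers one protein.
#' @return long tibble: `protein_id`, `finger`, `label`, `pos` (1-based
#'   residue index), `aa`, `class` (contacting/non_contacting).
#' @export
helix_position_map <- function(fingers, seqs) {
  if (nrow(fingers) == 0L) {
    return(tibble(protein_id = character(), finger = integer(),
                  label = character(), pos = integer(),
                  aa = character(), class = character()))
  }
  if (is.character(seqs) && length(seqs) == 1L && is.null(names(seqs)) &&
      !file.exists(seqs)) {
    ids <- unique(fingers$protein_id)
    if (length(ids) != 1L) abort("a single unnamed sequence needs a single protein_id")
    seqs <- setNames(seqs, ids)
  }
  seqs <- .as_protein_set(seqs)
  out <- purrr::pmap(fingers, function(protein_id, finger, start, end,
                                       cys1_pos, cys2_pos, his1_pos, his2_pos, ...) {
    pos <- c(cys1_pos + 2L, his1_pos + .helix_offsets)
    labels <- c("C2", names(.helix_offsets))
    if (pos[1] >= cys2_pos) {
      abort(sprintf("malformed finger %s/%d: C2 position not before the second Cys",
                    protein_id, finger))
    }
    if (any(pos[-1] <= cys2_pos)) {
      abort(sprintf("malformed finger %s/%d: helix positions overlap the Cys loop",
                    protein_id, finger))
    }
    seq <- seqs[[protein_id]]
    tibble(protein_id = protein_id, finger = finger, label = labels,
           pos = as.integer(pos),
           aa = substring(seq, pos, pos),
           class = position_class(labels))
  })
  bind_rows(out)
}

.tgekp <- c("T", "G", "E", "K", "P")

#' Identity of a linker to the canonical TGEKP motif
#'
#' Best number of exact matches over all alignments of the 5-residue
#' TGEKP motif against the linker (for linkers shorter than 5 the motif
#' slides so that the whole linker is compared against each in-frame
#' 5-mer window of TGEKP).
#'
#' @param linker character vector of linker sequences.
#' @return integer vector, 0--5.
#' @export
tgekp_identity <- function(linker) {
  vapply(linker, function(lk) {
    if (is.na(lk) || nchar(lk) == 0L) return(0L)
    ch <- strsplit(lk, "", fixed = TRUE)[[1]]
    len <- length(ch)
    if (len >= 5L) {
      best <- 0L
      for (s in seq_len(len - 4L)) {
        best <- max(best, sum(ch[s:(s + 4L)] == .tgekp))
      }
    } else {
      best <- 0L
      for (o in 0:(5L - len)) {
        best <- max(best, sum(ch == .tgekp[(1L + o):(len + o)]))
      }
    }
    as.integer(best)
  }, integer(1), USE.NAMES = FALSE)
}

#' Score inter-finger linkers for TGEKP-likeness
#'
#' The linker is the stretch of residues strictly between the second
#' conserved His of one finger and the first conserved Cys of the next.
#' A linker is TGEKP-like when its best TGEKP identity reaches
#' `min_identity` and its length falls within `len_range` (the canonical
#' linker TGEKP has length 5).
#'
#' @param fingers tibble of fingers for one or more proteins.
#' @param seqs named character vector of sequences or FASTA path.
#' @param min_identity minimum matches to TGEKP (default 3 of 5).
#' @param len_range allowed linker length range (default 4--8).
#' @return tibble: `protein_id`, `finger_left`, `finger_right`,
#'   `sequence`, `length`, `identity_to_TGEKP`, `is_tgekp_like`.
#' @export
score_linkers <- function(fingers, seqs, min_identity = 3L, len_range = c(4L, 8L)) {
  empty <- tibble(protein_id = character(), finger_left = integer(),
                  finger_right = integer(), sequence = character(),
                  length = integer(), identity_to_TGEKP = integer(),
                  is_tgekp_like = logical())
  if (nrow(fingers) < 2L) return(empty)
  seqs <- .as_protein_set(seqs)
  out <- fingers %>%
    arrange(.data$protein_id, .data$start) %>%
    group_by(.data$protein_id) %>%
    filter(n() >= 2L) %>%
    dplyr::reframe(
      finger_left = .data$finger[-n()],
      finger_right = .data$finger[-1L],
      from = .data$his2_pos[-n()] + 1L,
      to = .data$cys1_pos[-1L] - 1L
    )
  if (nrow(out) == 0L) return(empty)
  if (any(out$to < out$from - 1L)) abort("overlapping fingers: linker has negative length")
  out %>%
    mutate(
      sequence = unname(substring(seqs[.data$protein_id], .data$from, .data$to)),
      length = nchar(.data$sequence),
      identity_to_TGEKP = tgekp_identity(.data$sequence),
      is_tgekp_like = .data$identity_to_TGEKP >= min_identity &
        .data$length >= len_range[1] & .data$length <= len_range[2]
    ) %>%
    select(-"from", -"to")
}

#' Assemble finger arrays joined by TGEKP-like linkers
#'
#' A finger array is a maximal run of consecutive fingers in which every
#' adjacent pair is joined by a TGEKP-like linker; runs of at least
#' `min_fingers` (default 3) are reported. Arrays of three or more
#' TGEKP-linked fingers are the best available predictor that the array
#' binds DNA.
#'
#' @inheritParams score_linkers
#' @param min_fingers minimum fingers per array.
#' @return tibble: `protein_id`, `array_id`, `n_fingers`, `finger_first`,
#'   `finger_last`, `start`, `end`.
#' @export
assemble_arrays <- function(fingers, seqs, min_fingers = 3L,
                            min_identity = 3L, len_range = c(4L, 8L)) {
  empty <- tibble(protein_id = character(), array_id = character(),
                  n_fingers = integer(), finger_first = integer(),
                  finger_last = integer(), start = integer(), end = integer())
  if (nrow(fingers) == 0L) return(empty)
  linkers <- score_linkers(fingers, seqs, min_identity = min_identity,
                           len_range = len_range)
  out <- list()
  for (pid in unique(fingers$protein_id)) {
    ff <- fingers %>% filter(.data$protein_id == pid) %>% arrange(.data$start)
    if (nrow(ff) < min_fingers) next
    lk <- linkers %>% filter(.data$protein_id == pid) %>% arrange(.data$finger_left)
    pass <- lk$is_tgekp_like
    # run decomposition over the pass/fail chain of adjacent linkers
    run_start <- 1L
    k <- 0L
    for (j in seq_len(nrow(ff))) {
      run_ends <- j == nrow(ff) || !pass[j]
      if (run_ends) {
        run_len <- j - run_start + 1L
        if (run_len >= min_fingers) {
          k <- k + 1L
          out[[length(out) + 1L]] <- tibble(
            protein_id = pid,
            array_id = sprintf("%s.arr%d", pid, k),
            n_fingers = run_len,
            finger_first = ff$finger[run_start],
            finger_last = ff$finger[j],
            start = ff$start[run_start],
            end = ff$end[j]
          )
        }
        run_start <- j + 1L
      }
    }
  }
  if (length(out) == 0L) return(empty)
  bind_rows(out)
}

#' Scan a proteome end to end
#'
#' Convenience wrapper running [scan_fingers()], [helix_position_map()],
#' [score_linkers()] and [assemble_arrays()] on one FASTA or sequence set.
#'
#' @inheritParams assemble_arrays
#' @return list of tibbles: `fingers`, `helix`, `linkers`, `arrays`.
#' @export
scan_proteome <- function(seqs, min_fingers = 3L, min_identity = 3L,
                          len_range = c(4L, 8L)) {
  seqs <- .as_protein_set(seqs)
  fingers <- scan_fingers(seqs)
  list(
    fingers = fingers,
    helix = helix_position_map(fingers, seqs),
    linkers = score_linkers(fingers, seqs, min_identity, len_range),
    arrays = assemble_arrays(fingers, seqs, min_fingers, min_identity, len_range)
  )
}
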