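# Synthetic-data generators with planted ground truth. These stand in
# for the external resources a real analysis would use (a proteome, a
# genotyped cohort with a population panel, a variant table, predictor
# score tables and PFM predictions) so the whole pipeline can be
# validated against known truth.

.aa_no_ch <- setdiff(.aa20, c("C", "H"))

#' Simulation configuration
#'
#' Bundles every parameter of the synthetic cohort. The same
#' configuration (including seed) always reproduces byte-identical
#' outputs.
#'
#' @param seed integer RNG seed.
#' @param n_proteins total proteins emitted (planted + shuffled decoys).
#' @param n_planted_arrays proteins carrying a planted finger array.
#' @param fingers_per_array fingers per planted array (>= 3).
#' @param n_variants variants in the simulated variant table.
#' @param maf_spectrum optional numeric vector of allele frequencies in
#'   (0, 0.5] sampled for variant MAFs. Default (NULL) draws a 50/50
#'   mixture of rare Uniform(0.001, 0.01) and common Uniform(0.01, 0.5)
#'   frequencies so the 1% threshold partitions non-trivially.
#' @param n_individuals diploid individuals per population.
#' @param populations character vector of population labels.
#' @param inbreeding_f inbreeding coefficient used for simulated
#'   genotypes: a scalar for every SNP or a vector per SNP. Positive f
#'   depletes heterozygotes (negative D); f = 0 is HWE.
#' @param deleterious_fraction fraction of variants planted as
#'   deleterious per prediction method (scalar, or named per-method).
#' @param pfm_divergence column-mixing weight for variant PFMs (>= 0;
#'   values above 1 are treated as 1 = full replacement).
#' @param n_pfm_pairs number of reference/variant PFM pairs generated.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L, n_proteins = 200L, n_planted_arrays = 60L,
                       fingers_per_array = 4L, n_variants = 300L,
                       maf_spectrum = NULL, n_individuals = 100L,
                       populations = paste0("POP", 1:4), inbreeding_f = 0,
                       deleterious_fraction = 0.25, pfm_divergence = 0.3,
                       n_pfm_pairs = 40L) {
  if (fingers_per_array < 3L) abort("fingers_per_array must be >= 3")
  if (n_planted_arrays > n_proteins) abort("more planted arrays than proteins")
  if (!is.null(maf_spectrum) &&
      (any(maf_spectrum <= 0) || any(maf_spectrum > 0.5))) {
    abort("maf_spectrum values must lie in (0, 0.5]")
  }
  if (any(inbreeding_f < -1 | inbreeding_f > 1)) abort("inbreeding_f must lie in [-1, 1]")
  if (deleterious_fraction < 0 || deleterious_fraction > 1) {
    abort("deleterious_fraction must lie in [0, 1]")
  }
  if (pfm_divergence < 0) abort("pfm_divergence must be >= 0")
  structure(list(
    seed = as.integer(seed), n_proteins = as.integer(n_proteins),
    n_planted_arrays = as.integer(n_planted_arrays),
    fingers_per_array = as.integer(fingers_per_array),
    n_variants = as.integer(n_variants), maf_spectrum = maf_spectrum,
    n_individuals = as.integer(n_individuals), populations = populations,
    inbreeding_f = inbreeding_f, deleterious_fraction = deleterious_fraction,
    pfm_divergence = pfm_divergence, n_pfm_pairs = as.integer(n_pfm_pairs)
  ), class = "sim_config")
}

.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed %% .Machine$integer.max)
  force(code)
}

# One canonical C2H2 finger with randomized gaps and non-C/H filler so
# the planted boundaries are the unique pattern match.
.gen_finger <- function() {
  g1 <- sample(2:4, 1L)
  g3 <- sample(3:5, 1L)
  mid <- sample(.aa_no_ch, 12L, replace = TRUE)  # 12 residues between Cys2 and His1
  chars <- c("C", sample(.aa_no_ch, g1, replace = TRUE), "C", mid,
             "H", sample(.aa_no_ch, g3, replace = TRUE), "H")
  cys2 <- 1L + g1 + 1L
  his1 <- cys2 + 13L
  list(chars = chars, cys1 = 1L, cys2 = cys2, his1 = his1,
       his2 = his1 + g3 + 1L)
}

#' Generate a synthetic proteome with planted finger arrays
#'
#' Emits `n_proteins` sequences: `n_planted_arrays` of them carry an
#' array of `fingers_per_array` canonical C2H2 repeats joined by exact
#' TGEKP linkers; the remainder are residue-shuffled copies of planted
#' sequences (or random sequences when nothing is planted), which
#' destroys the motifs while preserving length and composition.
#'
#' @param cfg a [sim_config()].
#' @return list with `seqs` (named character vector), and `truth`
#'   (list of tibbles `arrays`, `fingers`, `helix` giving the planted
#'   coordinates and helix-position residues).
#' @export
gen_proteome <- function(cfg) {
  .with_seed(cfg$seed + 11L, {
    n_planted <- cfg$n_planted_arrays
    seqs <- character(0)
    fingers_truth <- list()
    arrays_truth <- list()
    for (i in seq_len(n_planted)) {
      pid <- sprintf("ZNFP%03d", i)
      nflank <- sample(15:30, 1L)
      chars <- sample(.aa_no_ch, nflank, replace = TRUE)
      ftab <- list()
      for (k in seq_len(cfg$fingers_per_array)) {
        fg <- .gen_finger()
        off <- length(chars)
        ftab[[k]] <- tibble(
          protein_id = pid, finger = k,
          start = off + fg$cys1, end = off + fg$his2,
          cys1_pos = off + fg$cys1, cys2_pos = off + fg$cys2,
          his1_pos = off + fg$his1, his2_pos = off + fg$his2
        )
        chars <- c(chars, fg$chars)
        if (k < cfg$fingers_per_array) chars <- c(chars, c("T", "G", "E", "K", "P"))
      }
      cflank <- sample(15:30, 1L)
      chars <- c(chars, sample(.aa_no_ch, cflank, replace = TRUE))
      seqs[pid] <- paste(chars, collapse = "")
      ftab <- bind_rows(ftab)
      fingers_truth[[pid]] <- ftab
      arrays_truth[[pid]] <- tibble(
        protein_id = pid, array_id = paste0(pid, ".arr1"),
        n_fingers = cfg$fingers_per_array,
        finger_first = 1L, finger_last = cfg$fingers_per_array,
        start = ftab$start[1], end = ftab$end[nrow(ftab)]
      )
    }
    n_decoys <- cfg$n_proteins - n_planted
    for (i in seq_len(n_decoys)) {
      pid <- sprintf("DECOY%03d", i)
      if (n_planted > 0L) {
        src <- seqs[[sample(n_planted, 1L)]]
        ch <- sample(strsplit(src, "", fixed = TRUE)[[1]])
      } else {
        ch <- sample(.aa20, sample(80:200, 1L), replace = TRUE)
      }
      seqs[pid] <- paste(ch, collapse = "")
    }
    fingers <- bind_rows(fingers_truth)
    helix <- if (nrow(fingers) > 0L) helix_position_map(fingers, seqs) else
      tibble(protein_id = character(), finger = integer(), label = character(),
             pos = integer(), aa = character(), class = character())
    list(seqs = seqs,
         truth = list(arrays = bind_rows(arrays_truth), fingers = fingers,
                      helix = helix))
  })
}

#' Simulate diploid genotypes for one SNP
#'
#' Draws genotypes independently with
#' `P(het) = 2pq(1-f)`, `P(hom_alt) = q^2 + pqf`,
#' `P(hom_ref) = p^2 + pqf`, where `q` is the minor allele frequency and
#' `f` the inbreeding coefficient. `f = 0` is Hardy-Weinberg
#' equilibrium; positive `f` depletes heterozygotes.
#'
#' @param n number of individuals.
#' @param maf minor allele frequency in (0, 0.5].
#' @param f inbreeding coefficient; must satisfy `f >= -maf/(1-maf)` so
#'   all genotype probabilities are non-negative.
#' @param seed optional seed making the draw self-contained; default uses
#'   the current RNG stream.
#' @return integer vector of alt-allele dosages (0 = hom ref, 1 = het,
#'   2 = hom alt).
#' @export
gen_genotypes <- function(n, maf, f = 0, seed = NULL) {
  if (maf <= 0 || maf > 0.5) abort("maf must lie in (0, 0.5]")
  if (f > 1 || f < -maf / (1 - maf)) {
    abort("f produces negative genotype probabilities")
  }
  q <- maf; p <- 1 - q
  probs <- c(p^2 + p * q * f, 2 * p * q * (1 - f), q^2 + p * q * f)
  draw <- function() sample(0:2, n, replace = TRUE, prob = probs)
  if (is.null(seed)) draw() else .with_seed(seed, draw())
}

#' Generate the simulated variant table
#'
#' Places variants at known helix positions of the planted fingers with
#' known class labels: missense at DNA-contacting positions, missense at
#' non-contacting positions, missense at the untracked helix position 4
#' (truth class unknown), plus silent and "other" (stop-type) variants
#' at tracked positions. MAFs are drawn from `cfg$maf_spectrum` when
#' `common_or = 1`; otherwise common/rare status is drawn per class with
#' the requested odds ratio (contacting vs non-contacting) and the MAF
#' drawn uniformly within the corresponding range, which plants a
#' common-variant depletion of known strength.
#'
#' @param cfg a [sim_config()].
#' @param truth the `truth` element of [gen_proteome()].
#' @param n_contacting,n_non_contacting,n_unknown,n_silent,n_other
#'   category counts; defaults split `cfg$n_variants` 35/35/10/10/10%.
#' @param common_or odds ratio of being common for contacting vs
#'   non-contacting missense variants (1 = no depletion).
#' @param p_common baseline probability of being common (non-contacting
#'   class) when `common_or != 1`.
#' @return list with `variants` (tibble: `variant_id`, `protein_id`,
#'   `residue_pos`, `ref_aa`, `alt_aa`, `maf`) and `truth` (tibble adding
#'   the planted `class`, `label` and `effect`).
#' @export
gen_variant_table <- function(cfg, truth,
                              n_contacting = NULL, n_non_contacting = NULL,
                              n_unknown = NULL, n_silent = NULL, n_other = NULL,
                              common_or = 1, p_common = 0.5) {
  nv <- cfg$n_variants
  n_non_contacting <- n_non_contacting %||% round(0.35 * nv)
  n_unknown <- n_unknown %||% round(0.10 * nv)
  n_silent <- n_silent %||% round(0.10 * nv)
  n_other <- n_other %||% round(0.10 * nv)
  n_contacting <- n_contacting %||%
    max(0L, nv - n_non_contacting - n_unknown - n_silent - n_other)
  .with_seed(cfg$seed + 12L, {
    hx <- truth$helix
    if (nrow(hx) == 0L) {
      if (n_contacting + n_non_contacting + n_unknown + n_silent + n_other > 0L) {
        abort("no planted fingers to place variants on")
      }
      empty <- tibble(variant_id = character(), protein_id = character(),
                      residue_pos = integer(), ref_aa = character(),
                      alt_aa = character(), maf = numeric())
      return(list(variants = empty,
                  truth = empty %>% mutate(class = character(0),
                                           label = character(0),
                                           effect = character(0))))
    }
    take <- function(pool, k, what) {
      if (k > nrow(pool)) abort(sprintf("not enough planted positions for %s variants", what))
      pool[sample(nrow(pool), k), , drop = FALSE]
    }
    con_pool <- hx %>% filter(.data$class == "contacting")
    non_pool <- hx %>% filter(.data$class == "non_contacting")
    # untracked helix position 4 sits one residue before position 5
    pos4 <- truth$fingers %>%
      mutate(label = "4", pos = .data$his1_pos - 3L,
             class = "unknown", aa = NA_character_) %>%
      select("protein_id", "finger", "label", "pos", "aa", "class")
    rows <- list(
      contacting = take(con_pool, n_contacting, "contacting") %>% mutate(effect = "missense"),
      non_contacting = take(non_pool, n_non_contacting, "non-contacting") %>% mutate(effect = "missense"),
      unknown = take(pos4, n_unknown, "unknown") %>% mutate(effect = "missense")
    )
    # silent and "other" variants reuse tracked positions not already used
    used <- bind_rows(rows$contacting, rows$non_contacting) %>%
      select("protein_id", "pos")
    rest_pool <- bind_rows(con_pool, non_pool) %>%
      anti_join(used, by = c("protein_id", "pos"))
    rows$silent <- take(rest_pool, n_silent, "silent") %>% mutate(effect = "silent")
    rest_pool2 <- rest_pool %>%
      anti_join(rows$silent %>% select("protein_id", "pos"),
                by = c("protein_id", "pos"))
    rows$other <- take(rest_pool2, n_other, "other") %>% mutate(effect = "other")
    all_rows <- bind_rows(rows)
    n_all <- nrow(all_rows)
    all_rows <- all_rows[sample(n_all), , drop = FALSE]
    aa <- all_rows$aa  # NA for untracked (position-4) rows; filled downstream
    cls <- all_rows$class
    if (common_or == 1 && !is.null(cfg$maf_spectrum)) {
      maf <- sample(cfg$maf_spectrum, n_all, replace = TRUE)
    } else {
      odds_base <- p_common / (1 - p_common)
      p_con <- (odds_base * common_or) / (1 + odds_base * common_or)
      pc <- ifelse(cls == "contacting" & all_rows$effect == "missense", p_con, p_common)
      is_common <- runif(n_all) < pc
      maf <- ifelse(is_common, runif(n_all, 0.01, 0.5), runif(n_all, 0.001, 0.00999))
    }
    alt <- character(n_all)
    for (i in seq_len(n_all)) {
      ref <- aa[i]
      if (all_rows$effect[i] == "silent") {
        alt[i] <- ref
      } else if (all_rows$effect[i] == "other") {
        alt[i] <- "*"
      } else {
        alt[i] <- sample(setdiff(.aa20, ref), 1L)
      }
    }
    out <- tibble(
      variant_id = sprintf("snp%04d", seq_len(n_all)),
      protein_id = all_rows$protein_id,
      residue_pos = as.integer(all_rows$pos),
      ref_aa = aa,
      alt_aa = alt,
      maf = maf
    )
    truth_tab <- out %>% mutate(class = cls,
                                label = all_rows$label,
                                effect = all_rows$effect)
    list(variants = out, truth = truth_tab)
  })
}

#' Simulate the genotyped cohort for a variant table
#'
#' Draws independent genotypes for every (variant, population) with the
#' variant's MAF and the configured inbreeding coefficient, one VCF per
#' cohort with populations only in the panel.
#'
#' @param cfg a [sim_config()].
#' @param variants variant tibble with `variant_id` and `maf`.
#' @param f inbreeding coefficient override (scalar or per variant);
#'   default `cfg$inbreeding_f`.
#' @return list: `gt` (integer dosage matrix, variants x samples),
#'   `panel` (tibble `sample`, `population`), `mafs` (named).
#' @export
gen_cohort <- function(cfg, variants, f = NULL) {
  f <- f %||% cfg$inbreeding_f
  nv <- nrow(variants)
  f <- rep_len(f, nv)
  .with_seed(cfg$seed + 13L, {
    pops <- rep(cfg$populations, each = cfg$n_individuals)
    samples <- sprintf("S%04d", seq_along(pops))
    gt <- matrix(NA_integer_, nv, length(samples),
                 dimnames = list(variants$variant_id, samples))
    for (i in seq_len(nv)) {
      for (p in unique(pops)) {
        idx <- which(pops == p)
        gt[i, idx] <- gen_genotypes(length(idx), variants$maf[i], f[i])
      }
    }
    list(gt = gt,
         panel = tibble(sample = samples, population = pops),
         mafs = setNames(variants$maf, variants$variant_id))
  })
}

#' Write a simulated cohort as VCF v4.2
#'
#' Biallelic SNPs, GT field only; placeholder coordinates (chromosome 1,
#' positions in input order).
#'
#' @param gt integer dosage matrix (variants x samples) from [gen_cohort()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sim_vcf <- function(gt, path) {
  gt_str <- matrix(c("0/0", "0/1", "1/1")[gt + 1L], nrow(gt), ncol(gt))
  gt_str[is.na(gt)] <- "./."
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=zfvar synthetic cohort",
    "##contig=<ID=1>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(gt)), collapse = "\t")
  )
  body <- vapply(seq_len(nrow(gt)), function(i) {
    paste(c("1", as.character(i * 500L), rownames(gt)[i], "A", "G", ".",
            "PASS", ".", "GT", gt_str[i, ]), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Generate a reference/variant PFM pair with controlled divergence
#'
#' Reference columns are Dirichlet draws; each variant column mixes the
#' reference column with an independent random column at weight
#' `divergence` (capped at 1). `divergence = 0` returns identical
#' matrices; larger weights give larger summed KL distances on average.
#'
#' @param divergence mixing weight, >= 0.
#' @param width number of PFM columns (3 for a single-finger site).
#' @param alpha Dirichlet concentration per base.
#' @param seed optional self-contained seed.
#' @return list with matrices `ref` and `snp`.
#' @export
gen_pfm_pair <- function(divergence, width = 3L, alpha = 0.5, seed = NULL) {
  if (divergence < 0) abort("divergence must be >= 0")
  w <- min(1, divergence)
  draw <- function() {
    rdir <- function() {
      g <- rgamma(4L, shape = alpha)
      while (sum(g) == 0) g <- rgamma(4L, shape = alpha)
      g / sum(g)
    }
    ref <- vapply(seq_len(width), function(j) rdir(), numeric(4))
    snp <- vapply(seq_len(width), function(j) (1 - w) * ref[, j] + w * rdir(),
                  numeric(4))
    rownames(ref) <- rownames(snp) <- c("A", "C", "G", "T")
    list(ref = ref, snp = snp)
  }
  if (is.null(seed)) draw() else .with_seed(seed, draw())
}

#' Generate a batch of PFM pairs, optionally written to disk
#'
#' @param cfg a [sim_config()].
#' @param pair_ids identifiers (default `pfm001`...).
#' @param divergence mixing weight(s), recycled; default `cfg$pfm_divergence`.
#' @param mafs optional MAF per pair carried into the manifest.
#' @param dir when given, each PFM is written as a 4-row TSV and a
#'   manifest tibble with file paths is returned.
#' @return tibble manifest: `pair_id`, `ref`/`snp` list-columns (and
#'   `ref_path`/`snp_path` when written), `divergence`, `maf`.
#' @export
gen_pfm_pairs <- function(cfg, pair_ids = NULL, divergence = NULL,
                          mafs = NULL, dir = NULL) {
  n <- cfg$n_pfm_pairs
  pair_ids <- pair_ids %||% sprintf("pfm%03d", seq_len(n))
  n <- length(pair_ids)
  divergence <- rep_len(divergence %||% cfg$pfm_divergence, n)
  .with_seed(cfg$seed + 14L, {
    pairs <- lapply(seq_len(n), function(i) gen_pfm_pair(divergence[i]))
    out <- tibble(
      pair_id = pair_ids,
      ref = lapply(pairs, `[[`, "ref"),
      snp = lapply(pairs, `[[`, "snp"),
      divergence = divergence
    )
    if (!is.null(mafs)) out$maf <- rep_len(mafs, n)
    if (!is.null(dir)) {
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      out$ref_path <- file.path(dir, paste0(pair_ids, "_ref.tsv"))
      out$snp_path <- file.path(dir, paste0(pair_ids, "_snp.tsv"))
      for (i in seq_len(n)) {
        .write_pfm(out$ref[[i]], out$ref_path[i])
        .write_pfm(out$snp[[i]], out$snp_path[i])
      }
    }
    out
  })
}

.write_pfm <- function(m, path) {
  lines <- vapply(rownames(m), function(b) {
    paste(c(b, format(m[b, ], digits = 12, scientific = FALSE, trim = TRUE)),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Generate prediction-score tables with planted deleterious calls
#'
#' For each variant and method, a Bernoulli draw at the planted fraction
#' decides deleteriousness, and the score is drawn on the corresponding
#' side of that method's threshold (SIFT < 0.05, PolyPhen2-HDIV > 0.95,
#' MutationTaster > 0.90, FATHMM < -1.5). A small fraction of
#' non-deleterious scores is set to NA, mimicking database sparsity.
#'
#' @param cfg a [sim_config()].
#' @param variant_ids identifiers for the score rows.
#' @param deleterious_fraction scalar or named per-method fractions;
#'   default `cfg$deleterious_fraction`.
#' @param na_fraction fraction of non-deleterious cells set NA.
#' @return list: `scores` tibble (`variant_id` + the four score columns)
#'   and `truth` tibble (`variant_id` + `<method>_del` logicals).
#' @export
gen_scores <- function(cfg, variant_ids, deleterious_fraction = NULL,
                       na_fraction = 0.05) {
  frac <- deleterious_fraction %||% cfg$deleterious_fraction
  if (is.null(names(frac))) {
    frac <- setNames(rep_len(frac, 4L), .score_methods)
  } else {
    frac <- setNames(frac[.score_methods], .score_methods)
    frac[is.na(frac)] <- 0
  }
  n <- length(variant_ids)
  .with_seed(cfg$seed + 15L, {
    draw_method <- function(method, del) {
      x <- switch(method,
        sift = ifelse(del, runif(n, 0, 0.049), runif(n, 0.06, 1)),
        polyphen2_hdiv = ifelse(del, runif(n, 0.951, 1), runif(n, 0, 0.949)),
        mutation_taster = ifelse(del, runif(n, 0.901, 1), runif(n, 0, 0.899)),
        fathmm = ifelse(del, runif(n, -6, -1.51), runif(n, -1.49, 3))
      )
      x[!del & runif(n) < na_fraction] <- NA_real_
      x
    }
    truth <- tibble(variant_id = variant_ids)
    scores <- tibble(variant_id = variant_ids)
    for (m in .score_methods) {
      del <- runif(n) < frac[[m]]
      truth[[paste0(m, "_del")]] <- del
      scores[[m]] <- draw_method(m, del)
    }
    list(scores = scores, truth = truth)
  })
}

#' Simulate a full study cohort, optionally writing all input files
#'
#' Runs every generator under the configuration's seed and, when
#' `out_dir` is given, writes the pipeline's input files: proteome FASTA,
#' variant TSV, cohort VCF + panel TSV, score TSV, PFM TSVs + manifest,
#' and a ground-truth JSON.
#'
#' @param cfg a [sim_config()].
#' @param out_dir optional directory for the generated files.
#' @return list: `cfg`, `proteome`, `variants` (with truth), `cohort`,
#'   `scores`, `pfms`, and `paths` when written.
#' @export
simulate_cohort <- function(cfg, out_dir = NULL) {
  prot <- gen_proteome(cfg)
  vt <- gen_variant_table(cfg, prot$truth)
  # fill reference residues for untracked-position variants
  vt$variants$ref_aa <- substring(prot$seqs[vt$variants$protein_id],
                                  vt$variants$residue_pos,
                                  vt$variants$residue_pos)
  vt$truth$ref_aa <- vt$variants$ref_aa
  silent <- vt$truth$effect == "silent"
  vt$variants$alt_aa[silent] <- vt$variants$ref_aa[silent]
  # a late-filled reference residue can collide with the sampled alt:
  # keep planted missense variants missense by rotating the alt residue
  clash <- vt$truth$effect == "missense" & vt$variants$alt_aa == vt$variants$ref_aa
  if (any(clash)) {
    idx <- match(vt$variants$ref_aa[clash], .aa20)
    vt$variants$alt_aa[clash] <- .aa20[idx %% length(.aa20) + 1L]
  }
  vt$truth$alt_aa <- vt$variants$alt_aa
  cohort <- gen_cohort(cfg, vt$variants)
  scores <- gen_scores(cfg, vt$variants$variant_id)
  kl_ids <- head(vt$variants$variant_id, cfg$n_pfm_pairs)
  pfms <- gen_pfm_pairs(cfg, pair_ids = kl_ids,
                        mafs = vt$variants$maf[match(kl_ids, vt$variants$variant_id)],
                        dir = if (is.null(out_dir)) NULL else file.path(out_dir, "pfm"))
  out <- list(cfg = cfg, proteome = prot, variants = vt, cohort = cohort,
              scores = scores, pfms = pfms)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      fasta = file.path(out_dir, "proteome.fasta"),
      variants = file.path(out_dir, "variants.tsv"),
      vcf = file.path(out_dir, "genotypes.vcf"),
      panel = file.path(out_dir, "panel.tsv"),
      scores = file.path(out_dir, "scores.tsv"),
      pfm_manifest = file.path(out_dir, "pfm_manifest.tsv"),
      truth = file.path(out_dir, "ground_truth.json")
    )
    writeLines(paste0(">", names(prot$seqs), "\n", unname(prot$seqs)), paths$fasta)
    readr::write_tsv(vt$variants, paths$variants)
    write_sim_vcf(cohort$gt, paths$vcf)
    readr::write_tsv(cohort$panel, paths$panel)
    readr::write_tsv(scores$scores, paths$scores)
    # manifest paths are stored relative to the manifest's directory so the
    # written cohort is relocatable (and byte-stable across runs)
    rel <- function(p) sub(paste0("^", gsub("([][{}()+*^$|\\\\.?])", "\\\\\\1", out_dir), "/?"),
                           "", p)
    readr::write_tsv(pfms %>%
                       mutate(ref_path = rel(.data$ref_path),
                              snp_path = rel(.data$snp_path)) %>%
                       select("pair_id", "ref_path", "snp_path", "maf"),
                     paths$pfm_manifest)
    jsonlite::write_json(
      list(arrays = prot$truth$arrays, fingers = prot$truth$fingers,
           helix = prot$truth$helix, variant_classes = vt$truth,
           inbreeding_f = rep_len(cfg$inbreeding_f, nrow(vt$variants)),
           deleterious = scores$truth,
           pfm_divergence = pfms %>% select("pair_id", "divergence")),
      paths$truth, digits = NA, auto_unbox = TRUE)
    out$paths <- paths
  }
  out
}
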