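# Amplitude change at bins `bins` caused by substituting value delta at
# position pos: X_var(n) = X_wt(n) + delta * exp(-i 2 pi n (pos-1)/N).
# O(1) per (candidate, bin), which is what makes the greedy search cheap.
delta_amplitude <- function(wt_coef, n_total, bins, pos, delta) {
  w <- exp(-2i * pi * bins * (pos - 1) / n_total)
  Mod(wt_coef[bins] + delta * w)^2 - Mod(wt_coef[bins])^2
}

#' Generate a synthetic dataset with a planted spectral signal
#'
#' Builds a random wild-type protein whose EIIP series carries a sinusoidal
#' component at a chosen frequency bin (so that bin dominates the wild-type
#' informational spectrum), then plants labeled substitutions: each MUT is a
#' substitution chosen by seeded greedy search to shift the amplitude at the
#' planted bin strongly and in a consistent direction, while each SNP is
#' chosen from the smallest decile of amplitude disturbance over the planted
#' bin and its 3 neighbours on either side. The realized standardized group
#' separation at the planted bin is recorded and must reach `effect_size`
#' (pooled-SD units), otherwise generation fails with a suggestion to
#' increase `length`.
#'
#' With `effect_size = 0` the construction degenerates to the null
#' generator: unplanted wild type and uniform random substitutions for both
#' classes, so the two groups are statistically indistinguishable at every
#' bin.
#'
#' Identical arguments and seed give byte-identical datasets.
#'
#' @param length Wild-type length (>= 50 residues).
#' @param planted_index Planted frequency bin n*, in 1..floor(length/2).
#' @param n_mut,n_snp Substitutions per class (>= 3 each).
#' @param effect_size Minimum standardized separation at the planted bin, in
#'   pooled-SD units (0 for a null dataset).
#' @param seed Integer seed.
#' @param scale EIIP scale.
#' @param max_candidates Cap on candidate (position, residue) evaluations per
#'   variant in the greedy search (default 5000).
#' @return Object of class `ism_dataset`: list with `wild_type`, `variants`
#'   (data frame: substitution, pos, wt, alt, label), `planted_index`,
#'   `planted_frequency`, `effect_size` (requested), `realized_separation`,
#'   and `seed`.
#' @export
#' @examples
#' d <- generate_planted_dataset(120, 40, 5, 5, effect_size = 3, seed = 1)
#' table(d$variants$label)
generate_planted_dataset <- function(length, planted_index, n_mut, n_snp,
                                     effect_size = 3, seed,
                                     scale = eiip_scale(),
                                     max_candidates = 5000L) {
  n_total <- as.integer(length)
  if (n_total < 50L) stop("length must be >= 50", call. = FALSE)
  m_bins <- n_total %/% 2L
  if (planted_index < 1L || planted_index > m_bins) {
    stop("planted_index must be in 1..floor(length/2)", call. = FALSE)
  }
  if (n_mut < 3L || n_snp < 3L) stop("need at least 3 variants per class", call. = FALSE)
  if (effect_size < 0) stop("effect_size must be >= 0", call. = FALSE)
  set.seed(as.integer(seed))

  if (effect_size == 0) {
    wt <- random_protein(n_total)
    variants <- rbind(
      uniform_substitutions(wt, n_mut, "MUT"),
      uniform_substitutions(wt, n_snp, "SNP"))
    return(new_ism_dataset(wt, variants, planted_index, n_total,
                           effect_size, realized = 0, seed = seed))
  }

  wt <- planted_wild_type(n_total, planted_index, scale)
  series <- encode_sequence(wt, scale)
  wt_coef_full <- stats::fft(series)
  coef_k <- function(n) wt_coef_full[n + 1L]  # X(n), n >= 1
  wt_coef <- wt_coef_full[-1L]  # index n -> wt_coef[n]

  residues <- as_residue_vector(wt)
  used <- character(0)  # "pos_alt" keys already taken
  ncand <- min(as.integer(max_candidates), 400L)

  draw_candidates <- function() {
    pos <- sample.int(n_total, ncand, replace = TRUE)
    alt <- sample(.canonical_residues, ncand, replace = TRUE)
    ok <- alt != residues[pos] & !(paste0(pos, "_", alt) %in% used)
    data.frame(pos = pos[ok], alt = alt[ok], stringsAsFactors = FALSE)
  }

  pick_mut <- function() {
    cand <- draw_candidates()
    if (!nrow(cand)) stop("candidate pool exhausted; increase length", call. = FALSE)
    delta <- scale[cand$alt] - scale[residues[cand$pos]]
    ds <- vapply(seq_len(nrow(cand)), function(i) {
      delta_amplitude(wt_coef, n_total, planted_index, cand$pos[i], delta[i])
    }, numeric(1))
    cand[which.max(ds), ]  # largest positive shift at the planted bin
  }

  window <- intersect((planted_index - 3L):(planted_index + 3L), seq_len(m_bins))
  pick_snp <- function() {
    cand <- draw_candidates()
    if (!nrow(cand)) stop("candidate pool exhausted; increase length", call. = FALSE)
    delta <- scale[cand$alt] - scale[residues[cand$pos]]
    dist <- vapply(seq_len(nrow(cand)), function(i) {
      max(abs(delta_amplitude(wt_coef, n_total, window, cand$pos[i], delta[i])))
    }, numeric(1))
    decile <- which(dist <= stats::quantile(dist, 0.1))
    cand[sample(decile, 1L), ]
  }

  take <- function(n, picker, label) {
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      v <- picker()
      used <<- c(used, paste0(v$pos, "_", v$alt))
      rows[[i]] <- data.frame(
        substitution = paste0(residues[v$pos], v$pos, v$alt),
        pos = v$pos, wt = residues[v$pos], alt = v$alt, label = label,
        stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  }

  variants <- rbind(take(n_mut, pick_mut, "MUT"), take(n_snp, pick_snp, "SNP"))

  # realized separation at the planted bin
  delta_sel <- scale[variants$alt] - scale[variants$wt]
  shift <- vapply(seq_len(nrow(variants)), function(i) {
    delta_amplitude(wt_coef, n_total, planted_index, variants$pos[i], delta_sel[i])
  }, numeric(1))
  g_mut <- shift[variants$label == "MUT"]
  g_snp <- shift[variants$label == "SNP"]
  pooled <- sqrt(((n_mut - 1) * stats::var(g_mut) +
                    (n_snp - 1) * stats::var(g_snp)) / (n_mut + n_snp - 2))
  realized <- abs(mean(g_mut) - mean(g_snp)) / pooled
  if (!is.finite(realized) || realized < effect_size) {
    stop("planted construction reached separation ", format(realized),
         " < requested effect size ", effect_size,
         "; try a larger sequence length", call. = FALSE)
  }
  new_ism_dataset(wt, variants, planted_index, n_total, effect_size,
                  realized, seed)
}

#' Generate a null synthetic dataset (no planted signal)
#'
#' Random wild type with substitutions drawn uniformly for both classes;
#' used to study the behaviour of the sequential frequency search when no
#' class difference exists (its discovery rate is well above the per-test
#' level because the search is uncorrected — a documented property of the
#' procedure).
#'
#' @param length Wild-type length (>= 50).
#' @param n_per_class Substitutions in each class (>= 1).
#' @param seed Integer seed.
#' @return An `ism_dataset` with `planted_index = NA`.
#' @export
generate_null_dataset <- function(length, n_per_class, seed) {
  n_total <- as.integer(length)
  if (n_total < 50L) stop("length must be >= 50", call. = FALSE)
  if (n_per_class < 1L) stop("n_per_class must be >= 1", call. = FALSE)
  set.seed(as.integer(seed))
  wt <- random_protein(n_total)
  variants <- rbind(
    uniform_substitutions(wt, n_per_class, "MUT"),
    uniform_substitutions(wt, n_per_class, "SNP"))
  new_ism_dataset(wt, variants, NA_integer_, n_total, effect_size = 0,
                  realized = 0, seed = seed)
}

new_ism_dataset <- function(wt, variants, planted_index, n_total,
                            effect_size, realized, seed) {
  rownames(variants) <- NULL
  structure(
    list(wild_type = wt, variants = variants,
         planted_index = planted_index,
         planted_frequency = if (is.na(planted_index)) NA_real_
                             else planted_index / n_total,
         effect_size = effect_size,
         realized_separation = realized,
         seed = seed),
    class = "ism_dataset")
}

#' @export
print.ism_dataset <- function(x, ...) {
  cat("Synthetic ISM dataset: wild type of", nchar(x$wild_type), "residues,",
      sum(x$variants$label == "MUT"), "MUT +",
      sum(x$variants$label == "SNP"), "SNP variants\n")
  if (!is.na(x$planted_index)) {
    cat(sprintf("  planted bin %d (f = %.3f), realized separation %.2f SD (requested >= %g)\n",
                x$planted_index, x$planted_frequency,
                x$realized_separation, x$effect_size))
  } else {
    cat("  null dataset (no planted signal)\n")
  }
  cat("  seed:", x$seed, "\n")
  invisible(x)
}

random_protein <- function(n) {
  paste(sample(.canonical_residues, n, replace = TRUE), collapse = "")
}

uniform_substitutions <- function(wt, n, label) {
  residues <- as_residue_vector(wt)
  rows <- vector("list", n)
  used <- character(0)
  for (i in seq_len(n)) {
    repeat {
      pos <- sample.int(length(residues), 1L)
      alt <- sample(.canonical_residues, 1L)
      key <- paste0(pos, "_", alt)
      if (alt != residues[pos] && !(key %in% used)) break
    }
    used <- c(used, key)
    rows[[i]] <- data.frame(substitution = paste0(residues[pos], pos, alt),
                            pos = pos, wt = residues[pos], alt = alt,
                            label = label, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

# Wild type whose EIIP series tracks c0 + a cos(2 pi n* (m-1)/N): at 80% of
# positions the residue is drawn from the two closest EIIP values to the
# sinusoid target, else uniformly. The cosine amplitude (~0.028 Ry) makes
# |X(n*)| ~ a N / 2, which dominates the O(sqrt(N) sd) amplitudes of
# unplanted bins for N >= 50.
planted_wild_type <- function(n_total, planted_index, scale) {
  target <- 0.055 + 0.028 * cos(2 * pi * planted_index * (seq_len(n_total) - 1) / n_total)
  ord <- names(scale)
  pick_near <- function(t) {
    near <- ord[order(abs(scale - t))[1:2]]
    sample(near, 1L)
  }
  res <- vapply(target, pick_near, character(1))
  uniform <- sample(.canonical_residues, n_total, replace = TRUE)
  use_uniform <- stats::runif(n_total) > 0.8
  res[use_uniform] <- uniform[use_uniform]
  paste(res, collapse = "")
}

#' Write a synthetic dataset as FASTA plus variant TSV
#'
#' Emits files directly consumable by [ism_fit()] via [read_protein_fasta()]
#' and [read_variant_table()].
#'
#' @param dataset An `ism_dataset`.
#' @param fasta,variants Output paths for the wild-type FASTA and the
#'   variant table.
#' @param gene Gene identifier used in both files (default `"SYNTH"`).
#' @return Invisibly, a character vector of the two paths.
#' @export
write_dataset <- function(dataset, fasta, variants, gene = "SYNTH") {
  stopifnot(inherits(dataset, "ism_dataset"))
  write_protein_fasta(stats::setNames(dataset$wild_type, gene), fasta)
  tab <- data.frame(gene = gene,
                    substitution = dataset$variants$substitution,
                    label = dataset$variants$label)
  utils::write.table(tab, variants, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fasta, variants))
}
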