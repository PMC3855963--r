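#' ISM deviation scores of variant spectra against the wild type
#'
#' For variant i and frequency bin j the score is the amplitude deviation
#' `S(i, j) = A(f_j)_var_i - A(f_j)_wt`: the exact elementwise difference of
#' the variant's informational spectrum from the wild type's, with no
#' normalisation. All spectra must come from sequences of the same length
#' (single-residue substitutions preserve length).
#'
#' @param wt Wild-type `informational_spectrum`.
#' @param variant_spectra List of `informational_spectrum` objects, one per
#'   variant.
#' @return Numeric matrix, one row per variant and one column per frequency
#'   bin, with the wild-type frequency grid in `dimnames` / attribute
#'   `frequency`.
#' @export
ism_scores <- function(wt, variant_spectra) {
  stopifnot(inherits(wt, "informational_spectrum"))
  if (inherits(variant_spectra, "informational_spectrum")) {
    variant_spectra <- list(variant_spectra)
  }
  amps <- lapply(variant_spectra, function(s) {
    stopifnot(inherits(s, "informational_spectrum"))
    if (s$source_length != wt$source_length) {
      stop("spectrum length mismatch: variant N = ", s$source_length,
           ", wild type N = ", wt$source_length, call. = FALSE)
    }
    s$amplitude
  })
  m <- do.call(rbind, amps)
  m <- sweep(m, 2L, wt$amplitude)
  rownames(m) <- names(variant_spectra)
  attr(m, "frequency") <- wt$frequency
  m
}

#' Fit an ISM mutation/SNP classifier for one protein
#'
#' Implements the informational-spectrum variant classifier: (1) the
#' wild-type sequence and every substituted sequence are EIIP-encoded and
#' Fourier-transformed into informational spectra; (2) each variant is scored
#' at every frequency by its amplitude deviation from the wild type;
#' (3) frequencies are visited in strictly descending order of wild-type
#' amplitude (ties broken by ascending frequency) and at each a two-sided
#' Mann-Whitney U test compares the mutation scores with the SNP scores;
#' (4) the first frequency with p below `alpha` is the classifier frequency;
#' (5) the wild-type amplitude at that frequency becomes the cutoff, and the
#' orientation sign records whether mutations sit above (+1) or below (-1)
#' the wild type there.
#'
#' Frequencies and cutoffs are protein-specific, so a model is fitted per
#' gene; pooling variants across proteins is not supported. No correction is
#' applied across the sequential tests; `frequencies_tested` exposes the
#' search depth.
#'
#' @param wildtype Wild-type protein sequence (string).
#' @param variants Substitution strings (`"L149Q"` style), or a data frame
#'   with a `substitution` column (and optionally `label`), as from
#'   [read_variant_table()].
#' @param labels Class labels, `"MUT"` / `"SNP"`, one per variant (taken
#'   from `variants$label` when omitted). Both classes must be non-empty.
#' @param alpha Significance level in (0, 1\] for the sequential search.
#' @param gene Optional gene identifier stored in the model.
#' @param scale EIIP scale, default [eiip_scale()].
#' @param exact Mann-Whitney p-value mode, see [mann_whitney_u()].
#' @return Object of class `ism_fit`. If some frequency reaches `p < alpha`
#'   the model has `found = TRUE`, the selected `frequency_index` / `frequency`,
#'   the wild-type `cutoff` amplitude, `orientation` (+1 or -1), `p_value`
#'   and `frequencies_tested`; otherwise `found = FALSE` (an explicit
#'   "no classifier found" result, not an error). Either way the object
#'   carries the full selection `trace`, the score matrix, the wild-type
#'   spectrum and the training variants.
#' @seealso [predict.ism_fit()], [ism_cv()], [oriented_score()]
#' @export
#' @examples
#' set.seed(1)
#' d <- generate_planted_dataset(length = 120, planted_index = 40,
#'                               n_mut = 8, n_snp = 8, effect_size = 3,
#'                               seed = 42)
#' fit <- ism_fit(d$wild_type, d$variants)
#' fit
ism_fit <- function(wildtype, variants, labels = NULL, alpha = 0.05,
                    gene = NULL, scale = eiip_scale(),
                    exact = c("auto", "exact", "approx")) {
  exact <- match.arg(exact)
  if (!(alpha > 0 && alpha <= 1)) stop("alpha must be in (0, 1]", call. = FALSE)
  if (is.data.frame(variants)) {
    if (is.null(labels) && !is.null(variants$label)) labels <- variants$label
    vtab <- parse_variant(variants$substitution)
  } else {
    vtab <- parse_variant(variants)
  }
  if (is.null(labels)) stop("labels are required (MUT/SNP)", call. = FALSE)
  labels <- toupper(as.character(labels))
  if (length(labels) != nrow(vtab)) {
    stop("labels length must match the number of variants", call. = FALSE)
  }
  if (!all(labels %in% c("MUT", "SNP"))) {
    stop("labels must be MUT or SNP", call. = FALSE)
  }
  if (!any(labels == "MUT") || !any(labels == "SNP")) {
    stop("both classes (MUT and SNP) must be non-empty", call. = FALSE)
  }

  wt_spec <- informational_spectrum(wildtype, scale)
  spectra <- lapply(seq_len(nrow(vtab)), function(i) {
    informational_spectrum(apply_variant(wildtype, vtab[i, , drop = FALSE]),
                           scale)
  })
  names(spectra) <- vtab$substitution
  scores <- ism_scores(wt_spec, spectra)

  sel <- select_frequency_from_scores(scores, wt_spec, labels, alpha, exact)

  structure(
    c(sel,
      list(gene = gene, alpha = alpha, labels = labels, variants = vtab,
           scores = scores, wt_spectrum = wt_spec, wildtype = toupper(wildtype),
           call = match.call())),
    class = "ism_fit")
}

# Sequential Mann-Whitney scan over frequency columns in descending order of
# wild-type amplitude (ties: ascending frequency). Shared by ism_fit and the
# cross-validation loop.
select_frequency_from_scores <- function(scores, wt_spec, labels, alpha,
                                         exact = "auto") {
  ord <- order(-wt_spec$amplitude, wt_spec$index)
  is_mut <- labels == "MUT"
  trace <- data.frame(index = integer(), frequency = numeric(),
                      wt_amplitude = numeric(), p = numeric())
  found <- FALSE
  sel_j <- NA_integer_
  p_sel <- NA_real_
  for (j in ord) {
    mw <- mann_whitney_u(scores[is_mut, j], scores[!is_mut, j], exact = exact)
    trace <- rbind(trace, data.frame(index = wt_spec$index[j],
                                     frequency = wt_spec$frequency[j],
                                     wt_amplitude = wt_spec$amplitude[j],
                                     p = mw$p))
    if (mw$p < alpha) {
      found <- TRUE
      sel_j <- j
      p_sel <- mw$p
      break
    }
  }
  if (found) {
    med_mut <- stats::median(scores[is_mut, sel_j])
    med_snp <- stats::median(scores[!is_mut, sel_j])
    orientation <- if (med_mut >= med_snp) 1L else -1L
    list(found = TRUE,
         frequency_index = wt_spec$index[sel_j],
         frequency = wt_spec$frequency[sel_j],
         cutoff = wt_spec$amplitude[sel_j],
         orientation = orientation,
         p_value = p_sel,
         frequencies_tested = nrow(trace),
         trace = trace)
  } else {
    list(found = FALSE,
         frequency_index = NA_integer_, frequency = NA_real_,
         cutoff = NA_real_, orientation = NA_integer_, p_value = NA_real_,
         frequencies_tested = nrow(trace), trace = trace)
  }
}

#' Classify an amplitude against a fitted cutoff
#'
#' A variant is called a mutation iff `orientation * (amplitude - cutoff)`
#' is strictly positive; an amplitude exactly at the cutoff is called SNP
#' (benign by default). With orientation -1, amplitudes *above* the wild
#' type are therefore SNP calls.
#'
#' @param amplitude Variant IS amplitude(s) at the classifier frequency.
#' @param model A fitted `ism_fit` (with `found = TRUE`).
#' @return Character vector of `"MUT"` / `"SNP"`.
#' @export
classify_amplitude <- function(amplitude, model) {
  check_found(model)
  ifelse(model$orientation * (amplitude - model$cutoff) > 0, "MUT", "SNP")
}

#' Orientation-adjusted ISM score
#'
#' Multiplies a raw deviation score by the model's orientation sign so that,
#' across genes, higher oriented scores always mean more mutation-like.
#' Used as the continuous score for ROC analysis.
#'
#' @param score Raw deviation score(s) `A_var - A_wt` at the classifier
#'   frequency.
#' @param model A fitted `ism_fit`, or directly an orientation of +1 / -1.
#' @return `orientation * score`.
#' @export
#' @examples
#' oriented_score(0.37473, -1)   # -0.37473
#' oriented_score(-0.24349, -1)  # 0.24349
oriented_score <- function(score, model) {
  orientation <- if (inherits(model, "ism_fit")) {
    check_found(model)
    model$orientation
  } else {
    model
  }
  if (!orientation %in% c(-1, 1)) stop("orientation must be +1 or -1", call. = FALSE)
  orientation * score
}

check_found <- function(model) {
  stopifnot(inherits(model, "ism_fit") || is.list(model))
  if (!isTRUE(model$found)) {
    stop("no classifier frequency was found (model has found = FALSE)",
         call. = FALSE)
  }
  invisible(model)
}

#' Predict classes for substitutions with a fitted ISM model
#'
#' Builds each substituted sequence, takes its IS amplitude at the model's
#' classifier frequency, and calls MUT or SNP against the wild-type cutoff
#' (see [classify_amplitude()]). With `newdata = NULL` the training variants
#' are classified.
#'
#' @param object A fitted `ism_fit` with `found = TRUE`.
#' @param newdata Substitution strings or a data frame with a `substitution`
#'   column; `NULL` for the training variants.
#' @param type `"class"` for labels plus scores (default), `"score"` for the
#'   oriented scores only.
#' @param ... Unused.
#' @return For `type = "class"`, a data frame with `substitution`,
#'   `amplitude`, `score` (raw deviation), `oriented_score` and `class`;
#'   for `type = "score"`, a numeric vector.
#' @export
predict.ism_fit <- function(object, newdata = NULL,
                            type = c("class", "score"), ...) {
  type <- match.arg(type)
  check_found(object)
  if (is.null(newdata)) {
    vtab <- object$variants
    amp <- object$scores[, object$frequency_index] + object$cutoff
  } else {
    if (is.data.frame(newdata)) newdata <- newdata$substitution
    vtab <- parse_variant(newdata)
    amp <- vapply(seq_len(nrow(vtab)), function(i) {
      s <- informational_spectrum(
        apply_variant(object$wildtype, vtab[i, , drop = FALSE]))
      s$amplitude[object$frequency_index]
    }, numeric(1))
  }
  raw <- amp - object$cutoff
  osc <- oriented_score(raw, object$orientation)
  if (type == "score") return(unname(osc))
  data.frame(substitution = vtab$substitution,
             amplitude = unname(amp),
             score = unname(raw),
             oriented_score = unname(osc),
             class = unname(classify_amplitude(amp, object)),
             stringsAsFactors = FALSE)
}

#' @export
print.ism_fit <- function(x, ...) {
  cat("ISM variant classifier",
      if (!is.null(x$gene)) paste0("for ", x$gene) else "", "\n")
  cat(sprintf("  wild type: N = %d residues, %d frequency bins\n",
              x$wt_spectrum$source_length, length(x$wt_spectrum$frequency)))
  cat(sprintf("  training variants: %d MUT, %d SNP\n",
              sum(x$labels == "MUT"), sum(x$labels == "SNP")))
  if (x$found) {
    cat(sprintf("  classifier frequency: F(%.3f) (bin %d), p = %.4g after %d test(s)\n",
                x$frequency, x$frequency_index, x$p_value, x$frequencies_tested))
    cat(sprintf("  cutoff amplitude: %.6g, orientation: %+d\n",
                x$cutoff, x$orientation))
  } else {
    cat(sprintf("  no classifier found: no frequency reached p < %g in %d tests\n",
                x$alpha, x$frequencies_tested))
  }
  invisible(x)
}

#' @export
coef.ism_fit <- function(object, ...) {
  c(frequency = object$frequency, cutoff = object$cutoff,
    orientation = as.numeric(object$orientation), p_value = object$p_value)
}

#' @export
summary.ism_fit <- function(object, ...) {
  res <- list(fit = object)
  if (object$found) {
    pr <- predict(object)
    res$training_evaluation <- evaluate_predictions(pr$oriented_score,
                                                    pr$class, object$labels)
  }
  class(res) <- "summary.ism_fit"
  res
}

#' @export
print.summary.ism_fit <- function(x, ...) {
  print(x$fit)
  cat("\nSelection trace (descending wild-type amplitude):\n")
  print(utils::head(x$fit$trace, 10L), row.names = FALSE)
  if (nrow(x$fit$trace) > 10L) cat("  ...", nrow(x$fit$trace), "rows\n")
  if (!is.null(x$training_evaluation)) {
    cat("\nIn-sample ")
    print(x$training_evaluation)
  }
  invisible(x)
}

#' @export
plot.ism_fit <- function(x, ...) {
  s <- x$wt_spectrum
  graphics::plot(s$frequency, s$amplitude, type = "h",
                 xlab = "frequency", ylab = "wild-type amplitude", ...)
  if (x$found) {
    graphics::points(x$frequency, x$cutoff, col = "red", pch = 19)
    graphics::legend("topright", bty = "n", col = "red", pch = 19,
                     legend = sprintf("classifier F(%.3f)", x$frequency))
  }
  invisible(x)
}

#' Cross-validate the classifier-frequency selection
#'
#' Randomly splits the labeled variants of one protein into `k` groups and,
#' leaving out each group in turn, re-runs the frequency selection on the
#' remaining k-1 groups. Stability of the selected frequency across folds
#' indicates that the choice is not driven by a few variants.
#'
#' @inheritParams ism_fit
#' @param k Number of folds (default 5).
#' @param seed Integer seed for the fold assignment.
#' @return Data frame with one row per fold: `fold`, `status` (`"selected"`,
#'   `"none"`, or `"degenerate"` when a training split loses one class),
#'   `frequency_index`, `frequency`, `p_value`.
#' @export
ism_cv <- function(wildtype, variants, labels = NULL, k = 5, seed = NULL,
                   alpha = 0.05, gene = NULL, scale = eiip_scale(),
                   exact = c("auto", "exact", "approx")) {
  exact <- match.arg(exact)
  if (is.data.frame(variants)) {
    if (is.null(labels) && !is.null(variants$label)) labels <- variants$label
    vtab <- parse_variant(variants$substitution)
  } else {
    vtab <- parse_variant(variants)
  }
  labels <- toupper(as.character(labels))
  n <- nrow(vtab)
  if (!is.null(seed)) set.seed(as.integer(seed))
  fold <- sample(rep_len(seq_len(k), n))

  # spectra computed once, reused across folds
  wt_spec <- informational_spectrum(wildtype, scale)
  spectra <- lapply(seq_len(n), function(i) {
    informational_spectrum(apply_variant(wildtype, vtab[i, , drop = FALSE]),
                           scale)
  })
  scores <- ism_scores(wt_spec, spectra)

  res <- lapply(seq_len(k), function(f) {
    keep <- fold != f
    lab <- labels[keep]
    if (sum(keep) < 2L || length(unique(lab)) < 2L) {
      return(data.frame(fold = f, status = "degenerate",
                        frequency_index = NA_integer_, frequency = NA_real_,
                        p_value = NA_real_))
    }
    sel <- select_frequency_from_scores(scores[keep, , drop = FALSE],
                                        wt_spec, lab, alpha, exact)
    data.frame(fold = f,
               status = if (sel$found) "selected" else "none",
               frequency_index = sel$frequency_index,
               frequency = sel$frequency,
               p_value = sel$p_value)
  })
  do.call(rbind, res)
}

#' Serialize a fitted ISM model to a key-value text file
#'
#' Writes everything [read_ism_model()] needs to rebuild a predictive model:
#' gene, selected frequency index and value, cutoff, orientation, p-value,
#' alpha, search depth, and the wild-type sequence itself (variant spectra
#' are recomputed at prediction time).
#'
#' @param model A fitted `ism_fit` with `found = TRUE`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_ism_model <- function(model, path) {
  check_found(model)
  lines <- c(
    paste0("gene\t", if (is.null(model$gene)) "NA" else model$gene),
    paste0("frequency_index\t", model$frequency_index),
    paste0("frequency\t", format(model$frequency, digits = 17)),
    paste0("cutoff\t", format(model$cutoff, digits = 17)),
    paste0("orientation\t", model$orientation),
    paste0("p_value\t", format(model$p_value, digits = 17)),
    paste0("alpha\t", format(model$alpha, digits = 17)),
    paste0("frequencies_tested\t", model$frequencies_tested),
    paste0("wildtype\t", model$wildtype))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_ism_model
#' @return `read_ism_model`: an object of class `ism_fit` (without training
#'   scores or trace) usable with [predict.ism_fit()].
#' @export
read_ism_model <- function(path) {
  kv <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = c("key", "value"))
  get <- function(k) kv$value[match(k, kv$key)]
  gene <- get("gene")
  structure(
    list(found = TRUE,
         gene = if (identical(gene, "NA")) NULL else gene,
         frequency_index = as.integer(get("frequency_index")),
         frequency = as.numeric(get("frequency")),
         cutoff = as.numeric(get("cutoff")),
         orientation = as.integer(get("orientation")),
         p_value = as.numeric(get("p_value")),
         alpha = as.numeric(get("alpha")),
         frequencies_tested = as.integer(get("frequencies_tested")),
         wildtype = get("wildtype"),
         wt_spectrum = informational_spectrum(get("wildtype")),
         labels = NULL, variants = NULL, scores = NULL),
    class = "ism_fit")
}
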