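#' Parse amino acid substitutions in `X123Y` / `p.X123Y` notation
#'
#' @param text Character vector of substitution strings (one-letter wild-type
#'   residue, 1-based position, one-letter alternate residue; an HGVS-style
#'   `p.` prefix is tolerated and stripped).
#' @return Data frame with one row per input and columns `substitution`
#'   (normalised, prefix-free, uppercase), `pos`, `wt` and `alt`.
#' @export
#' @examples
#' parse_variant(c("L149Q", "p.A384T"))
parse_variant <- function(text) {
  if (!is.character(text) || length(text) == 0L) {
    stop("text must be a non-empty character vector", call. = FALSE)
  }
  stripped <- toupper(sub("^p\\.", "", trimws(text)))
  m <- regmatches(stripped, regexec("^([A-Z])([0-9]+)([A-Z])$", stripped))
  bad <- which(lengths(m) != 4L)
  if (length(bad)) {
    stop("malformed substitution: '", text[bad[1L]], "'", call. = FALSE)
  }
  wt <- vapply(m, `[`, character(1), 2L)
  pos <- as.integer(vapply(m, `[`, character(1), 3L))
  alt <- vapply(m, `[`, character(1), 4L)
  noncanon <- !(wt %in% .canonical_residues) | !(alt %in% .canonical_residues)
  if (any(noncanon)) {
    stop("non-canonical residue in substitution: '",
         text[which(noncanon)[1L]], "'", call. = FALSE)
  }
  if (any(pos < 1L)) {
    stop("substitution position must be >= 1: '",
         text[which(pos < 1L)[1L]], "'", call. = FALSE)
  }
  same <- wt == alt
  if (any(same)) {
    stop("wild-type and alternate residue are identical: '",
         text[which(same)[1L]], "'", call. = FALSE)
  }
  data.frame(substitution = stripped, pos = pos, wt = wt, alt = alt,
             stringsAsFactors = FALSE)
}

#' Apply a substitution to a protein sequence
#'
#' @param sequence Protein sequence string.
#' @param variant A substitution string (`"K2R"`), or a one-row data frame
#'   with `pos`, `wt`, `alt` columns as produced by [parse_variant()].
#' @return The mutated sequence: same length, differing from the input only
#'   at the substituted position. The stated wild-type residue must match the
#'   sequence, otherwise a consistency error names the expected and found
#'   residues.
#' @export
#' @examples
#' apply_variant("MKL", "K2R")  # "MRL"
apply_variant <- function(sequence, variant) {
  if (is.character(variant)) variant <- parse_variant(variant)
  if (nrow(variant) != 1L) stop("variant must be a single substitution", call. = FALSE)
  residues <- as_residue_vector(sequence)
  pos <- variant$pos
  if (pos > length(residues)) {
    stop("position ", pos, " out of range for sequence of length ",
         length(residues), call. = FALSE)
  }
  found <- residues[pos]
  if (found != variant$wt) {
    stop("wild-type mismatch at position ", pos, ": variant states '",
         variant$wt, "' but sequence has '", found, "'", call. = FALSE)
  }
  residues[pos] <- variant$alt
  paste(residues, collapse = "")
}

#' Read a conserved-functional-domain (CFD) interval table
#'
#' Tab- or comma-delimited text with columns `gene`, `domain`, `start`,
#' `end`; coordinates are 1-based and inclusive on both ends. Intervals may
#' not overlap within a gene.
#'
#' @param path Path to the table. The default is the packaged annotation of
#'   the four myeloid-malignancy epigenetic regulators (ASXL1, EZH2, DNMT3A,
#'   TET2) used throughout the examples.
#' @return Data frame with columns `gene`, `domain`, `start`, `end`.
#' @export
read_domain_table <- function(path = system.file("extdata", "cfd_domains.tsv",
                                                 package = "ismvar")) {
  d <- read_delimited(path, c("gene", "domain", "start", "end"))
  d$start <- as.integer(d$start)
  d$end <- as.integer(d$end)
  if (anyNA(d$start) || anyNA(d$end)) {
    stop("non-integer interval bound in ", path, call. = FALSE)
  }
  if (any(d$start > d$end)) stop("interval with start > end in ", path, call. = FALSE)
  for (g in unique(d$gene)) {
    iv <- d[d$gene == g, , drop = FALSE]
    iv <- iv[order(iv$start), , drop = FALSE]
    if (nrow(iv) > 1L && any(iv$start[-1L] <= iv$end[-nrow(iv)])) {
      stop("overlapping domain intervals for gene ", g, call. = FALSE)
    }
  }
  d[, c("gene", "domain", "start", "end")]
}

#' Packaged CFD domain intervals
#'
#' Convenience accessor for the packaged domain-interval annotation
#' (HARE/ASXH/PHD for ASXL1, SANT1/SANT2/SET for EZH2, PWWP/PHD/MTase for
#' DNMT3A, BOX1/BOX2 for TET2).
#'
#' @return Data frame as from [read_domain_table()].
#' @export
cfd_domains <- function() read_domain_table()

#' Classify substitution positions as inside or outside conserved domains
#'
#' A position is `CFD` iff `start <= pos <= end` for some interval of its
#' gene (both bounds inclusive); otherwise `nCFD`. The classification is
#' exhaustive and exclusive. A gene absent from the annotation has no
#' conserved intervals, so all its positions are `nCFD`; if `strict = TRUE`
#' an unknown gene is an error instead.
#'
#' @param gene Character vector of gene identifiers (recycled to match `pos`).
#' @param pos Integer vector of 1-based substitution positions.
#' @param domains Domain table from [read_domain_table()]; defaults to the
#'   packaged annotation.
#' @param strict Error on genes absent from the annotation (default FALSE).
#' @return Character vector, `"CFD"` or `"nCFD"`, one per position.
#' @export
#' @examples
#' classify_region("ASXL1", c(5, 50, 83))  # nCFD, CFD, CFD
classify_region <- function(gene, pos, domains = cfd_domains(),
                            strict = FALSE) {
  if (length(gene) == 1L) gene <- rep(gene, length(pos))
  if (length(gene) != length(pos)) {
    stop("gene and pos lengths differ", call. = FALSE)
  }
  if (strict) {
    unknown <- setdiff(unique(gene), unique(domains$gene))
    if (length(unknown)) {
      stop("gene(s) absent from domain annotation: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  vapply(seq_along(pos), function(i) {
    iv <- domains[domains$gene == gene[i], , drop = FALSE]
    if (nrow(iv) && any(iv$start <= pos[i] & pos[i] <= iv$end)) "CFD" else "nCFD"
  }, character(1))
}

#' Read a labeled variant table
#'
#' Delimited text (tab or comma; autodetected) with a header naming at least
#' `gene`, `substitution` and `label` columns (case-insensitive); an optional
#' `disease` column is carried through. Labels must be `SNP` or `MUT`.
#' Duplicate (gene, substitution) rows are collapsed to one with a warning
#' (a substitution reported in several diseases is a single variant); a
#' substitution listed under *both* labels is conflicting and is excluded,
#' with a warning.
#'
#' @param path Path to the table.
#' @return Data frame with columns `gene`, `substitution`, `pos`, `wt`,
#'   `alt`, `label`.
#' @export
read_variant_table <- function(path) {
  d <- read_delimited(path, c("gene", "substitution", "label"))
  if (nrow(d) == 0L) {
    return(data.frame(gene = character(), substitution = character(),
                      pos = integer(), wt = character(), alt = character(),
                      label = character(), stringsAsFactors = FALSE))
  }
  d$label <- toupper(trimws(d$label))
  bad <- !(d$label %in% c("SNP", "MUT"))
  if (any(bad)) {
    stop("unknown label '", d$label[which(bad)[1L]],
         "' in ", path, " (expected SNP or MUT)", call. = FALSE)
  }
  parsed <- parse_variant(d$substitution)
  d$substitution <- parsed$substitution
  d$pos <- parsed$pos
  d$wt <- parsed$wt
  d$alt <- parsed$alt

  key <- paste(d$gene, d$substitution)
  # a key is conflicting iff it appears with both labels
  n_labels <- tapply(d$label, key, function(l) length(unique(l)))
  conflict_keys <- names(n_labels)[n_labels > 1L]
  if (length(conflict_keys)) {
    warning(length(conflict_keys),
            " variant(s) labeled both SNP and MUT excluded: ",
            paste(utils::head(conflict_keys, 5L), collapse = "; "),
            call. = FALSE)
    d <- d[!(key %in% conflict_keys), , drop = FALSE]
    key <- paste(d$gene, d$substitution)
  }
  if (anyDuplicated(key)) {
    warning(sum(duplicated(key)), " duplicate (gene, substitution) row(s) collapsed",
            call. = FALSE)
    d <- d[!duplicated(key), , drop = FALSE]
  }
  rownames(d) <- NULL
  d[, intersect(c("gene", "substitution", "pos", "wt", "alt", "label", "disease"),
                names(d))]
}

#' Summarize a variant dataset by gene, label and domain region
#'
#' Cross-tabulates variants by gene, class label (SNP/MUT) and position
#' relative to conserved functional domains (CFD/nCFD). Every variant falls
#' in exactly one cell, so the counts partition the dataset.
#'
#' @param variants Data frame from [read_variant_table()].
#' @param domains Domain table from [read_domain_table()].
#' @return List with `by_gene` (data frame: gene, SNP_nCFD, SNP_CFD,
#'   MUT_nCFD, MUT_CFD, total), `by_region` (named vector: CFD, nCFD),
#'   `by_label` (named vector: SNP, MUT) and `total`.
#' @export
summarize_dataset <- function(variants, domains = cfd_domains()) {
  if (nrow(variants) == 0L) {
    return(list(by_gene = data.frame(gene = character(),
                                     SNP_nCFD = integer(), SNP_CFD = integer(),
                                     MUT_nCFD = integer(), MUT_CFD = integer(),
                                     total = integer()),
                by_region = c(CFD = 0L, nCFD = 0L),
                by_label = c(SNP = 0L, MUT = 0L), total = 0L))
  }
  region <- classify_region(variants$gene, variants$pos, domains)
  genes <- unique(variants$gene)
  cell <- function(g, lab, reg) {
    sum(variants$gene == g & variants$label == lab & region == reg)
  }
  by_gene <- data.frame(
    gene = genes,
    SNP_nCFD = vapply(genes, cell, integer(1), lab = "SNP", reg = "nCFD"),
    SNP_CFD = vapply(genes, cell, integer(1), lab = "SNP", reg = "CFD"),
    MUT_nCFD = vapply(genes, cell, integer(1), lab = "MUT", reg = "nCFD"),
    MUT_CFD = vapply(genes, cell, integer(1), lab = "MUT", reg = "CFD"),
    row.names = NULL, stringsAsFactors = FALSE)
  by_gene$total <- rowSums(by_gene[, 2:5])
  list(by_gene = by_gene,
       by_region = c(CFD = sum(region == "CFD"), nCFD = sum(region == "nCFD")),
       by_label = c(SNP = sum(variants$label == "SNP"),
                    MUT = sum(variants$label == "MUT")),
       total = nrow(variants))
}

# Delimiter-autodetecting reader for small tables; lowercases and checks the
# header for the required columns.
read_delimited <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) {
    stop("empty file (no header): ", path, call. = FALSE)
  }
  sep <- if (grepl("\t", first)) "\t" else if (grepl(",", first)) "," else ""
  d <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE, check.names = FALSE,
                         comment.char = "", quote = "\"",
                         blank.lines.skip = TRUE)
  names(d) <- tolower(trimws(names(d)))
  missing <- setdiff(required, names(d))
  if (length(missing)) {
    stop("missing column(s) ", paste(missing, collapse = ", "),
         " in ", path, call. = FALSE)
  }
  d
}
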