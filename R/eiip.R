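# Electron-ion interaction potential (EIIP) values, in Rydbergs, for the 20
# canonical residues. Leucine/isoleucine share 0, serine/cysteine share 0.0829.
.eiip_default <- c(
  L = 0.0000, I = 0.0000, N = 0.0036, G = 0.0050, V = 0.0057,
  E = 0.0058, P = 0.0198, H = 0.0242, K = 0.0371, A = 0.0373,
  Y = 0.0516, W = 0.0548, Q = 0.0761, M = 0.0823, S = 0.0829,
  C = 0.0829, T = 0.0941, F = 0.0954, R = 0.0956, D = 0.1263
)

.canonical_residues <- names(.eiip_default)

#' EIIP encoding scale
#'
#' Returns the electron-ion interaction potential (EIIP) value, in Rydberg
#' units, for each of the 20 canonical amino acids, as a named numeric vector
#' keyed by one-letter residue code. The EIIP approximates the energy of a
#' residue's valence electrons; its distribution along a protein sequence
#' carries periodicities that correlate with the protein's long-range
#' interactions, which is what the informational spectrum extracts.
#'
#' Alternative scales can be loaded from a two-column delimited text file
#' (residue, value) with [read_eiip_scale()] and passed wherever a `scale`
#' argument is accepted.
#'
#' @return Named numeric vector of length 20; names are one-letter residue
#'   codes, values are EIIP in Rydbergs (all within \[0, 0.13\]).
#' @seealso [encode_sequence()], [read_eiip_scale()], [write_eiip_scale()]
#' @export
#' @examples
#' eiip_scale()[c("L", "I", "N", "D")]
eiip_scale <- function() {
  .eiip_default
}

validate_eiip_scale <- function(scale) {
  if (!is.numeric(scale) || is.null(names(scale))) {
    stop("EIIP scale must be a named numeric vector", call. = FALSE)
  }
  missing <- setdiff(.canonical_residues, names(scale))
  if (length(missing)) {
    stop("EIIP scale is missing residues: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  extra <- setdiff(names(scale), .canonical_residues)
  if (length(extra)) {
    stop("EIIP scale has non-canonical residues: ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  if (anyNA(scale)) stop("EIIP scale contains NA values", call. = FALSE)
  invisible(scale)
}

#' Read an EIIP-style residue scale from a delimited file
#'
#' The file must have two columns (residue one-letter code, numeric value),
#' with or without a header; tab, comma or whitespace separated.
#'
#' @param path Path to the scale file.
#' @return Named numeric vector keyed by residue, validated to cover exactly
#'   the 20 canonical residues.
#' @export
read_eiip_scale <- function(path) {
  raw <- utils::read.table(path, header = FALSE, sep = "",
                           stringsAsFactors = FALSE,
                           col.names = c("residue", "value"),
                           colClasses = c("character", "character"))
  # tolerate a header row
  suppressWarnings(vals <- as.numeric(raw$value))
  if (is.na(vals[1]) && nrow(raw) > 1) {
    raw <- raw[-1, , drop = FALSE]
    vals <- as.numeric(raw$value)
  }
  if (anyNA(vals)) stop("non-numeric value in scale file: ", path, call. = FALSE)
  scale <- stats::setNames(vals, toupper(raw$residue))
  validate_eiip_scale(scale)
  scale
}

#' Write a residue scale to a two-column tab-delimited file
#'
#' @param scale Named numeric vector (residue -> value).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_eiip_scale <- function(scale, path) {
  validate_eiip_scale(scale)
  utils::write.table(
    data.frame(residue = names(scale), value = unname(scale)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Encode a protein sequence as an EIIP numeric series
#'
#' Maps each residue of a protein sequence to its electron-ion interaction
#' potential, producing the numeric series whose discrete Fourier spectrum is
#' the informational spectrum. Input is uppercased before lookup.
#'
#' @param sequence Protein sequence: a single string of one-letter residue
#'   codes, or a character vector of single residues.
#' @param scale Residue-to-value map, default [eiip_scale()].
#' @param unknown How to handle non-canonical characters (X, B, Z, U, `*`,
#'   gaps...): `"error"` (default) rejects them, naming the offending
#'   positions; `"mean"` imputes the mean EIIP of the canonical residues in
#'   the sequence.
#' @return Numeric vector of the same length as the sequence (Rydberg units).
#' @export
#' @examples
#' encode_sequence("LIN")   # c(0.0000, 0.0000, 0.0036)
encode_sequence <- function(sequence, scale = eiip_scale(),
                            unknown = c("error", "mean")) {
  unknown <- match.arg(unknown)
  validate_eiip_scale(scale)
  residues <- as_residue_vector(sequence)
  if (length(residues) == 0L) {
    stop("sequence is empty", call. = FALSE)
  }
  values <- unname(scale[residues])
  bad <- which(is.na(values))
  if (length(bad)) {
    if (unknown == "error") {
      stop("non-canonical residue(s) '",
           paste(unique(residues[bad]), collapse = "', '"),
           "' at position(s) ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    if (length(bad) == length(values)) {
      stop("sequence has no canonical residues to impute from", call. = FALSE)
    }
    values[bad] <- mean(values[-bad])
  }
  values
}

# Split a sequence given as one string (or residue vector) into uppercase
# single characters.
as_residue_vector <- function(sequence) {
  if (!is.character(sequence)) {
    stop("sequence must be a character string", call. = FALSE)
  }
  if (length(sequence) == 1L) {
    sequence <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  } else if (any(nchar(sequence) != 1L)) {
    stop("sequence must be a single string or a vector of single residues",
         call. = FALSE)
  }
  toupper(sequence)
}

#' Read protein sequences from a FASTA file
#'
#' Standard single- or multi-record protein FASTA. The record identifier is
#' the first whitespace-delimited token of the description line.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of uppercase protein sequences.
#' @export
read_protein_fasta <- function(path) {
  recs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                             forceDNAtolower = FALSE)
  out <- toupper(vapply(recs, function(r) as.character(r)[1L], character(1)))
  names(out) <- names(recs)
  out
}

#' Write protein sequences to a FASTA file
#'
#' @param sequences Named character vector of protein sequences.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_protein_fasta <- function(sequences, path) {
  if (is.null(names(sequences)) || any(!nzchar(names(sequences)))) {
    stop("sequences must be named", call. = FALSE)
  }
  seqinr::write.fasta(as.list(unname(sequences)), names = names(sequences),
                      file.out = path, as.string = TRUE, nbchar = 60)
  invisible(path)
}
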