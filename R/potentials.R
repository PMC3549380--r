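#' The 20 standard residue three-letter codes
#' @keywords internal
.standardResidues <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU",
                       "GLY", "HIS", "ILE", "LEU", "LYS", "MET", "PHE",
                       "PRO", "SER", "THR", "TRP", "TYR", "VAL")

# Common nonstandard / variant residue names mapped onto standard types.
.residueAliases <- c(MSE = "MET", SEC = "CYS", CSE = "CYS",
                     HSD = "HIS", HSE = "HIS", HSP = "HIS",
                     HID = "HIS", HIE = "HIS", HIP = "HIS",
                     CYX = "CYS", CYM = "CYS", ASH = "ASP", GLH = "GLU",
                     LYN = "LYS", ARN = "ARG")

#' Load a residue contact-potential table
#'
#' Reads a whitespace- or comma-delimited 20 x 20 matrix (full or lower
#' triangular) with three-letter residue codes as row and column headers and
#' validates it: all 210 unordered residue pairs present, symmetric to 1e-9,
#' and (by default) global minimum/maximum equal to -1.19 / 0.76, the printed
#' range of the self-consistent contact potential the link weights emulate.
#'
#' The bundled default table is a synthetic reconstruction (see
#' `system.file("extdata", "README.md", package = "aanet")`): pairwise
#' energies derived from a published one-body contact-energy scale plus a
#' like-charge repulsion term, calibrated so the global extremes match the
#' published -1.19 / 0.76. Any table in the same format can be dropped in.
#'
#' @param source path to a table file, or `NULL` for the bundled default.
#' @param rangeCheck validate the global extremes against -1.19 / 0.76
#'   (printed precision, 0.005 tolerance). Set `FALSE` to load an
#'   alternative potential.
#' @return a [ContactPotential-class] object.
#' @examples
#' pot <- loadPotentialTable()
#' range(energies(pot))
#' @export
loadPotentialTable <- function(source = NULL, rangeCheck = TRUE) {
  provenance <- if (is.null(source)) {
    source <- system.file("extdata", "contact_potential_synthetic.tsv",
                          package = "aanet", mustWork = TRUE)
    "bundled synthetic table calibrated to the published [-1.19, 0.76] range"
  } else sprintf("loaded from %s", source)
  raw <- read.table(source, header = TRUE, sep = "", check.names = FALSE,
                    row.names = 1, stringsAsFactors = FALSE,
                    comment.char = "#", fill = TRUE)
  if (ncol(raw) == 1 && grepl(",", readLines(source, n = 1)))
    raw <- read.table(source, header = TRUE, sep = ",", check.names = FALSE,
                      row.names = 1, stringsAsFactors = FALSE, fill = TRUE)
  m <- as.matrix(raw)
  codes <- .standardResidues
  missingCodes <- setdiff(codes, intersect(rownames(m), colnames(m)))
  if (length(missingCodes))
    stop("contact table is missing residue(s): ",
         paste(missingCodes, collapse = ", "))
  m <- m[codes, codes]
  # lower-triangular input: mirror into the empty half
  if (anyNA(m)) {
    lo <- is.na(m) & !is.na(t(m))
    m[lo] <- t(m)[lo]
    if (anyNA(m)) {
      bad <- which(is.na(m), arr.ind = TRUE)[1, ]
      stop(sprintf("contact table lacks an energy for pair %s-%s",
                   codes[bad[1]], codes[bad[2]]))
    }
  }
  asym <- max(abs(m - t(m)))
  if (asym > 1e-9)
    stop(sprintf("contact table is asymmetric (max |e(a,b)-e(b,a)| = %g)",
                 asym))
  m <- (m + t(m)) / 2
  if (rangeCheck &&
      (abs(min(m) - (-1.19)) > 5e-3 || abs(max(m) - 0.76) > 5e-3))
    stop(sprintf(
      "contact table range [%.3f, %.3f] does not match the expected [-1.19, 0.76]",
      min(m), max(m)))
  new("ContactPotential", energies = m, provenance = provenance)
}

#' Write a contact-potential table
#'
#' Serializes the full 20 x 20 matrix as tab-separated text in the format
#' [loadPotentialTable()] reads; a write/read round trip reproduces every
#' entry exactly.
#'
#' @param table a [ContactPotential-class] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writePotentialTable <- function(table, path) {
  stopifnot(is(table, "ContactPotential"))
  e <- energies(table)
  df <- data.frame(RES = rownames(e),
                   format(e, digits = 17, trim = TRUE, scientific = FALSE),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Map a residue code to a standard type
#'
#' @param code three-letter residue code.
#' @param strict if `TRUE`, unmappable codes raise an error; otherwise `NA`
#'   is returned with a warning (caller skips the node).
#' @return a standard three-letter code, or `NA` in lenient mode.
#' @export
mapResidueCode <- function(code, strict = FALSE) {
  code <- toupper(code)
  out <- ifelse(code %in% .standardResidues, code,
                unname(.residueAliases[code]))
  if (anyNA(out)) {
    bad <- unique(code[is.na(out)])
    if (strict)
      stop("unmappable residue code(s): ", paste(bad, collapse = ", "))
    warning("skipping unmappable residue code(s): ",
            paste(bad, collapse = ", "))
  }
  out
}

#' Look up a pairwise contact energy
#'
#' Returns the contact energy w for a residue-type pair; negative values are
#' attractive (similar weight), positive repulsive (dissimilar weight).
#' Nonstandard codes are mapped through a small alias table (e.g. MSE to
#' MET); in strict mode anything unmappable is an error.
#'
#' @param table a [ContactPotential-class] object.
#' @param resA,resB three-letter residue codes.
#' @param strict passed to [mapResidueCode()].
#' @return numeric contact energy (RT units), `NA` if a code could not be
#'   mapped in lenient mode.
#' @examples
#' pot <- loadPotentialTable()
#' lookupWeight(pot, "ALA", "LEU")
#' @export
lookupWeight <- function(table, resA, resB, strict = FALSE) {
  stopifnot(is(table, "ContactPotential"))
  a <- mapResidueCode(resA, strict = strict)
  b <- mapResidueCode(resB, strict = strict)
  out <- rep(NA_real_, length(a))
  ok <- !is.na(a) & !is.na(b)
  out[ok] <- energies(table)[cbind(a[ok], b[ok])]
  out
}
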