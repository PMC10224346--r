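#' Read a FASTA file into sequence records
#'
#' Thin wrapper over [Biostrings::readBStringSet()] returning a plain list of
#' records, one per header, in file order.  Residues are uppercased.
#'
#' @param path Path to a FASTA file.
#' @param moltype `"nucleotide"` or `"protein"`; stored on each record and
#'   checked against the residue alphabet.
#' @return A list of `mt_seq` records, each with fields `id` (first header
#'   token), `description` (remainder of the header), `residues` and
#'   `moltype`.
#' @export
read_fasta <- function(path, moltype = c("nucleotide", "protein")) {
  moltype <- match.arg(moltype)
  stopifnot(file.exists(path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no records in FASTA file '", path, "'")
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  seqs <- toupper(as.character(set))
  empty <- !nzchar(seqs)
  if (any(empty)) {
    stop("record '", ids[which(empty)[1L]], "' has an empty sequence")
  }
  recs <- Map(function(id, d, s) mt_seq(id, s, moltype = moltype, description = d),
              ids, desc, seqs)
  names(recs) <- ids
  unname(recs)
}

#' Construct a sequence record
#'
#' @param id Non-empty identifier token (no whitespace).
#' @param residues Non-empty residue string; uppercased on construction.
#' @param moltype `"nucleotide"` (alphabet `ACGTN`) or `"protein"` (the 20
#'   amino-acid letters plus `X` and `*`).
#' @param description Free-text description.
#' @return An object of class `mt_seq`.
#' @export
mt_seq <- function(id, residues, moltype = c("nucleotide", "protein"),
                   description = "") {
  moltype <- match.arg(moltype)
  id <- as.character(id)
  residues <- toupper(as.character(residues))
  if (!nzchar(id) || grepl("\\s", id)) stop("record id must be a non-empty token")
  if (!nzchar(residues)) stop("record '", id, "' has an empty sequence")
  alphabet <- if (moltype == "nucleotide") "^[ACGTN]+$" else "^[ACDEFGHIKLMNPQRSTVWYX*]+$"
  if (!grepl(alphabet, residues)) {
    stop("record '", id, "' contains characters outside the ", moltype, " alphabet")
  }
  structure(list(id = id, description = description,
                 residues = residues, moltype = moltype),
            class = "mt_seq")
}

#' @export
print.mt_seq <- function(x, ...) {
  cat(sprintf("<mt_seq %s> %s, %d residues\n", x$id, x$moltype, nchar(x$residues)))
  invisible(x)
}

#' Write sequence records to FASTA
#'
#' @param records List of `mt_seq` records.
#' @param path Output file path.
#' @param width Line width for wrapping.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(records, path, width = 70L) {
  if (inherits(records, "mt_seq")) records <- list(records)
  set <- Biostrings::BStringSet(vapply(records, `[[`, "", "residues"))
  names(set) <- vapply(records, function(r) {
    if (nzchar(r$description)) paste(r$id, r$description) else r$id
  }, "")
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}
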