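#' Parse one printed length-table cell
#'
#' The published cluster tables print lengths in a small dialect: plain
#' integers (optionally with comma thousands separators), approximate values
#' prefixed with a plus-minus sign, ranges joined by a hyphen or en-dash
#' (`"7186-7219"`), per-copy values for tandem Mt1 duplicates
#' (`"611(a)-578(b)"`), and blank cells for measurements the study could not
#' make.
#'
#' @param text A single raw cell string.
#' @return A `length_cell` with fields `value` (integer bp, `NA` when the
#'   cell is blank), `approximate` (logical), `range_high` (integer or
#'   `NULL`) and `multi` (named integer vector keyed by copy letter, or
#'   `NULL`).
#' @export
parse_length_cell <- function(text) {
  stopifnot(length(text) == 1L)
  raw <- if (is.na(text)) "" else trimws(text)
  txt <- gsub(",", "", raw, fixed = TRUE)
  cell <- function(value = NA_integer_, approximate = FALSE,
                   range_high = NULL, multi = NULL) {
    structure(list(value = as.integer(value), approximate = approximate,
                   range_high = range_high, multi = multi),
              class = "length_cell")
  }
  if (!nzchar(txt)) return(cell())
  if (grepl("^±\\s*[0-9]+$", txt)) {
    return(cell(as.integer(sub("^±\\s*", "", txt)), approximate = TRUE))
  }
  # per-copy cells: one or more "<n>(<letter>)" joined by - or en-dash
  if (grepl("^[0-9]+\\([a-z]\\)([-–][0-9]+\\([a-z]\\))*$", txt)) {
    parts <- strsplit(txt, "[-–]")[[1L]]
    vals <- as.integer(sub("^([0-9]+)\\(.*$", "\\1", parts))
    labs <- sub("^[0-9]+\\(([a-z])\\)$", "\\1", parts)
    return(cell(vals[1L], multi = setNames(vals, labs)))
  }
  if (grepl("^[0-9]+[-–][0-9]+$", txt)) {
    ab <- as.integer(strsplit(txt, "[-–]")[[1L]])
    if (ab[2L] < ab[1L]) stop("range cell '", raw, "' has high < low")
    return(cell(ab[1L], range_high = ab[2L]))
  }
  if (grepl("^[0-9]+$", txt)) return(cell(as.integer(txt)))
  stop("unparsable length cell: '", raw, "'")
}

#' Format a length cell back to its printed form
#'
#' Inverse of [parse_length_cell()]: `parse_length_cell(format(cell))`
#' recovers the cell (en-dash is the canonical range separator on output).
#'
#' @param x A `length_cell`.
#' @param ... Ignored.
#' @export
format.length_cell <- function(x, ...) {
  if (!is.null(x$multi)) {
    return(paste(sprintf("%d(%s)", unname(x$multi), names(x$multi)), collapse = "-"))
  }
  if (!is.null(x$range_high)) return(sprintf("%d–%d", x$value, x$range_high))
  if (is.na(x$value)) return("")
  if (x$approximate) return(sprintf("±%d", x$value))
  sprintf("%d", x$value)
}

#' @export
print.length_cell <- function(x, ...) {
  cat("<length_cell>", format(x), "\n")
  invisible(x)
}

.fixture_files <- c(
  species_inventory = "species_inventory.tsv",
  igr_lengths       = "igr_lengths.tsv",
  exon_lengths      = "exon_lengths.tsv",
  intron_lengths    = "intron_lengths.tsv"
)

#' Load a packaged table transcription
#'
#' The package ships TSV transcriptions of the published per-species
#' measurements of the cetacean metallothionein cluster: the species/family
#' inventory, intergenic-region (IGR) lengths between adjacent cluster
#' genes, exon lengths (4 genes x 3 exons) and intron lengths (4 genes x 2
#' introns).  Only per-species cells are stored; the published summary rows
#' (average, SD, min-max) are deliberately absent so that downstream code
#' recomputes them.
#'
#' @param name One of `"species_inventory"`, `"igr_lengths"`,
#'   `"exon_lengths"`, `"intron_lengths"`.
#' @return An object of class `mt_fixture_table`: a list with `name`, `data`
#'   (the raw character data frame, one row per species) and, for the three
#'   length tables, `cells` — a named list mapping each measurement column to
#'   a list of `length_cell` objects, one per species row.
#' @export
load_fixture_table <- function(name = c("species_inventory", "igr_lengths",
                                        "exon_lengths", "intron_lengths")) {
  name <- match.arg(name)
  path <- system.file("extdata", .fixture_files[[name]], package = "cetamt",
                      mustWork = TRUE)
  data <- read.delim(path, check.names = FALSE, colClasses = "character",
                     na.strings = NULL, fileEncoding = "UTF-8")
  if (anyDuplicated(data$species)) stop("duplicate species in fixture ", name)
  cells <- NULL
  if (name != "species_inventory") {
    value_cols <- setdiff(names(data), c("species", "family"))
    cells <- lapply(data[value_cols], function(col) lapply(col, parse_length_cell))
    names(cells) <- value_cols
  }
  structure(list(name = name, data = data, cells = cells),
            class = "mt_fixture_table")
}

#' @export
print.mt_fixture_table <- function(x, ...) {
  cat(sprintf("<mt_fixture_table %s> %d species x %d columns\n",
              x$name, nrow(x$data), ncol(x$data) - 1L))
  invisible(x)
}
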