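#' Restriction enzymes with degenerate recognition sites
#'
#' A `restriction_enzyme` holds a recognition motif over the IUPAC DNA
#' alphabet together with the top- and bottom-strand cut offsets, both
#' measured in bases from the start of the recognition sequence. The cut
#' offsets are fixed biochemical facts (REBASE convention); the bundled
#' table covers the enzymes commonly screened for ddRAD work.
#'
#' @param name Short enzyme identifier, e.g. `"AvaII"`.
#' @param recognition Recognition sequence, 5'→3', IUPAC letters only.
#' @param cut_offset_top Bases from recognition start to the top-strand cut.
#' @param cut_offset_bottom Bases from recognition start to the bottom-strand
#'   cut (expressed in top-strand coordinates).
#' @return An object of class `restriction_enzyme`: a list with fields
#'   `name`, `recognition`, `cut_offset_top`, `cut_offset_bottom` and the
#'   derived logical `self_rc` (TRUE when the expanded recognition set is
#'   closed under reverse complement, so minus-strand scanning adds nothing).
#' @examples
#' restriction_enzyme("AvaII", "GGWCC", 1, 4)
#' @export
restriction_enzyme <- function(name, recognition, cut_offset_top, cut_offset_bottom) {
  recognition <- toupper(recognition)
  check_iupac(recognition)
  len <- nchar(recognition)
  if (cut_offset_top < 0 || cut_offset_top > len ||
      cut_offset_bottom < 0 || cut_offset_bottom > len) {
    abort(sprintf("Cut offsets for %s must lie in [0, %d].", name, len))
  }
  enz <- structure(
    list(
      name = name,
      recognition = recognition,
      cut_offset_top = as.integer(cut_offset_top),
      cut_offset_bottom = as.integer(cut_offset_bottom)
    ),
    class = "restriction_enzyme"
  )
  enz$self_rc <- is_self_rc(enz)
  enz
}

#' @export
print.restriction_enzyme <- function(x, ...) {
  cat(sprintf(
    "<restriction_enzyme> %s  %s  cut top %d / bottom %d  %s\n",
    x$name, x$recognition, x$cut_offset_top, x$cut_offset_bottom,
    if (x$self_rc) "(palindromic match set)" else "(strand-specific)"
  ))
  invisible(x)
}

check_iupac <- function(pattern) {
  if (!nzchar(pattern)) abort("Recognition pattern must be non-empty.")
  letters <- strsplit(pattern, "")[[1]]
  bad <- setdiff(letters, names(Biostrings::IUPAC_CODE_MAP))
  if (length(bad) > 0) {
    abort(sprintf("Invalid IUPAC character(s) in pattern: %s",
                  paste(unique(bad), collapse = ", ")))
  }
  invisible(pattern)
}

#' Expand an IUPAC pattern to its concrete DNA strings
#'
#' @param pattern IUPAC DNA string.
#' @return Character vector of all concrete ACGT strings matching `pattern`;
#'   its length is the product of the per-position degeneracies.
#' @examples
#' expand_iupac("GGWCC")
#' @export
expand_iupac <- function(pattern) {
  check_iupac(toupper(pattern))
  choices <- strsplit(Biostrings::IUPAC_CODE_MAP[strsplit(toupper(pattern), "")[[1]]], "")
  out <- do.call(expand.grid, c(rev(choices), list(stringsAsFactors = FALSE)))
  sort(apply(out[, rev(seq_along(choices)), drop = FALSE], 1, paste0, collapse = ""))
}

#' Is an enzyme's recognition set closed under reverse complement?
#'
#' @param enzyme A [restriction_enzyme()] (or a bare IUPAC pattern).
#' @return TRUE iff every concrete expansion's reverse complement is itself
#'   in the expansion set; such enzymes need no minus-strand scan.
#' @export
is_self_rc <- function(enzyme) {
  pattern <- if (inherits(enzyme, "restriction_enzyme")) enzyme$recognition else toupper(enzyme)
  fwd <- expand_iupac(pattern)
  setequal(fwd, revcomp(fwd))
}

# Bundled enzyme table (REBASE-standard offsets); user enzymes load from the
# same TSV format via load_enzyme_table().
builtin_enzyme_path <- function() {
  system.file("extdata", "enzymes.tsv", package = "ddradkit", mustWork = TRUE)
}

#' Load a restriction-enzyme table
#'
#' Reads a TSV with columns `name`, `recognition`, `cut_offset_top`,
#' `cut_offset_bottom`. With no argument, returns the bundled table
#' (SbfI, EcoRI, MluCI, MspI, PstI, AvaII, NlaIII).
#'
#' @param path Optional path to a user TSV in the same format.
#' @return A tibble with one row per enzyme plus a `self_rc` column.
#' @export
load_enzyme_table <- function(path = NULL) {
  if (is.null(path) && !is.null(.enzyme_cache$builtin)) {
    return(.enzyme_cache$builtin)
  }
  builtin <- is.null(path)
  path <- path %||% builtin_enzyme_path()
  tab <- readr::read_tsv(path, col_types = readr::cols(
    name = readr::col_character(),
    recognition = readr::col_character(),
    cut_offset_top = readr::col_integer(),
    cut_offset_bottom = readr::col_integer()
  ))
  tab <- dplyr::mutate(tab, self_rc = vapply(.data$recognition, is_self_rc,
                                             logical(1), USE.NAMES = FALSE))
  if (builtin) .enzyme_cache$builtin <- tab
  tab
}

# session cache for the bundled table and constructed enzymes
.enzyme_cache <- new.env(parent = emptyenv())

#' Look up an enzyme by name
#'
#' @param name Enzyme name as in the table (case-sensitive, e.g. `"MspI"`).
#' @param table Optional tibble from [load_enzyme_table()]; defaults to the
#'   bundled table.
#' @return A [restriction_enzyme()].
#' @export
get_enzyme <- function(name, table = NULL) {
  if (inherits(name, "restriction_enzyme")) return(name)
  if (is.null(table)) {
    cached <- .enzyme_cache[[paste0("enzyme_", name)]]
    if (!is.null(cached)) return(cached)
  }
  lookup <- table %||% load_enzyme_table()
  row <- lookup[lookup$name == name, ]
  if (nrow(row) != 1) {
    abort(sprintf("Enzyme '%s' not found in the enzyme table (have: %s).",
                  name, paste(lookup$name, collapse = ", ")))
  }
  enz <- restriction_enzyme(row$name, row$recognition,
                            row$cut_offset_top, row$cut_offset_bottom)
  if (is.null(table)) .enzyme_cache[[paste0("enzyme_", name)]] <- enz
  enz
}

#' Locate an enzyme's cut sites on DNA sequences
#'
#' Scans every contig for all matches of the enzyme's expanded recognition
#' set on the forward strand, plus minus-strand matches when the set is not
#' closed under reverse complement. Overlapping matches are all reported.
#' Windows containing a non-ACGT character (assembly gaps, ambiguity codes)
#' never match.
#'
#' @param sequence Genome input accepted by [double_digest()]: FASTA path,
#'   DNAStringSet, or character vector of sequences.
#' @param enzyme A [restriction_enzyme()] or enzyme name.
#' @return A tibble sorted by `(contig, match_start)` with columns `contig`,
#'   `match_start` (0-based), `cut_pos` (0-based top-strand cut coordinate),
#'   `enzyme`, `strand`.
#' @examples
#' find_sites("AGGACCA", get_enzyme("AvaII"))
#' @export
find_sites <- function(sequence, enzyme) {
  enzyme <- get_enzyme(enzyme)
  seqs <- as_genome(sequence)
  len <- nchar(enzyme$recognition)

  fwd <- expand_iupac(enzyme$recognition)
  # Minus-strand matches are located by scanning for the reverse complement
  # of the recognition set on the top strand.
  rev_extra <- if (enzyme$self_rc) character(0) else setdiff(revcomp(fwd), fwd)

  one_contig <- function(contig, subject) {
    hit_rows <- function(patterns, strand) {
      starts <- unlist(lapply(patterns, function(p) {
        Biostrings::start(Biostrings::matchPattern(p, subject, fixed = TRUE))
      }))
      if (length(starts) == 0) return(NULL)
      ms <- sort(unique(as.integer(starts) - 1L))
      cut <- if (strand == "+") {
        ms + enzyme$cut_offset_top
      } else {
        # a minus-strand match cuts the top strand at the mirrored offset
        ms + (len - enzyme$cut_offset_bottom)
      }
      tibble(contig = contig, match_start = ms, cut_pos = cut,
             enzyme = enzyme$name, strand = strand)
    }
    dplyr::bind_rows(hit_rows(fwd, "+"), hit_rows(rev_extra, "-"))
  }

  out <- purrr::map2(names(seqs), as.list(seqs), one_contig)
  out <- dplyr::bind_rows(out)
  if (nrow(out) == 0) {
    return(tibble(contig = character(), match_start = integer(),
                  cut_pos = integer(), enzyme = character(), strand = character()))
  }
  dplyr::arrange(out, .data$contig, .data$match_start)
}

# Remnant read immediately after the barcode on read1 (P1 side): the
# recognition tail downstream of the outermost cut, as an IUPAC pattern
# (AvaII G^GWCC -> "GWCC"; PstI CTGCA^G -> "TGCAG").
p1_remnant <- function(enzyme) {
  enzyme <- get_enzyme(enzyme)
  lo <- min(enzyme$cut_offset_top, enzyme$cut_offset_bottom)
  substr(enzyme$recognition, lo + 1, nchar(enzyme$recognition))
}

# Remnant at the start of read2 (P2 side): reverse complement of the
# recognition head up to the outermost cut (MspI C^CGG -> "CGG").
p2_remnant <- function(enzyme) {
  enzyme <- get_enzyme(enzyme)
  hi <- max(enzyme$cut_offset_top, enzyme$cut_offset_bottom)
  revcomp(substr(enzyme$recognition, 1, hi))
}
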