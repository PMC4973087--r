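#' Generate a variable-length inline barcode set
#'
#' Searches (rejection/greedy over random candidates) for a set of inline
#' barcodes of staggered lengths satisfying the design constraints that make
#' variable-length barcodes demultiplexable and sequencer-friendly:
#'
#' * prefix-free — no barcode is a prefix of another (with variable lengths
#'   the restriction remnant, not a fixed position, delimits the barcode);
#' * pairwise Levenshtein distance >= `min_dist` (1-error detection at the
#'   default of 2);
#' * no barcode ends in bases that would reconstitute the P1 enzyme's
#'   recognition site when followed by the read-side remnant (for AvaII,
#'   remnant GWCC: the last base must not be G);
#' * lengths balanced across `length_range` (each length class within +/- 1
#'   of an equal share), which staggers the restriction remnant across
#'   sequencing cycles and improves base diversity near the cut site.
#'
#' @param count Number of barcodes, a positive multiple of 20 (sets are used
#'   in multiples of 20 with pool indexes supplying further multiplexing).
#' @param length_range Inclusive length bounds, default `c(4, 8)`.
#' @param seed Integer seed; generation is deterministic per seed.
#' @param enzyme_a P1-side enzyme whose site must not be reconstituted.
#' @param min_dist Minimum pairwise Levenshtein distance (default 2).
#' @param max_tries Candidate draws before giving up.
#' @return A `barcode_set`: tibble with `barcode` and `length`, plus
#'   attributes `seed`, `enzyme_a`, `min_dist`.
#' @export
generate_barcode_set <- function(count = 20, length_range = c(4, 8), seed = 1,
                                 enzyme_a = "AvaII", min_dist = 2,
                                 max_tries = 20000) {
  if (count <= 0 || count %% 20 != 0) abort("`count` must be a positive multiple of 20.")
  lens <- seq(length_range[1], length_range[2])
  if (any(lens < 1)) abort("Barcode lengths must be positive.")
  enzyme_a <- get_enzyme(enzyme_a)

  # balanced target: each length class within +/-1 of count/n_classes
  quota <- rep(count %/% length(lens), length(lens))
  extra <- count %% length(lens)
  if (extra > 0) quota[seq_len(extra)] <- quota[seq_len(extra)] + 1L
  names(quota) <- as.character(lens)

  with_seed(seed, {
    chosen <- character(0)
    got <- setNames(rep(0L, length(lens)), names(quota))
    tries <- 0L
    # fill longer barcodes first: prefix-freeness then constrains new
    # (shorter) candidates against fewer existing prefixes
    for (len in rev(lens)) {
      while (got[as.character(len)] < quota[as.character(len)]) {
        tries <- tries + 1L
        if (tries > max_tries) {
          abort(sprintf(
            "Could not satisfy barcode constraints for count=%d in %d tries.",
            count, max_tries))
        }
        cand <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                      collapse = "")
        if (barcode_ok(cand, chosen, enzyme_a, min_dist)) {
          chosen <- c(chosen, cand)
          got[as.character(len)] <- got[as.character(len)] + 1L
        }
      }
    }
    out <- tibble(barcode = chosen, length = nchar(chosen))
    out <- dplyr::arrange(out, .data$length, .data$barcode)
    structure(out,
              class = c("barcode_set", class(out)),
              seed = seed, enzyme_a = enzyme_a$name, min_dist = min_dist)
  })
}

# Would appending the read-side remnant to this barcode recreate the
# recognition site across the junction? The read-side remnant is the
# recognition tail beyond the outermost cut, so reconstitution happens when
# the barcode's terminal bases match the recognition head before that cut
# (AvaII G^GWCC: last base G; PstI CTGCA^G read-side remnant TGCAG: last
# base C).
reconstitutes_site <- function(barcode, enzyme_a) {
  k <- min(enzyme_a$cut_offset_top, enzyme_a$cut_offset_bottom)
  if (k == 0) return(FALSE)
  if (nchar(barcode) < k) return(FALSE)
  tail_bases <- substr(barcode, nchar(barcode) - k + 1, nchar(barcode))
  head_pat <- substr(enzyme_a$recognition, 1, k)
  tail_bases %in% expand_iupac(head_pat)
}

is_prefix <- function(a, b) {
  # is a a prefix of b (a shorter or equal)?
  nchar(a) <= nchar(b) && substr(b, 1, nchar(a)) == a
}

barcode_ok <- function(cand, chosen, enzyme_a, min_dist) {
  if (reconstitutes_site(cand, enzyme_a)) return(FALSE)
  if (length(chosen) == 0) return(TRUE)
  if (any(vapply(chosen, function(b) is_prefix(cand, b) || is_prefix(b, cand),
                 logical(1)))) {
    return(FALSE)
  }
  all(adist(cand, chosen) >= min_dist)
}

#' Validate a barcode set against the design constraints
#'
#' Violations are data, not errors: the report lists every failed rule with
#' the offending barcode(s) so a hand-edited set can be audited.
#'
#' @param set A `barcode_set` tibble, or a character vector of barcodes.
#' @param enzyme_a P1-side enzyme for the site-reconstitution rule.
#' @param min_dist Minimum pairwise Levenshtein distance required.
#' @param check_balance Check the length-balance rule (skipped for ad hoc
#'   sets whose size is not a multiple of the length-class count).
#' @return A tibble with columns `rule`, `detail`; zero rows means valid.
#' @export
validate_barcode_set <- function(set, enzyme_a = "AvaII", min_dist = 2,
                                 check_balance = FALSE) {
  barcodes <- if (is.data.frame(set)) set$barcode else set
  enzyme_a <- get_enzyme(enzyme_a)
  bad <- list()

  not_acgt <- barcodes[grepl("[^ACGT]", barcodes)]
  for (b in not_acgt) {
    bad <- c(bad, list(tibble(rule = "alphabet", detail = b)))
  }

  if (length(barcodes) > 1) {
    for (i in seq_along(barcodes)) {
      for (j in seq_along(barcodes)) {
        if (i < j) {
          a <- barcodes[i]; b <- barcodes[j]
          if (is_prefix(a, b) || is_prefix(b, a)) {
            bad <- c(bad, list(tibble(rule = "prefix_free",
                                      detail = paste(a, b, sep = " / "))))
          }
          if (adist(a, b) < min_dist) {
            bad <- c(bad, list(tibble(rule = "min_distance",
                                      detail = paste(a, b, sep = " / "))))
          }
        }
      }
    }
  }

  recon <- barcodes[vapply(barcodes, reconstitutes_site, logical(1),
                           enzyme_a = enzyme_a)]
  for (b in recon) {
    bad <- c(bad, list(tibble(rule = "site_reconstitution", detail = b)))
  }

  if (check_balance) {
    tab <- table(nchar(barcodes))
    if (max(tab) - min(tab) > 1) {
      bad <- c(bad, list(tibble(
        rule = "length_balance",
        detail = paste(names(tab), tab, sep = ":", collapse = ", ")
      )))
    }
  }

  if (length(bad) == 0) {
    tibble(rule = character(), detail = character())
  } else {
    dplyr::bind_rows(bad)
  }
}

#' Assemble the P1/P2 adapter pair for one barcode
#'
#' The P1 top-strand oligo is `[20-base stub][barcode][sticky-end overhang
#' complementary to enzyme A's cut]`, so its length is always
#' `20 + barcode length` (25 bp for the usual 5-bp barcode, shortened from
#' the 37-bp original design). P2 is a fixed oligo ending in the overhang
#' complementary to enzyme B's cut. The stub content is an
#' Illumina-compatible placeholder; the length contract and the overhangs
#' are the normative parts. Blunt-cutting enzymes are rejected: the ligation
#' chemistry requires sticky ends.
#'
#' @param barcode Barcode string (ACGT, 4–8 bp).
#' @param enzyme_a,enzyme_b P1- and P2-side enzymes.
#' @return An `adapter_pair`: list with `p1_top`, `p2_top`, `barcode`,
#'   `p1_overhang`, `p2_overhang`.
#' @export
build_adapters <- function(barcode, enzyme_a = "AvaII", enzyme_b = "MspI") {
  enzyme_a <- get_enzyme(enzyme_a)
  enzyme_b <- get_enzyme(enzyme_b)
  if (grepl("[^ACGT]", barcode)) abort("Barcode must be ACGT only.")
  ov_a <- enzyme_overhang(enzyme_a)
  ov_b <- enzyme_overhang(enzyme_b)
  if (!nzchar(ov_a)) abort(sprintf("%s cuts blunt; sticky ends are required.", enzyme_a$name))
  if (!nzchar(ov_b)) abort(sprintf("%s cuts blunt; sticky ends are required.", enzyme_b$name))
  # stub + overhang total 20 fixed bases, so |P1| = 20 + |barcode|
  # (25 bp for the usual 5-bp barcode); stub content is an
  # Illumina-compatible placeholder
  p1_stub <- substr("ACACTCTTTCCCTACACGAC", 1, 20 - nchar(ov_a))
  p2_core <- "GTGACTGGAGTTCAGACGTGTGCTCTTCCGATC"
  structure(
    list(
      barcode = barcode,
      p1_top = paste0(p1_stub, barcode, ov_a),
      p2_top = paste0(p2_core, ov_b),
      p1_overhang = ov_a,
      p2_overhang = ov_b
    ),
    class = "adapter_pair"
  )
}

# Single-stranded overhang left by the cut, as the sequence the adapter must
# present (complementary to the fragment's protruding strand). A 5' overhang
# of length |top - bottom| bases; blunt cut -> "".
enzyme_overhang <- function(enzyme) {
  enzyme <- get_enzyme(enzyme)
  lo <- min(enzyme$cut_offset_top, enzyme$cut_offset_bottom)
  hi <- max(enzyme$cut_offset_top, enzyme$cut_offset_bottom)
  if (lo == hi) return("")
  # one representative expansion of the protruding recognition span
  span <- substr(enzyme$recognition, lo + 1, hi)
  expand_iupac(span)[1]
}

#' @export
print.adapter_pair <- function(x, ...) {
  cat(sprintf("<adapter_pair> barcode %s\n  P1 (%d bp): %s\n  P2 (%d bp): %s\n",
              x$barcode, nchar(x$p1_top), x$p1_top, nchar(x$p2_top), x$p2_top))
  invisible(x)
}

#' Build a combinatorial (barcode x pool index) sample sheet
#'
#' Assigns samples round-robin to (barcode, pool) pairs: sample i gets
#' barcode `(i-1) %% n_barcodes + 1` in pool `(i-1) %/% n_barcodes + 1`,
#' so a 40-sample run with 20 barcodes uses every barcode exactly twice,
#' once per pool. No (barcode, pool) pair is reused.
#'
#' @param samples Character vector of sample ids (must be unique).
#' @param set A `barcode_set` or character vector of barcodes.
#' @param n_pools Number of sub-library pool indexes available.
#' @return A `sample_sheet` tibble: `sample_id`, `barcode`, `pool_index`.
#' @export
build_sample_sheet <- function(samples, set, n_pools = 1) {
  barcodes <- if (is.data.frame(set)) set$barcode else set
  if (anyDuplicated(samples)) abort("Sample ids must be unique.")
  capacity <- length(barcodes) * n_pools
  if (length(samples) > capacity) {
    abort(sprintf("Too many samples: %d requested but capacity is %d (%d barcodes x %d pools).",
                  length(samples), capacity, length(barcodes), n_pools))
  }
  i <- seq_along(samples) - 1L
  out <- tibble(
    sample_id = samples,
    barcode = barcodes[(i %% length(barcodes)) + 1L],
    pool_index = (i %/% length(barcodes)) + 1L
  )
  structure(out, class = c("sample_sheet", class(out)))
}

#' Read / write sample sheets and barcode sets as TSV
#'
#' Sample sheets round-trip through `sample_id<TAB>barcode<TAB>pool_index`;
#' barcode sets through `barcode<TAB>length`.
#'
#' @param x A `sample_sheet` or `barcode_set` tibble.
#' @param path File path.
#' @return For writers, `path` invisibly; for readers, the tibble.
#' @export
write_sample_sheet <- function(x, path) {
  readr::write_tsv(x[, c("sample_id", "barcode", "pool_index")], path)
  invisible(path)
}

#' @rdname write_sample_sheet
#' @export
read_sample_sheet <- function(path) {
  out <- readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(),
    barcode = readr::col_character(),
    pool_index = readr::col_integer()
  ))
  structure(out, class = c("sample_sheet", class(out)))
}

#' @rdname write_sample_sheet
#' @export
write_barcode_set <- function(x, path) {
  readr::write_tsv(x[, c("barcode", "length")], path)
  invisible(path)
}

#' @rdname write_sample_sheet
#' @export
read_barcode_set <- function(path) {
  out <- readr::read_tsv(path, col_types = readr::cols(
    barcode = readr::col_character(),
    length = readr::col_integer()
  ))
  structure(out, class = c("barcode_set", class(out)))
}
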