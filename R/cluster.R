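#' Clustering parameters for RAD tag assembly
#'
#' Mirrors the conventional m/M/n parameterisation of RAD tag clustering:
#' `m` is the minimum number of identical reads required to seed a stack,
#' `M` the mismatch limit when merging stacks into a within-sample tag and
#' `n` the mismatch limit when merging tags into catalog loci across
#' samples.
#'
#' @param m Minimum stack depth (default 10).
#' @param M Max mismatches merging stacks within a sample (default 3).
#' @param n Max mismatches merging tags across samples (default 5).
#' @param tag_length Truncation length in bp (default 140, the PE150
#'   convention after barcode removal).
#' @return A `cluster_params` list.
#' @export
cluster_params <- function(m = 10, M = 3, n = 5, tag_length = 140) {
  if (m < 1) abort("m must be >= 1.")
  if (M < 0 || n < 0) abort("M and n must be >= 0.")
  if (n < M) warn("n < M: catalog merging is stricter than within-sample merging.")
  structure(list(m = m, M = M, n = n, tag_length = tag_length),
            class = "cluster_params")
}

#' Truncate reads to a fixed tag length
#'
#' @param reads Character vector of (barcode-trimmed) read sequences, or a
#'   tibble with a `seq` column.
#' @param tag_length Target length; longer reads are cut to an exact-length
#'   prefix, shorter reads are dropped.
#' @return Character vector of `tag_length`-bp sequences with attribute
#'   `n_dropped` counting the too-short reads.
#' @export
truncate_reads <- function(reads, tag_length = 140) {
  if (is.data.frame(reads)) reads <- reads$seq
  long_enough <- nchar(reads) >= tag_length
  out <- substr(reads[long_enough], 1, tag_length)
  attr(out, "n_dropped") <- sum(!long_enough)
  out
}

# Column-wise majority consensus of equal-length sequences weighted by
# depth; ties broken to the lexicographically smallest base.
consensus_of <- function(seqs, depths) {
  if (length(seqs) == 1) return(seqs)
  mat <- do.call(rbind, strsplit(seqs, ""))
  apply_col <- vapply(seq_len(ncol(mat)), function(j) {
    tab <- tapply(depths, mat[, j], sum)
    names(tab)[order(-tab, names(tab))][1]
  }, character(1))
  paste(apply_col, collapse = "")
}

variant_columns <- function(seqs) {
  if (length(seqs) < 2) return(integer(0))
  mat <- do.call(rbind, strsplit(seqs, ""))
  which(vapply(seq_len(ncol(mat)), function(j) length(unique(mat[, j])) > 1,
               logical(1)))
}

#' Assemble per-sample tags from truncated reads
#'
#' A simplified within-sample RAD clustering: identical reads form exact
#' stacks; stacks with depth >= `m` become primary stacks, of which those
#' with depth above mean + 3 sd of primary depths are flagged repetitive
#' and excluded (a lumberjack-style cutoff standing in for more elaborate
#' repeat-removal heuristics). Every remaining stack (primary or shallow)
#' merges into its nearest primary within `M` Hamming mismatches — ties go
#' to the deeper primary, then to the lexicographically smaller consensus.
#' Each merged group becomes a tag whose consensus is the depth-weighted
#' per-column majority and whose alleles are the distinct member haplotypes
#' restricted to the variant columns.
#'
#' @param reads Fixed-length read vector (see [truncate_reads()]) for one
#'   sample, or a tibble with `seq`.
#' @param params A [cluster_params()].
#' @param sample Sample id recorded on the tags.
#' @return A tibble of tags: `sample`, `consensus`, `depth`, `n_stacks`,
#'   `alleles` (list column of tibbles `haplotype`, `depth`), sorted by
#'   consensus. Attributes `n_repetitive` (reads in excluded repetitive
#'   stacks) and `n_unmerged` (reads in stacks that matched no primary)
#'   support read-conservation accounting.
#' @export
build_stacks <- function(reads, params = cluster_params(), sample = "sample1") {
  if (is.data.frame(reads)) reads <- reads$seq
  if (length(reads) == 0) {
    out <- tibble(sample = character(), consensus = character(),
                  depth = integer(), n_stacks = integer(), alleles = list())
    attr(out, "n_repetitive") <- 0L
    attr(out, "n_unmerged") <- 0L
    return(out)
  }
  stopifnot(length(unique(nchar(reads))) == 1)

  tab <- table(reads)
  stacks <- tibble(seq = names(tab), depth = as.integer(tab))
  stacks <- dplyr::arrange(stacks, dplyr::desc(.data$depth), .data$seq)

  primary <- stacks$depth >= params$m
  n_repetitive <- 0L
  if (any(primary)) {
    pd <- stacks$depth[primary]
    cutoff <- mean(pd) + 3 * (if (length(pd) > 1) sd(pd) else 0)
    repetitive <- primary & stacks$depth > cutoff
    # with a single primary, sd is 0 and the cutoff equals its own depth,
    # so a lone deep stack is never self-excluded (depth > cutoff is strict)
    n_repetitive <- sum(stacks$depth[repetitive])
    primary <- primary & !repetitive
    stacks <- stacks[!repetitive, ]
    primary <- stacks$depth >= params$m & !(stacks$depth > cutoff)
  }

  prim_idx <- which(primary)
  if (length(prim_idx) == 0) {
    out <- tibble(sample = character(), consensus = character(),
                  depth = integer(), n_stacks = integer(), alleles = list())
    attr(out, "n_repetitive") <- n_repetitive
    attr(out, "n_unmerged") <- sum(stacks$depth)
    return(out)
  }

  # primaries within M of an already-seeded primary fuse into one tag
  # (deeper stacks seed first, so the deepest haplotype anchors the tag);
  # shallow stacks then join the nearest seed, ties to the deeper one
  seed_of <- integer(0)  # indices into stacks that anchor a tag
  assign_to <- rep(NA_integer_, nrow(stacks))
  for (i in prim_idx) {  # prim_idx is depth-ordered (stacks sorted above)
    if (length(seed_of) > 0) {
      d <- hamming(stacks$seq[i], stacks$seq[seed_of])
      ok <- d <= params$M
    } else ok <- logical(0)
    if (any(ok)) {
      cand <- seed_of[ok][order(d[ok], -stacks$depth[seed_of][ok],
                                stacks$seq[seed_of][ok])]
      assign_to[i] <- cand[1]
    } else {
      seed_of <- c(seed_of, i)
      assign_to[i] <- i
    }
  }
  n_unmerged <- 0L
  for (i in setdiff(seq_len(nrow(stacks)), prim_idx)) {
    d <- hamming(stacks$seq[i], stacks$seq[seed_of])
    ok <- d <= params$M
    if (!any(ok)) {
      n_unmerged <- n_unmerged + stacks$depth[i]
      next
    }
    cand <- seed_of[ok][order(d[ok], -stacks$depth[seed_of][ok],
                              stacks$seq[seed_of][ok])]
    assign_to[i] <- cand[1]
  }

  groups <- split(which(!is.na(assign_to)), assign_to[!is.na(assign_to)])
  tags <- purrr::map(groups, function(members) {
    seqs <- stacks$seq[members]
    depths <- stacks$depth[members]
    cons <- consensus_of(seqs, depths)
    vc <- variant_columns(seqs)
    alleles <- if (length(vc) == 0) {
      tibble(haplotype = "", depth = sum(depths))
    } else {
      hap <- vapply(seqs, function(s) {
        paste(strsplit(s, "")[[1]][vc], collapse = "")
      }, character(1), USE.NAMES = FALSE)
      dplyr::arrange(
        dplyr::summarise(dplyr::group_by(tibble(haplotype = hap, depth = depths),
                                         .data$haplotype),
                         depth = sum(.data$depth), .groups = "drop"),
        dplyr::desc(.data$depth), .data$haplotype)
    }
    tibble(sample = sample, consensus = cons, depth = sum(depths),
           n_stacks = length(members), alleles = list(alleles),
           variant_cols = list(vc))
  })
  out <- dplyr::arrange(dplyr::bind_rows(tags), .data$consensus)
  attr(out, "n_repetitive") <- n_repetitive
  attr(out, "n_unmerged") <- n_unmerged
  out
}

#' Merge per-sample tags into a catalog of loci
#'
#' Greedy single-linkage over tag consensuses: tags are processed in
#' deterministic order (sample name, then consensus) and each joins the
#' first existing locus whose consensus is within `n` Hamming mismatches
#' (nearest locus on ties), or founds a new locus. Locus consensuses are
#' the depth-weighted column-wise majority over member tags.
#'
#' @param tags A tibble of tags from [build_stacks()], rows from all
#'   samples bound together.
#' @param params A [cluster_params()].
#' @return A `catalog`: tibble with `locus_id`, `consensus`, `n_samples`,
#'   `variant_columns` (list of 1-based positions), `members` (list of the
#'   member tag rows).
#' @export
build_catalog <- function(tags, params = cluster_params()) {
  if (nrow(tags) == 0) abort("No tags to catalog.")
  tags <- dplyr::arrange(tags, .data$sample, .data$consensus)
  loci <- list()  # each: list(consensus, members = tibble rows)
  for (i in seq_len(nrow(tags))) {
    cons_i <- tags$consensus[i]
    if (length(loci) > 0) {
      d <- hamming(cons_i, vapply(loci, `[[`, character(1), "consensus"))
      ok <- which(d <= params$n)
    } else ok <- integer(0)
    if (length(ok) > 0) {
      j <- ok[order(d[ok], ok)][1]
      loci[[j]]$members <- dplyr::bind_rows(loci[[j]]$members, tags[i, ])
      loci[[j]]$consensus <- consensus_of(loci[[j]]$members$consensus,
                                          loci[[j]]$members$depth)
    } else {
      loci[[length(loci) + 1]] <- list(consensus = cons_i, members = tags[i, ])
    }
  }
  out <- purrr::imap(loci, function(lc, j) {
    vc <- variant_columns(lc$members$consensus)
    tibble(
      locus_id = j,
      consensus = lc$consensus,
      n_samples = length(unique(lc$members$sample)),
      variant_columns = list(vc),
      members = list(lc$members)
    )
  })
  out <- dplyr::bind_rows(out)
  structure(out, class = c("catalog", class(out)))
}

# unique best locus for one consensus, NA if none within n or tied
best_locus <- function(cons, catalog, n) {
  d <- hamming(cons, catalog$consensus)
  if (min(d) > n) return(NA_integer_)
  best <- which(d == min(d))
  if (length(best) > 1) return(NA_integer_)
  catalog$locus_id[best]
}

#' Match sample tags against the catalog and call genotypes
#'
#' Each sample tag is assigned to its unique best catalog locus within `n`
#' mismatches; its bases at the locus's variant columns become the sample's
#' call, collapsed to an IUPAC ambiguity code when the tag carries more
#' than one allele at a column. Samples with no tag at a locus are called
#' missing (`N`).
#'
#' @param tags All samples' tags (as passed to [build_catalog()]).
#' @param catalog A [build_catalog()] result.
#' @param params A [cluster_params()].
#' @return A `snp_matrix`: tibble with one row per sample and one column
#'   per variant site named `L<locus>_<column>`, values single IUPAC
#'   letters. Attribute `sites` maps columns to (locus_id, position).
#' @export
match_and_genotype <- function(tags, catalog, params = cluster_params()) {
  site_info <- dplyr::bind_rows(purrr::pmap(
    list(catalog$locus_id, catalog$variant_columns),
    function(lid, vc) {
      if (length(vc) == 0) return(NULL)
      tibble(locus_id = lid, column = vc,
             site = sprintf("L%d_%d", lid, vc))
    }))
  if (nrow(site_info) == 0) {
    site_info <- tibble(locus_id = integer(), column = integer(),
                        site = character())
  }
  samples <- sort(unique(tags$sample))

  calls <- matrix("N", nrow = length(samples),
                  ncol = if (nrow(site_info)) nrow(site_info) else 0,
                  dimnames = list(samples, site_info$site))
  for (i in seq_len(nrow(tags))) {
    lid <- best_locus(tags$consensus[i], catalog, params$n)
    if (is.na(lid)) next
    sites_here <- site_info[site_info$locus_id == lid, ]
    if (nrow(sites_here) == 0) next
    # bases carried by this tag at the variant columns; tags with multiple
    # alleles contribute an ambiguity code at their own variant columns
    vc <- sites_here$column
    alleles <- tags$alleles[[i]]
    tag_vc <- if ("variant_cols" %in% names(tags)) tags$variant_cols[[i]] else integer(0)
    base_at <- vapply(vc, function(col) {
      j <- match(col, tag_vc)
      if (!is.na(j) && nrow(alleles) > 1) {
        iupac_code(unique(substr(alleles$haplotype, j, j)))
      } else {
        substr(tags$consensus[i], col, col)
      }
    }, character(1))
    calls[tags$sample[i], sites_here$site] <- base_at
  }
  out <- dplyr::bind_cols(tibble(sample = samples),
                          as_tibble(calls, .name_repair = "minimal"))
  attr(out, "sites") <- site_info
  structure(out, class = c("snp_matrix", class(out)))
}

iupac_code <- function(bases) {
  bases <- sort(unique(bases))
  key <- paste(bases, collapse = "")
  codes <- c(A = "A", C = "C", G = "G", T = "T",
             AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K",
             ACG = "V", ACT = "H", AGT = "D", CGT = "B", ACGT = "N")
  unname(codes[key] %||% "N")
}

#' Export a SNP matrix in sequential Phylip format
#'
#' Header `<n_samples> <n_columns>`, sample names padded to 10 characters,
#' calls concatenated. At least 3 samples are needed for an informative
#' unrooted tree; fewer triggers a warning.
#'
#' @param matrix A [match_and_genotype()] result (or any tibble whose first
#'   column is `sample` and remaining columns are single-letter calls).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_phylip <- function(matrix, path) {
  sample_names <- matrix$sample
  if (anyDuplicated(sample_names)) abort("Duplicate sample names.")
  calls <- as.matrix(matrix[, setdiff(names(matrix), "sample"), drop = FALSE])
  if (nrow(calls) == 0 || ncol(calls) == 0) abort("SNP matrix is empty.")
  if (nrow(calls) < 3) warn("Fewer than 3 samples: unrooted trees will be uninformative.")
  lines <- c(
    sprintf("%d %d", nrow(calls), ncol(calls)),
    vapply(seq_len(nrow(calls)), function(i) {
      paste0(formatC(substr(sample_names[i], 1, 10), width = -10),
             paste(calls[i, ], collapse = ""))
    }, character(1))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a sequential Phylip file back into a tibble
#'
#' @param path Phylip file written by [export_phylip()].
#' @return Tibble with `sample` and one column per site (`site1`, ...).
#' @export
read_phylip <- function(path) {
  lines <- readLines(path)
  header <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]])
  body <- lines[-1]
  samples <- trimws(substr(body, 1, 10))
  seqs <- trimws(substr(body, 11, nchar(body)))
  mat <- do.call(rbind, strsplit(seqs, ""))
  colnames(mat) <- paste0("site", seq_len(header[2]))
  dplyr::bind_cols(tibble(sample = samples), as_tibble(mat))
}

#' Fixed-within / variable-among SNP filter
#'
#' Keeps variant columns where every sample group (e.g. species) is fixed
#' for one base but at least two groups differ — the classic marker filter
#' for inter-specific phylogenetics from RAD data.
#'
#' @param matrix A `snp_matrix` tibble.
#' @param groups Named character vector mapping `sample` -> group.
#' @param max_missing Maximum fraction of missing (`N`) calls tolerated per
#'   column (default 0: no missing data).
#' @return The filtered matrix (same shape, fewer site columns).
#' @export
filter_fixed_among <- function(matrix, groups, max_missing = 0) {
  site_cols <- setdiff(names(matrix), "sample")
  grp <- groups[matrix$sample]
  keep <- vapply(site_cols, function(sc) {
    v <- matrix[[sc]]
    miss <- v == "N"
    if (mean(miss) > max_missing) return(FALSE)
    per_group <- tapply(v[!miss], grp[!miss], function(x) length(unique(x)))
    if (any(per_group > 1)) return(FALSE)
    reps <- tapply(v[!miss], grp[!miss], `[`, 1)
    length(unique(reps)) >= 2
  }, logical(1))
  out <- matrix[, c("sample", site_cols[keep])]
  attr(out, "sites") <- attr(matrix, "sites")[keep, ]
  out
}
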