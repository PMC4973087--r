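#' Generate a synthetic genome
#'
#' Draws random contigs at a target GC content and, optionally, overlays
#' repeats as tandem/dispersed copies of one sampled repeat unit so that
#' repeat-region behaviour (e.g. deep repetitive stacks) can be exercised.
#' A placement log of every repeat copy is attached, so the realised repeat
#' coverage can be computed exactly from the generator's own bookkeeping.
#'
#' @param n_contigs Number of contigs.
#' @param contig_length Length of each contig in bp.
#' @param gc_fraction Target GC content in `[0, 1]`.
#' @param repeat_fraction Approximate fraction of bases to cover with copies
#'   of the repeat unit, in `[0, 1]`.
#' @param seed Integer seed; output is deterministic per seed.
#' @param repeat_unit_length Length of the sampled repeat unit (default 200).
#' @return A `synth_genome`: list with `sequences` (named DNAStringSet),
#'   `repeats` (tibble `contig`, `start`, `end` of each placed copy,
#'   0-based half-open) and the generation parameters.
#' @export
synth_genome <- function(n_contigs = 1, contig_length = 10000,
                         gc_fraction = 0.5, repeat_fraction = 0,
                         seed = 1, repeat_unit_length = 200) {
  if (n_contigs < 1 || contig_length < 1) abort("Contig count and length must be positive.")
  if (gc_fraction < 0 || gc_fraction > 1) abort("gc_fraction must be in [0, 1].")
  if (repeat_fraction < 0 || repeat_fraction > 1) abort("repeat_fraction must be in [0, 1].")

  base_probs <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
                  G = gc_fraction / 2, T = (1 - gc_fraction) / 2)

  with_seed(seed, {
    unit <- paste(sample(names(base_probs), repeat_unit_length,
                         replace = TRUE, prob = base_probs), collapse = "")
    placements <- list()
    seqs <- vapply(seq_len(n_contigs), function(ci) {
      s <- sample(names(base_probs), contig_length, replace = TRUE, prob = base_probs)
      if (repeat_fraction > 0 && contig_length >= repeat_unit_length) {
        n_copies <- floor(repeat_fraction * contig_length / repeat_unit_length)
        # place copies on non-overlapping unit-width slots so the realised
        # coverage equals the requested fraction; adjacent sampled slots
        # form tandem runs, isolated ones dispersed copies
        n_slots <- contig_length %/% repeat_unit_length
        if (n_copies > 0 && n_slots > 0) {
          n_copies <- min(n_copies, n_slots)
          starts <- (sort(sample.int(n_slots, n_copies)) - 1L) * repeat_unit_length
          unit_chars <- strsplit(unit, "")[[1]]
          for (st in starts) {
            s[(st + 1):(st + repeat_unit_length)] <- unit_chars
          }
          placements[[length(placements) + 1]] <<- tibble(
            contig = paste0("contig", ci),
            start = starts,
            end = starts + repeat_unit_length
          )
        }
      }
      paste(s, collapse = "")
    }, character(1))
    names(seqs) <- paste0("contig", seq_len(n_contigs))

    structure(
      list(
        sequences = Biostrings::DNAStringSet(seqs),
        repeats = if (length(placements)) dplyr::bind_rows(placements) else
          tibble(contig = character(), start = integer(), end = integer()),
        repeat_unit = unit,
        params = list(n_contigs = n_contigs, contig_length = contig_length,
                      gc_fraction = gc_fraction, repeat_fraction = repeat_fraction,
                      seed = seed, repeat_unit_length = repeat_unit_length)
      ),
      class = "synth_genome"
    )
  })
}

#' @export
print.synth_genome <- function(x, ...) {
  cat(sprintf("<synth_genome> %d contig(s) x %s bp, GC %.2f, repeat fraction %.2f, seed %d\n",
              x$params$n_contigs, format(x$params$contig_length, big.mark = ","),
              x$params$gc_fraction, x$params$repeat_fraction, x$params$seed))
  invisible(x)
}

#' Simulation configuration for a paired-end ddRAD run
#'
#' @param read_length Read length in bp (150 for PE150, 100 for PE100).
#' @param mean_depth Mean read pairs per fragment per sample.
#' @param depth_dispersion Negative-binomial size parameter for per-fragment
#'   depth; `Inf` gives exactly `mean_depth` pairs per fragment (the
#'   deterministic limit). Smaller values give more pool imbalance.
#' @param error_rate Per-base substitution error rate in `[0, 0.5)`.
#' @param window [size_window()] of fragments entering the library.
#' @param seed Integer seed.
#' @param read_through Simulate adapter read-through on short inserts.
#' @param base_quality Phred score of the constant quality model.
#' @param taper_3prime Number of 3'-end bases over which quality tapers
#'   down (0 = flat).
#' @return A `sim_config` list.
#' @export
sim_config <- function(read_length = 150, mean_depth = 20,
                       depth_dispersion = Inf, error_rate = 0,
                       window = size_window(), seed = 1,
                       read_through = FALSE, base_quality = 37,
                       taper_3prime = 0) {
  if (read_length <= 0) abort("read_length must be positive.")
  if (mean_depth <= 0) abort("mean_depth must be positive.")
  if (error_rate < 0 || error_rate >= 0.5) abort("error_rate must be in [0, 0.5).")
  structure(
    list(read_length = read_length, mean_depth = mean_depth,
         depth_dispersion = depth_dispersion, error_rate = error_rate,
         window = window, seed = seed, read_through = read_through,
         base_quality = base_quality, taper_3prime = taper_3prime),
    class = "sim_config"
  )
}

# Quality string for one read length under the config's model.
quality_string <- function(n, config) {
  q <- rep(config$base_quality, n)
  k <- min(config$taper_3prime, n)
  if (k > 0) {
    q[(n - k + 1):n] <- pmax(2, round(seq(config$base_quality, config$base_quality - k, length.out = k)))
  }
  rawToChar(as.raw(q + 33L))
}

# vectorised quality lookup: one string per distinct read length
quals_for <- function(lens, config) {
  u <- unique(lens)
  lut <- setNames(vapply(u, quality_string, character(1), config = config),
                  as.character(u))
  unname(lut[as.character(lens)])
}

apply_errors <- function(seqs, rate) {
  if (rate == 0) return(seqs)
  vapply(seqs, function(s) {
    n <- nchar(s)
    hit <- which(runif(n) < rate)
    if (length(hit) == 0) return(s)
    chars <- strsplit(s, "")[[1]]
    for (i in hit) {
      chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1)
    }
    paste(chars, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Substitute per-sample variants into a genome: variants is a tibble
# (sample, contig, pos [0-based], base).
apply_variants <- function(seqs, variants, sample_id) {
  if (is.null(variants)) return(seqs)
  v <- variants[variants$sample == sample_id, ]
  if (nrow(v) == 0) return(seqs)
  out <- as.character(seqs)
  for (i in seq_len(nrow(v))) {
    s <- out[[v$contig[i]]]
    substr(s, v$pos[i] + 1, v$pos[i] + 1) <- v$base[i]
    out[[v$contig[i]]] <- s
  }
  res <- Biostrings::DNAStringSet(out)
  names(res) <- names(seqs)
  res
}

#' Simulate a ddRAD paired-end library
#'
#' For every sample on the sheet, every size-window AB fragment of the
#' (per-sample) genome receives k read pairs, with k drawn from a negative
#' binomial around `mean_depth` (or exactly `mean_depth` when
#' `depth_dispersion = Inf`). The read anatomy follows the double-digest
#' protocol: read1 is the sample's inline barcode, then the enzyme-A
#' restriction remnant as present at the fragment's A end, then insert;
#' read2 starts with the enzyme-B remnant and reads the fragment from the
#' other end on the opposite strand. Read1 always starts at the P1
#' (enzyme-A) end, whichever side of the fragment carries it. When
#' read-through is enabled and the insert is shorter than the read, the read
#' continues into the reverse complement of the opposite adapter, the
#' classic short-insert contamination signature. Substitution errors are
#' i.i.d. at `error_rate`.
#'
#' @param genome Genome input (see [double_digest()]).
#' @param sheet A [build_sample_sheet()] tibble.
#' @param adapters An `adapter_pair` from [build_adapters()] (barcode field
#'   is ignored; per-sample barcodes come from the sheet), used for the
#'   read-through adapter sequence.
#' @param config A [sim_config()].
#' @param enzyme_a,enzyme_b The digestion pair.
#' @param variants Optional tibble (`sample`, `contig`, `pos` 0-based,
#'   `base`) of per-sample substitutions planted before digestion/read
#'   generation — ground truth for SNP-recovery tests.
#' @param out_dir Optional directory; when given, gzipped
#'   `<pool>_R1.fastq.gz` / `<pool>_R2.fastq.gz` files, a manifest TSV and a
#'   config JSON echo are written there.
#' @return A `sim_library`: list with `r1`, `r2` (read tibbles: `id`, `seq`,
#'   `qual`, `sample_id`, `pool_index`), `manifest` (per sample x fragment:
#'   coordinates and pair count) and `config`.
#' @export
simulate_library <- function(genome, sheet, adapters, config = sim_config(),
                             enzyme_a = "AvaII", enzyme_b = "MspI",
                             variants = NULL, out_dir = NULL) {
  if (nrow(sheet) == 0) abort("Sample sheet is empty.")
  enzyme_a <- get_enzyme(enzyme_a)
  enzyme_b <- get_enzyme(enzyme_b)
  seqs0 <- as_genome(genome)

  p2_rc <- revcomp(adapters$p2_top)
  stub_len <- nchar(adapters$p1_top) - nchar(adapters$barcode) -
    nchar(adapters$p1_overhang)
  p1_for_sample <- function(bc) paste0(substr(adapters$p1_top, 1, stub_len), bc,
                                       adapters$p1_overhang)

  with_seed(config$seed, {
    all_r1 <- list(); all_r2 <- list(); manifest <- list()

    for (si in seq_len(nrow(sheet))) {
      sample_id <- sheet$sample_id[si]
      barcode <- sheet$barcode[si]
      pool <- sheet$pool_index[si]
      seqs <- apply_variants(seqs0, variants, sample_id)
      frags <- double_digest(seqs, enzyme_a, enzyme_b)
      ab <- frags[frags$end_class == "AB" &
                    frags$length >= config$window$min_len &
                    frags$length <= config$window$max_len, ]
      if (nrow(ab) == 0) {
        warn(sprintf("No in-window AB fragments for sample %s.", sample_id))
        manifest[[length(manifest) + 1]] <- tibble(
          sample_id = sample_id, pool_index = pool,
          contig = character(), start = integer(), end = integer(),
          a_end = character(), n_pairs = integer()
        )
        next
      }

      depth <- if (is.infinite(config$depth_dispersion)) {
        rep(as.integer(round(config$mean_depth)), nrow(ab))
      } else {
        rnbinom(nrow(ab), mu = config$mean_depth, size = config$depth_dispersion)
      }

      # the fragment's A (P1) end: left when the left cut is enzyme A
      a_left <- ab$left_enzyme == enzyme_a$name
      # extend each enzyme end to the outermost cut so the sticky-end bases
      # filled in during library prep are part of the sequenced molecule;
      # fragment boundaries themselves stay at top-strand cuts
      ext_lut_l <- c(end_extension(enzyme_a$name, "left"),
                     end_extension(enzyme_b$name, "left"))
      ext_lut_r <- c(end_extension(enzyme_a$name, "right"),
                     end_extension(enzyme_b$name, "right"))
      names(ext_lut_l) <- names(ext_lut_r) <- c(enzyme_a$name, enzyme_b$name)
      ext_l <- unname(ext_lut_l[ab$left_enzyme])
      ext_r <- unname(ext_lut_r[ab$right_enzyme])
      frag_seq <- as.character(Biostrings::subseq(
        seqs[ab$contig], start = ab$start + 1 - ext_l, end = ab$end + ext_r))
      # read1 template: the strand whose 5' end is the A (P1) cut; read2
      # template is its reverse complement, starting at the B end
      r1_template <- ifelse(a_left, frag_seq, revcomp(frag_seq))
      r2_template <- revcomp(r1_template)

      rows <- rep(seq_len(nrow(ab)), times = depth)
      if (length(rows) > 0) {
        r1_full <- paste0(barcode, r1_template[rows])
        r2_full <- r2_template[rows]
        r1_seq <- clip_read(r1_full, config, p2_rc)
        r2_seq <- clip_read(r2_full, config, revcomp(p1_for_sample(barcode)))
        r1_seq <- apply_errors(r1_seq, config$error_rate)
        r2_seq <- apply_errors(r2_seq, config$error_rate)
        ids <- sprintf("%s:%s:%d-%d:%d", sample_id, ab$contig[rows],
                       ab$start[rows], ab$end[rows],
                       sequence(depth[depth > 0]))
        all_r1[[length(all_r1) + 1]] <- tibble(
          id = ids, seq = r1_seq,
          qual = quals_for(nchar(r1_seq), config),
          sample_id = sample_id, pool_index = pool
        )
        all_r2[[length(all_r2) + 1]] <- tibble(
          id = ids, seq = r2_seq,
          qual = quals_for(nchar(r2_seq), config),
          sample_id = sample_id, pool_index = pool
        )
      }
      manifest[[length(manifest) + 1]] <- tibble(
        sample_id = sample_id, pool_index = pool,
        contig = ab$contig, start = ab$start, end = ab$end,
        a_end = ifelse(a_left, "left", "right"), n_pairs = as.integer(depth)
      )
    }

    out <- structure(
      list(
        r1 = dplyr::bind_rows(all_r1),
        r2 = dplyr::bind_rows(all_r2),
        manifest = dplyr::bind_rows(manifest),
        config = config,
        enzyme_a = enzyme_a$name, enzyme_b = enzyme_b$name
      ),
      class = "sim_library"
    )
    if (!is.null(out_dir)) write_sim_library(out, out_dir)
    out
  })
}

# Bases beyond the top-strand cut that belong to the sequenced molecule
# after sticky-end fill-in: at a left fragment boundary the molecule extends
# down to min(cut_top, cut_bottom); at a right boundary up to max(...).
# TERMINAL ends do not extend. The extension always stays inside the
# recognition match, hence inside the contig.
end_extension <- function(enzyme_name, side) {
  if (enzyme_name == "TERMINAL") return(0L)
  e <- get_enzyme(enzyme_name)
  if (side == "left") {
    as.integer(max(0L, e$cut_offset_top - e$cut_offset_bottom))
  } else {
    as.integer(max(0L, e$cut_offset_bottom - e$cut_offset_top))
  }
}

clip_read <- function(full, config, adapter_rc) {
  n <- config$read_length
  short <- nchar(full) < n
  if (config$read_through) {
    full[short] <- substr(paste0(full[short], adapter_rc,
                                 strrep("A", n)), 1, n)
  }
  substr(full, 1, n)
}

#' @export
print.sim_library <- function(x, ...) {
  cat(sprintf("<sim_library> %d read pairs, %d samples, %s+%s, read length %d\n",
              nrow(x$r1), length(unique(x$manifest$sample_id)),
              x$enzyme_a, x$enzyme_b, x$config$read_length))
  invisible(x)
}

#' Write a simulated library to disk
#'
#' One gzipped R1/R2 FASTQ pair per pool index, a manifest TSV and a JSON
#' echo of the simulation configuration.
#'
#' @param lib A `sim_library` from [simulate_library()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_library <- function(lib, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (pool in sort(unique(lib$r1$pool_index))) {
    write_fastq(lib$r1[lib$r1$pool_index == pool, ],
                file.path(dir, sprintf("pool%d_R1.fastq.gz", pool)))
    write_fastq(lib$r2[lib$r2$pool_index == pool, ],
                file.path(dir, sprintf("pool%d_R2.fastq.gz", pool)))
  }
  readr::write_tsv(lib$manifest, file.path(dir, "manifest.tsv"))
  cfg <- lib$config
  cfg$window <- unclass(cfg$window)
  jsonlite::write_json(unclass(cfg), file.path(dir, "sim_config.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  invisible(dir)
}
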