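# Shared fixtures and independent brute-force oracles used across tests.
# Oracles deliberately avoid the package's own matching machinery: they test
# every offset against concrete substrings in plain R.

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

rc_plain <- function(x) {
  chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN",
         vapply(strsplit(x, ""), function(ch) paste(rev(ch), collapse = ""),
                character(1)))
}

# expand an IUPAC pattern by explicit recursion (independent of the package)
expand_brute <- function(pattern) {
  map <- c(A = "A", C = "C", G = "G", T = "T", R = "AG", Y = "CT", S = "CG",
           W = "AT", K = "GT", M = "AC", B = "CGT", D = "AGT", H = "ACT",
           V = "ACG", N = "ACGT")
  chars <- strsplit(pattern, "")[[1]]
  out <- ""
  for (ch in chars) out <- as.vector(outer(out, strsplit(map[[ch]], "")[[1]], paste0))
  sort(out)
}

# brute-force cut-site scan: test every offset against every concrete
# expansion on both strands (minus strand only when the set is not closed
# under reverse complement)
brute_sites <- function(seq, recognition, cut_top, cut_bottom) {
  fwd <- expand_brute(recognition)
  self_rc <- setequal(fwd, rc_plain(fwd))
  len <- nchar(recognition)
  L <- nchar(seq)
  out <- NULL
  for (i in 0:(L - len)) {
    win <- substr(seq, i + 1, i + len)
    if (win %in% fwd) {
      out <- rbind(out, data.frame(match_start = i, cut_pos = i + cut_top,
                                   strand = "+"))
    }
    if (!self_rc && win %in% rc_plain(fwd)) {
      out <- rbind(out, data.frame(match_start = i,
                                   cut_pos = i + (len - cut_bottom),
                                   strand = "-"))
    }
  }
  if (is.null(out)) data.frame(match_start = integer(), cut_pos = integer(),
                               strand = character())
  else out[order(out$match_start), ]
}

# brute-force double digester: pooled dedup-sorted cut positions split the
# contig; ends labelled by the enzyme of the adjacent cut (alphabetical on
# coincident cuts, matching the documented tie-break)
brute_digest <- function(seq, enzymes) {
  cuts <- NULL
  for (e in enzymes) {
    s <- brute_sites(seq, e$recognition, e$cut_offset_top, e$cut_offset_bottom)
    if (nrow(s) > 0) cuts <- rbind(cuts, data.frame(pos = s$cut_pos, enz = e$name))
  }
  L <- nchar(seq)
  if (!is.null(cuts)) {
    cuts <- cuts[cuts$pos > 0 & cuts$pos < L, ]
    cuts <- cuts[order(cuts$pos, cuts$enz), ]
    cuts <- cuts[!duplicated(cuts$pos), ]
  }
  bounds <- c(0, if (!is.null(cuts)) cuts$pos, L)
  labels <- c("TERMINAL", if (!is.null(cuts)) cuts$enz, "TERMINAL")
  data.frame(
    start = bounds[-length(bounds)],
    end = bounds[-1],
    left_enzyme = labels[-length(labels)],
    right_enzyme = labels[-1]
  )
}

# closed-form simple linear regression (oracle for the lm-backed fit)
ols_oracle <- function(x, y) {
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  a <- mean(y) - b * mean(x)
  yhat <- a + b * x
  r2 <- 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  list(slope = b, intercept = a, r_squared = r2)
}

# closed-form Pearson correlation
pearson_oracle <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# small deterministic test genome with known site content
toy_contig <- "TTTGGACCTTTTCCGGTTT"
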