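# Independent oracles and small generators used across the suite.

rnd_seq <- function(n, alphabet = c("A", "C", "G", "T"), t_bias = 0) {
  prob <- rep(1, length(alphabet))
  if (t_bias > 0 && "T" %in% alphabet) prob[alphabet == "T"] <- 1 + t_bias
  paste(sample(alphabet, n, replace = TRUE, prob = prob), collapse = "")
}

rc_oracle <- function(s) {
  paste(rev(chartr("ACGT", "TGCA",
                   strsplit(s, "", fixed = TRUE)[[1]])), collapse = "")
}

# --- exhaustive affine-gap local alignment score (no canonicalisation) ---
# Plain three-state DP written independently of the package's C++ core.
# gap_open/gap_extend are named per-base costs; NA bans gaps over a base.
oracle_local_score <- function(read, ref, match = 1, mismatch = 18,
                               gap_open = c(A = NA, C = NA, G = NA, T = 0),
                               gap_extend = c(A = NA, C = NA, G = NA, T = 0)) {
  r <- strsplit(read, "", fixed = TRUE)[[1]]
  f <- strsplit(ref, "", fixed = TRUE)[[1]]
  n <- length(r); m <- length(f)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)  # gap in read (ref base skipped)
  Y <- matrix(NEG, n + 1, m + 1)  # gap in ref (read base skipped)
  M[1, ] <- 0; M[, 1] <- 0
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- if (r[i - 1] == f[j - 1]) match else -mismatch
      M[i, j] <- max(0, M[i - 1, j - 1], X[i - 1, j - 1],
                     Y[i - 1, j - 1]) + s
      go <- gap_open[[f[j - 1]]]; ge <- gap_extend[[f[j - 1]]]
      if (!is.na(go)) {
        X[i, j] <- max(M[i, j - 1] - go - ge, X[i, j - 1] - ge)
      }
      go <- gap_open[[r[i - 1]]]; ge <- gap_extend[[r[i - 1]]]
      if (!is.na(go)) {
        Y[i, j] <- max(M[i - 1, j] - go - ge, Y[i - 1, j] - ge)
      }
      best <- max(best, M[i, j])
    }
  }
  best
}

# --- skeleton-matching oracle for the strict scheme -----------------------
# With free T gaps, banned A/C/G gaps and no mismatches, the best local
# alignment pairs a contiguous block of read skeleton bases with an equal
# block of ref skeleton bases and matches min(run_read, run_ref) Ts at
# every shared site (interior sites plus the two flanking ones).
oracle_strict_score <- function(read, ref, match = 1) {
  dr <- decompose(read); df <- decompose(ref)
  rb <- strsplit(dr$bases, "", fixed = TRUE)[[1]]
  fb <- strsplit(df$bases, "", fixed = TRUE)[[1]]
  nr <- length(rb); nf <- length(fb)
  best <- 0
  # pure-T alignments
  if (length(dr$runs) && length(df$runs)) {
    best <- min(max(dr$runs), max(df$runs))
  }
  if (nr > 0 && nf > 0) {
    for (i1 in seq_len(nr)) for (i2 in i1:nr) {
      if (i2 - i1 + 1 > nf) next
      w <- rb[i1:i2]
      for (p in seq_len(nf - (i2 - i1))) {
        if (!identical(w, fb[p:(p + i2 - i1)])) next
        sc <- (i2 - i1 + 1)
        # shared sites: before i1 .. after i2 (0-based sites i1-1 .. i2)
        for (k in 0:(i2 - i1 + 1)) {
          sc <- sc + min(dr$runs[i1 + k - 1 + 1], df$runs[p + k - 1 + 1])
        }
        best <- max(best, sc)
      }
    }
  }
  best * match
}

# can `read` be explained as a U-indel-only variant of some contiguous
# stretch of `ref`?  (contiguous skeleton substring match using all read
# skeleton bases)
oracle_skeleton_mappable <- function(read, ref) {
  dr <- decompose(read)
  df <- decompose(ref)
  if (nchar(dr$bases) == 0) return(FALSE)
  grepl(dr$bases, df$bases, fixed = TRUE)
}

# --- three-frame longest-ORF oracle ---------------------------------------
oracle_longest_orf <- function(s, code = "4") {
  gc <- Biostrings::getGeneticCode(code)
  stops <- names(gc)[gc == "*"]
  best <- ""
  for (frame in 0:2) {
    i <- frame + 1
    codons <- character(0)
    starts <- integer(0)
    while (i + 2 <= nchar(s)) {
      codons <- c(codons, substr(s, i, i + 2))
      starts <- c(starts, i)
      i <- i + 3
    }
    open <- NA
    for (k in seq_along(codons)) {
      if (is.na(open) && codons[k] == "ATG") open <- k
      if (!is.na(open) && codons[k] %in% stops) {
        orf <- substr(s, starts[open], starts[k] - 1)
        if (nchar(orf) > nchar(best)) best <- orf
        open <- NA
      }
    }
    if (!is.na(open)) {
      orf <- substr(s, starts[open], starts[length(starts)] + 2)
      if (nchar(orf) > nchar(best)) best <- orf
    }
  }
  best
}

# --- gRNA search oracles --------------------------------------------------
# brute-force: all 25-nt windows of a subject strand that differ from
# some domain seed only by A->G / C->T substitutions (genome relative to
# seed), at most max_w of them
oracle_grna_windows <- function(mrna, domains, subject, max_w = 5) {
  L <- nchar(mrna)
  rc <- rc_oracle(mrna)
  seeds <- integer(0)
  for (d in domains) {
    lo <- L - d[2]; hi <- L - d[1]
    if (hi - lo >= 25) seeds <- c(seeds, seq(lo, hi - 25))
  }
  hits <- list()
  for (s in seeds) {
    sd <- strsplit(substr(rc, s + 1, s + 25), "")[[1]]
    for (g in 0:(nchar(subject) - 25)) {
      w <- strsplit(substr(subject, g + 1, g + 25), "")[[1]]
      diffs <- which(w != sd)
      ok <- all(sd[diffs] == "A" & w[diffs] == "G" |
                  sd[diffs] == "C" & w[diffs] == "T")
      if (ok && length(diffs) <= max_w) {
        hits[[length(hits) + 1]] <- c(g, s)
      }
    }
  }
  if (length(hits) == 0) return(matrix(integer(0), ncol = 2))
  do.call(rbind, hits)
}

# blocks anchor extension past [lo, hi) (0-based nt interval): the mRNA
# characters adjacent to the stretch become "A", whose seed-side
# complement "T" pairs with neither all-C contig flanks nor any allowed
# wobble direction
block_extension <- function(mrna, lo, hi) {
  chars <- strsplit(mrna, "", fixed = TRUE)[[1]]
  if (lo >= 1) chars[lo] <- "A"
  if (hi + 1 <= length(chars)) chars[hi + 1] <- "A"
  paste(chars, collapse = "")
}

# random full-range editing state for a cryptogene
rnd_state <- function(crypt, p_edit = 0.4) {
  pre <- crypt$skeleton$runs
  runs <- pre
  for (i in seq_along(runs)) {
    if (runif(1) < p_edit) {
      runs[i] <- if (runif(1) < 0.7 || runs[i] == 0) {
        runs[i] + sample.int(3, 1)
      } else {
        runs[i] - sample.int(runs[i], 1)
      }
    }
  }
  editing_state(crypt$id, 0L, length(runs), runs)
}

# quick synthetic alignment row (uncensored interior) for merge tests
aln_row <- function(read_id, site_lo, runs, censored = TRUE) {
  tibble::tibble(read_id = read_id, cryptogene_id = "cg", mapped = TRUE,
                 reason = "mapped", strand = "+", score = 0L,
                 mismatches = 0L,
                 site_lo = as.integer(site_lo),
                 site_hi = as.integer(site_lo + length(runs)),
                 runs = list(as.integer(runs)),
                 censored_lo = censored, censored_hi = censored,
                 ref_start = 0L, ref_end = 0L, read_len = 0L,
                 cigar = "*", seed_start = 0L, seed_end = 0L)
}
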