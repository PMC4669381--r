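#' Editing-aware local alignment
#'
#' Smith-Waterman local alignment under a nucleotide-specific gap scoring
#' scheme (see [scoring_scheme()]).  Among equal-scoring traces, gaps are
#' canonicalised to the leftmost position within a T run, so the reported
#' trace is deterministic.
#'
#' @param read,ref Sequences (T, not U; read in the orientation to align).
#' @param scheme A [scoring_scheme()].
#' @param band Optional band half-width: only cells with
#'   `|(ref_pos - read_pos) - band_diag| <= band` are filled.  `NULL` runs
#'   the exact full dynamic programme.
#' @param band_diag Centre diagonal of the band (expected `ref_start -
#'   read_start` offset).
#' @return A list of class `uindel_alignment` with `score`, `ops` (a
#'   string over `M`/`I`/`D`; `I` = extra read base, `D` = skipped ref
#'   base), 0-based half-open `read_start`/`read_end` and
#'   `ref_start`/`ref_end`, `matches` and `mismatches`.
#' @examples
#' sw_align("ACGTTTTAGC", "ACGTTAGC", scheme_strict())$score  # 8
#' @export
sw_align <- function(read, ref, scheme = scheme_strict(), band = NULL,
                     band_diag = 0L) {
  read <- chartr("U", "T", toupper(read))
  ref <- chartr("U", "T", toupper(ref))
  stopifnot(nchar(read) > 0, nchar(ref) > 0)
  pen <- scheme_penalties(scheme)
  res <- sw_core(read, ref, scheme$match_score, scheme$mismatch_penalty,
                 pen$gap_open, pen$gap_extend,
                 if (is.null(band)) -1L else as.integer(band),
                 as.integer(band_diag))
  res$read <- read
  res$ref <- ref
  class(res) <- "uindel_alignment"
  res
}

#' @export
print.uindel_alignment <- function(x, ...) {
  cat("<uindel_alignment> score ", x$score, ", read [", x$read_start, ",",
      x$read_end, "), ref [", x$ref_start, ",", x$ref_end, "), ",
      x$mismatches, " mismatch(es)\n", sep = "")
  cat("  cigar:", alignment_cigar(x), "\n")
  invisible(x)
}

# run-length encode ops + soft clips into a CIGAR string
alignment_cigar <- function(aln) {
  ops <- aln$ops
  pre <- aln$read_start
  post <- nchar(aln$read) - aln$read_end
  if (nchar(ops) == 0) return("*")
  r <- rle(strsplit(ops, "", fixed = TRUE)[[1]])
  body <- paste0(r$lengths, r$values, collapse = "")
  paste0(if (pre > 0) paste0(pre, "S") else "",
         body,
         if (post > 0) paste0(post, "S") else "")
}

# Extract the per-site editing state observed by an alignment against a
# template whose skeleton bases equal the cryptogene's (template may be a
# partially edited intermediate: site indices are shared).
# Returns NULL when the alignment touches no skeleton base.
alignment_state <- function(aln, crypt_id) {
  cols <- strsplit(aln$ops, "", fixed = TRUE)[[1]]
  if (length(cols) == 0) return(NULL)
  ref_chars <- strsplit(aln$ref, "", fixed = TRUE)[[1]]
  read_chars <- strsplit(aln$read, "", fixed = TRUE)[[1]]
  consume_read <- cols != "D"
  consume_ref <- cols != "I"
  # 1-based index of the char consumed at each column (NA when none)
  ridx <- ifelse(consume_read, aln$read_start + cumsum(consume_read), NA)
  fidx <- ifelse(consume_ref, aln$ref_start + cumsum(consume_ref), NA)
  # skeleton-base count of the template up to each position
  base_cum <- cumsum(ref_chars != "T")
  # site of each column: Ts after skeleton base k belong to site k
  site <- integer(length(cols))
  consumed_before <- aln$ref_start + cumsum(consume_ref) - consume_ref
  site <- ifelse(consume_ref,
                 ifelse(ref_chars[fidx] == "T", base_cum[fidx], NA),
                 ifelse(consumed_before > 0, base_cum[consumed_before], 0L))
  # columns contributing an observed T: read char is T
  rchar <- ifelse(is.na(ridx), "", read_chars[ridx])
  is_obs_t <- rchar == "T" & !is.na(site)
  # skeleton bases covered (columns where a non-T ref base is consumed)
  base_cols <- which(consume_ref & ref_chars[fidx] != "T")
  if (length(base_cols) == 0) return(NULL)
  b_first <- base_cum[fidx[base_cols[1]]]            # 1-based base count
  b_last <- base_cum[fidx[base_cols[length(base_cols)]]]
  site_lo <- b_first - 1L
  site_hi <- b_last + 1L
  obs_sites <- site[is_obs_t]
  runs <- tabulate(obs_sites - site_lo + 1L, nbins = site_hi - site_lo)
  editing_state(crypt_id, site_lo, site_hi, runs,
                censored_lo = TRUE, censored_hi = TRUE)
}

unmapped_row <- function(read_id, crypt_id, reason) {
  tibble::tibble(read_id = read_id, cryptogene_id = crypt_id,
                 mapped = FALSE, reason = reason,
                 strand = NA_character_, score = NA_integer_,
                 mismatches = NA_integer_,
                 site_lo = NA_integer_, site_hi = NA_integer_,
                 runs = list(NULL),
                 censored_lo = NA, censored_hi = NA,
                 ref_start = NA_integer_, ref_end = NA_integer_,
                 read_len = NA_integer_, cigar = NA_character_,
                 seed_start = NA_integer_, seed_end = NA_integer_)
}

#' Map one read onto a cryptogene template
#'
#' Seed-anchored, editing-aware mapping: a read is mapped only when (i) it
#' contains the seed exactly, (ii) at least part of the read lies 5' of the
#' seed, (iii) the alignment contains only T-indels beyond what the scheme
#' allows, and (iv) it has at most `scheme$max_mismatches` mismatches.
#' Boundary sites truncated by the read ends are flagged censored.
#' Unmapped is a normal outcome and carries a reason code (`no-seed`,
#' `no-5prime-extension`, `too-many-mismatches`, `non-T-indel`).
#'
#' @param read Read sequence (as sequenced).
#' @param crypt A [cryptogene()].
#' @param seed Seed string(s); each must be a substring of the current
#'   template.  With several seeds a read is admitted when any of them
#'   gates it (see [tile_seeds()]).
#' @param scheme A [scoring_scheme()].
#' @param template Template sequence to align against; defaults to the
#'   pre-edited cryptogene.  A partially edited template shares the
#'   cryptogene's skeleton, so site coordinates are unchanged.
#' @param strand_specific If `TRUE`, only the sense orientation of the
#'   read is tried; otherwise the reverse complement is tried as well.
#' @param read_id Identifier used in the output row.
#' @param band Optional band half-width passed to [sw_align()].
#' @return A one-row tibble (see [map_all()] for the columns).
#' @export
map_read <- function(read, crypt, seed = NULL, scheme = scheme_strict(),
                     template = NULL, strand_specific = FALSE,
                     read_id = "read", band = NULL) {
  stopifnot(inherits(crypt, "uindel_cryptogene"))
  if (is.null(template)) template <- crypt$pre_edited
  if (is.null(seed)) seed <- default_seed(crypt, template)
  read <- chartr("U", "T", toupper(read))
  seed_t <- vapply(seed, function(s) {
    as.integer(regexpr(s, template, fixed = TRUE))
  }, integer(1))
  if (any(seed_t < 0)) stop("seed is not a substring of the template",
                            call. = FALSE)
  orientations <- list(c("+", read))
  if (!strand_specific) orientations <- c(orientations,
                                          list(c("-", revcomp(read))))
  best <- NULL
  reason <- "no-seed"
  for (o in orientations) {
    strand <- o[1]; rseq <- o[2]
    hit <- 0L
    for (k in seq_along(seed)) {
      sp <- as.integer(regexpr(seed[k], rseq, fixed = TRUE))
      if (sp < 0) next
      if (sp == 1L) {  # read starts at this seed: no 5' extension
        if (reason == "no-seed") reason <- "no-5prime-extension"
        next
      }
      hit <- k
      break
    }
    if (hit == 0L) next
    sp <- as.integer(regexpr(seed[hit], rseq, fixed = TRUE))
    aln <- sw_align(rseq, template, scheme, band = band,
                    band_diag = if (!is.null(band)) seed_t[hit] - sp else 0L)
    chk <- check_alignment(aln, scheme)
    if (!chk$ok) { reason <- chk$reason; next }
    if (is.null(best) || aln$score > best$aln$score) {
      best <- list(aln = aln, strand = strand, seed_hit = hit)
    }
  }
  if (is.null(best)) return(unmapped_row(read_id, crypt$id, reason))
  aln <- best$aln
  seed_hit_t <- seed_t[best$seed_hit]
  seed_hit_len <- nchar(seed[best$seed_hit])
  st <- alignment_state(aln, crypt$id)
  if (is.null(st)) return(unmapped_row(read_id, crypt$id, "non-T-indel"))
  tibble::tibble(read_id = read_id, cryptogene_id = crypt$id,
                 mapped = TRUE, reason = "mapped",
                 strand = best$strand,
                 score = aln$score, mismatches = aln$mismatches,
                 site_lo = st$site_lo, site_hi = st$site_hi,
                 runs = list(st$runs),
                 censored_lo = st$censored_lo, censored_hi = st$censored_hi,
                 ref_start = aln$ref_start, ref_end = aln$ref_end,
                 read_len = nchar(read), cigar = alignment_cigar(aln),
                 seed_start = seed_hit_t - 1L,
                 seed_end = seed_hit_t - 1L + seed_hit_len)
}

# alignment-quality gate shared by map_read: the read must be consumed in
# full, except overhangs past the template ends and (when terminal gaps are
# allowed) short terminal clips
check_alignment <- function(aln, scheme, max_clip = 3L) {
  if (nchar(aln$ops) == 0) return(list(ok = FALSE, reason = "non-T-indel"))
  if (aln$mismatches > scheme$max_mismatches) {
    return(list(ok = FALSE, reason = "too-many-mismatches"))
  }
  allowed <- if (scheme$allow_terminal_gap) max_clip else 0L
  pre_clip <- aln$read_start
  post_clip <- nchar(aln$read) - aln$read_end
  pre_ok <- pre_clip == 0 || aln$ref_start == 0 || pre_clip <= allowed
  post_ok <- post_clip == 0 || aln$ref_end == nchar(aln$ref) ||
    post_clip <= allowed
  if (!pre_ok || !post_ok) return(list(ok = FALSE, reason = "non-T-indel"))
  list(ok = TRUE, reason = "mapped")
}

#' Tile anchoring seeds along a template
#'
#' For exhaustive (re-)mapping against a known (fully or partially)
#' edited template — e.g. when classifying all reads after the main
#' pathway has been reconstructed — seeds are tiled along the whole
#' template at a fixed spacing, so that every read contains at least one
#' seed regardless of which part of the transcript it covers.
#'
#' @param template Template sequence.
#' @param seed_length Seed length in nt.
#' @param spacing Spacing between seed starts in nt.
#' @return Character vector of unique seed substrings.
#' @export
tile_seeds <- function(template, seed_length = 14L, spacing = 20L) {
  n <- nchar(template)
  starts <- seq(1L, max(1L, n - seed_length + 1L), by = spacing)
  if (starts[length(starts)] != n - seed_length + 1L && n > seed_length) {
    starts <- c(starts, n - seed_length + 1L)
  }
  unique(substring(template, starts, pmin(n, starts + seed_length - 1L)))
}

# default anchoring seed: the cryptogene's seed region on the template.
# The template may carry different T runs, so the region is re-extracted
# via skeleton coordinates.
default_seed <- function(crypt, template = crypt$pre_edited) {
  if (is.null(crypt$seed_region)) {
    stop("cryptogene has no seed region; supply `seed`", call. = FALSE)
  }
  if (template == crypt$pre_edited) {
    return(substr(crypt$pre_edited, crypt$seed_region[1] + 1L,
                  crypt$seed_region[2]))
  }
  # map the seed region's skeleton bases onto the template
  sk <- crypt$skeleton
  bases <- strsplit(sk$bases, "", fixed = TRUE)[[1]]
  pos_pre <- cumsum(sk$runs[seq_along(bases)] + 1L) - 1L  # 0-based positions
  bsel <- which(pos_pre >= crypt$seed_region[1] &
                pos_pre < crypt$seed_region[2])
  tsk <- decompose(template)
  pos_t <- cumsum(tsk$runs[seq_along(bases)] + 1L) - 1L
  substr(template, pos_t[min(bsel)] + 1L, pos_t[max(bsel)] + 1L)
}

#' Map a set of reads onto a cryptogene
#'
#' Applies [map_read()] to every read and returns one row per read, in
#' read-id order (deterministic output).  A mapping report (counts per
#' outcome) is attached as attribute `"report"` and shown by
#' [glance.uindel_alignments()].
#'
#' @param reads A tibble with columns `read_id` and `seq`, or a (named)
#'   character vector of read sequences.
#' @inheritParams map_read
#' @return A tibble of class `uindel_alignments` with columns `read_id`,
#'   `cryptogene_id`, `mapped`, `reason`, `strand`, `score`, `mismatches`,
#'   `site_lo`, `site_hi`, `runs` (list-column of per-site T-run counts),
#'   `censored_lo`, `censored_hi`, `ref_start`, `ref_end`, `read_len`,
#'   `cigar`, `seed_start`, `seed_end`.
#' @export
map_all <- function(reads, crypt, seed = NULL, scheme = scheme_strict(),
                    template = NULL, strand_specific = FALSE, band = NULL) {
  reads <- as_read_tbl(reads)
  if (is.null(template)) template <- crypt$pre_edited
  if (is.null(seed)) seed <- default_seed(crypt, template)
  out <- purrr::map_dfr(seq_len(nrow(reads)), function(i) {
    map_read(reads$seq[i], crypt, seed = seed, scheme = scheme,
             template = template, strand_specific = strand_specific,
             read_id = reads$read_id[i], band = band)
  })
  if (nrow(out) == 0) out <- unmapped_row("x", crypt$id, "no-seed")[0, ]
  out <- dplyr::arrange(out, .data$read_id)
  report <- dplyr::count(out, .data$reason, name = "n_reads")
  attr(out, "report") <- report
  class(out) <- c("uindel_alignments", class(out))
  out
}

as_read_tbl <- function(reads) {
  if (is.character(reads)) {
    ids <- names(reads)
    if (is.null(ids)) ids <- sprintf("read%06d", seq_along(reads))
    reads <- tibble::tibble(read_id = ids, seq = unname(reads))
  }
  stopifnot(all(c("read_id", "seq") %in% names(reads)))
  tibble::as_tibble(reads[, c("read_id", "seq")])
}

#' @export
glance.uindel_alignments <- function(x, ...) {
  rep <- attr(x, "report")
  tibble::tibble(n_reads = nrow(x),
                 n_mapped = sum(x$mapped),
                 n_unmapped = sum(!x$mapped),
                 report = list(rep))
}

#' Per-position coverage track
#'
#' Counts aligned reference positions per strand, as plotted for
#' strand-specific RNA-seq coverage of mitochondrial scaffolds.
#'
#' @param alignments A [map_all()] result (unmapped rows are ignored).
#' @param length Template/scaffold length in nt.
#' @param strand_aware If `FALSE`, both strands are pooled into `sense`.
#' @return A tibble of class `uindel_coverage` with `position` (0-based),
#'   `sense` and `antisense` depth columns; total depth equals the total
#'   aligned reference length.
#' @export
coverage_track <- function(alignments, length, strand_aware = TRUE) {
  m <- dplyr::filter(alignments, .data$mapped)
  depth1 <- function(rows) {
    d <- integer(length + 1L)
    if (nrow(rows) > 0) {
      for (i in seq_len(nrow(rows))) {
        d[rows$ref_start[i] + 1L] <- d[rows$ref_start[i] + 1L] + 1L
        d[rows$ref_end[i] + 1L] <- d[rows$ref_end[i] + 1L] - 1L
      }
    }
    cumsum(d)[seq_len(length)]
  }
  if (strand_aware) {
    sense <- depth1(dplyr::filter(m, .data$strand == "+"))
    anti <- depth1(dplyr::filter(m, .data$strand == "-"))
  } else {
    sense <- depth1(m)
    anti <- integer(length)
  }
  out <- tibble::tibble(position = seq_len(length) - 1L,
                        sense = sense, antisense = anti)
  class(out) <- c("uindel_coverage", class(out))
  out
}
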