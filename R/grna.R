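#' Search genomic contigs for candidate gRNA genes
#'
#' A guide RNA is complementary to a stretch of the *edited* mRNA, with
#' G-U wobble pairs allowed.  The search reverse-complements the edited
#' transcript, cuts the regions undergoing editing into 25-nt seeds with a
#' step of 1 nt, and matches every seed against both strands of the
#' contigs allowing up to `max_wobble` A-to-G and/or C-to-T substitutions
#' (genome relative to seed — the two substitutions that create G-U pairs
#' in the gRNA:mRNA duplex; the reverse substitutions are not allowed).
#' Overlapping seed hits on the same contig/strand/diagonal are merged
#' into maximal anchors (every constituent 25-mer respects the wobble
#' cap), and candidates are kept only when supported by at least one
#' transcriptomic read containing a >= 25-nt exact substring of the
#' genomic anchor.
#'
#' @param edited_mrna Edited mRNA sequence (sense orientation).
#' @param editing_domains List of 0-based half-open *nt* intervals of the
#'   transcript undergoing editing.
#' @param contigs Named character vector (or `DNAStringSet`) of genomic
#'   contigs.
#' @param reads Character vector (or tibble with `seq`) of RNA-seq reads.
#' @param seed_len Seed length (default 25 nt).
#' @param max_wobble Maximum wobble substitutions per seed window
#'   (default 5).
#' @param flank_width Width of the reported flanking sequences
#'   (default 30 nt).
#' @param strand_specific If `TRUE`, a read supports an anchor only in
#'   its sequenced orientation; otherwise its reverse complement is tried
#'   too.
#' @return A tibble of class `uindel_grna`, sorted by (contig, start,
#'   strand): `contig_id`, `start`, `end` (0-based half-open on the
#'   contig's plus strand), `strand`, `mrna_lo`, `mrna_hi` (matched
#'   transcript interval), `n_wobble`, `read_support`, `anchor_seq`
#'   (gRNA-sense), `flank_up`, `flank_down` (gRNA-sense flanks).
#'   [glance()] reports the raw seed-hit and merged-anchor counts.
#' @export
find_grna_candidates <- function(edited_mrna, editing_domains, contigs,
                                 reads, seed_len = 25L, max_wobble = 5L,
                                 flank_width = 30L,
                                 strand_specific = FALSE) {
  mrna <- chartr("U", "T", toupper(edited_mrna))
  L <- nchar(mrna)
  contigs <- as_named_seqs(contigs, "contig")
  if (is.data.frame(reads)) reads <- reads$seq
  reads <- chartr("U", "T", toupper(reads))
  if (length(editing_domains) == 0) {
    warning("no editing domains supplied; no seeds generated")
    return(empty_grna())
  }
  rc <- revcomp(mrna)
  # domain intervals on the reverse complement
  rc_dom <- lapply(editing_domains, function(d) c(L - d[2], L - d[1]))
  seed_starts <- sort(unique(unlist(lapply(rc_dom, function(d) {
    if (d[2] - d[1] < seed_len) return(integer(0))
    seq(d[1], d[2] - seed_len)
  }))))
  if (length(seed_starts) == 0) {
    warning("editing domains shorter than the seed length")
    return(empty_grna())
  }
  # degenerate seed alphabet: A matches A/G, C matches C/T in the genome
  deg <- chartr("AC", "RY", rc)

  hits <- list()
  for (cid in names(contigs)) {
    cseq <- contigs[[cid]]
    for (strand in c("+", "-")) {
      subject <- if (strand == "+") cseq else revcomp(cseq)
      subj <- Biostrings::DNAString(subject)
      for (s in seed_starts) {
        pat <- substr(deg, s + 1L, s + seed_len)
        m <- Biostrings::matchPattern(pat, subj, fixed = FALSE)
        if (length(m) == 0) next
        starts <- Biostrings::start(m) - 1L  # 0-based in subject
        # count actual wobbles; the degenerate match already restricts
        # substitutions to the allowed directions
        sd <- substr(rc, s + 1L, s + seed_len)
        nw <- vapply(starts, function(g) {
          sum(utf8ToInt(substr(subject, g + 1L, g + seed_len)) !=
                utf8ToInt(sd))
        }, integer(1))
        ok <- nw <= max_wobble
        if (any(ok)) {
          hits[[length(hits) + 1L]] <- tibble::tibble(
            contig_id = cid, strand = strand,
            g_start = starts[ok], seed_pos = s)
        }
      }
    }
  }
  n_seed_hits <- if (length(hits)) sum(vapply(hits, nrow, integer(1))) else 0L
  if (n_seed_hits == 0) return(empty_grna(n_seed_hits = 0L))
  hits <- dplyr::bind_rows(hits)
  hits$diagonal <- hits$g_start - hits$seed_pos

  # merge runs of step-1 consecutive hits on the same diagonal
  anchors <- hits |>
    dplyr::group_by(.data$contig_id, .data$strand, .data$diagonal) |>
    dplyr::arrange(.data$seed_pos, .by_group = TRUE) |>
    dplyr::mutate(run = cumsum(c(1L, diff(.data$seed_pos) != 1L))) |>
    dplyr::group_by(.data$run, .add = TRUE) |>
    dplyr::summarise(s_lo = min(.data$seed_pos),
                     s_hi = max(.data$seed_pos) + seed_len,
                     g_lo = min(.data$g_start),
                     g_hi = max(.data$g_start) + seed_len,
                     .groups = "drop")

  # read 25-mer index for support counting
  read_kmers <- lapply(reads, function(r) {
    k <- seq_kmers(r, seed_len)
    if (!strand_specific) k <- unique(c(k, seq_kmers(revcomp(r), seed_len)))
    k
  })

  out <- purrr::map_dfr(seq_len(nrow(anchors)), function(i) {
    a <- anchors[i, ]
    cseq <- contigs[[a$contig_id]]
    clen <- nchar(cseq)
    subject <- if (a$strand == "+") cseq else revcomp(cseq)
    anchor_seq <- substr(subject, a$g_lo + 1L, a$g_hi)
    rc_seg <- substr(rc, a$s_lo + 1L, a$s_hi)
    n_wob <- sum(utf8ToInt(anchor_seq) != utf8ToInt(rc_seg))
    ak <- seq_kmers(anchor_seq, seed_len)
    supp <- sum(vapply(read_kmers, function(k) any(k %in% ak), logical(1)))
    flank_up <- substr(subject, max(1L, a$g_lo - flank_width + 1L), a$g_lo)
    flank_down <- substr(subject, a$g_hi + 1L,
                         min(clen, a$g_hi + flank_width))
    # contig plus-strand coordinates
    if (a$strand == "+") {
      start <- a$g_lo; end <- a$g_hi
    } else {
      start <- clen - a$g_hi; end <- clen - a$g_lo
    }
    tibble::tibble(contig_id = a$contig_id, start = start, end = end,
                   strand = a$strand,
                   mrna_lo = L - a$s_hi, mrna_hi = L - a$s_lo,
                   n_wobble = n_wob, read_support = supp,
                   anchor_seq = anchor_seq,
                   flank_up = flank_up, flank_down = flank_down)
  })
  n_anchors <- nrow(out)
  out <- dplyr::filter(out, .data$read_support >= 1L)
  out <- dplyr::arrange(out, .data$contig_id, .data$start, .data$strand)
  attr(out, "n_seed_hits") <- n_seed_hits
  attr(out, "n_anchors") <- n_anchors
  class(out) <- c("uindel_grna", class(out))
  out
}

empty_grna <- function(n_seed_hits = 0L) {
  out <- tibble::tibble(contig_id = character(0), start = integer(0),
                        end = integer(0), strand = character(0),
                        mrna_lo = integer(0), mrna_hi = integer(0),
                        n_wobble = integer(0), read_support = integer(0),
                        anchor_seq = character(0), flank_up = character(0),
                        flank_down = character(0))
  attr(out, "n_seed_hits") <- n_seed_hits
  attr(out, "n_anchors") <- 0L
  class(out) <- c("uindel_grna", class(out))
  out
}

seq_kmers <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  substring(s, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L)
}

as_named_seqs <- function(x, prefix) {
  if (methods::is(x, "DNAStringSet")) x <- as.character(x)
  nms <- names(x)
  x <- as.character(x)
  if (is.null(nms) || any(nms == "")) {
    nms <- sprintf("%s%03d", prefix, seq_along(x))
  }
  setNames(chartr("U", "T", toupper(x)), nms)
}

#' @export
glance.uindel_grna <- function(x, ...) {
  tibble::tibble(n_candidates = nrow(x),
                 n_anchors = attr(x, "n_anchors"),
                 n_seed_hits = attr(x, "n_seed_hits"),
                 n_contigs = dplyr::n_distinct(x$contig_id))
}

#' Annotate candidate flanks with upstream base composition
#'
#' gRNA genes typically carry an A- or A/C-rich tract immediately
#' upstream of the mRNA-complementary region; this adds the A and A+C
#' fractions of the upstream flank (purely descriptive, no threshold).
#'
#' @param candidates A [find_grna_candidates()] result.
#' @return The input with added `flank_a_fraction` and
#'   `flank_ac_fraction` columns (computed over the available flank
#'   bases; `NA` for an empty flank).
#' @export
annotate_flanks <- function(candidates) {
  frac <- function(fl, chars) {
    n <- nchar(fl)
    ifelse(n == 0, NA_real_,
           vapply(seq_along(fl), function(i) {
             sum(strsplit(fl[i], "", fixed = TRUE)[[1]] %in% chars) /
               nchar(fl[i])
           }, numeric(1)))
  }
  dplyr::mutate(candidates,
                flank_a_fraction = frac(.data$flank_up, "A"),
                flank_ac_fraction = frac(.data$flank_up, c("A", "C")))
}
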