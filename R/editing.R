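#' Apply an editing state to a cryptogene
#'
#' Rebuilds the edited sequence by interleaving the cryptogene's non-T
#' skeleton with the T-run lengths of a full-range editing state: the
#' inverse of [diff_editing()].
#'
#' @param crypt A [cryptogene()].
#' @param state A full-range, uncensored [editing_state()] (or an integer
#'   run vector of length `N + 1`).
#' @return The edited DNA sequence as a single string.
#' @examples
#' cg <- cryptogene("g", "ATGC")
#' apply_editing(cg, c(0, 3, 0, 1))  # "ATTTGCT"
#' @export
apply_editing <- function(crypt, state) {
  stopifnot(inherits(crypt, "uindel_cryptogene"))
  ns <- n_sites(crypt$skeleton)
  if (inherits(state, "uindel_state")) {
    if (state$site_lo != 0L || state$site_hi != ns) {
      stop("state must cover the full site range [0,", ns, "), got [",
           state$site_lo, ",", state$site_hi, ")", call. = FALSE)
    }
    if (state$censored_lo || state$censored_hi) {
      stop("cannot apply a censored editing state", call. = FALSE)
    }
    runs <- state$runs
  } else {
    runs <- as.integer(state)
    if (length(runs) != ns) {
      stop("state must cover the full site range [0,", ns, "), got ",
           length(runs), " runs", call. = FALSE)
    }
  }
  recompose(crypt$skeleton, runs)
}

#' Extract the editing state relating two sequences
#'
#' Compares a pre-edited and an edited sequence that share the same non-T
#' skeleton and returns the full-range editing state of the edited one.
#' A skeleton mismatch signals substitutions or non-U indels, which U-indel
#' editing cannot produce, and is an error.
#'
#' @param pre Pre-edited sequence (string or [cryptogene()]).
#' @param edited Edited sequence.
#' @return A full-range `uindel_state` with the edited T-run lengths.
#' @examples
#' st <- diff_editing("GAG", "GATTG")
#' st$runs  # 0 0 2 0
#' @export
diff_editing <- function(pre, edited) {
  if (inherits(pre, "uindel_cryptogene")) {
    id <- pre$id
    sk_pre <- pre$skeleton
  } else {
    id <- "pre"
    sk_pre <- decompose(pre)
  }
  sk_ed <- decompose(edited)
  if (sk_pre$bases != sk_ed$bases) {
    a <- strsplit(sk_pre$bases, "", fixed = TRUE)[[1]]
    b <- strsplit(sk_ed$bases, "", fixed = TRUE)[[1]]
    n <- min(length(a), length(b))
    diffpos <- if (n > 0) which(a[seq_len(n)] != b[seq_len(n)]) else integer(0)
    first <- if (length(diffpos)) diffpos[1] - 1L else n
    stop("non-T skeletons differ at skeleton position ", first,
         " (0-based): U-indel editing cannot change A/C/G bases",
         call. = FALSE)
  }
  editing_state(id, 0L, n_sites(sk_pre), sk_ed$runs)
}

# per-site insertion/deletion/changed counts between two run vectors
count_edits <- function(pre_runs, ed_runs) {
  d <- ed_runs - pre_runs
  list(u_insertions = sum(pmax(d, 0L)),
       u_deletions = sum(pmax(-d, 0L)),
       edited_sites = sum(d != 0L))
}

round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Editing statistics for an edited transcript
#'
#' Computes the per-gene and per-domain editing summary reported for edited
#' mitochondrial mRNAs: sizes, percent size increase, percent U in the ORF,
#' protein length, and per-domain U-insertion / U-deletion / edited-site
#' counts.  Percentages are rounded half-up to integers (raw values are
#' also returned).  The conservation identity
#' `edited_size = pre_edited_size + u_insertions - u_deletions` holds by
#' construction.
#'
#' @param crypt A [cryptogene()] (its domains are used unless `domains` is
#'   given).
#' @param edited Edited sequence with the same non-T skeleton.
#' @param domains Optional list of 0-based half-open site intervals; when
#'   absent the whole site range is treated as one domain.
#' @return A one-row tibble of gene-level statistics with a `by_domain`
#'   list-column of per-domain counts.
#' @export
editing_stats <- function(crypt, edited, domains = NULL) {
  stopifnot(inherits(crypt, "uindel_cryptogene"))
  st <- diff_editing(crypt, edited)
  pre_runs <- crypt$skeleton$runs
  ed_runs <- st$runs
  if (is.null(domains)) domains <- crypt$editing_domains
  if (length(domains) == 0) domains <- list(c(0L, n_sites(crypt$skeleton)))

  per_dom <- purrr::map_dfr(seq_along(domains), function(i) {
    d <- domains[[i]]
    idx <- seq(d[1] + 1L, d[2])  # runs index of sites [lo, hi)
    cnt <- count_edits(pre_runs[idx], ed_runs[idx])
    # nt length of the pre-edited region spanned by the domain's sites:
    # the Ts of the sites plus the bases strictly between them
    n_inner_bases <- max(0L, d[2] - d[1] - 1L)
    tibble::tibble(domain = i,
                   site_lo = d[1], site_hi = d[2],
                   pre_edited_region_length = sum(pre_runs[idx]) + n_inner_bases,
                   u_insertions = cnt$u_insertions,
                   u_deletions = cnt$u_deletions,
                   edited_sites = cnt$edited_sites)
  })

  tot <- count_edits(pre_runs, ed_runs)
  pre_n <- nchar(crypt$pre_edited)
  ed_n <- nchar(edited)
  prot <- translate_edited(edited)
  orf <- attr(prot, "orf")
  pct_u_orf_raw <- if (!is.null(orf) && nchar(orf) > 0) {
    100 * stringr::str_count(orf, "T") / nchar(orf)
  } else NA_real_
  pct_inc_raw <- 100 * (ed_n - pre_n) / pre_n

  tibble::tibble(
    gene = crypt$id,
    pre_edited_size = pre_n,
    edited_size = ed_n,
    pct_size_increase = round_half_up(pct_inc_raw),
    pct_size_increase_raw = pct_inc_raw,
    pct_U_in_orf = round_half_up(pct_u_orf_raw),
    pct_U_in_orf_raw = pct_u_orf_raw,
    protein_length = if (nchar(prot) > 0) nchar(prot) else NA_integer_,
    u_insertions = tot$u_insertions,
    u_deletions = tot$u_deletions,
    edited_sites = tot$edited_sites,
    by_domain = list(per_dom)
  )
}

#' Translate an edited mRNA
#'
#' Finds the longest open reading frame on the sense strand (all three
#' frames) and translates it under the mold/protozoan mitochondrial genetic
#' code (NCBI table 4), in which TGA encodes tryptophan — the usage of
#' kinetoplastid mitochondria.  The terminal stop is not included; an ORF
#' is also accepted when it runs into the end of the sequence without a
#' stop codon.
#'
#' @param mrna Edited mRNA (sense orientation, T or U).
#' @param code Genetic code table, as for [Biostrings::getGeneticCode()].
#' @return Protein string (possibly empty), with the nucleotide ORF in
#'   attribute `"orf"` and its 0-based start in attribute `"orf_start"`.
#' @examples
#' translate_edited("ATGTTTTAA")  # "MF"
#' @export
translate_edited <- function(mrna, code = "4") {
  s <- chartr("U", "T", toupper(mrna))
  gc <- Biostrings::getGeneticCode(code)
  stops <- names(gc)[gc == "*"]
  best <- ""
  best_start <- NA_integer_
  n <- nchar(s)
  for (frame in 0:2) {
    i <- frame + 1L
    orf_start <- NA_integer_
    while (i + 2L <= n) {
      codon <- substr(s, i, i + 2L)
      if (is.na(orf_start) && codon == "ATG") orf_start <- i
      if (!is.na(orf_start) && codon %in% stops) {
        len <- i - orf_start
        if (len > nchar(best)) {
          best <- substr(s, orf_start, i - 1L)
          best_start <- orf_start
        }
        orf_start <- NA_integer_
      }
      i <- i + 3L
    }
    if (!is.na(orf_start)) {  # ORF open at sequence end
      len <- (i - orf_start)
      if (len >= 3 && len > nchar(best)) {
        best <- substr(s, orf_start, orf_start + (len %/% 3L) * 3L - 1L)
        best_start <- orf_start
      }
    }
  }
  prot <- if (nchar(best) >= 3) {
    as.character(Biostrings::translate(Biostrings::DNAString(best),
                                       genetic.code = gc))
  } else ""
  structure(prot, orf = if (nchar(best) >= 3) best else NULL,
            orf_start = if (!is.na(best_start)) best_start - 1L else NULL)
}

#' Pairwise percent identity between two sequences
#'
#' Global alignment with unit mismatch and indel costs; every non-identical
#' alignment column (including gap columns) counts as a difference, so
#' `n_differences` equals the unit-cost edit distance.  Percent identity is
#' `100 * identical_columns / alignment_length`, rounded half-up to an
#' integer (the raw value is also returned).
#'
#' @param a,b DNA strings.
#' @return A one-row tibble with `pct_identity`, `pct_identity_raw`,
#'   `n_differences` and `alignment_length`.
#' @export
pairwise_identity <- function(a, b) {
  a <- chartr("U", "T", toupper(a)); b <- chartr("U", "T", toupper(b))
  if (nchar(a) == 0 || nchar(b) == 0) {
    stop("pairwise_identity() requires non-empty sequences", call. = FALSE)
  }
  letters4 <- c("A", "C", "G", "T")
  subm <- matrix(-1, 4, 4, dimnames = list(letters4, letters4))
  diag(subm) <- 0
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b),
    substitutionMatrix = subm, gapOpening = 0, gapExtension = 1,
    type = "global")
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  ps <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  len <- length(pa)
  ident <- sum(pa == ps)
  tibble::tibble(pct_identity = round_half_up(100 * ident / len),
                 pct_identity_raw = 100 * ident / len,
                 n_differences = len - ident,
                 alignment_length = len)
}
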