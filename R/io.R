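#' Read and write sequence files
#'
#' Thin wrappers around Biostrings for the formats used throughout:
#' FASTA for cryptogenes, contigs and edited products; FASTA/FASTQ for
#' reads (qualities are ignored).
#'
#' @param path File path.
#' @return `read_fasta()`: a named character vector.  `read_reads()`: a
#'   tibble with `read_id` and `seq` (format auto-detected from the
#'   first character).
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fasta")
  setNames(chartr("U", "T", toupper(as.character(x))), names(x))
}

#' @rdname read_fasta
#' @export
read_reads <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0) {
    return(tibble::tibble(read_id = character(0), seq = character(0)))
  }
  fmt <- if (startsWith(first, "@")) "fastq" else "fasta"
  x <- Biostrings::readDNAStringSet(path, format = fmt)
  ids <- sub("\\s.*$", "", names(x))
  tibble::tibble(read_id = unname(ids),
                 seq = unname(chartr("U", "T", toupper(as.character(x)))))
}

#' @rdname read_fasta
#' @param seqs Named character vector of sequences.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(chartr("U", "T", toupper(seqs))), path)
  invisible(path)
}

#' @rdname read_fasta
#' @param reads Tibble with `read_id` and `seq`.
#' @export
write_fastq <- function(reads, path) {
  reads <- as_read_tbl(reads)
  lines <- character(4L * nrow(reads))
  if (nrow(reads) > 0) {
    i <- seq_len(nrow(reads))
    lines[4 * i - 3] <- paste0("@", reads$read_id)
    lines[4 * i - 2] <- reads$seq
    lines[4 * i - 1] <- "+"
    lines[4 * i] <- strrep("I", nchar(reads$seq))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write alignments as SAM
#'
#' Standard SAM (1-based positions, soft-clip CIGARs) with custom tags
#' carrying the editing state: `ZS:i` first covered site, `ZR:Z`
#' comma-separated per-site T-run counts, `ZC:Z` censoring flags of the
#' boundary sites, plus `NM:i` (mismatches) and `AS:i` (score).
#'
#' @param alignments A [map_all()] result.
#' @param templates Named character vector of reference sequences (for
#'   the header `@SQ` lines).
#' @param path Output path.
#' @param reads Optional read tibble supplying SEQ fields.
#' @export
write_sam <- function(alignments, templates, path, reads = NULL) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           vapply(names(templates), function(nm) {
             paste0("@SQ\tSN:", nm, "\tLN:", nchar(templates[[nm]]))
           }, character(1)))
  seq_of <- function(id) {
    if (is.null(reads)) return("*")
    i <- match(id, reads$read_id)
    if (is.na(i)) "*" else reads$seq[i]
  }
  recs <- vapply(seq_len(nrow(alignments)), function(i) {
    r <- alignments[i, ]
    if (!r$mapped) {
      return(paste(r$read_id, 4L, "*", 0L, 0L, "*", "*", 0L, 0L,
                   seq_of(r$read_id), "*",
                   paste0("ZU:Z:", r$reason), sep = "\t"))
    }
    flag <- if (identical(r$strand, "-")) 16L else 0L
    s <- seq_of(r$read_id)
    if (flag == 16L && s != "*") s <- revcomp(s)
    paste(r$read_id, flag, r$cryptogene_id, r$ref_start + 1L, 255L,
          r$cigar, "*", 0L, 0L, s, "*",
          paste0("NM:i:", r$mismatches), paste0("AS:i:", r$score),
          paste0("ZS:i:", r$site_lo),
          paste0("ZR:Z:", paste(r$runs[[1]], collapse = ",")),
          paste0("ZC:Z:", paste0(as.integer(r$censored_lo),
                                 as.integer(r$censored_hi))),
          sep = "\t")
  }, character(1))
  writeLines(c(hdr, recs), path)
  invisible(path)
}

#' Write the editing-site matrix of a set of alignments
#'
#' A TSV with one row per read and one column per skeleton site: the
#' observed T-run count, `.` for uncovered sites and `?` for censored
#' boundary sites.
#'
#' @param alignments A [map_all()] result.
#' @param crypt The [cryptogene()].
#' @param path Output path.
#' @export
write_site_matrix <- function(alignments, crypt, path) {
  ns <- n_sites(crypt$skeleton)
  m <- dplyr::filter(alignments, .data$mapped)
  rows <- vapply(seq_len(nrow(m)), function(i) {
    v <- rep(".", ns)
    idx <- seq(m$site_lo[i] + 1L, m$site_hi[i])
    v[idx] <- as.character(m$runs[[i]])
    if (m$censored_lo[i]) v[idx[1]] <- "?"
    if (m$censored_hi[i]) v[idx[length(idx)]] <- "?"
    paste(c(m$read_id[i], v), collapse = "\t")
  }, character(1))
  hdr <- paste(c("read_id", paste0("s", seq_len(ns) - 1L)), collapse = "\t")
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Monospaced text rendering of editing intermediates
#'
#' Renders intermediates against the pre-edited and main-pathway run
#' vectors, one column per editing site: `.` site not covered, `=`
#' unedited, `+`/`-` insertion/deletion matching the main pathway
#' direction, `I`/`D` alternative insertion/deletion at a site the main
#' product never edits or beyond its length, `R` editing direction
#' reversed.
#'
#' @param intermediates A [merge_intermediates()] result.
#' @param crypt The [cryptogene()].
#' @param main A `uindel_pathway`.
#' @param path Optional output path; the lines are returned invisibly.
#' @export
render_intermediates <- function(intermediates, crypt, main, path = NULL) {
  pre <- crypt$skeleton$runs
  mr <- main$state$runs
  ns <- length(pre)
  head1 <- paste0(format("pre-edited", width = 14),
                  paste(ifelse(pre > 9, "#", pre), collapse = ""))
  head2 <- paste0(format("main", width = 14),
                  paste(ifelse(mr > 9, "#", mr), collapse = ""))
  lines <- c(head1, head2, strrep("-", 14 + ns))
  for (i in seq_len(nrow(intermediates))) {
    v <- rep(".", ns)
    sites <- seq(intermediates$site_lo[i], intermediates$site_hi[i] - 1L)
    runs <- intermediates$runs[[i]]
    for (j in seq_along(sites)) {
      s <- sites[j] + 1L
      r <- runs[j]
      v[s] <- if (r == pre[s]) "="
      else if (mr[s] == pre[s]) if (r > pre[s]) "I" else "D"
      else if (sign(r - pre[s]) != sign(mr[s] - pre[s])) "R"
      else if (abs(r - pre[s]) <= abs(mr[s] - pre[s])) {
        if (r > pre[s]) "+" else "-"
      } else if (r > pre[s]) "I" else "D"
    }
    lab <- sprintf("int%03d %6.2f ", intermediates$intermediate[i],
                   intermediates$support[i])
    lines <- c(lines, paste0(format(lab, width = 14),
                             paste(v, collapse = "")))
  }
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' Write per-gene editing statistics as TSV
#'
#' One row per gene in the column order of published per-gene editing
#' tables: sizes, percent size increase, percent U in the ORF, protein
#' length, then per-region lengths and U-insertion / U-deletion /
#' edited-site counts (regions joined with `+`).
#'
#' @param stats One or more [editing_stats()] rows (bind with
#'   `dplyr::bind_rows()`).
#' @param path Output path.
#' @export
write_stats_tsv <- function(stats, path) {
  fmt_dom <- function(bd, col) {
    vapply(bd, function(d) paste(d[[col]], collapse = "+"), character(1))
  }
  flat <- dplyr::mutate(
    stats,
    pre_edited_region_length = fmt_dom(.data$by_domain,
                                       "pre_edited_region_length"),
    u_insertions_by_region = fmt_dom(.data$by_domain, "u_insertions"),
    u_deletions_by_region = fmt_dom(.data$by_domain, "u_deletions"),
    edited_sites_by_region = fmt_dom(.data$by_domain, "edited_sites"))
  flat <- dplyr::select(flat, "gene", "pre_edited_size", "edited_size",
                        "pct_size_increase", "pct_U_in_orf",
                        "protein_length", "pre_edited_region_length",
                        "u_insertions_by_region", "u_deletions_by_region",
                        "edited_sites_by_region", "u_insertions",
                        "u_deletions", "edited_sites")
  readr::write_tsv(flat, path)
  invisible(path)
}
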