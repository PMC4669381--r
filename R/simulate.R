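#' Simulation configuration
#'
#' Parameters of the synthetic editing model: a random cryptogene, a mature
#' editing state produced by a 3'-to-5' cascade of gRNA-sized blocks, a
#' population of partially edited transcripts (each with an editing
#' "frontier": blocks 3' of it edited, 5' of it pre-edited), misediting at
#' two granularities (terminal alternative stretches at the frontier and
#' internal alternative sites inside canonically edited sequence), and
#' error-free reads of configurable length and strandedness.
#'
#' @param rng_seed Integer seed; all sampling is driven by it.
#' @param n_bases Number of non-T skeleton bases of the cryptogene.
#' @param pre_run_mean Mean pre-edited T-run length (geometric).
#' @param n_domains Number of editing domains (1 or 2) when `domains` is
#'   `NULL`.
#' @param domains Optional explicit list of 0-based half-open site
#'   intervals.
#' @param p_ins,p_del Per-site probabilities that the mature state inserts
#'   at / deletes from a domain site.
#' @param ins_size_mean Mean size of a mature U-insertion (geometric,
#'   >= 1).
#' @param grna_block_length Length in nt of the edited stretch covered by
#'   one gRNA; domains are tiled 3' to 5' into blocks of roughly this
#'   extent (default 45 nt, the span covered by an average gRNA).
#' @param coverage Mean read depth over the mature transcript.
#' @param read_len Length range `c(min, max)` of simulated reads.
#' @param strand_specific If `TRUE` all reads are sense reads; otherwise
#'   strands are drawn 50/50.
#' @param misedit_rate Per-read probability that the block beyond the
#'   frontier carries a terminal alternative stretch (1-3 sites).
#' @param internal_misedit_rate Per-site probability of an alternative
#'   value inside the canonically edited region.
#' @param mature_fraction Probability that a transcript is fully edited;
#'   the remaining mass is uniform over the intermediate frontiers.
#' @param seq_error_rate Per-base substitution error rate of reads
#'   (default 0: the analysis treats mismatches as near-disqualifying).
#' @param ensure_block_edits Force at least one mature-edited site per
#'   gRNA block (default `TRUE` whenever any editing is simulated; the
#'   closed-form misediting expectations assume it).  Automatically off
#'   when `p_ins + p_del == 0`.
#' @return A list of class `uindel_config`.
#' @export
simulation_config <- function(rng_seed = 1L,
                              n_bases = 120L,
                              pre_run_mean = 0.6,
                              n_domains = 2L,
                              domains = NULL,
                              p_ins = 0.35,
                              p_del = 0.08,
                              ins_size_mean = 2,
                              grna_block_length = 45L,
                              coverage = 100,
                              read_len = c(80L, 150L),
                              strand_specific = TRUE,
                              misedit_rate = 0.1,
                              internal_misedit_rate = 0.01,
                              mature_fraction = 0.5,
                              seq_error_rate = 0,
                              ensure_block_edits = TRUE) {
  cfg <- list(rng_seed = as.integer(rng_seed), n_bases = as.integer(n_bases),
              pre_run_mean = pre_run_mean, n_domains = as.integer(n_domains),
              domains = domains, p_ins = p_ins, p_del = p_del,
              ins_size_mean = ins_size_mean,
              grna_block_length = as.integer(grna_block_length),
              coverage = coverage, read_len = as.integer(read_len),
              strand_specific = isTRUE(strand_specific),
              misedit_rate = misedit_rate,
              internal_misedit_rate = internal_misedit_rate,
              mature_fraction = mature_fraction,
              seq_error_rate = seq_error_rate,
              ensure_block_edits = isTRUE(ensure_block_edits) &&
                p_ins + p_del > 0)
  stopifnot(cfg$p_ins >= 0, cfg$p_del >= 0, cfg$p_ins + cfg$p_del <= 1,
            cfg$misedit_rate >= 0, cfg$misedit_rate <= 1,
            cfg$internal_misedit_rate >= 0, cfg$internal_misedit_rate <= 1,
            cfg$mature_fraction >= 0, cfg$mature_fraction <= 1,
            length(cfg$read_len) == 2L, cfg$read_len[1] <= cfg$read_len[2])
  class(cfg) <- "uindel_config"
  cfg
}

# evaluate code under a fixed seed without disturbing the caller's RNG
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

#' Simulate a cryptogene locus with a planted mature editing state
#'
#' Generates a random cryptogene (skeleton bases over A/C/G, geometric
#' pre-edited T runs), editing domains, a mature editing state that
#' differs from the pre-edited runs only inside the domains, and the
#' gRNA-block tiling that defines the order of the editing cascade.
#' Block order follows the editing progression seen in multi-domain
#' transcripts: the 5' domain is completed before the 3' domain, and
#' editing runs 3' to 5' within each domain.  Every block is guaranteed at
#' least one edited site.  Output is bit-reproducible under
#' `config$rng_seed`.
#'
#' @param config A [simulation_config()].
#' @return A list of class `uindel_locus`: `crypt` (a [cryptogene()] with
#'   a never-edited 3' seed region), `mature_state`, `mature_seq`,
#'   `blocks` (tibble with `block`, `domain`, `site_lo`, `site_hi`,
#'   `order`; order 1 = first block edited), and `config`.
#' @export
simulate_locus <- function(config = simulation_config()) {
  with_local_seed(config$rng_seed, {
    n <- config$n_bases
    bases <- paste(sample(c("A", "C", "G"), n, replace = TRUE),
                   collapse = "")
    p_geom <- 1 / (1 + config$pre_run_mean)
    pre_runs <- rgeom(n + 1L, p_geom)
    sk <- new_skeleton(bases, pre_runs)
    ns <- n_sites(sk)

    tail_sites <- 16L  # never-edited 3' anchor region
    domains <- config$domains
    if (is.null(domains)) {
      lo <- 4L
      hi <- ns - tail_sites
      stopifnot(hi - lo >= 8L)
      if (config$n_domains >= 2L) {
        gap <- 6L
        half <- (hi - lo - gap) %/% 2L
        domains <- list(c(lo, lo + half), c(lo + half + gap, hi))
      } else {
        domains <- list(c(lo, hi))
      }
    }

    # mature state
    mature <- pre_runs
    for (d in domains) {
      for (s in seq(d[1], d[2] - 1L)) {
        u <- runif(1)
        if (u < config$p_ins) {
          mature[s + 1L] <- mature[s + 1L] + 1L +
            rgeom(1, 1 / config$ins_size_mean)
        } else if (u < config$p_ins + config$p_del && mature[s + 1L] > 0L) {
          mature[s + 1L] <- mature[s + 1L] -
            sample.int(mature[s + 1L], 1L)
        }
      }
    }

    # tile domains into gRNA-sized blocks (site granularity); the 5'
    # domain is edited first, 3' to 5' within each domain
    dom_sites <- sum(vapply(domains, function(d) d[2] - d[1], integer(1)))
    nt_per_site <- (sum(mature) + n) / ns
    block_sites <- max(2L, as.integer(round(config$grna_block_length /
                                              nt_per_site)))
    blocks <- purrr::map_dfr(seq_along(domains), function(di) {
      d <- domains[[di]]
      cuts <- seq(d[2], d[1], by = -block_sites)
      if (cuts[length(cuts)] != d[1]) cuts <- c(cuts, d[1])
      tibble::tibble(domain = di,
                     site_lo = rev(cuts)[-length(cuts)],
                     site_hi = rev(cuts)[-1])
    })
    blocks <- dplyr::arrange(blocks, .data$domain, dplyr::desc(.data$site_lo))
    blocks$block <- seq_len(nrow(blocks))
    blocks$order <- seq_len(nrow(blocks))

    # every block must contain at least one mature-edited site (so that
    # partially edited transcripts are distinguishable per block)
    if (config$ensure_block_edits) {
      for (b in seq_len(nrow(blocks))) {
        idx <- seq(blocks$site_lo[b] + 1L, blocks$site_hi[b])
        if (all(mature[idx] == pre_runs[idx])) {
          mid <- idx[ceiling(length(idx) / 2)]
          mature[mid] <- mature[mid] + 1L
        }
      }
    }

    # seed region in the never-edited 3' tail (sequence coordinates)
    last_hi <- max(vapply(domains, `[`, integer(1), 2))
    seed_bases <- seq(last_hi + 1L, min(n - 1L, last_hi + 12L))
    pos <- vapply(seed_bases, function(b) base_position(pre_runs, b),
                  integer(1))
    seed_region <- c(min(pos), max(pos) + 1L)

    crypt <- cryptogene("sim_locus", recompose(sk), domains, seed_region)
    mature_state <- editing_state(crypt$id, 0L, ns, mature)
    structure(list(crypt = crypt,
                   mature_state = mature_state,
                   mature_seq = recompose(sk, mature),
                   blocks = blocks,
                   config = config),
              class = "uindel_locus")
  })
}

#' @export
print.uindel_locus <- function(x, ...) {
  cat("<uindel_locus> ", nchar(x$crypt$pre_edited), " nt pre-edited, ",
      nchar(x$mature_seq), " nt mature, ", nrow(x$blocks),
      " gRNA block(s)\n", sep = "")
  invisible(x)
}

# alternative (main-pathway-violating) run value at one site
alt_run_value <- function(pre, mature) {
  if (mature > pre) mature + 1L + rgeom(1, 0.5)   # longer insertion
  else pre + 1L   # insertion where main deletes / never edits
}

#' Simulate reads from a population of partially edited transcripts
#'
#' Each read is drawn from a transcript with an editing frontier `f`
#' (blocks of cascade order `<= f` edited, the rest pre-edited), with a
#' terminal alternative stretch just past the frontier with probability
#' `misedit_rate` and per-site internal alternative values inside the
#' edited region with probability `internal_misedit_rate`.  Reads are
#' error-free substrings of the transcript unless `seq_error_rate > 0`.
#'
#' @param locus A [simulate_locus()] result.
#' @param config A [simulation_config()]; defaults to the locus' own.
#' @return A tibble of class `uindel_simreads`: `read_id`, `seq` (as
#'   sequenced), `strand`, `frontier`, `tx_start`, `tx_len` (0-based
#'   transcript window), `obs_lo`/`obs_hi` (the uncensored site range the
#'   read observes), `alt_sites` (list-column of planted alternative
#'   site indices), `alt_observed` (those the read observes uncensored),
#'   and `is_alternative` (truth label: observes >= 1 alternative site).
#' @export
simulate_reads <- function(locus, config = locus$config) {
  stopifnot(inherits(locus, "uindel_locus"))
  with_local_seed(config$rng_seed + 1L, {
    crypt <- locus$crypt
    sk <- crypt$skeleton
    pre <- sk$runs
    mat <- locus$mature_state$runs
    blocks <- locus$blocks
    B <- nrow(blocks)
    mean_len <- mean(config$read_len)
    n_reads <- max(1L, ceiling(config$coverage * nchar(locus$mature_seq) /
                                 mean_len))
    w <- c(rep((1 - config$mature_fraction) / B, B), config$mature_fraction)
    rows <- vector("list", n_reads)
    for (i in seq_len(n_reads)) {
      f <- sample(0:B, 1L, prob = w)
      runs <- pre
      if (f > 0) {
        for (b in which(blocks$order <= f)) {
          idx <- seq(blocks$site_lo[b] + 1L, blocks$site_hi[b])
          runs[idx] <- mat[idx]
        }
      }
      alt_sites <- integer(0)
      if (f < B && runif(1) < config$misedit_rate) {
        nb <- which(blocks$order == f + 1L)
        idx <- seq(blocks$site_lo[nb] + 1L, blocks$site_hi[nb])
        n_t <- sample.int(min(3L, length(idx)), 1L)
        # terminal stretch: sites adjacent to the already-edited region,
        # i.e. the 3'-most sites of the next block in the cascade
        tgt <- sort(idx, decreasing = TRUE)[seq_len(n_t)]
        for (s in tgt) runs[s] <- alt_run_value(pre[s], mat[s])
        alt_sites <- c(alt_sites, tgt - 1L)  # 0-based site indices
      }
      if (f > 0 && config$internal_misedit_rate > 0) {
        edited_idx <- unlist(lapply(which(blocks$order <= f), function(b) {
          seq(blocks$site_lo[b] + 1L, blocks$site_hi[b])
        }))
        hit <- edited_idx[runif(length(edited_idx)) <
                            config$internal_misedit_rate]
        for (s in hit) runs[s] <- alt_run_value(pre[s], mat[s])
        alt_sites <- c(alt_sites, hit - 1L)
      }
      alt_sites <- sort(unique(alt_sites))
      tx <- recompose(sk, runs)
      L <- nchar(tx)
      len_draw <- if (config$read_len[1] == config$read_len[2]) {
        config$read_len[1]
      } else {
        config$read_len[1] + sample.int(config$read_len[2] -
                                          config$read_len[1] + 1L, 1L) - 1L
      }
      len <- min(L, len_draw)
      start <- sample.int(L - len + 1L, 1L) - 1L  # 0-based
      seq <- substr(tx, start + 1L, start + len)
      if (config$seq_error_rate > 0) {
        chars <- strsplit(seq, "", fixed = TRUE)[[1]]
        err <- which(runif(length(chars)) < config$seq_error_rate)
        for (e in err) {
          chars[e] <- sample(setdiff(c("A", "C", "G", "T"), chars[e]), 1L)
        }
        seq <- paste(chars, collapse = "")
      }
      strand <- if (config$strand_specific || runif(1) < 0.5) "+" else "-"
      if (strand == "-") seq <- revcomp(seq)
      # sites observed uncensored by the read window (transcript coords)
      bp <- cumsum(runs[seq_len(length(runs) - 1L)] + 1L) - 1L  # base pos
      covered <- which(bp >= start & bp < start + len)  # 1-based base idx
      unc <- if (length(covered) >= 2) {
        seq(min(covered), max(covered) - 1L)  # 0-based interior sites
      } else integer(0)
      alt_obs <- intersect(alt_sites, unc)
      rows[[i]] <- tibble::tibble(
        read_id = sprintf("sim%06d", i), seq = seq, strand = strand,
        frontier = f, tx_start = start, tx_len = len,
        obs_lo = if (length(unc)) min(unc) else NA_integer_,
        obs_hi = if (length(unc)) max(unc) else NA_integer_,
        alt_sites = list(alt_sites), alt_observed = list(alt_obs),
        is_alternative = length(alt_obs) > 0)
    }
    out <- dplyr::bind_rows(rows)
    class(out) <- c("uindel_simreads", class(out))
    out
  })
}

#' Analytic expectation of the alternatively edited read fraction
#'
#' For full-length reads (reads spanning the whole transcript) the
#' probability that a read is alternatively edited, and the probability
#' that it is edited at all, follow in closed form from the frontier
#' distribution and the two misediting rates.  Used as the independent
#' oracle for [misediting_summary()] on simulated data.
#'
#' @param locus A [simulate_locus()] result.
#' @param config A [simulation_config()].
#' @return A list with `p_alternative`, `p_edited` and
#'   `expected_fraction` (= alternative among edited).
#' @export
expected_alternative_fraction <- function(locus, config = locus$config) {
  blocks <- locus$blocks
  B <- nrow(blocks)
  sites_per_block <- blocks$site_hi - blocks$site_lo
  w <- c(rep((1 - config$mature_fraction) / B, B), config$mature_fraction)
  f_vals <- 0:B
  s_f <- c(0, cumsum(sites_per_block[order(blocks$order)]))
  m_t <- config$misedit_rate
  m_i <- config$internal_misedit_rate
  p_alt_f <- 1 - (1 - m_t * (f_vals < B)) * (1 - m_i)^s_f
  p_edit_f <- ifelse(f_vals >= 1, 1, m_t)
  p_alt <- sum(w * p_alt_f)
  p_edit <- sum(w * p_edit_f)
  list(p_alternative = p_alt, p_edited = p_edit,
       expected_fraction = p_alt / p_edit)
}

#' Synthetic transcript pair planting exact editing counts
#'
#' Builds a deterministic, fully synthetic pre-edited/edited sequence pair
#' whose per-domain U-insertion, U-deletion and edited-site counts equal
#' the requested values.  This is the stand-in used to exercise the
#' editing-count bookkeeping at the scale of published per-gene tables
#' when the underlying transcript sequences are not available: the
#' sequences are synthetic, only the planted counts are meaningful.
#'
#' @param gene Identifier for the cryptogene.
#' @param pre_size Total pre-edited length in nt.
#' @param region_lengths Integer vector of pre-edited editing-region
#'   lengths (nt), 5' to 3'.
#' @param ins,del,sites Integer vectors (same length) of U-insertion,
#'   U-deletion and edited-site counts per region.
#' @return A list: `crypt` (a [cryptogene()] with the regions as editing
#'   domains and a 3' seed region), `edited` (edited sequence),
#'   `mature_state`.
#' @export
synthetic_transcripts_from_counts <- function(gene, pre_size, region_lengths,
                                              ins, del, sites) {
  k <- length(region_lengths)
  stopifnot(length(ins) == k, length(del) == k, length(sites) == k)
  # feasibility per region
  n_b_region <- region_lengths - del
  stopifnot(all(n_b_region - 1L >= sites), all(sites >= 0))

  flank_total <- pre_size - sum(region_lengths)
  stopifnot(flank_total >= (k + 1L) * 6L)
  # lead / gaps / tail split of the non-edited remainder
  n_flanks <- k + 1L
  flank <- rep(flank_total %/% n_flanks, n_flanks)
  flank[n_flanks] <- flank[n_flanks] + flank_total %% n_flanks

  acg <- function(n) {
    if (n == 0) return("")
    paste(rep_len(c("A", "C", "G"), n), collapse = "")
  }

  pre_parts <- character(0)
  pre_runs_parts <- list()
  domains <- list()
  base_count <- 0L
  mature_parts <- list()
  for (r in seq_len(k)) {
    fl <- flank[r]
    pre_parts <- c(pre_parts, acg(fl))
    pre_runs_parts <- c(pre_runs_parts, list(rep(0L, fl)))
    mature_parts <- c(mature_parts, list(rep(0L, fl)))
    base_count <- base_count + fl

    S <- sites[r]; D <- del[r]; I <- ins[r]
    n_b <- n_b_region[r]
    d_sites <- max(min(D, S), S - I)
    i_sites <- S - d_sites
    stopifnot(d_sites <= D || d_sites == 0, i_sites <= I || i_sites == 0)
    # interior sites of the region: choose the first S
    site_pre <- rep(0L, n_b - 1L)
    site_ed <- rep(0L, n_b - 1L)
    if (d_sites > 0) {
      per <- rep(1L, d_sites); per[1] <- per[1] + (D - d_sites)
      site_pre[seq_len(d_sites)] <- per
    }
    if (i_sites > 0) {
      per <- rep(1L, i_sites); per[1] <- per[1] + (I - i_sites)
      site_ed[d_sites + seq_len(i_sites)] <- per
    }
    region_bases <- acg(n_b)
    region_seq <- paste0(
      paste0(strsplit(region_bases, "")[[1]][-n_b],
             vapply(site_pre, function(x) strrep("T", x), character(1)),
             collapse = ""),
      substr(region_bases, n_b, n_b))
    stopifnot(nchar(region_seq) == region_lengths[r])
    pre_parts <- c(pre_parts, region_seq)
    # runs: first region base has site run 0 before it (belongs to flank),
    # interior sites carry site_pre, handled via per-base accounting below
    pre_runs_parts <- c(pre_runs_parts, list(c(0L, site_pre)))
    mature_parts <- c(mature_parts, list(c(0L, site_ed)))
    domains <- c(domains, list(c(base_count + 1L, base_count + n_b)))
    base_count <- base_count + n_b
  }
  fl <- flank[n_flanks]
  pre_parts <- c(pre_parts, acg(fl))
  pre_runs_parts <- c(pre_runs_parts, list(rep(0L, fl)))
  mature_parts <- c(mature_parts, list(rep(0L, fl)))
  base_count <- base_count + fl

  pre_seq <- paste(pre_parts, collapse = "")
  stopifnot(nchar(pre_seq) == pre_size)
  # seed region: inside the 3' tail, skipping 2 bases after the last domain
  tail_start_base <- base_count - fl + 2L
  sk <- decompose(pre_seq)
  pos_a <- base_position(sk$runs, tail_start_base)
  pos_b <- base_position(sk$runs, min(base_count - 1L, tail_start_base + 13L))
  crypt <- cryptogene(gene, pre_seq, domains, c(pos_a, pos_b + 1L))

  # mature runs per site from the per-base accounting
  pre_site_runs <- unlist(pre_runs_parts)
  ed_site_runs <- unlist(mature_parts)
  # runs vectors are per-base "run before base"; append trailing run 0
  runs_pre <- c(pre_site_runs, 0L)
  runs_ed <- c(ed_site_runs, 0L)
  stopifnot(identical(as.integer(runs_pre), crypt$skeleton$runs))
  st <- editing_state(gene, 0L, length(runs_ed), runs_ed)
  list(crypt = crypt, edited = apply_editing(crypt, st), mature_state = st)
}

#' Published per-gene editing counts used as synthetic-construction inputs
#'
#' The per-domain U-insertion/U-deletion/edited-site counts and sizes
#' reported for the six edited mitochondrial mRNAs of the two *Perkinsela*
#' strains.  These printed counts serve as inputs to
#' [synthetic_transcripts_from_counts()]; the sequences built from them
#' are synthetic.
#'
#' @return A tibble with one row per strain/gene: `strain`, `gene`,
#'   `pre_edited_size`, `edited_size_printed`, `region_lengths`, `ins`,
#'   `del`, `sites` (the last four are list-columns, one element per
#'   editing region 5' to 3').
#' @export
perkinsela_editing_counts <- function() {
  tibble::tribble(
    ~strain, ~gene, ~pre_edited_size, ~edited_size_printed,
    ~region_lengths, ~ins, ~del, ~sites,
    "CCAP1560/4", "cob", 964L, 1136L, c(35L, 134L), c(41L, 146L),
    c(3L, 13L), c(14L, 68L),
    "GillNOR1/I", "cob", 936L, 1125L, c(36L, 134L), c(45L, 141L),
    c(4L, 8L), c(15L, 66L),
    "CCAP1560/4", "cox1", 1374L, 1567L, c(78L, 107L), c(77L, 121L),
    c(3L, 3L), c(31L, 54L),
    "GillNOR1/I", "cox1", 1365L, 1589L, c(68L, 103L), c(77L, 125L),
    c(2L, 3L), c(30L, 53L),
    "CCAP1560/4", "cox2", 486L, 661L, c(55L, 227L), c(57L, 151L),
    c(6L, 28L), c(23L, 102L),
    "GillNOR1/I", "cox2", 487L, 710L, c(57L, 177L), c(58L, 148L),
    c(8L, 26L), c(24L, 98L),
    "CCAP1560/4", "cox3", 656L, 814L, c(45L, 89L), c(69L, 93L),
    c(2L, 2L), c(31L, 47L),
    "GillNOR1/I", "cox3", 624L, 801L, c(54L, 97L), c(71L, 93L),
    c(3L, 2L), c(31L, 47L),
    "CCAP1560/4", "rps12", 157L, 268L, 123L, 123L, 13L, 52L,
    "GillNOR1/I", "rps12", 150L, 257L, 110L, 123L, 12L, 52L,
    "CCAP1560/4", "atp6", 363L, 651L, 309L, 318L, 30L, 154L,
    "GillNOR1/I", "atp6", 321L, 625L, 298L, 311L, 28L, 152L)
}
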