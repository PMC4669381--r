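#' Reconstruct the main editing pathway
#'
#' Follows the 3'-to-5' progression of U-indel editing: sites are
#' processed from the 3'-most edited site towards 5'.  At each site the
#' voters are reads that (i) observe it uncensored, (ii) agree with the
#' reconstruction at every more-3' site they cover, and (iii) are
#' themselves edited at or 5' of the site — since editing progresses 3'
#' to 5', such reads have passed through the site and their value there
#' is final, whereas unedited precursors (whose editing has not reached
#' the site yet) abstain.  The modal value among voters is adopted, a
#' non-pre-edited value additionally requiring at least `min_support`
#' supporting reads (otherwise the pre-edited value is kept), and at
#' least a fraction `min_fraction` of the eligible edited reads
#' observing the site — the main pathway is the *predominant* product,
#' so a couple of coinciding misedits among hundreds of edited reads
#' must not extend it.  The agreement filter lets partially edited reads
#' drop out of the vote 5' of their own editing frontier.  Ties break
#' towards the smaller
#' `|run - pre_run|`, then towards insertion.  When raw reads are
#' supplied, up to `max_iterations` rounds of re-mapping are performed on
#' the partially edited template, with the anchoring seed shifting in the
#' 5' direction — reads edited over their whole length lack a seed match
#' on the pre-edited sequence and only become mappable on a partially
#' edited template.
#'
#' A user-supplied mature mRNA (`mature`) bypasses reconstruction
#' entirely and defines the main pathway directly.
#'
#' @param alignments A [map_all()] result (may be `NULL` when `reads` are
#'   given).
#' @param crypt The [cryptogene()].
#' @param reads Optional reads (tibble with `read_id`, `seq`, or named
#'   character) enabling iterative re-mapping.
#' @param scheme [scoring_scheme()] used for re-mapping.
#' @param min_support Minimum read count for adopting an edited value.
#' @param min_fraction Minimum fraction of eligible edited reads
#'   observing a site that must carry the adopted value.
#' @param max_iterations Maximum mapping/reconstruction rounds.
#' @param mature Optional known mature mRNA sequence (bypass mode).
#' @param seed_length Approximate seed length (nt) for re-seeding.
#' @param strand_specific Passed to [map_all()] on re-mapping.
#' @return An object of class `uindel_pathway`: the full main-pathway
#'   editing state, per-site support counts, `iterations_used`, the 5'
#'   `frontier` site (the 5'-most site down to which every more-3'
#'   domain site had eligible read coverage), and `alignments`, the
#'   merged mapped-read set accumulated over the mapping iterations
#'   (editing states are always expressed in cryptogene site
#'   coordinates, whichever template a read was mapped against).
#' @export
reconstruct_main <- function(alignments, crypt, reads = NULL,
                             scheme = scheme_strict(), min_support = 2L,
                             min_fraction = 0.25, max_iterations = 3L,
                             mature = NULL, seed_length = 14L,
                             strand_specific = FALSE) {
  stopifnot(inherits(crypt, "uindel_cryptogene"))
  ns <- n_sites(crypt$skeleton)
  if (!is.null(mature)) {
    st <- diff_editing(crypt, mature)
    aln <- if (!is.null(alignments)) {
      dplyr::filter(alignments, .data$mapped)
    } else NULL
    return(structure(list(cryptogene_id = crypt$id, state = st,
                          support = rep(NA_integer_, ns),
                          iterations_used = 0L,
                          frontier = min_domain_site(crypt),
                          min_support = min_support,
                          alignments = aln),
                     class = "uindel_pathway"))
  }
  if (is.null(alignments) && is.null(reads)) {
    stop("supply alignments, reads, or a mature sequence", call. = FALSE)
  }
  if (is.null(alignments)) {
    alignments <- map_all(reads, crypt, scheme = scheme,
                          strand_specific = strand_specific)
  }
  all_aln <- dplyr::filter(alignments, .data$mapped)
  pass <- recon_pass(all_aln, crypt, min_support, min_fraction)
  iterations <- 1L

  while (!is.null(reads) && iterations < max_iterations) {
    template <- recompose(crypt$skeleton, pass$runs)
    # re-seed along the whole current template (its 3' part carries the
    # reconstruction so far): the generalisation of shifting the seed in
    # the 3'-to-5' direction over successive mapping rounds
    seed <- tile_seeds(template, seed_length,
                       spacing = max(6L, seed_length %/% 2L))
    new_aln <- map_all(reads, crypt, seed = seed, scheme = scheme,
                       template = template,
                       strand_specific = strand_specific)
    n_before <- nrow(all_aln)
    merged <- dplyr::bind_rows(all_aln,
                               dplyr::filter(new_aln, .data$mapped))
    merged <- dplyr::arrange(merged, .data$read_id, dplyr::desc(.data$score))
    all_aln <- dplyr::distinct(merged, .data$read_id, .keep_all = TRUE)
    new_pass <- recon_pass(all_aln, crypt, min_support, min_fraction)
    iterations <- iterations + 1L
    no_progress <- identical(new_pass$runs, pass$runs) &&
      nrow(all_aln) == n_before
    pass <- new_pass
    if (no_progress) break
  }

  structure(list(cryptogene_id = crypt$id,
                 state = editing_state(crypt$id, 0L, ns, pass$runs),
                 support = pass$support,
                 iterations_used = iterations,
                 frontier = pass$frontier,
                 min_support = min_support,
                 alignments = all_aln),
            class = "uindel_pathway")
}

min_domain_site <- function(crypt) {
  if (length(crypt$editing_domains) == 0) return(0L)
  min(vapply(crypt$editing_domains, `[`, integer(1), 1))
}

domain_site_set <- function(crypt) {
  if (length(crypt$editing_domains) == 0) return(integer(0))
  sort(unique(unlist(lapply(crypt$editing_domains, function(d) {
    seq(d[1], d[2] - 1L)
  }))))
}

# one 3'->5' reconstruction pass over a fixed alignment set
recon_pass <- function(aln, crypt, min_support, min_fraction = 0.25) {
  pre <- crypt$skeleton$runs
  ns <- length(pre)
  cur <- pre
  support <- rep(0L, ns)
  dom <- domain_site_set(crypt)
  n <- nrow(aln)
  if (n == 0) {
    return(list(runs = cur, support = support,
                frontier = if (length(dom)) max(dom) + 1L else 0L))
  }
  ulo <- aln$site_lo + as.integer(aln$censored_lo)
  uhi <- aln$site_hi - 1L - as.integer(aln$censored_hi)
  runs <- aln$runs
  slo <- aln$site_lo
  # 5'-most site at which each read itself deviates from the pre-edited
  # runs: since editing progresses 3' to 5', a read edited at or 5' of a
  # site has passed through it and its value there is final ("informed");
  # reads whose editing has not reached a site abstain from its vote, so
  # unedited precursors do not drown out edited reads
  medit <- vapply(seq_len(n), function(i) {
    if (uhi[i] < ulo[i]) return(NA_integer_)
    sites <- ulo[i]:uhi[i]
    v <- runs[[i]][sites - slo[i] + 1L]
    ed <- sites[v != pre[sites + 1L]]
    if (length(ed) == 0) NA_integer_ else min(ed)
  }, integer(1))
  consistent <- rep(TRUE, n)
  covered <- rep(FALSE, ns)

  for (s in seq(ns - 1L, 0L)) {
    obs <- which(consistent & ulo <= s & uhi >= s)
    vals <- vapply(obs, function(i) runs[[i]][s - slo[i] + 1L], integer(1))
    in_dom <- s %in% dom
    if (in_dom && length(obs) > 0) {
      covered[s + 1L] <- TRUE
      informed <- !is.na(medit[obs]) & medit[obs] <= s
      if (any(informed)) {
        tab <- table(vals[informed])
        cand <- as.integer(names(tab)[tab == max(tab)])
        if (length(cand) > 1) {  # tie-breaks
          dd <- abs(cand - pre[s + 1L])
          cand <- cand[dd == min(dd)]
          cand <- max(cand)      # towards insertion
        }
        # predominance guard: the adopted value must be carried by a
        # minimum fraction of the edited reads observing the site, so a
        # couple of coinciding misedits cannot extend the main pathway
        # past the true 5' end of editing
        n_edited_obs <- sum(!is.na(medit[obs]))
        if (cand != pre[s + 1L] && max(tab) >= min_support &&
            max(tab) >= min_fraction * n_edited_obs) {
          cur[s + 1L] <- cand
        }
        support[s + 1L] <- sum(vals[informed] == cur[s + 1L])
      }
    }
    # reads disagreeing with the reconstruction at this (more-3') site
    # become ineligible further 5'
    if (length(obs) > 0) {
      bad <- obs[vals != cur[s + 1L]]
      consistent[bad] <- FALSE
    }
  }
  uncov <- dom[!covered[dom + 1L]]
  frontier <- if (length(uncov) == 0) {
    if (length(dom)) min(dom) else 0L
  } else max(uncov) + 1L
  list(runs = cur, support = support, frontier = frontier)
}

#' @export
print.uindel_pathway <- function(x, ...) {
  cat("<uindel_pathway> ", x$cryptogene_id, ": ", x$iterations_used,
      " iteration(s), 5' frontier at site ", x$frontier, "\n", sep = "")
  invisible(x)
}

#' @rdname reconstruct_main
#' @param x A `uindel_pathway`.
#' @param ... Unused.
#' @export
tidy.uindel_pathway <- function(x, ...) {
  ns <- length(x$support)
  tibble::tibble(site = seq_len(ns) - 1L,
                 main_run = x$state$runs,
                 support = x$support)
}

#' @rdname reconstruct_main
#' @export
glance.uindel_pathway <- function(x, ...) {
  tibble::tibble(cryptogene_id = x$cryptogene_id,
                 iterations_used = x$iterations_used,
                 frontier = x$frontier,
                 n_sites = length(x$support))
}

#' Classify one read against the main editing pathway
#'
#' Site-level rules: a site observed with its pre-edited run is
#' `unedited`; a site whose run lies between the pre-edited and
#' main-pathway values (same direction, shorter or equal) is
#' `main_consistent`; anything else is `alternative`, subtyped
#' `never-edited-site` (edited where the main product is not),
#' `longer-indel` (same direction but longer than the main product) or
#' `direction-reversed` (insertion where the main product deletes, or
#' vice versa).  Read-level trichotomy: `reference` (all observed sites
#' pre-edited), `main` (no alternative site), `alternative` (at least
#' one).  Censored boundary sites are excluded and never create
#' alternative calls.
#'
#' @param state A (possibly censored) [editing_state()].
#' @param crypt The [cryptogene()].
#' @param main A `uindel_pathway` from [reconstruct_main()].
#' @return A list with `class` and `site_calls` (tibble: `site`,
#'   `pre_run`, `main_run`, `read_run`, `class`, `subtype`).
#' @export
classify_read <- function(state, crypt, main) {
  pre <- crypt$skeleton$runs
  mr <- main$state$runs
  sites <- uncensored_sites(state)
  if (length(sites) == 0) {
    return(list(class = "reference",
                site_calls = site_call_tbl(integer(0), integer(0),
                                           integer(0), character(0),
                                           character(0))))
  }
  p <- pre[sites + 1L]
  m <- mr[sites + 1L]
  r <- vapply(sites, function(s) state_run(state, s), integer(1))
  cls <- character(length(sites))
  sub <- rep(NA_character_, length(sites))
  for (i in seq_along(sites)) {
    cls[i] <- site_class(p[i], m[i], r[i])
    if (cls[i] == "alternative") sub[i] <- site_subtype(p[i], m[i], r[i])
  }
  read_class <- if (all(r == p)) "reference"
  else if (!any(cls == "alternative")) "main"
  else "alternative"
  list(class = read_class,
       site_calls = site_call_tbl(sites, p, m, r, cls, sub))
}

site_call_tbl <- function(sites, p, m, r, cls, sub = rep(NA_character_,
                                                         length(sites))) {
  tibble::tibble(site = as.integer(sites), pre_run = as.integer(p),
                 main_run = as.integer(m), read_run = as.integer(r),
                 class = cls, subtype = sub)
}

site_class <- function(p, m, r) {
  if (r == p) return("unedited")
  if (m == p) return("alternative")              # never edited in main
  same_dir <- sign(r - p) == sign(m - p)
  if (same_dir && abs(r - p) <= abs(m - p)) return("main_consistent")
  "alternative"
}

site_subtype <- function(p, m, r) {
  if (m == p) return("never-edited-site")
  if (sign(r - p) == sign(m - p)) return("longer-indel")
  "direction-reversed"
}

#' Classify all mapped reads
#'
#' Applies [classify_read()] to every mapped row of a [map_all()] result.
#'
#' @param alignments A [map_all()] result.
#' @inheritParams classify_read
#' @return The mapped rows with added columns `class`, `n_edited_sites`
#'   (observed non-pre-edited uncensored sites), `n_alt_sites`, and a
#'   `site_calls` list-column.
#' @export
classify_reads <- function(alignments, crypt, main) {
  m <- dplyr::filter(alignments, .data$mapped)
  if (nrow(m) == 0) {
    m$class <- character(0)
    m$n_edited_sites <- integer(0)
    m$n_alt_sites <- integer(0)
    m$site_calls <- list()
    return(m)
  }
  res <- purrr::map(seq_len(nrow(m)), function(i) {
    st <- editing_state(m$cryptogene_id[i], m$site_lo[i], m$site_hi[i],
                        m$runs[[i]], m$censored_lo[i], m$censored_hi[i])
    classify_read(st, crypt, main)
  })
  m$class <- vapply(res, `[[`, character(1), "class")
  m$site_calls <- purrr::map(res, "site_calls")
  m$n_edited_sites <- vapply(res, function(x) {
    sum(x$site_calls$read_run != x$site_calls$pre_run)
  }, integer(1))
  m$n_alt_sites <- vapply(res, function(x) {
    sum(x$site_calls$class == "alternative")
  }, integer(1))
  class(m) <- c("uindel_classified", class(m))
  m
}

# uncensored state of one alignment row as a plain list
row_state <- function(rows, i) {
  lo <- rows$site_lo[i] + as.integer(rows$censored_lo[i])
  hi <- rows$site_hi[i] - 1L - as.integer(rows$censored_hi[i])
  if (hi < lo) return(NULL)
  runs <- rows$runs[[i]][(lo - rows$site_lo[i] + 1L):
                           (hi - rows$site_lo[i] + 1L)]
  list(lo = lo, hi = hi, runs = as.integer(runs))
}

state_contains <- function(big, small) {
  if (small$lo < big$lo || small$hi > big$hi) return(FALSE)
  off <- small$lo - big$lo
  identical(small$runs, big$runs[(off + 1L):(off + length(small$runs))])
}

#' Merge alternatively edited reads into editing intermediates
#'
#' Reads whose editing state over their covered (uncensored) site range is
#' contained in a longer read's state merge into that read's
#' intermediate.  Containment is resolved against maximal intermediates
#' only; a read contained in `k > 1` retained intermediates contributes
#' `1/k` support to each, so the supports of all intermediates sum to the
#' number of merged reads exactly.
#'
#' @param alignments Alternative-class rows of a [classify_reads()]
#'   result (reads of the reference and main-pathway groups must be
#'   excluded before merging).
#' @param crypt,main Optional; when given, alternative stretches of each
#'   intermediate are annotated `terminal` (no canonically edited site 5'
#'   of the stretch within the read: abortive editing at the frontier),
#'   `internal`, or `mixed`.
#' @return A tibble of class `uindel_intermediates`: `intermediate`,
#'   `site_lo`, `site_hi`, `runs` (list), `n_members`, `support`,
#'   `read_ids` (list) and, when annotated, `stretch_type` and
#'   `n_alt_sites`.
#' @export
merge_intermediates <- function(alignments, crypt = NULL, main = NULL) {
  rows <- alignments
  n <- nrow(rows)
  if (n == 0) {
    return(structure(tibble::tibble(intermediate = integer(0),
                                    site_lo = integer(0),
                                    site_hi = integer(0), runs = list(),
                                    n_members = integer(0),
                                    support = numeric(0),
                                    read_ids = list()),
                     class = c("uindel_intermediates", "tbl_df", "tbl",
                               "data.frame")))
  }
  states <- purrr::map(seq_len(n), function(i) row_state(rows, i))
  keep <- !vapply(states, is.null, logical(1))
  states <- states[keep]
  ids <- rows$read_id[keep]
  keys <- vapply(states, function(s) {
    paste(s$lo, s$hi, paste(s$runs, collapse = ","), sep = ":")
  }, character(1))
  uk <- unique(keys)
  ustates <- states[match(uk, keys)]
  nu <- length(uk)
  # maximal states: not strictly contained in any other unique state
  maximal <- rep(TRUE, nu)
  for (i in seq_len(nu)) {
    for (j in seq_len(nu)) {
      if (i != j && state_contains(ustates[[j]], ustates[[i]])) {
        maximal[i] <- FALSE
        break
      }
    }
  }
  midx <- which(maximal)
  support <- numeric(length(midx))
  members <- vector("list", length(midx))
  exact <- integer(length(midx))
  for (r in seq_along(states)) {
    inm <- which(vapply(midx, function(mi) {
      state_contains(ustates[[mi]], states[[r]])
    }, logical(1)))
    k <- length(inm)
    for (mi in inm) {
      support[mi] <- support[mi] + 1 / k
      members[[mi]] <- c(members[[mi]], ids[r])
    }
  }
  out <- tibble::tibble(
    intermediate = seq_along(midx),
    site_lo = vapply(midx, function(i) ustates[[i]]$lo, integer(1)),
    site_hi = vapply(midx, function(i) ustates[[i]]$hi + 1L, integer(1)),
    runs = purrr::map(midx, function(i) ustates[[i]]$runs),
    n_members = vapply(midx, function(i) sum(keys == uk[i]), integer(1)),
    support = support,
    read_ids = members)
  if (!is.null(crypt) && !is.null(main)) {
    ann <- purrr::map(seq_len(nrow(out)), function(i) {
      st <- editing_state(crypt$id, out$site_lo[i], out$site_hi[i],
                          out$runs[[i]])
      annotate_stretches(st, crypt, main)
    })
    out$stretch_type <- vapply(ann, `[[`, character(1), "type")
    out$n_alt_sites <- vapply(ann, `[[`, integer(1), "n_alt")
  }
  out <- dplyr::arrange(out, dplyr::desc(.data$support), .data$site_lo)
  out$intermediate <- seq_len(nrow(out))
  class(out) <- c("uindel_intermediates", class(out))
  out
}

# terminal vs internal annotation of the alternative stretches of a state
annotate_stretches <- function(state, crypt, main) {
  calls <- classify_read(state, crypt, main)$site_calls
  alt <- calls$class == "alternative"
  n_alt <- sum(alt)
  if (n_alt == 0) return(list(type = NA_character_, n_alt = 0L))
  edited_main <- calls$class == "main_consistent"
  # stretches: runs of alternative sites separated by canonically edited
  # sites; unedited sites do not break a stretch
  grp <- cumsum(edited_main)[alt]
  types <- vapply(split(which(alt), grp), function(ix) {
    first <- min(ix)
    before <- seq_len(first - 1L)
    if (length(before) == 0 || !any(edited_main[before])) "terminal"
    else "internal"
  }, character(1))
  type <- if (all(types == "terminal")) "terminal"
  else if (all(types == "internal")) "internal" else "mixed"
  list(type = type, n_alt = as.integer(n_alt))
}

#' Summarise alternative editing and misediting
#'
#' Per-domain counts of reference / main-pathway / alternative reads, the
#' percentage of alternatively edited reads among edited reads, a
#' histogram of alternative-site counts per read, and the editing
#' intermediates ranked by support.
#'
#' @param classified A [classify_reads()] result.
#' @param intermediates Optional [merge_intermediates()] result.
#' @param crypt The [cryptogene()].
#' @param domains Optional list of site intervals; defaults to the
#'   cryptogene's editing domains.
#' @return A list of class `uindel_misediting` with elements `by_domain`,
#'   `overall`, `alt_site_histogram` and `intermediates`.
#' @export
misediting_summary <- function(classified, intermediates = NULL, crypt,
                               domains = NULL) {
  if (is.null(domains)) domains <- crypt$editing_domains
  if (length(domains) == 0) {
    domains <- list(c(0L, n_sites(crypt$skeleton)))
  }
  by_domain <- purrr::map_dfr(seq_along(domains), function(di) {
    d <- domains[[di]]
    cls <- domain_classes(classified, d)
    n_ref <- sum(cls == "reference")
    n_main <- sum(cls == "main")
    n_alt <- sum(cls == "alternative")
    n_edited <- n_main + n_alt
    tibble::tibble(domain = di, site_lo = d[1], site_hi = d[2],
                   n_reads = length(cls),
                   n_reference = n_ref, n_main = n_main,
                   n_alternative = n_alt, n_edited = n_edited,
                   pct_alternative = if (n_edited > 0)
                     100 * n_alt / n_edited else NA_real_)
  })
  n_edited_all <- sum(classified$n_edited_sites > 0)
  n_alt_all <- sum(classified$class == "alternative")
  overall <- tibble::tibble(
    n_reads = nrow(classified),
    n_reference = sum(classified$class == "reference"),
    n_main = sum(classified$class == "main"),
    n_alternative = n_alt_all,
    n_edited = n_edited_all,
    pct_alternative = if (n_edited_all > 0)
      100 * n_alt_all / n_edited_all else NA_real_)
  hist <- dplyr::count(
    dplyr::filter(classified, .data$n_alt_sites > 0),
    .data$n_alt_sites, name = "n_reads")
  structure(list(by_domain = by_domain, overall = overall,
                 alt_site_histogram = hist,
                 intermediates = intermediates),
            class = "uindel_misediting")
}

# read classes restricted to one domain's sites
domain_classes <- function(classified, d) {
  keep <- vapply(seq_len(nrow(classified)), function(i) {
    calls <- classified$site_calls[[i]]
    any(calls$site >= d[1] & calls$site < d[2])
  }, logical(1))
  vapply(which(keep), function(i) {
    calls <- classified$site_calls[[i]]
    calls <- calls[calls$site >= d[1] & calls$site < d[2], ]
    if (any(calls$class == "alternative")) "alternative"
    else if (any(calls$read_run != calls$pre_run)) "main"
    else "reference"
  }, character(1))
}

#' @export
print.uindel_misediting <- function(x, ...) {
  cat("<uindel_misediting>\n")
  print(x$by_domain)
  invisible(x)
}

#' @rdname misediting_summary
#' @param x A `uindel_misediting`.
#' @param ... Unused.
#' @export
tidy.uindel_misediting <- function(x, ...) x$by_domain

#' @rdname misediting_summary
#' @export
glance.uindel_misediting <- function(x, ...) x$overall

#' Editing order of two domains
#'
#' Counts, among reads spanning both domains, the four combinations of
#' "domain edited" (at least one uncensored non-pre-edited site in the
#' domain).  Used to test whether one domain is edited before the other:
#' under strict 5'-before-3' order, the "3' only" cell is empty.
#'
#' @param classified A [classify_reads()] result.
#' @param domain_a,domain_b Site intervals (0-based half-open) of the two
#'   domains, 5' and 3' respectively.
#' @return A tibble with `a_edited`, `b_edited` and `n` (four rows).
#' @export
domain_order_analysis <- function(classified, domain_a, domain_b) {
  res <- purrr::map_dfr(seq_len(nrow(classified)), function(i) {
    calls <- classified$site_calls[[i]]
    in_a <- calls$site >= domain_a[1] & calls$site < domain_a[2]
    in_b <- calls$site >= domain_b[1] & calls$site < domain_b[2]
    if (!any(in_a) || !any(in_b)) return(NULL)
    tibble::tibble(a_edited = any(calls$read_run[in_a] !=
                                    calls$pre_run[in_a]),
                   b_edited = any(calls$read_run[in_b] !=
                                    calls$pre_run[in_b]))
  })
  grid <- tidyr::expand_grid(a_edited = c(TRUE, FALSE),
                             b_edited = c(TRUE, FALSE))
  if (nrow(res) == 0) return(dplyr::mutate(grid, n = 0L))
  counts <- dplyr::count(res, .data$a_edited, .data$b_edited)
  out <- dplyr::left_join(grid, counts, by = c("a_edited", "b_edited"))
  dplyr::mutate(out, n = dplyr::coalesce(.data$n, 0L))
}
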