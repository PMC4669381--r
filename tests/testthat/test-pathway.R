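make_pathway <- function(crypt, main_runs) {
  reconstruct_main(NULL, crypt,
                   mature = recompose(crypt$skeleton,
                                      as.integer(main_runs)))
}

test_that("site calls follow the three alternative-site rules", {
  # crypt with a single informative interior site (site 1): pre run p
  mk <- function(p, m, r) {
    crypt <- cryptogene("cg", recompose(new_skeleton("AG", c(0L, p, 0L))))
    main <- make_pathway(crypt, c(0L, m, 0L))
    st <- editing_state("cg", 0L, 3L, c(0L, r, 0L))
    classify_read(st, crypt, main)
  }
  # shorter insertion in the main direction is main-consistent
  res <- mk(1L, 3L, 2L)
  expect_equal(res$class, "main")
  expect_equal(res$site_calls$class[2], "main_consistent")
  # editing at a site the main product never edits
  res <- mk(1L, 1L, 2L)
  expect_equal(res$class, "alternative")
  expect_equal(res$site_calls$subtype[2], "never-edited-site")
  # deletion where the main product inserts
  res <- mk(2L, 4L, 1L)
  expect_equal(res$class, "alternative")
  expect_equal(res$site_calls$subtype[2], "direction-reversed")
  # longer indel in the same direction
  res <- mk(1L, 3L, 5L)
  expect_equal(res$site_calls$subtype[2], "longer-indel")
  # exact main value and exact pre value
  expect_equal(mk(1L, 3L, 3L)$class, "main")
  expect_equal(mk(1L, 3L, 1L)$class, "reference")
})

test_that("censored boundary sites never create alternative calls", {
  crypt <- cryptogene("cg", recompose(new_skeleton("ACG",
                                                   c(0L, 1L, 1L, 0L))))
  main <- make_pathway(crypt, c(0L, 1L, 1L, 0L))
  st <- editing_state("cg", 1L, 4L, c(5L, 1L, 0L),
                      censored_lo = TRUE, censored_hi = FALSE)
  # site 1 (run 5, would be alternative) is the censored boundary here
  res <- classify_read(st, crypt, main)
  expect_false(1L %in% res$site_calls$site)
  expect_equal(res$class, "reference")
})

test_that("reconstruction of pre-edited reads returns the pre-edited state", {
  set.seed(120)
  cg <- cryptogene("g", rnd_seq(70, t_bias = 1), list(c(5L, 40L)),
                   NULL)
  pre <- cg$pre_edited
  reads <- tibble::tibble(
    read_id = sprintf("r%02d", 1:30),
    seq = vapply(1:30, function(i) {
      lo <- sample.int(20, 1)
      substr(pre, lo, min(nchar(pre), lo + 50))
    }, character(1)))
  aln <- map_all(reads, cg, seed = substr(pre, nchar(pre) - 14,
                                          nchar(pre)),
                 scheme = scheme_strict(), strand_specific = TRUE)
  main <- reconstruct_main(aln, cg, min_support = 2L)
  expect_identical(main$state$runs, cg$skeleton$runs)
})

test_that("reconstruction recovers a planted cascade", {
  # about 20 edited sites, misedit rate 0.1, several hundred reads
  cfg <- simulation_config(rng_seed = 7, n_bases = 45, n_domains = 1,
                           coverage = 400, read_len = c(60, 90),
                           misedit_rate = 0.1,
                           internal_misedit_rate = 0.01,
                           strand_specific = TRUE)
  loc <- simulate_locus(cfg)
  reads <- simulate_reads(loc)
  expect_gt(nrow(reads), 400)
  main <- reconstruct_main(NULL, loc$crypt, reads = reads,
                           scheme = scheme_strict(),
                           strand_specific = TRUE)
  expect_identical(main$state$runs, loc$mature_state$runs)
})

test_that("a supplied mature mRNA bypasses reconstruction identically", {
  cfg <- simulation_config(rng_seed = 13, n_bases = 60, n_domains = 1,
                           coverage = 80, read_len = c(60, 90),
                           misedit_rate = 0.1,
                           internal_misedit_rate = 0.01,
                           strand_specific = TRUE)
  loc <- simulate_locus(cfg)
  reads <- simulate_reads(loc)
  rec <- reconstruct_main(NULL, loc$crypt, reads = reads,
                          scheme = scheme_strict(),
                          strand_specific = TRUE)
  byp <- reconstruct_main(NULL, loc$crypt, mature = loc$mature_seq)
  expect_identical(rec$state$runs, byp$state$runs)
  expect_equal(byp$iterations_used, 0L)
  # identical downstream classification
  tmpl <- loc$mature_seq
  aln <- map_all(reads, loc$crypt, seed = tile_seeds(tmpl, 14, 7),
                 template = tmpl, scheme = scheme_strict(),
                 strand_specific = TRUE)
  c1 <- classify_reads(aln, loc$crypt, rec)
  c2 <- classify_reads(aln, loc$crypt, byp)
  expect_identical(c1$class, c2$class)
})

test_that("reconstruction is idempotent on reads from its own output", {
  cfg <- simulation_config(rng_seed = 17, n_bases = 50, n_domains = 1,
                           coverage = 80, read_len = c(60, 90),
                           misedit_rate = 0, internal_misedit_rate = 0,
                           strand_specific = TRUE)
  loc <- simulate_locus(cfg)
  reads <- simulate_reads(loc)
  m1 <- reconstruct_main(NULL, loc$crypt, reads = reads,
                         scheme = scheme_strict(), strand_specific = TRUE)
  loc2 <- loc
  loc2$mature_state <- m1$state
  loc2$mature_seq <- recompose(loc$crypt$skeleton, m1$state$runs)
  reads2 <- simulate_reads(loc2, cfg)
  m2 <- reconstruct_main(NULL, loc$crypt, reads = reads2,
                         scheme = scheme_strict(), strand_specific = TRUE)
  expect_identical(m2$state$runs, m1$state$runs)
})

test_that("insufficient coverage yields a partial pathway with a frontier", {
  set.seed(121)
  cg <- cryptogene("g", rnd_seq(60, c("A", "C", "G")), list(c(5L, 40L)))
  runs <- cg$skeleton$runs
  runs[(10:35) + 1L] <- 2L
  edited <- recompose(cg$skeleton, runs)
  # only 3'-anchored short reads: the 5' part of the domain is never seen
  reads <- tibble::tibble(
    read_id = sprintf("r%02d", 1:10),
    seq = substr(edited, 60, nchar(edited)))
  aln <- map_all(reads, cg,
                 seed = substr(edited, nchar(edited) - 12, nchar(edited)),
                 template = edited, scheme = scheme_strict(),
                 strand_specific = TRUE)
  main <- reconstruct_main(aln, cg)
  expect_gt(main$frontier, 5L)
  # sites 5' of the frontier stay pre-edited
  pre5 <- seq_len(main$frontier)
  expect_identical(main$state$runs[pre5], cg$skeleton$runs[pre5])
})

test_that("intermediate merging follows the 1/k support rule", {
  # X and Y distinct maximal reads, A contained in both
  x <- aln_row("X", 0L, c(0L, 5L, 1L, 2L, 0L), censored = FALSE)
  y <- aln_row("Y", 2L, c(1L, 2L, 0L, 3L, 3L), censored = FALSE)
  a <- aln_row("A", 2L, c(1L, 2L, 0L), censored = FALSE)
  ints <- merge_intermediates(dplyr::bind_rows(x, y, a))
  expect_equal(nrow(ints), 2L)
  expect_equal(sort(ints$support), c(1.5, 1.5))
  expect_equal(sum(ints$support), 3)

  # single read
  one <- merge_intermediates(a)
  expect_equal(nrow(one), 1L)
  expect_equal(one$support, 1)

  # n identical reads collapse into one intermediate with support n
  same <- dplyr::bind_rows(lapply(1:5, function(i) {
    aln_row(paste0("r", i), 3L, c(2L, 0L, 4L), censored = FALSE)
  }))
  m <- merge_intermediates(same)
  expect_equal(nrow(m), 1L)
  expect_equal(m$support, 5)
  expect_equal(m$n_members, 5L)
})

test_that("support is conserved on random merge problems", {
  set.seed(122)
  for (rep in 1:25) {
    n <- sample(5:25, 1)
    rows <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
      lo <- sample(0:10, 1)
      len <- sample(2:8, 1)
      aln_row(sprintf("r%03d", i), lo,
              sample(0:3, len, replace = TRUE), censored = FALSE)
    }))
    ints <- merge_intermediates(rows)
    expect_equal(sum(ints$support), n, tolerance = 1e-9)
    # no retained intermediate is contained in another
    if (nrow(ints) > 1) {
      sts <- lapply(seq_len(nrow(ints)), function(i) {
        list(lo = ints$site_lo[i], hi = ints$site_hi[i] - 1L,
             runs = ints$runs[[i]])
      })
      for (i in seq_along(sts)) for (j in seq_along(sts)) {
        if (i != j) expect_false(uindel:::state_contains(sts[[j]],
                                                         sts[[i]]))
      }
    }
  }
})

test_that("terminal and internal alternative stretches are distinguished", {
  crypt <- cryptogene("cg",
                      recompose(new_skeleton(strrep("A", 9),
                                             rep(1L, 10))),
                      list(c(1L, 9L)))
  main <- make_pathway(crypt, c(1L, rep(3L, 8L), 1L))
  # terminal: alternative site at the 5' end of the edited stretch,
  # pre-edited 5' of it (abortive editing at the frontier)
  term <- aln_row("t", 0L, c(1L, 1L, 1L, 5L, 3L, 3L, 3L, 3L, 3L, 1L),
                  censored = FALSE)
  # internal: alternative site framed by canonically edited sites
  intl <- aln_row("i", 0L, c(1L, 3L, 3L, 5L, 3L, 3L, 3L, 3L, 3L, 1L),
                  censored = FALSE)
  ints <- merge_intermediates(dplyr::bind_rows(term, intl), crypt, main)
  types <- setNames(ints$stretch_type,
                    vapply(ints$read_ids, paste, character(1),
                           collapse = ","))
  expect_equal(unname(types[names(types) == "t"]), "terminal")
  expect_equal(unname(types[names(types) == "i"]), "internal")
})

test_that("misediting summary counts domains, histogram and percentages", {
  cfg <- simulation_config(rng_seed = 19, n_bases = 80, n_domains = 2,
                           coverage = 60, read_len = c(70, 110),
                           misedit_rate = 0.15,
                           internal_misedit_rate = 0.02,
                           strand_specific = TRUE)
  loc <- simulate_locus(cfg)
  reads <- simulate_reads(loc)
  main <- reconstruct_main(NULL, loc$crypt, mature = loc$mature_seq)
  tmpl <- loc$mature_seq
  aln <- map_all(reads, loc$crypt, seed = tile_seeds(tmpl, 14, 7),
                 template = tmpl, scheme = scheme_strict(),
                 strand_specific = TRUE)
  cls <- classify_reads(aln, loc$crypt, main)
  alt <- dplyr::filter(cls, .data$class == "alternative")
  ints <- merge_intermediates(alt, loc$crypt, main)
  summ <- misediting_summary(cls, ints, loc$crypt)
  expect_equal(nrow(summ$by_domain), 2L)
  with(summ$by_domain, {
    expect_true(all(n_reference + n_main + n_alternative == n_reads))
    expect_true(all(n_edited == n_main + n_alternative))
  })
  expect_equal(sum(summ$alt_site_histogram$n_reads *
                     summ$alt_site_histogram$n_alt_sites),
               sum(cls$n_alt_sites))
  # intermediates ranked by support
  expect_true(!is.unsorted(rev(summ$intermediates$support)))
  # trichotomy
  expect_true(all(cls$class %in% c("reference", "main", "alternative")))

  # no alternative reads -> 0% alternative
  cls0 <- dplyr::filter(cls, .data$class != "alternative")
  s0 <- misediting_summary(cls0, NULL, loc$crypt)
  expect_true(all(s0$by_domain$pct_alternative %in% c(0, NA)))
})

test_that("domain order analysis counts spanning reads only", {
  cfg <- simulation_config(rng_seed = 23, n_bases = 80, n_domains = 2,
                           coverage = 80, read_len = c(100, 160),
                           misedit_rate = 0, internal_misedit_rate = 0,
                           strand_specific = TRUE)
  loc <- simulate_locus(cfg)
  reads <- simulate_reads(loc)
  main <- reconstruct_main(NULL, loc$crypt, mature = loc$mature_seq)
  tmpl <- loc$mature_seq
  aln <- map_all(reads, loc$crypt, seed = tile_seeds(tmpl, 14, 7),
                 template = tmpl, scheme = scheme_strict(),
                 strand_specific = TRUE)
  cls <- classify_reads(aln, loc$crypt, main)
  da <- loc$crypt$editing_domains[[1]]
  db <- loc$crypt$editing_domains[[2]]
  tab <- domain_order_analysis(cls, da, db)
  # the 5' domain is edited before the 3' one: "3' only" must be empty
  expect_equal(tab$n[tab$b_edited & !tab$a_edited], 0L)
  # conservation: cells sum to the number of spanning reads
  spanning <- sum(vapply(seq_len(nrow(cls)), function(i) {
    s <- cls$site_calls[[i]]$site
    any(s >= da[1] & s < da[2]) && any(s >= db[1] & s < db[2])
  }, logical(1)))
  expect_equal(sum(tab$n), spanning)

  # reads spanning a single domain are excluded
  one_dom <- dplyr::filter(cls, purrr::map_lgl(.data$site_calls, function(s) {
    !any(s$site >= db[1] & s$site < db[2])
  }))
  tab0 <- domain_order_analysis(one_dom, da, db)
  expect_equal(sum(tab0$n), 0L)
})
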