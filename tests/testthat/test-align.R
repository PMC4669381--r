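test_that("sw_align() scores U-indel alignments as expected", {
  a <- sw_align("ACGTTTTAGC", "ACGTTAGC", scheme_strict())
  expect_equal(a$score, 8L)          # all 8 ref bases matched, T gap free
  expect_equal(a$mismatches, 0L)
  # one site with two extra Us, gap leftmost within the T run
  expect_equal(a$ops, "MMMIIMMMMM")

  # a non-T insertion cannot gap in strict mode: the best local
  # alignment is the longer exact flank, with no indel columns
  b <- sw_align("ACGGACTA", "ACGACTA", scheme_strict())
  expect_equal(b$score, 5L)          # "GACTA"
  expect_false(grepl("[ID]", b$ops))
})

test_that("reported score decomposes into matches, mismatches and gaps", {
  set.seed(108)
  sch <- scheme_mapping()
  for (i in 1:40) {
    read <- rnd_seq(sample(10:50, 1), t_bias = 2)
    ref <- rnd_seq(sample(10:50, 1), t_bias = 2)
    a <- sw_align(read, ref, sch)
    # recompute gap costs from the ops string
    cols <- strsplit(a$ops, "", fixed = TRUE)[[1]]
    rp <- a$read_start; fp <- a$ref_start
    gap_cost <- 0
    prev <- "M"
    for (k in seq_along(cols)) {
      if (cols[k] == "D") {
        b <- substr(ref, fp + 1, fp + 1)
        gap_cost <- gap_cost + sch$gap_extend[[b]] +
          if (prev != "D") sch$gap_open[[b]] else 0
        fp <- fp + 1
      } else if (cols[k] == "I") {
        b <- substr(read, rp + 1, rp + 1)
        gap_cost <- gap_cost + sch$gap_extend[[b]] +
          if (prev != "I") sch$gap_open[[b]] else 0
        rp <- rp + 1
      } else {
        rp <- rp + 1; fp <- fp + 1
      }
      prev <- cols[k]
    }
    expect_equal(a$score,
                 a$matches * sch$match_score -
                   a$mismatches * sch$mismatch_penalty - gap_cost)
  }
})

test_that("sw_align() matches the exhaustive DP oracle", {
  set.seed(109)
  strict_hard <- scoring_scheme(match_score = 1, mismatch_penalty = 1000,
                                gap_open = c(A = NA, C = NA, G = NA, T = 0),
                                gap_extend = c(A = NA, C = NA, G = NA, T = 0))
  for (i in 1:50) {
    read <- rnd_seq(sample(5:60, 1), t_bias = 2)
    ref <- rnd_seq(sample(5:60, 1), t_bias = 2)
    # strict scoring vs the skeleton closed form
    expect_equal(sw_align(read, ref, strict_hard)$score,
                 oracle_strict_score(read, ref),
                 info = paste(read, ref))
    # permissive scoring vs the affine DP oracle
    expect_equal(sw_align(read, ref, scheme_mapping())$score,
                 oracle_local_score(read, ref, 1, 18,
                                    c(A = 10, C = 10, G = 10, T = 1),
                                    c(A = 10, C = 10, G = 10, T = 1)),
                 info = paste(read, ref))
  }
})

test_that("banded DP equals exact DP when the band covers the drift", {
  set.seed(110)
  cg <- cryptogene("g", rnd_seq(100, t_bias = 1))
  st <- rnd_state(cg)
  edited <- apply_editing(cg, st)
  read <- substr(edited, 10, 80)
  exact <- sw_align(read, cg$pre_edited, scheme_strict())
  banded <- sw_align(read, cg$pre_edited, scheme_strict(), band = 60,
                     band_diag = 0)
  expect_equal(banded$score, exact$score)
})

test_that("map_read() enforces the seed and 5' extension rules", {
  pre <- paste0("ACGAGCAGGA", "TTACGGA", "GCGATCGCAT")
  cg <- cryptogene("g", pre, list(c(2L, 8L)), c(17L, 27L))
  seed <- substr(pre, 18, 27)
  # a read equal to the seed alone has no 5' extension
  r <- map_read(seed, cg, seed, scheme_strict(), strand_specific = TRUE)
  expect_false(r$mapped)
  expect_equal(r$reason, "no-5prime-extension")
  # a read lacking the seed is unmapped with reason no-seed
  r2 <- map_read("ACGAGCAGGA", cg, seed, scheme_strict(),
                 strand_specific = TRUE)
  expect_equal(r2$reason, "no-seed")
})

test_that("map_read() recovers planted insertions 5' of the seed", {
  set.seed(111)
  cg <- cryptogene("g", rnd_seq(80, c("A", "C", "G")),
                   list(c(10L, 50L)), c(60L, 78L))
  runs <- cg$skeleton$runs
  runs[c(20L, 30L, 40L) + 1L] <- c(2L, 1L, 3L)
  edited <- recompose(cg$skeleton, runs)
  r <- map_read(edited, cg, scheme = scheme_strict(), read_id = "t1",
                strand_specific = TRUE)
  expect_true(r$mapped)
  got <- r$runs[[1]]
  sites <- seq(r$site_lo, r$site_hi - 1L)
  interior <- sites > r$site_lo & sites < r$site_hi - 1L
  expect_identical(got[interior], runs[sites[interior] + 1L])
})

test_that("strand handling follows the library orientation contract", {
  set.seed(112)
  cg <- cryptogene("g", rnd_seq(60, c("A", "C", "G")), list(c(5L, 35L)),
                   c(42L, 58L))
  read <- substr(cg$pre_edited, 20, 60)
  rc <- rc_oracle(read)
  expect_false(map_read(rc, cg, scheme = scheme_strict(),
                        strand_specific = TRUE)$mapped)
  r <- map_read(rc, cg, scheme = scheme_strict(), strand_specific = FALSE)
  expect_true(r$mapped)
  expect_equal(r$strand, "-")
})

test_that("strict-mode mapping is equivalent to skeleton matching", {
  set.seed(113)
  n_true <- 0; n_false <- 0
  for (i in 1:120) {
    ref <- rnd_seq(60, t_bias = 1)
    cg <- cryptogene("g", ref, seed_region = c(44L, 58L))
    st <- rnd_state(cg)
    # keep the 3' anchor region (sequence positions >= 38) unedited so
    # the seed stays findable in edited reads
    pre_runs <- cg$skeleton$runs
    nb <- length(cg$skeleton)
    pos <- vapply(seq_len(nb) - 1L, function(b) {
      uindel:::base_position(pre_runs, b)
    }, integer(1))
    b0 <- min(which(pos >= 38L))
    st$runs[b0:length(st$runs)] <- pre_runs[b0:length(pre_runs)]
    ed <- apply_editing(cg, st)
    # read: 3'-anchored stretch of a true U-indel variant...
    lo <- sample.int(20, 1)
    read <- substr(ed, lo, nchar(ed))
    if (i %% 2 == 0) {
      # ...or the same with a mid-read skeleton corruption (substitution
      # or non-T indel), which U-indel editing cannot produce
      chars <- strsplit(read, "", fixed = TRUE)[[1]]
      p <- length(chars) %/% 2
      if (i %% 4 == 0) {
        chars[p] <- setdiff(c("A", "C", "G"), chars[p])[1]
      } else {
        chars <- append(chars, setdiff(c("A", "C", "G"), chars[p])[1], p)
      }
      read <- paste(chars, collapse = "")
    }
    r <- map_read(read, cg, scheme = scheme_strict(),
                  strand_specific = TRUE)
    mappable <- oracle_skeleton_mappable(read, ref)
    if (r$mapped) expect_true(mappable, info = paste(i, read))
    if (mappable) n_true <- n_true + 1 else n_false <- n_false + 1
    if (!mappable) expect_false(r$mapped, info = paste(i, read))
    if (i %% 2 == 1) expect_true(r$mapped, info = paste(i, read))
  }
  expect_gt(n_true, 30)
  expect_gt(n_false, 30)
})

test_that("map_all() is deterministic and reports per-reason counts", {
  cfg <- simulation_config(rng_seed = 3, n_bases = 50, n_domains = 1,
                           coverage = 30, read_len = c(50, 70),
                           misedit_rate = 0, internal_misedit_rate = 0)
  loc <- simulate_locus(cfg)
  reads <- simulate_reads(loc)
  a1 <- map_all(reads, loc$crypt, scheme = scheme_strict(),
                strand_specific = TRUE)
  a2 <- map_all(reads, loc$crypt, scheme = scheme_strict(),
                strand_specific = TRUE)
  expect_identical(a1, a2)
  rep <- attr(a1, "report")
  expect_equal(sum(rep$n_reads), nrow(reads))
  expect_s3_class(glance(a1), "tbl_df")

  empty <- map_all(tibble::tibble(read_id = character(0),
                                  seq = character(0)),
                   loc$crypt, scheme = scheme_strict())
  expect_equal(nrow(empty), 0L)
})

test_that("all seed-gated sense reads map when misediting is off", {
  cfg <- simulation_config(rng_seed = 1, n_bases = 50, n_domains = 1,
                           coverage = 40, read_len = c(50, 70),
                           misedit_rate = 0, internal_misedit_rate = 0)
  loc <- simulate_locus(cfg)
  reads <- simulate_reads(loc)
  tmpl <- loc$mature_seq
  aln <- map_all(reads, loc$crypt, seed = tile_seeds(tmpl, 14, 7),
                 template = tmpl, scheme = scheme_strict(),
                 strand_specific = TRUE)
  # every unmapped read must have a gating reason, not an alignment one
  expect_true(all(aln$reason[!aln$mapped] %in%
                    c("no-seed", "no-5prime-extension")))
  expect_gt(mean(aln$mapped), 0.8)
})

test_that("coverage_track() matches a naive per-position recount", {
  cfg <- simulation_config(rng_seed = 5, n_bases = 40, n_domains = 1,
                           coverage = 20, read_len = c(30, 50),
                           misedit_rate = 0, strand_specific = TRUE)
  loc <- simulate_locus(cfg)
  reads <- simulate_reads(loc)
  aln <- map_all(reads, loc$crypt, scheme = scheme_strict(),
                 strand_specific = TRUE)
  L <- nchar(loc$crypt$pre_edited)
  cov <- coverage_track(aln, L)
  m <- dplyr::filter(aln, mapped)
  naive <- integer(L)
  for (i in seq_len(nrow(m))) {
    idx <- seq(m$ref_start[i] + 1L, m$ref_end[i])
    naive[idx] <- naive[idx] + 1L
  }
  expect_equal(cov$sense, naive)
  expect_true(all(cov$antisense == 0L))  # sense-only simulation
  expect_equal(sum(cov$sense) + sum(cov$antisense),
               sum(m$ref_end - m$ref_start))

  # single synthetic read of length L at depth 1
  one <- aln_row("r1", 0L, c(0L, 0L, 0L))
  one$ref_start <- 5L; one$ref_end <- 15L; one$strand <- "+"
  cov1 <- coverage_track(one, 20L)
  expect_equal(sum(cov1$sense), 10L)
  expect_true(all(cov1$sense[6:15] == 1L))
})
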