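#' Decompose a sequence into its T-skeleton
#'
#' U-indel editing inserts and deletes uridines only, so any (pre-)edited
#' sequence is fully described by the ordered string of its non-T bases (the
#' "skeleton") together with the number of T residues at every inter-base
#' site.  `decompose()` computes that representation; [recompose()] is its
#' exact inverse.  U is normalised to T on input.
#'
#' For a skeleton of `N` bases there are `N + 1` sites, indexed 0-based:
#' site 0 holds the leading Ts, site `i` the Ts between bases `i - 1` and
#' `i`, and site `N` the trailing Ts.
#'
#' @param seq A single DNA/RNA string over `A`, `C`, `G`, `T`, `U`
#'   (case-insensitive).
#' @return An object of class `uindel_skeleton`: a list with `bases`
#'   (character scalar over A/C/G) and `runs` (integer vector, length
#'   `nchar(bases) + 1`).
#' @examples
#' sk <- decompose("ACGTTA")
#' sk$bases          # "ACGA"
#' sk$runs           # 0 0 0 2 0
#' recompose(sk)     # "ACGTTA"
#' @export
decompose <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L, !is.na(seq))
  s <- chartr("u", "t", chartr("U", "T", toupper(seq)))
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% c("A", "C", "G", "T"))
  if (length(bad) > 0) {
    stop("invalid character '", chars[bad[1]], "' at position ", bad[1],
         " (sequences must be over A/C/G/T/U)", call. = FALSE)
  }
  is_t <- chars == "T"
  bases <- chars[!is_t]
  n <- length(bases)
  # site index of every T = number of non-T characters before it
  site_of_t <- cumsum(!is_t)[is_t]
  runs <- tabulate(site_of_t + 1L, nbins = n + 1L)
  new_skeleton(paste(bases, collapse = ""), as.integer(runs))
}

new_skeleton <- function(bases, runs) {
  stopifnot(nchar(bases) + 1L == length(runs), all(runs >= 0L))
  structure(list(bases = bases, runs = as.integer(runs)),
            class = "uindel_skeleton")
}

#' Recompose a sequence from a skeleton (and optionally new runs)
#'
#' @param skeleton A `uindel_skeleton` from [decompose()].
#' @param runs Optional replacement T-run vector of the same length as
#'   `skeleton$runs`; defaults to the skeleton's own runs.
#' @return A single DNA string (T, not U).
#' @export
recompose <- function(skeleton, runs = skeleton$runs) {
  stopifnot(inherits(skeleton, "uindel_skeleton"))
  runs <- as.integer(runs)
  if (length(runs) != length(skeleton$runs)) {
    stop("runs must have length ", length(skeleton$runs), call. = FALSE)
  }
  if (any(runs < 0L)) stop("runs must be non-negative", call. = FALSE)
  bases <- strsplit(skeleton$bases, "", fixed = TRUE)[[1]]
  ts <- vapply(runs, function(k) strrep("T", k), character(1))
  paste0(paste0(ts[seq_along(bases)], bases, collapse = ""),
         ts[length(runs)])
}

#' @export
print.uindel_skeleton <- function(x, ...) {
  cat("<uindel_skeleton> ", nchar(x$bases), " bases, ",
      sum(x$runs), " Ts over ", length(x$runs), " sites\n", sep = "")
  invisible(x)
}

#' @export
length.uindel_skeleton <- function(x) nchar(x$bases)

n_sites <- function(skeleton) length(skeleton$runs)

#' Construct an editing state
#'
#' An editing state records the observed T-run length at each skeleton site
#' of a contiguous site range `[site_lo, site_hi)` (0-based half-open) of a
#' cryptogene.  Boundary sites whose run is truncated by a read end carry
#' censoring flags and are excluded from state comparisons.
#'
#' @param cryptogene_id Identifier of the cryptogene the sites refer to.
#' @param site_lo,site_hi 0-based half-open site range.
#' @param runs Integer vector of length `site_hi - site_lo`.
#' @param censored_lo,censored_hi Whether the first/last covered site is
#'   truncated by a read boundary.
#' @return An object of class `uindel_state`.
#' @export
editing_state <- function(cryptogene_id, site_lo, site_hi, runs,
                          censored_lo = FALSE, censored_hi = FALSE) {
  runs <- as.integer(runs)
  stopifnot(site_hi - site_lo == length(runs), site_lo >= 0, all(runs >= 0L))
  structure(list(cryptogene_id = cryptogene_id,
                 site_lo = as.integer(site_lo),
                 site_hi = as.integer(site_hi),
                 runs = runs,
                 censored_lo = isTRUE(censored_lo),
                 censored_hi = isTRUE(censored_hi)),
            class = "uindel_state")
}

#' @export
print.uindel_state <- function(x, ...) {
  cat("<uindel_state> ", x$cryptogene_id, " sites [", x$site_lo, ",",
      x$site_hi, ") censored ", x$censored_lo, "/", x$censored_hi, "\n",
      sep = "")
  invisible(x)
}

# sites of a state that are observed in full (uncensored), as 0-based indices
uncensored_sites <- function(state) {
  sites <- seq(state$site_lo, state$site_hi - 1L)
  keep <- rep(TRUE, length(sites))
  if (state$censored_lo && length(keep)) keep[1] <- FALSE
  if (state$censored_hi && length(keep)) keep[length(keep)] <- FALSE
  sites[keep]
}

# run value of `state` at 0-based site index (must be covered)
state_run <- function(state, site) {
  state$runs[site - state$site_lo + 1L]
}

#' Construct a cryptogene reference
#'
#' A cryptogene is a pre-edited mitochondrial gene: the reference against
#' which edited reads are aligned and editing states are expressed.  Editing
#' domains are the site ranges expected to undergo editing; the seed region
#' is a never-edited (or universally edited) stretch of the 3' end used to
#' anchor read mapping and must not overlap any domain.
#'
#' @param id Gene identifier.
#' @param pre_edited Pre-edited sequence (sense orientation, T not U).
#' @param editing_domains List of 0-based half-open site intervals
#'   `c(lo, hi)`, disjoint and sorted 5' to 3'.
#' @param seed_region Optional 0-based half-open interval in *sequence*
#'   coordinates of `pre_edited` used for seed anchoring.
#' @return An object of class `uindel_cryptogene`.
#' @export
cryptogene <- function(id, pre_edited, editing_domains = list(),
                       seed_region = NULL) {
  sk <- decompose(pre_edited)
  ns <- n_sites(sk)
  editing_domains <- lapply(editing_domains, function(d) {
    d <- as.integer(d)
    stopifnot(length(d) == 2L, d[1] >= 0L, d[2] <= ns, d[1] < d[2])
    d
  })
  if (length(editing_domains) > 1) {
    los <- vapply(editing_domains, `[`, integer(1), 1)
    his <- vapply(editing_domains, `[`, integer(1), 2)
    if (is.unsorted(los, strictly = TRUE) || any(los[-1] < his[-length(his)])) {
      stop("editing domains must be disjoint and sorted", call. = FALSE)
    }
  }
  if (!is.null(seed_region)) {
    seed_region <- as.integer(seed_region)
    stopifnot(length(seed_region) == 2L, seed_region[1] >= 0,
              seed_region[2] <= nchar(pre_edited),
              seed_region[1] < seed_region[2])
    # seed sites must not fall inside any editing domain
    seed_sites <- covered_site_range(sk, seed_region)
    for (d in editing_domains) {
      if (seed_sites[1] < d[2] && d[1] < seed_sites[2]) {
        stop("seed region overlaps an editing domain", call. = FALSE)
      }
    }
  }
  structure(list(id = id,
                 pre_edited = chartr("U", "T", toupper(pre_edited)),
                 skeleton = sk,
                 editing_domains = editing_domains,
                 seed_region = seed_region),
            class = "uindel_cryptogene")
}

#' @export
print.uindel_cryptogene <- function(x, ...) {
  cat("<uindel_cryptogene> ", x$id, ": ", nchar(x$pre_edited), " nt, ",
      length(x$skeleton), " skeleton bases, ",
      length(x$editing_domains), " editing domain(s)\n", sep = "")
  invisible(x)
}

# 0-based half-open site range whose T-runs are (partly) inside the 0-based
# half-open sequence interval [lo, hi)
covered_site_range <- function(skeleton, interval) {
  bases <- strsplit(skeleton$bases, "", fixed = TRUE)[[1]]
  # sequence position (0-based) of each skeleton base
  pos <- cumsum(skeleton$runs[seq_along(bases)] + 1L) - 1L
  inside <- which(pos >= interval[1] & pos < interval[2])
  if (length(inside) == 0) return(c(0L, 0L))
  c(min(inside) - 1L, max(inside))  # sites strictly between covered bases
}

# 0-based sequence position of skeleton base b (0-based) under given runs
base_position <- function(runs, b) {
  if (b == 0L) return(runs[1])
  sum(runs[seq_len(b + 1L)]) + b
}

#' Full pre-edited editing state of a cryptogene
#' @param crypt A [cryptogene()].
#' @return A full-range `uindel_state` equal to the pre-edited runs.
#' @export
pre_edited_state <- function(crypt) {
  editing_state(crypt$id, 0L, n_sites(crypt$skeleton), crypt$skeleton$runs)
}

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}
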