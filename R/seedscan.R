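# Seed-site detection and classification.
#
# Register arithmetic: in the ungapped antiparallel duplex, if miRNA
# position 1 is aligned with UTR position p1 (the "anchor"), then miRNA
# position k is aligned with UTR position p1 - (k - 1). A 6mer core on the
# 2-7 register occupying UTR [s, s+5] therefore has anchor p1 = s + 6; a
# 3-8 register core at [s, s+5] has anchor p1 = s + 7.

SITE_CATEGORIES <- c("6mer", "7mer-A1", "7mer-m8", "8mer")

# Category priority used by effective_site(): strongest first.
CATEGORY_PRIORITY <- c("8mer" = 4L, "7mer-m8" = 3L, "7mer-A1" = 2L, "6mer" = 1L)

#' Classify the pairing of a miRNA base against a target base
#'
#' Watson-Crick (`"WC"`): A:U, U:A, G:C, C:G. Wobble (`"GU"`): G:U, U:G
#' (miRNA:target order). Everything else is `"NONE"`.
#'
#' @param mirna_base,utr_base single RNA bases (vectorized).
#' @return character vector of `"WC"`, `"GU"` or `"NONE"`.
#' @export
pair_type <- function(mirna_base, utr_base) {
  key <- paste0(mirna_base, utr_base)
  out <- rep("NONE", length(key))
  out[key %in% c("AU", "UA", "GC", "CG")] <- "WC"
  out[key %in% c("GU", "UG")] <- "GU"
  out
}

# Match one register over all UTR windows at once. Returns a data.frame of
# matching 6mer cores (utr_start/utr_end of the core, anchor, gu_count,
# gu_mirna_pos). `positions` is the vector of required miRNA seed positions
# (2:7 or 3:8).
scan_register <- function(m, u, positions) {
  Lu <- length(u)
  n_win <- Lu - 5L
  if (n_win < 1L) {
    return(data.frame(utr_start = integer(), anchor = integer(),
                      gu_count = integer(), gu_mirna_pos = integer()))
  }
  starts <- seq_len(n_win)
  p1 <- starts + max(positions) - 1L  # anchor: miRNA position 1 alignment
  wc <- matrix(FALSE, n_win, 6L)
  gu <- matrix(FALSE, n_win, 6L)
  for (j in seq_along(positions)) {
    k <- positions[j]
    ub <- u[p1 - (k - 1L)]
    mb <- m[k]
    wc[, j] <- (mb == "A" & ub == "U") | (mb == "U" & ub == "A") |
               (mb == "G" & ub == "C") | (mb == "C" & ub == "G")
    gu[, j] <- (mb == "G" & ub == "U") | (mb == "U" & ub == "G")
  }
  n_gu <- rowSums(gu)
  ok <- rowSums(wc | gu) == 6L & n_gu <= 1L
  hit <- which(ok)
  gu_pos <- rep(NA_integer_, length(hit))
  if (length(hit)) {
    for (i in seq_along(hit)) {
      j <- which(gu[hit[i], ])
      if (length(j)) gu_pos[i] <- positions[j]
    }
  }
  data.frame(utr_start = starts[hit], anchor = p1[hit],
             gu_count = as.integer(n_gu[hit]), gu_mirna_pos = gu_pos)
}

#' Find and classify seed-matching sites of a miRNA on a 3'UTR
#'
#' Every UTR window whose antiparallel pairing against miRNA seed positions
#' 2-7 (or, failing that, 3-8) is all Watson-Crick with at most one G:U
#' wobble yields a 6mer core. Cores on the 2-7 register are then upgraded:
#' to `7mer-m8` when the UTR base opposite miRNA position 8 is Watson-Crick
#' paired, to `7mer-A1` when the UTR base aligned with miRNA position 1 is
#' an A, and to `8mer` when both hold; the site interval is extended
#' accordingly. Cores detected only on the 3-8 register stay `6mer`.
#'
#' @param mirna,utr RNA strings (normalized; see [normalize_rna()]).
#' @return data.frame, sorted by `utr_start`, with columns `utr_start`,
#'   `utr_end` (1-based closed interval), `category`, `seed_register`
#'   (`"2-7"` or `"3-8"`), `gu_count` (0 or 1), `gu_mirna_pos` (NA if no
#'   wobble), `anchor` (UTR position aligned with miRNA position 1; may lie
#'   one base past the UTR end).
#' @export
find_sites <- function(mirna, utr) {
  m <- seq_chars(mirna)
  u <- seq_chars(utr)
  if (length(m) < 8L) stop("miRNA shorter than the 8-nt seed region",
                           call. = FALSE)
  if (length(u) < 6L) return(empty_sites())
  core27 <- scan_register(m, u, 2:7)
  core38 <- scan_register(m, u, 3:8)
  # one site per window; the 2-7 register (the one carrying upgrades) wins
  core38 <- core38[!(core38$utr_start %in% core27$utr_start), , drop = FALSE]
  Lu <- length(u)
  out <- list()
  if (nrow(core27)) {
    s <- core27$utr_start
    p1 <- core27$anchor
    m8_pos <- s - 1L  # UTR base opposite miRNA position 8
    has_m8 <- m8_pos >= 1L &
      pair_type(rep(m[8L], nrow(core27)), ifelse(m8_pos >= 1L, u[pmax(m8_pos, 1L)], "")) == "WC"
    has_a1 <- p1 <= Lu & ifelse(p1 <= Lu, u[pmin(p1, Lu)], "") == "A"
    category <- rep("6mer", nrow(core27))
    category[has_m8 & !has_a1] <- "7mer-m8"
    category[!has_m8 & has_a1] <- "7mer-A1"
    category[has_m8 & has_a1] <- "8mer"
    utr_start <- ifelse(has_m8, s - 1L, s)
    utr_end <- ifelse(has_a1, p1, s + 5L)
    out$r27 <- data.frame(utr_start = as.integer(utr_start),
                          utr_end = as.integer(utr_end),
                          category = category, seed_register = "2-7",
                          gu_count = core27$gu_count,
                          gu_mirna_pos = core27$gu_mirna_pos,
                          anchor = p1, stringsAsFactors = FALSE)
  }
  if (nrow(core38)) {
    out$r38 <- data.frame(utr_start = core38$utr_start,
                          utr_end = core38$utr_start + 5L,
                          category = "6mer", seed_register = "3-8",
                          gu_count = core38$gu_count,
                          gu_mirna_pos = core38$gu_mirna_pos,
                          anchor = core38$anchor, stringsAsFactors = FALSE)
  }
  if (!length(out)) return(empty_sites())
  sites <- do.call(rbind, out)
  sites <- sites[order(sites$utr_start, sites$utr_end), , drop = FALSE]
  rownames(sites) <- NULL
  sites
}

empty_sites <- function() {
  data.frame(utr_start = integer(), utr_end = integer(),
             category = character(), seed_register = character(),
             gu_count = integer(), gu_mirna_pos = integer(),
             anchor = integer(), stringsAsFactors = FALSE)
}

#' Pick the effective seed-matching site among candidates
#'
#' Priority `8mer` > `7mer-m8` > `7mer-A1` > `6mer`; ties broken by fewer
#' G:U wobbles, then smallest `utr_start`.
#'
#' @param sites data.frame as returned by [find_sites()].
#' @return a one-row data.frame, or `NULL` when `sites` is empty.
#' @export
effective_site <- function(sites) {
  if (is.null(sites) || nrow(sites) == 0L) return(NULL)
  pri <- CATEGORY_PRIORITY[sites$category]
  ord <- order(-pri, sites$gu_count, sites$utr_start)
  sites[ord[1L], , drop = FALSE]
}

#' 3'-supplementary pairing flag for a seed site
#'
#' In the ungapped antiparallel register anchored at the site (miRNA
#' position 1 opposite the site's anchor base), the flag is 1 iff all four
#' UTR bases opposite miRNA positions 13-16 are Watson-Crick paired, and 0
#' whenever any opposite base falls outside the UTR. Additional pairing at
#' positions 12 and 17 never changes the flag; its count (0-2) is attached
#' as attribute `"ext_count"`.
#'
#' @param mirna,utr RNA strings.
#' @param site one-row data.frame from [find_sites()].
#' @return integer 0/1 with attribute `ext_count`.
#' @export
supplementary_pairing <- function(mirna, utr, site) {
  m <- seq_chars(mirna)
  if (length(m) < 16L) stop("miRNA shorter than 16 nt: no positions 13-16",
                            call. = FALSE)
  u <- seq_chars(utr)
  p1 <- site$anchor[1L]
  opp <- p1 - (13:16 - 1L)
  flag <- 0L
  if (all(opp >= 1L & opp <= length(u)) &&
      all(pair_type(m[13:16], u[opp]) == "WC")) {
    flag <- 1L
  }
  ext <- 0L
  if (flag == 1L) {
    for (k in c(12L, 17L)) {
      if (k > length(m)) next
      o <- p1 - (k - 1L)
      if (o >= 1L && o <= length(u) && pair_type(m[k], u[o]) == "WC") {
        ext <- ext + 1L
      }
    }
  }
  structure(flag, ext_count = ext)
}

#' AU-rich flank flag for a seed site
#'
#' Pools up to `window` nt immediately upstream and `window` nt immediately
#' downstream of the site (truncated at the UTR ends, site excluded) and
#' sets the flag to 1 iff the pooled A+U fraction is at least `threshold`.
#' An empty pooled region gives 0. The flank substrings are attached as
#' attributes `flank_up` and `flank_down`.
#'
#' @param utr RNA string.
#' @param site one-row data.frame from [find_sites()].
#' @param window flank width in nt on each side (default 30).
#' @param threshold minimum A+U fraction (default 0.60).
#' @return integer 0/1 with attributes `flank_up`, `flank_down`.
#' @export
au_flank_flag <- function(utr, site, window = 30L, threshold = 0.60) {
  stopifnot(window >= 1L)
  fl <- site_flanks(utr, site$utr_start[1L], site$utr_end[1L], window)
  pooled <- paste0(fl$up, fl$down)
  n <- nchar(pooled)
  flag <- 0L
  if (n > 0L) {
    au <- sum(seq_chars(pooled) %in% c("A", "U"))
    if (au / n >= threshold) flag <- 1L
  }
  structure(flag, flank_up = fl$up, flank_down = fl$down)
}

# Upstream/downstream flank substrings of [start, end], truncated at UTR
# boundaries; each has length min(window, available).
site_flanks <- function(utr, start, end, window = 30L) {
  Lu <- nchar(utr)
  up_from <- max(1L, start - window)
  up <- if (start > 1L) substr(utr, up_from, start - 1L) else ""
  down_to <- min(Lu, end + window)
  down <- if (end < Lu) substr(utr, end + 1L, down_to) else ""
  list(up = up, down = down)
}
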