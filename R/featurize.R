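# The immutable 90-feature targeting-site context catalog and per-pair
# feature extraction.
#
# Index scheme (nucleotide order A, U, G, C throughout; dinucleotide order
# first letter A,U,G,C x second letter A,U,G,C):
#   category 1 (1-12):  per-category site counts over the whole UTR
#                       (order 6mer, 7mer-m8, 7mer-A1, 8mer; indices 1-4),
#                       supplementary-pairing flag of each category's
#                       effective site (5-8, same order), AU-rich flank
#                       flag of each category's effective site (9-12);
#   category 2 (13-16): A,U,G,C counts in the effective site;
#   category 3 (17-20): A,U,G,C counts in the pooled 30-nt flanks;
#   category 4 (21-36): 16 dinucleotide counts in the effective site;
#   category 5 (37-52): 16 dinucleotide counts in the flanks (each flank
#                       scanned separately; dinucleotides never span the
#                       site);
#   category 6 (53-58): seed base-pair counts, order A:U, U:A, U:G, G:C,
#                       G:U, C:G (miRNA:target), over the required
#                       seed-match positions (A1 anchor excluded);
#   category 7 (59-90): consecutive base-pair bigrams read 5'->3' along the
#                       miRNA; first pair in block order A:U, U:A, G:C,
#                       C:G, G:U, U:G, second pair in the same order,
#                       minus the four wobble-wobble combinations (a single
#                       G:U wobble per site makes them impossible) = 32.
# "Frequency" means the raw count within the region; the SVM scaler
# absorbs overall scale.

NUC_ORDER <- c("A", "U", "G", "C")
DINUC_ORDER <- as.vector(t(outer(NUC_ORDER, NUC_ORDER, paste0)))  # AA,AU,AG,AC,UA,...
PAIR6_ORDER <- c("AU", "UA", "UG", "GC", "GU", "CG")      # category 6
BIPAIR_FIRST <- c("AU", "UA", "GC", "CG", "GU", "UG")     # category 7 blocks
CAT1_SITE_ORDER <- c("6mer", "7mer-m8", "7mer-A1", "8mer")

bipair_order <- function() {
  grid <- expand.grid(second = BIPAIR_FIRST, first = BIPAIR_FIRST,
                      stringsAsFactors = FALSE)[, 2:1]
  keys <- paste(grid$first, grid$second, sep = "-")
  wob <- c("GU-GU", "GU-UG", "UG-GU", "UG-UG")
  keys[!(keys %in% wob)]
}

cat1_long_name <- function(stem) {
  nm <- c("6mer" = "six mer", "7mer-m8" = "seven mer m8",
          "7mer-A1" = "seven mer A1", "8mer" = "eight mer")
  paste0(stem, " ", nm[CAT1_SITE_ORDER])
}

#' The 90-feature targeting-site context catalog
#'
#' Deterministic, bit-identical across runs. Category sizes are
#' 12/4/4/16/16/6/32 for categories 1-7. The catalog also carries the
#' published 39-feature selection and its 22-member common-feature subset
#' (features retained by at least 90% of archived non-dominated solutions
#' in the original selection run), so the published model configuration can
#' be instantiated without re-running the optimizer.
#'
#' @return object of class `feature_catalog`: list with `entries`
#'   (data.frame `index`, `name`, `category`), `selected` (39 indices),
#'   `common` (22 indices), `version`.
#' @export
feature_catalog <- function() {
  entries <- rbind(
    data.frame(index = 1:4, category = 1L,
               name = cat1_long_name("Number of"),
               stringsAsFactors = FALSE),
    data.frame(index = 5:8, category = 1L,
               name = cat1_long_name(
                 "Number of additional Watson-Crick pairing associated with effective")),
    data.frame(index = 9:12, category = 1L,
               name = cat1_long_name(
                 "AU rich flanking region associated with effective")),
    data.frame(index = 13:16, category = 2L,
               name = paste0(NUC_ORDER, "'s frequency in effective seed matching site")),
    data.frame(index = 17:20, category = 3L,
               name = paste0(NUC_ORDER, "'s frequency in effective seed matching out site")),
    data.frame(index = 21:36, category = 4L,
               name = paste0(DINUC_ORDER, "'s frequency in effective seed matching site")),
    data.frame(index = 37:52, category = 5L,
               name = paste0(DINUC_ORDER, "'s frequency in effective seed matching out site")),
    data.frame(index = 53:58, category = 6L,
               name = paste0("Frequency of ", PAIR6_ORDER, " base pair")),
    data.frame(index = 59:90, category = 7L,
               name = paste0("Frequency of ", bipair_order()))
  )
  rownames(entries) <- NULL
  selected <- c(6L, 19L, 22L, 24L, 25L, 26L, 28L, 30L, 32L, 35L, 36L,
                38L, 39L, 40L, 42L, 44L, 45L, 47L, 48L,
                53L, 54L, 56L, 57L, 58L,
                59L, 62L, 64L, 65L, 67L, 68L, 69L, 70L, 73L, 74L, 78L,
                79L, 83L, 84L, 86L)
  common <- c(6L, 26L, 28L, 30L, 35L, 36L,
              39L, 40L, 42L, 44L,
              53L, 56L, 57L, 58L,
              59L, 62L, 64L, 68L, 70L, 78L, 79L, 84L)
  structure(list(entries = entries, selected = selected, common = common,
                 version = "context90/v1"),
            class = "feature_catalog")
}

#' @export
print.feature_catalog <- function(x, ...) {
  cat("Targeting-site context feature catalog (", x$version, ")\n", sep = "")
  cat("  ", nrow(x$entries), " features in ",
      length(unique(x$entries$category)), " categories; ",
      length(x$selected), " in the published selection (",
      length(x$common), " common)\n", sep = "")
  invisible(x)
}

# Count occurrences of each element of `alphabet` in string `s` (counts,
# not proportions). Dinucleotides are counted over overlapping windows.
count_kmers <- function(s, alphabet, k = 1L) {
  out <- setNames(numeric(length(alphabet)), alphabet)
  n <- nchar(s)
  if (n < k) return(out)
  ch <- seq_chars(s)
  kmers <- if (k == 1L) ch else paste0(ch[-n], ch[-1L])
  tab <- table(factor(kmers, levels = alphabet))
  out[] <- as.numeric(tab)
  out
}

# Required seed-match miRNA positions of a site: 2-7 for 6mer (2-7
# register) and 7mer-A1, 2-8 for 7mer-m8 and 8mer, 3-8 for the 3-8
# register. The A1 anchor is an identity test, never a counted pair.
required_positions <- function(site) {
  if (site$seed_register == "3-8") return(3:8)
  if (site$category %in% c("7mer-m8", "8mer")) 2:8 else 2:7
}

# Seed base-pair labels (miRNA:target, e.g. "GC") of a site, ordered by
# increasing miRNA position (5'->3' along the miRNA).
site_pair_labels <- function(mirna, utr, site) {
  m <- seq_chars(mirna)
  u <- seq_chars(utr)
  ks <- required_positions(site)
  opp <- site$anchor - (ks - 1L)
  paste0(m[ks], u[opp])
}

#' Extract the 90-feature context vector of one miRNA-UTR pair
#'
#' Scans the UTR for seed sites, picks the effective site, and fills the
#' catalog-ordered feature vector. A pair without any seed site gets the
#' all-zero vector.
#'
#' @param mirna,utr RNA strings.
#' @param catalog a [feature_catalog()] (rebuilt when omitted).
#' @return numeric vector of length 90, names `f1..f90`, with the effective
#'   site (one-row data.frame or `NULL`) attached as attribute
#'   `"effective_site"`.
#' @export
extract_features <- function(mirna, utr, catalog = feature_catalog()) {
  v <- setNames(numeric(90L), paste0("f", 1:90))
  sites <- find_sites(mirna, utr)
  if (nrow(sites) == 0L) {
    attr(v, "effective_site") <- NULL
    return(v)
  }
  # category 1: site counts, then per-category effective-site flags
  for (i in seq_along(CAT1_SITE_ORDER)) {
    cat_sites <- sites[sites$category == CAT1_SITE_ORDER[i], , drop = FALSE]
    v[i] <- nrow(cat_sites)
    if (nrow(cat_sites)) {
      eff_c <- effective_site(cat_sites)
      if (nchar(mirna) >= 16L) {
        v[4L + i] <- as.integer(supplementary_pairing(mirna, utr, eff_c))
      }
      v[8L + i] <- as.integer(au_flank_flag(utr, eff_c))
    }
  }
  eff <- effective_site(sites)
  site_seq <- substr(utr, eff$utr_start, eff$utr_end)
  fl <- site_flanks(utr, eff$utr_start, eff$utr_end, 30L)
  # categories 2-5: composition of the site and its flanks
  v[13:16] <- count_kmers(site_seq, NUC_ORDER, 1L)
  v[17:20] <- count_kmers(fl$up, NUC_ORDER, 1L) + count_kmers(fl$down, NUC_ORDER, 1L)
  v[21:36] <- count_kmers(site_seq, DINUC_ORDER, 2L)
  v[37:52] <- count_kmers(fl$up, DINUC_ORDER, 2L) + count_kmers(fl$down, DINUC_ORDER, 2L)
  # categories 6-7: seed pairing pattern of the effective site
  labels <- site_pair_labels(mirna, utr, eff)
  v[53:58] <- as.numeric(table(factor(labels, levels = PAIR6_ORDER)))
  if (length(labels) > 1L) {
    big <- paste(labels[-length(labels)], labels[-1L], sep = "-")
    v[59:90] <- as.numeric(table(factor(big, levels = bipair_order())))
  }
  attr(v, "effective_site") <- eff
  v
}

#' Subset a feature vector (or matrix) by a feature-index mask
#'
#' @param vec numeric length-90 vector or a matrix with 90 columns.
#' @param mask nonempty set of catalog indices (subset of 1..90).
#' @return values at the mask indices, in ascending index order.
#' @export
subset_features <- function(vec, mask) {
  if (length(mask) == 0L) stop("empty feature mask", call. = FALSE)
  mask <- sort(unique(as.integer(mask)))
  if (any(mask < 1L | mask > 90L)) stop("mask indices must lie in 1..90",
                                        call. = FALSE)
  if (is.matrix(vec)) vec[, mask, drop = FALSE] else vec[mask]
}

#' Featurize a labeled dataset of miRNA-UTR pairs
#'
#' Pairs whose miRNA or UTR id cannot be resolved are skipped with a
#' warning, not an error.
#'
#' @param pairs data.frame from [read_pairs()].
#' @param mirnas,utrs named character vectors from [read_fasta()].
#' @param catalog a [feature_catalog()].
#' @return list with `X` (n x 90 numeric matrix, columns `f1..f90`), `y`
#'   (integer +1/-1 labels), `pairs` (the rows actually featurized).
#' @export
featurize_dataset <- function(pairs, mirnas, utrs, catalog = feature_catalog()) {
  ok <- pairs$mirna_id %in% names(mirnas) & pairs$utr_id %in% names(utrs)
  if (any(!ok)) {
    bad <- pairs[!ok, , drop = FALSE]
    warning(sum(!ok), " pair(s) with unresolvable ids skipped (first: ",
            bad$mirna_id[1L], " / ", bad$utr_id[1L], ")", call. = FALSE)
    pairs <- pairs[ok, , drop = FALSE]
  }
  X <- matrix(0, nrow = nrow(pairs), ncol = 90L,
              dimnames = list(NULL, paste0("f", 1:90)))
  for (i in seq_len(nrow(pairs))) {
    X[i, ] <- extract_features(mirnas[[pairs$mirna_id[i]]],
                               utrs[[pairs$utr_id[i]]], catalog)
  }
  list(X = X, y = as.integer(pairs$label), pairs = pairs)
}
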