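# Independent oracles, deliberately written as plain loops so they share no
# code path with the package implementation.

# Base-pair class of (miRNA base, target base): "WC", "GU" or "NONE".
oracle_pair <- function(mb, ub) {
  wc <- list(c("A", "U"), c("U", "A"), c("G", "C"), c("C", "G"))
  gu <- list(c("G", "U"), c("U", "G"))
  for (p in wc) if (mb == p[1] && ub == p[2]) return("WC")
  for (p in gu) if (mb == p[1] && ub == p[2]) return("GU")
  "NONE"
}

# Brute-force seed-site scanner: tests every 6-nt UTR window against every
# register, position by position, then applies the upgrade rules literally.
oracle_scan <- function(mirna, utr) {
  m <- strsplit(mirna, "")[[1]]
  u <- strsplit(utr, "")[[1]]
  out <- NULL
  for (s in seq_len(max(0, length(u) - 5))) {
    hit <- NULL
    for (reg in list(2:7, 3:8)) {
      p1 <- as.integer(s + max(reg) - 1L)  # opposite miRNA position 1
      n_gu <- 0L; ok <- TRUE
      gu_at <- NA_integer_
      for (k in reg) {
        pt <- oracle_pair(m[k], u[p1 - (k - 1L)])
        if (pt == "NONE") { ok <- FALSE; break }
        if (pt == "GU") { n_gu <- n_gu + 1L; gu_at <- as.integer(k) }
      }
      if (ok && n_gu <= 1) {
        hit <- list(reg = reg, p1 = p1, gu = n_gu,
                    gu_at = if (n_gu > 0) gu_at else NA_integer_)
        break  # 2-7 register preferred; one site per window
      }
    }
    if (is.null(hit)) next
    start <- as.integer(s); end <- as.integer(s + 5L)
    category <- "6mer"
    register <- if (identical(hit$reg, 2:7)) "2-7" else "3-8"
    if (register == "2-7") {
      has_m8 <- s - 1 >= 1 && oracle_pair(m[8], u[s - 1]) == "WC"
      has_a1 <- hit$p1 <= length(u) && u[hit$p1] == "A"
      if (has_m8) start <- as.integer(s - 1L)
      if (has_a1) end <- hit$p1
      category <- if (has_m8 && has_a1) "8mer"
      else if (has_m8) "7mer-m8"
      else if (has_a1) "7mer-A1"
      else "6mer"
    }
    out <- rbind(out, data.frame(
      utr_start = start, utr_end = end, category = category,
      seed_register = register, gu_count = hit$gu,
      gu_mirna_pos = hit$gu_at, anchor = hit$p1,
      stringsAsFactors = FALSE))
  }
  if (is.null(out)) {
    out <- data.frame(utr_start = integer(), utr_end = integer(),
                      category = character(), seed_register = character(),
                      gu_count = integer(), gu_mirna_pos = integer(),
                      anchor = integer(), stringsAsFactors = FALSE)
  }
  out <- out[order(out$utr_start, out$utr_end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Direct-formula confusion metrics.
oracle_metrics <- function(tp, tn, fp, fn) {
  sn <- tp / (tp + fn)
  sp <- tn / (tn + fp)
  num <- tp * tn - fp * fn
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (den == 0) 0 else num / den
  c(Sn = sn, Sp = sp, MCC = mcc, ACA = (sn + sp) / 2)
}

# Brute-force AUC: fraction of correctly ordered (positive, negative)
# pairs, half credit for ties.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == -1]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

random_rna <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

# A deterministic, well-separated two-class feature matrix used by the
# classifier and metrics tests (2 informative columns among `p`).
separable_data <- function(n_per_class = 20, p = 5, shift = 4, seed = 42) {
  set.seed(seed)
  n <- 2 * n_per_class
  X <- matrix(rnorm(n * p), n, p)
  y <- rep(c(1L, -1L), each = n_per_class)
  X[y == 1L, 1:2] <- X[y == 1L, 1:2] + shift
  list(X = X, y = y)
}

LET7A <- "UGAGGUAGUAGGUUGUAUAGUU"
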