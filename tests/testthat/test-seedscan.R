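# Seed-site detection, classification, and site-context predicates.

test_that("base-pair classification follows Watson-Crick and wobble rules", {
  expect_equal(pair_type("A", "U"), "WC")
  expect_equal(pair_type("G", "U"), "GU")
  expect_equal(pair_type("U", "G"), "GU")
  expect_equal(pair_type("A", "G"), "NONE")
  bases <- c("A", "C", "G", "U")
  for (mb in bases) for (ub in bases) {
    expect_equal(pair_type(mb, ub), oracle_pair(mb, ub),
                 info = paste(mb, ub))
  }
})

test_that("a perfect 2-7 seed complement is detected as a 6mer", {
  utr <- paste0(strrep("G", 10), "UACCUC", strrep("G", 10))
  s <- find_sites(LET7A, utr)
  s27 <- s[s$seed_register == "2-7", ]
  expect_equal(nrow(s27), 1L)
  expect_equal(s27$utr_start, 11L)
  expect_equal(s27$category, "6mer")
  expect_equal(s27$gu_count, 0L)
})

test_that("a single G:U wobble is tolerated and located", {
  utr <- paste0(strrep("G", 10), "UACCUU", strrep("G", 10))
  s <- find_sites(LET7A, utr)
  expect_equal(nrow(s), 1L)
  expect_equal(s$category, "6mer")
  expect_equal(s$gu_count, 1L)
  expect_equal(s$gu_mirna_pos, 2L)  # miRNA G2 against target U
})

test_that("no complementarity yields no sites", {
  expect_equal(nrow(find_sites(LET7A, "GGGGGGGGGG")), 0L)
})

test_that("upgrade rules produce 7mer-m8, 7mer-A1 and 8mer", {
  flank <- strrep("G", 10)
  m8 <- find_sites(LET7A, paste0(flank, "CUACCUC", flank))
  expect_true("7mer-m8" %in% m8$category)
  expect_equal(m8$utr_end[m8$category == "7mer-m8"] -
               m8$utr_start[m8$category == "7mer-m8"] + 1L, 7L)

  a1 <- find_sites(LET7A, paste0(flank, "UACCUCA", flank))
  expect_true("7mer-A1" %in% a1$category)

  e8 <- find_sites(LET7A, paste0(flank, "CUACCUCA", flank))
  expect_true("8mer" %in% e8$category)
  expect_equal(e8$utr_end[e8$category == "8mer"] -
               e8$utr_start[e8$category == "8mer"] + 1L, 8L)
})

test_that("site intervals have the category-defined lengths and gu <= 1", {
  set.seed(101)
  for (i in 1:200) {
    s <- find_sites(random_rna(22), random_rna(80))
    if (nrow(s) == 0) next
    len <- s$utr_end - s$utr_start + 1L
    want <- c("6mer" = 6L, "7mer-A1" = 7L, "7mer-m8" = 7L, "8mer" = 8L)
    expect_equal(len, unname(want[s$category]))
    expect_true(all(s$gu_count <= 1L))
  }
})

test_that("scanner matches the brute-force window oracle on random pairs", {
  set.seed(202)
  for (i in 1:300) {
    mirna <- random_rna(sample(16:24, 1))
    utr <- random_rna(sample(20:200, 1))
    expect_equal(find_sites(mirna, utr), oracle_scan(mirna, utr),
                     info = paste("case", i))
  }
})

test_that("effective_site follows category priority then wobbles then position", {
  sites <- find_sites(LET7A, paste0(strrep("G", 5), "UACCUC", strrep("G", 30),
                                    "CUACCUCA", strrep("G", 5)))
  eff <- effective_site(sites)
  expect_equal(eff$category, "8mer")

  # positional tie-break between two identical-category sites
  utr <- paste0(strrep("G", 5), "CUACCUC", strrep("G", 20), "CUACCUC",
                strrep("G", 5))
  sites2 <- find_sites(LET7A, utr)
  m8 <- sites2[sites2$category == "7mer-m8", ]
  expect_equal(nrow(m8), 2L)
  expect_equal(effective_site(m8)$utr_start, min(m8$utr_start))

  expect_null(effective_site(find_sites(LET7A, "GGGGGGGG")))
})

test_that("supplementary pairing requires WC at miRNA 13-16 in register", {
  # build a UTR by implanting an 8mer plus the 13-16 complement
  mirna <- gen_mirna(22, seed = 7)
  utr0 <- gen_utr(120, 0.5, seed = 8)
  utr <- implant_site(utr0, mirna, "8mer", 60, with_supplementary = TRUE)
  site <- effective_site(find_sites(mirna, utr))
  expect_equal(as.integer(supplementary_pairing(mirna, utr, site)), 1L)

  # break one of the four opposite bases
  u <- strsplit(utr, "")[[1]]
  opp <- site$anchor - (14 - 1)  # base opposite miRNA position 14
  u[opp] <- setdiff(c("A", "C", "G", "U"),
                    c(u[opp], switch(substr(mirna, 14, 14),
                                     A = "U", U = "A", G = "C", C = "G")))[1]
  utr_broken <- paste(u, collapse = "")
  site_b <- find_sites(mirna, utr_broken)
  site_b <- site_b[site_b$utr_start == site$utr_start, ]
  expect_equal(as.integer(supplementary_pairing(mirna, utr_broken, site_b)), 0L)

  # opposite positions falling off the UTR give 0
  early <- find_sites(LET7A, paste0("UACCUC", strrep("G", 20)))
  early <- early[early$utr_start == 1L, ]
  expect_equal(as.integer(supplementary_pairing(LET7A, paste0(
    "UACCUC", strrep("G", 20)), early)), 0L)
})

test_that("AU flank flag pools both 30-nt flanks with a >= 60% threshold", {
  core <- "UACCUC"
  all_a <- paste0(strrep("A", 30), core, strrep("A", 30))
  s <- find_sites(LET7A, all_a)
  s <- s[s$seed_register == "2-7", ][1, ]
  expect_equal(as.integer(au_flank_flag(all_a, s)), 1L)

  all_g <- paste0(strrep("G", 30), core, strrep("G", 30))
  s2 <- find_sites(LET7A, all_g)[1, ]
  expect_equal(as.integer(au_flank_flag(all_g, s2)), 0L)

  # exactly 36 A/U of 60 pooled nt sits on the >= boundary
  flank36 <- paste0(strrep("A", 18), strrep("G", 12))
  utr_b <- paste0(flank36, core, strrep("G", 12), strrep("A", 18))
  s3 <- find_sites(LET7A, utr_b)
  s3 <- s3[s3$utr_start == 31L, ][1, ]
  expect_equal(as.integer(au_flank_flag(utr_b, s3)), 1L)

  # one fewer A/U drops below
  flank35 <- paste0(strrep("A", 17), strrep("G", 13))
  utr_c <- paste0(flank35, core, strrep("G", 12), strrep("A", 18))
  s4 <- find_sites(LET7A, utr_c)
  s4 <- s4[s4$utr_start == 31L, ][1, ]
  expect_equal(as.integer(au_flank_flag(utr_c, s4)), 0L)
})

test_that("flank lengths truncate at UTR boundaries", {
  utr <- paste0("UACCUC", strrep("G", 10))  # site at the very 5' end
  s <- find_sites(LET7A, utr)
  s <- s[s$utr_start == 1L, ][1, ]
  flag <- au_flank_flag(utr, s)
  expect_equal(nchar(attr(flag, "flank_up")), 0L)
  expect_equal(nchar(attr(flag, "flank_down")),
               min(30L, nchar(utr) - s$utr_end))
})
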