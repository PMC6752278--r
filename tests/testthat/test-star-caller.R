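test_that("an all-reference haplotype matches only the reference allele", {
  tbl <- ladder_table()
  expect_identical(candidate_matches(make_hap(tbl), tbl), "*1")
  call <- resolve_call(make_hap(tbl), tbl)
  expect_identical(call$status, "single")
  expect_identical(call$resolved_label, "*1")
  expect_false(call$wildtype_disclaimer)
})

test_that("a single tag variant suffices to detect its allele", {
  txt <- paste(
    "gene\tlabel\tfunction\tstructural\t10:94781859:G:A:rs4244285",
    "CYP2C19\t*1\tnormal\tnone\t",
    "CYP2C19\t*2\tno_function\tnone\talt", sep = "\n")
  tbl <- parse_definition_table(txt)
  hap <- make_hap(tbl, alt = "10:94781859:G:A")
  expect_identical(candidate_matches(hap, tbl), "*2")
  expect_identical(resolve_call(hap, tbl)$resolved_label, "*2")
})

test_that("missing states never satisfy a requirement", {
  tbl <- ladder_table()
  vids <- tbl$variants$variant_id
  # *4 requires v2+v3; with v3 missing it must not match, but stays compatible
  hap <- make_hap(tbl, alt = vids[2], missing = vids[3])
  expect_false("*4" %in% candidate_matches(hap, tbl))
  expect_true("*4" %in% compatible_matches(hap, tbl))
})

test_that("candidate matching equals the brute-force per-allele oracle", {
  set.seed(101)
  n_checked <- 0
  for (t in 1:60) {
    tbl <- random_table(n_variants = sample(2:12, 1),
                        n_alleles = sample(1:8, 1))
    for (h in 1:25) {
      hap <- random_hap(tbl)
      expect_identical(sort(candidate_matches(hap, tbl)),
                       oracle_matches(hap, tbl))
      n_checked <- n_checked + 1
    }
  }
  expect_gte(n_checked, 1500)
})

test_that("nonfunctional alleles override all other matches", {
  tbl <- ladder_table()
  vids <- tbl$variants$variant_id
  # carries the nonfunctional *2 variant plus *3's variant
  call <- resolve_call(make_hap(tbl, alt = vids[c(1, 2)]), tbl)
  expect_identical(call$status, "single")
  expect_identical(call$resolved_label, "*2")
  expect_identical(call$resolved_function, "no_function")
  # the *3 variant is left unexplained by the overriding call
  expect_identical(call$unexplained_variants[[1]], vids[2])
})

test_that("a decreased-function match overrides normal-function matches", {
  tbl <- ladder_table()
  vids <- tbl$variants$variant_id
  # v2+v3 matches *4 (decreased) and *3 (normal); definitions overlap at v2
  call <- resolve_call(make_hap(tbl, alt = vids[c(2, 3)]), tbl)
  expect_identical(call$status, "single")
  expect_identical(call$resolved_label, "*4")
  expect_identical(call$resolved_function, "decreased")
})

test_that("disjoint co-occurring alleles resolve as a composite call", {
  tbl <- ladder_table()
  vids <- tbl$variants$variant_id
  # *3 {v2} and *5 {v4}: disjoint, union explains all observed alt states
  call <- resolve_call(make_hap(tbl, alt = vids[c(2, 4)]), tbl)
  expect_identical(call$status, "composite")
  expect_identical(call$resolved_label, "*3+*5")
  expect_match(call$resolved_label, "+", fixed = TRUE)
  expect_identical(call$unexplained_variants[[1]], character(0))
  # composite severity >= each member (here all normal)
  expect_identical(call$resolved_function, "normal")
  # a decreased + normal pair on one haplotype is still a composite,
  # not an override
  tbl2 <- allele_table(
    "CYP4F2L", fix_variants(2),
    tibble::tibble(label = c("*1", "*2", "*3"),
                   function_class = c("normal", "decreased", "normal"),
                   structural = "none"),
    tibble::tibble(label = c("*2", "*3"), variant_id = fix_vids(2),
                   state = "alt"))
  both <- resolve_call(make_hap(tbl2, alt = fix_vids(2)), tbl2)
  expect_identical(both$status, "composite")
  expect_identical(both$resolved_label, "*2+*3")
  expect_identical(both$resolved_function, "decreased")
})

test_that("unresolvable multi-matches stay ambiguous with candidates kept", {
  tbl <- ladder_table()
  vids <- tbl$variants$variant_id
  # v2+v5 alt: *3 {v2} and *9 {v2,v5} overlap at v2, both normal
  call <- resolve_call(make_hap(tbl, alt = vids[c(2, 5)]), tbl)
  expect_identical(call$status, "ambiguous")
  expect_setequal(call$candidates[[1]], c("*3", "*9"))
  expect_true(is.na(call$resolved_label))
})

test_that("single-variant alleles with an unexplained partner are ambiguous", {
  # *5 {vA}, *6 {vB}, *9 {vB,vC,vD}; observed alts {vA,vB,vC}, vD missing
  vids <- fix_vids(4)
  tbl <- allele_table(
    "DPYDL", fix_variants(4),
    tibble::tibble(label = c("*1", "*5", "*6", "*9"),
                   function_class = "normal", structural = "none"),
    tibble::tibble(label = c("*5", "*6", "*9", "*9", "*9"),
                   variant_id = vids[c(1, 2, 2, 3, 4)], state = "alt"))
  hap <- make_hap(tbl, alt = vids[1:3], missing = vids[4])
  call <- resolve_call(hap, tbl)
  expect_identical(call$status, "ambiguous")
  expect_setequal(call$candidates[[1]], c("*5", "*6"))
  expect_true("*9" %in% call$compatible[[1]])
  expect_identical(call$unexplained_variants[[1]], vids[3])
})

test_that("unmatched alternate states yield no_match", {
  tbl <- ladder_table()
  vids <- tbl$variants$variant_id
  # v3 alone corresponds to no allele (only *4 uses v3, and needs v2 too)
  call <- resolve_call(make_hap(tbl, alt = vids[3]), tbl)
  expect_identical(call$status, "no_match")
  expect_identical(call$candidates[[1]], character(0))
  expect_identical(call$unexplained_variants[[1]], vids[3])
})

test_that("reference calls with missing table variants carry the disclaimer", {
  tbl <- ladder_table()
  vids <- tbl$variants$variant_id
  call <- resolve_call(make_hap(tbl, missing = vids[1]), tbl)
  expect_identical(call$resolved_label, "*1")
  expect_true(call$wildtype_disclaimer)
})

test_that("statuses partition outcomes and calling is deterministic", {
  set.seed(202)
  for (t in 1:20) {
    tbl <- random_table(n_variants = sample(2:8, 1),
                        n_alleles = sample(1:6, 1))
    for (h in 1:10) {
      hap <- random_hap(tbl)
      c1 <- resolve_call(hap, tbl)
      c2 <- resolve_call(hap, tbl)
      expect_identical(c1$status,
                       c2$status)
      expect_identical(c1$resolved_label, c2$resolved_label)
      expect_true(c1$status %in% c("single", "composite", "ambiguous",
                                   "no_match"))
      if (c1$status == "single") {
        expect_identical(length(c1$resolved_label), 1L)
        expect_false(is.na(c1$resolved_label))
      }
      if (c1$status == "no_match") {
        expect_identical(c1$candidates[[1]], character(0))
        expect_gte(length(c1$unexplained_variants[[1]]), 1)
      }
      if (c1$status == "composite") {
        expect_match(c1$resolved_label, "+", fixed = TRUE)
        members <- strsplit(c1$resolved_label, "+", fixed = TRUE)[[1]]
        mem_fn <- tbl$alleles$function_class[match(members,
                                                   tbl$alleles$label)]
        expect_gte(function_severity(c1$resolved_function),
                   max(function_severity(mem_fn)))
      }
    }
  }
})

test_that("added missingness only defaults toward reference or widens sets", {
  # a masked haplotype must never produce a confident non-reference single
  # call that contradicts the unmasked haplotype's observed states
  set.seed(303)
  for (t in 1:15) {
    tbl <- random_table(n_variants = sample(3:8, 1),
                        n_alleles = sample(2:6, 1))
    for (h in 1:10) {
      hap <- random_hap(tbl, p_missing = 0)
      full <- resolve_call(hap, tbl)
      masked_hap <- hap
      mask <- runif(length(hap)) < 0.4
      masked_hap[mask] <- "missing"
      masked <- resolve_call(masked_hap, tbl)
      if (masked$status == "single" &&
          masked$resolved_label != tbl$reference_label) {
        # the masked call must be compatible with the unmasked observations
        expect_true(masked$resolved_label %in% compatible_matches(hap, tbl))
      }
    }
  }
})

test_that("cohort-level calling equals per-sample calling", {
  spec <- default_simulation_spec(n_samples = 25, seed = 99)
  sim <- simulate_cohort(spec)
  gt <- read_phased_vcf(sim$vcf)
  tbl <- sim$tables$CYP4F2S
  chaps <- cohort_haplotypes(gt, tbl)
  bulk <- call_gene_cohort(chaps, tbl)
  for (s in unique(chaps$sample)[1:8]) {
    single <- call_sample_gene(
      build_sample_haplotypes(gt, tbl, s), tbl)
    b <- bulk[bulk$sample == s, ]
    expect_identical(b$status, single$status)
    expect_identical(b$resolved_label, single$resolved_label)
  }
})
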