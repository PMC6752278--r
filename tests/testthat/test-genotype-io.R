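test_that("phased VCF records map to per-sample site genotypes", {
  f <- withr::local_tempfile(fileext = ".vcf")
  write_test_vcf(f, list(
    c("10", "100", "rs4244285", "G", "A", ".", "PASS", ".", "GT:OR:GP",
      "0|1:G:.", "./.:G:.", "1|1:I:0.99"),
    c("10", "200", ".", "C", "T,G", ".", "PASS", ".", "GT:OR:GP",
      "0|2:G:.", "1/0:G:.", "0|0:G:.")),
    samples = c("A", "B", "C"))
  gt <- read_phased_vcf(f)
  # biallelic decomposition: 2nd record splits into C>T and C>G rows
  expect_identical(nrow(gt), 3L * 3L)
  r1 <- gt[gt$pos == 100 & gt$sample == "A", ]
  expect_identical(c(r1$allele_a, r1$allele_b), c("ref", "alt"))
  expect_identical(r1$origin, "genotyped")
  expect_identical(r1$rsid, "rs4244285")
  r2 <- gt[gt$pos == 100 & gt$sample == "B", ]
  expect_identical(c(r2$allele_a, r2$allele_b), c("missing", "missing"))
  r3 <- gt[gt$pos == 100 & gt$sample == "C", ]
  expect_identical(r3$origin, "imputed")
  expect_equal(r3$gp, 0.99)
  # sample A carries the second ALT: alt on the C>G row, ref on the C>T row
  ct <- gt[gt$variant_id == "10:200:C:T" & gt$sample == "A", ]
  cg <- gt[gt$variant_id == "10:200:C:G" & gt$sample == "A", ]
  expect_identical(c(ct$allele_a, ct$allele_b), c("ref", "ref"))
  expect_identical(c(cg$allele_a, cg$allele_b), c("ref", "alt"))
  # unphased het is kept but flagged
  bt <- gt[gt$variant_id == "10:200:C:T" & gt$sample == "B", ]
  expect_false(bt$phased)
})

test_that("malformed GT fields raise a parse error with coordinates", {
  f <- withr::local_tempfile(fileext = ".vcf")
  write_test_vcf(f, list(
    c("10", "100", ".", "G", "A", ".", "PASS", ".", "GT:OR:GP",
      "0|7:G:.")), samples = "A")
  expect_error(read_phased_vcf(f), "parse error.*10:100")
})

test_that("the probability filter is strict and origin-specific", {
  # exhaustive origin x gp sweep against the rule's truth table
  grid <- tidyr::expand_grid(
    origin = c("genotyped", "imputed"),
    gp = c(0.10, 0.50, 0.85, 0.8999, 0.90, 0.95, 1.0))
  gt <- tibble::tibble(
    sample = sprintf("S%02d", seq_len(nrow(grid))),
    variant_id = "1:10:A:G",
    allele_a = "ref", allele_b = "alt", phased = TRUE,
    origin = grid$origin, gp = grid$gp)
  out <- apply_probability_filter(gt, threshold = 0.90)
  expect_filtered <- grid$origin == "imputed" & grid$gp < 0.90
  expect_identical(out$allele_a == "missing", expect_filtered)
  expect_identical(out$allele_b == "missing", expect_filtered)
  # boundary: gp == threshold is kept ("lower than" is strict)
  kept <- out[grid$origin == "imputed" & grid$gp == 0.90, ]
  expect_identical(kept$allele_b, "alt")
  # genotyped gp 0.10 untouched
  g10 <- out[grid$origin == "genotyped" & grid$gp == 0.10, ]
  expect_identical(g10$allele_b, "alt")
  expect_error(apply_probability_filter(gt, 0), "precondition")
  # imputed records must carry a probability
  gt$gp[1] <- NA; gt$origin[1] <- "imputed"
  expect_error(apply_probability_filter(gt), "data error")
})

test_that("merge keeps the union of keys with genotyped calls winning", {
  set.seed(31)
  for (i in 1:20) {
    n_g <- sample(0:15, 1); n_i <- sample(0:15, 1)
    keys <- sprintf("S%d|1:%d:A:G", sample(1:6, 30, TRUE),
                    sample(1:5, 30, TRUE) * 10)
    gk <- unique(keys[seq_len(n_g)]); ik <- unique(keys[15 + seq_len(n_i)])
    mk <- function(k, org, st) {
      p <- strsplit(k, "|", fixed = TRUE)
      tibble::tibble(sample = vapply(p, `[[`, "", 1),
                     variant_id = vapply(p, `[[`, "", 2),
                     allele_a = st, allele_b = st, phased = TRUE,
                     origin = org, gp = ifelse(org == "imputed", 0.99, NA))
    }
    g <- mk(gk, "genotyped", "ref"); im <- mk(ik, "imputed", "alt")
    out <- merge_sources(g, im)
    okey <- paste(out$sample, out$variant_id, sep = "|")
    expect_setequal(okey, union(gk, ik))
    # every overlapping key kept the genotyped state
    overlap <- intersect(gk, ik)
    expect_true(all(out$allele_a[okey %in% overlap] == "ref"))
    expect_identical(sum(out$origin == "genotyped"), length(gk))
  }
  dup <- tibble::tibble(sample = c("A", "A"), variant_id = c("v", "v"),
                        allele_a = "ref", allele_b = "ref", phased = TRUE,
                        origin = "genotyped", gp = NA_real_)
  expect_error(merge_sources(dup, dup[0, ]), "duplicate")
})

test_that("genotyped-over-imputed: one-VCF merge equals explicit merge", {
  # a genotyped (ref,alt) beats an imputed (ref,ref) at the same key
  g <- tibble::tibble(sample = "A", variant_id = "1:10:A:G",
                      allele_a = "ref", allele_b = "alt", phased = TRUE,
                      origin = "genotyped", gp = NA_real_)
  im <- g |> dplyr::mutate(allele_b = "ref", origin = "imputed", gp = 0.99)
  out <- merge_sources(g, im)
  expect_identical(nrow(out), 1L)
  expect_identical(out$allele_b, "alt")
  # imputed-only key survives
  im2 <- im |> dplyr::mutate(variant_id = "1:20:C:T")
  out2 <- merge_sources(g, im2)
  expect_setequal(out2$variant_id, c("1:10:A:G", "1:20:C:T"))
})

test_that("filtering and merging commute (genotyped records are gp-exempt)", {
  set.seed(77)
  for (i in 1:10) {
    mk <- function(n, org) tibble::tibble(
      sample = sample(sprintf("S%d", 1:4), n, TRUE),
      variant_id = sample(sprintf("1:%d:A:G", (1:6) * 10), n, TRUE),
      allele_a = sample(c("ref", "alt"), n, TRUE),
      allele_b = sample(c("ref", "alt"), n, TRUE),
      phased = TRUE, origin = org,
      gp = round(runif(n, 0.5, 1), 3)) |>
      dplyr::distinct(sample, variant_id, .keep_all = TRUE)
    g <- mk(sample(1:12, 1), "genotyped")
    im <- mk(sample(1:12, 1), "imputed")
    a <- apply_probability_filter(merge_sources(g, im))
    b <- merge_sources(apply_probability_filter(g),
                       apply_probability_filter(im))
    key <- function(d) d[order(d$sample, d$variant_id), ]
    expect_equal(as.data.frame(key(a)), as.data.frame(key(b)))
  }
})

test_that("projection covers exactly the table's variants, missing untyped", {
  tbl <- ladder_table()
  vids <- tbl$variants$variant_id
  gt <- tibble::tibble(
    sample = "S1",
    variant_id = vids[1:2],
    allele_a = c("ref", "alt"), allele_b = c("alt", "alt"),
    phased = TRUE, origin = "genotyped", gp = NA_real_)
  hp <- build_sample_haplotypes(gt, tbl, "S1")
  expect_identical(hp$variant_id, vids)
  expect_identical(hp$hapA, c("ref", "alt", "missing", "missing", "missing"))
  expect_identical(hp$hapB, c("alt", "alt", "missing", "missing", "missing"))
})

test_that("one unphased het is tolerated; two are an ambiguity error", {
  tbl <- ladder_table()
  vids <- tbl$variants$variant_id
  one_het <- tibble::tibble(
    sample = "S1", variant_id = vids[1:3],
    allele_a = c("ref", "alt", "alt"), allele_b = c("alt", "alt", "alt"),
    phased = c(FALSE, FALSE, FALSE), origin = "genotyped", gp = NA_real_)
  expect_silent(build_sample_haplotypes(one_het, tbl, "S1"))
  two_het <- one_het |>
    dplyr::mutate(allele_b = c("alt", "ref", "alt"))
  expect_error(build_sample_haplotypes(two_het, tbl, "S1"),
               "ambiguity error")
  expect_error(cohort_haplotypes(two_het, tbl), "ambiguity error")
})

test_that("simulator VCF round-trips to the generator's truth states", {
  spec <- default_simulation_spec(n_samples = 30, seed = 23)
  sim <- simulate_cohort(spec)
  gt <- read_phased_vcf(sim$vcf)
  tbl <- sim$tables$CYP2C19S
  chaps <- cohort_haplotypes(gt, tbl)
  truth <- sim$truth[sim$truth$gene == "CYP2C19S", ]
  req_alts <- function(lab) unique(unlist(lapply(
    strsplit(lab, "+", fixed = TRUE)[[1]],
    function(m) tbl$requirements$variant_id[
      tbl$requirements$label == m & tbl$requirements$state == "alt"])))
  for (s in truth$sample[1:10]) {
    h <- chaps[chaps$sample == s, ]
    expect_alt <- h$variant_id %in% req_alts(truth$hap_a[truth$sample == s])
    expect_identical(h$hapA == "alt", expect_alt, info = s)
  }
})
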