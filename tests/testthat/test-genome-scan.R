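annot <- function(ids, chrom, pos) {
  data.frame(feature_id = ids, chrom = chrom, pos = pos,
             stringsAsFactors = FALSE)
}

test_that("cis windows apply the stated boundary conventions", {
  tr <- annot("tx1", "chr1", 1000000)
  cpg_in <- annot("cpgA", "chr1", 1000000 + 1499)
  cpg_out <- annot("cpgB", "chr1", 1000000 + 1500)  # strict '<' boundary
  snp_in <- annot("snp1", "chr1", 1000000 + 100000)  # inclusive '<=' boundary
  snp_out <- annot("snp2", "chr1", 1000000 + 100001)

  both_cpg <- rbind(cpg_in, cpg_out)
  both_snp <- rbind(snp_in, snp_out)
  tri <- pair_cis(tr, both_cpg, both_snp)
  expect_identical(sort(unique(tri$cpg_id)), "cpgA")
  expect_identical(sort(unique(tri$snp_id)), "snp1")

  # different chromosome never pairs
  tri2 <- pair_cis(tr, annot("cpgC", "chr2", 1000100), both_snp)
  expect_identical(nrow(tri2), 0L)
})

test_that("triplet combinatorics multiply CpG pairs by cis-SNP count", {
  tr <- annot("tx1", "chr5", 500000)
  cpgs <- annot(c("cpg1", "cpg2"), "chr5", c(500400, 499300))
  snps <- annot(c("s1", "s2", "s3"), "chr5", c(450000, 520000, 599999))
  tri <- pair_cis(tr, cpgs, snps)
  expect_identical(nrow(tri), 6L)  # 2 CpGs x 3 SNPs

  # two transcripts sharing the features double the count
  tr2 <- rbind(tr, annot("tx2", "chr5", 500500))
  tri2 <- pair_cis(tr2, cpgs, snps)
  expect_identical(nrow(tri2), 12L)

  expect_error(pair_cis(rbind(tr, tr), cpgs, snps), "duplicate")
})

make_scan_data <- function(n_pairs, n_snps_per, n = 200, t = 4, seed = 1,
                           planted = NULL, beta = 0, pve_delta = 0) {
  set.seed(seed)
  expr <- list(); meth <- list(); geno <- NULL; tri <- NULL
  for (k in seq_len(n_pairs)) {
    tx <- sprintf("tx%02d", k); cg <- sprintf("cpg%02d", k)
    m <- gen_methylation(n, t, diag(t))
    snp_ids <- sprintf("s%02d_%d", k, seq_len(n_snps_per))
    gs <- sapply(seq_len(n_snps_per), function(j) gen_genotypes(n, 0.3))
    p0 <- sim_params(n_subjects = n, n_tissues = t, tau = 1, theta = 0,
                     eps = 1, lam = 0.3)
    if (!is.null(planted) && k == planted) {
      vc <- pve_to_variances(0, pve_delta, tau = 1, theta = 0, eps = 1)
      p0$delta <- unname(vc["delta"])
      p0$beta <- beta
      y <- gen_expression(p0, gs[, 1], m)   # signal rides on the first SNP
    } else {
      y <- gen_expression(p0, rep(0L, n), m)
    }
    expr[[tx]] <- y
    meth[[cg]] <- m
    geno <- rbind(geno, t(gs))
    rownames(geno)[(nrow(geno) - n_snps_per + 1):nrow(geno)] <- snp_ids
    tri <- rbind(tri, data.frame(transcript_id = tx, cpg_id = cg,
                                 snp_id = snp_ids, stringsAsFactors = FALSE))
  }
  list(expr = expr, meth = meth, geno = geno, triplets = tri)
}

test_that("a planted eQTL is recovered as the top scan hit with the right driver", {
  hits <- 0L; drivers <- 0L
  n_runs <- 12L
  for (run in seq_len(n_runs)) {
    sd0 <- make_scan_data(10, 5, n = 300, seed = 400 + run, planted = 1,
                          beta = 0.5)
    res <- scan_triplets(sd0$expr, sd0$meth, sd0$geno, sd0$triplets,
                         method = "joint")
    best <- res[which.min(res$p_value), ]
    if (best$transcript_id == "tx01" && best$snp_id == "s01_1") {
      hits <- hits + 1L
      if (isTRUE(best$significant) && isTRUE(best$driver_additive))
        drivers <- drivers + 1L
    }
  }
  expect_gte(hits, 10L)
  expect_gte(drivers, 9L)
})

test_that("a planted three-way interaction shifts the scan ranking upward", {
  # the G-by-M-by-T component has bounded per-locus information under the
  # per-subject generative model, so a strong planted interaction enriches
  # the top of the ranking rather than dominating it outright
  ranks <- integer(24)
  for (run in seq_len(24)) {
    sd0 <- make_scan_data(10, 5, n = 300, seed = 430 + run, planted = 1,
                          pve_delta = 30)
    res <- scan_triplets(sd0$expr, sd0$meth, sd0$geno, sd0$triplets,
                         method = "joint")
    ip <- which(res$transcript_id == "tx01" & res$snp_id == "s01_1")
    ranks[run] <- rank(res$p_value)[ip]
  }
  # under the global null the planted rank would be uniform on 1..50
  # (mean 25.5, SE of the 24-run mean ~ 2.9); the interaction signal pulls
  # the average well below that
  expect_lt(mean(ranks), 22)
})

test_that("the scan controls discoveries under the global null", {
  clean <- 0L
  for (run in 1:5) {
    sd0 <- make_scan_data(20, 5, n = 150, seed = 500 + run)
    res <- scan_triplets(sd0$expr, sd0$meth, sd0$geno, sd0$triplets,
                         method = "joint")
    if (sum(res$significant) == 0) clean <- clean + 1L
    # q-values are a monotone transform of p-values
    o <- order(res$p_value)
    expect_true(all(diff(res$q_value[o]) >= -1e-15))
  }
  expect_gte(clean, 4L)
})

test_that("scan output is independent of triplet ordering", {
  sd0 <- make_scan_data(5, 4, n = 120, seed = 600, planted = 2)
  res1 <- scan_triplets(sd0$expr, sd0$meth, sd0$geno, sd0$triplets, "joint")
  shuf <- sd0$triplets[sample(nrow(sd0$triplets)), ]
  res2 <- scan_triplets(sd0$expr, sd0$meth, sd0$geno, shuf, "joint")
  key <- function(d) paste(d$transcript_id, d$cpg_id, d$snp_id)
  expect_equal(res2$p_value[match(key(res1), key(res2))], res1$p_value)
})

test_that("tissue-by-tissue scans use min-q across regions at fdr / t", {
  sd0 <- make_scan_data(4, 3, n = 100, seed = 700)
  res <- scan_triplets(sd0$expr, sd0$meth, sd0$geno, sd0$triplets,
                       method = "tbtm", fdr = 0.05)
  expect_true(all(c("p_value", "q_value", "significant") %in% names(res)))
  expect_identical(res$significant, res$q_value <= 0.05 / 4)

  res2 <- scan_triplets(sd0$expr, sd0$meth, sd0$geno, sd0$triplets,
                        method = "tbt", fdr = 0.05)
  expect_identical(nrow(res2), nrow(sd0$triplets))
})

test_that("missing features are skipped with a warning; empty input is empty", {
  sd0 <- make_scan_data(3, 2, n = 80, seed = 800)
  tri_bad <- rbind(sd0$triplets,
                   data.frame(transcript_id = "ghost", cpg_id = "cpg01",
                              snp_id = "s01_1"))
  expect_warning(res <- scan_triplets(sd0$expr, sd0$meth, sd0$geno, tri_bad,
                                      "jaguar"), "skipped")
  expect_identical(nrow(res), nrow(sd0$triplets))

  empty <- scan_triplets(sd0$expr, sd0$meth, sd0$geno,
                         sd0$triplets[0, ], "joint")
  expect_identical(nrow(empty), 0L)
})

test_that("matrix and genotype stores round-trip through TSV", {
  sd0 <- make_scan_data(2, 3, n = 15, seed = 900)
  dir <- withr::local_tempdir()
  ep <- file.path(dir, "expr.tsv")
  write_matrix_store(sd0$expr, ep)
  back <- read_matrix_store(ep)
  expect_setequal(names(back), names(sd0$expr))
  for (id in names(back))
    expect_equal(unname(back[[id]]), unname(sd0$expr[[id]]), tolerance = 1e-12)

  gp <- file.path(dir, "geno.tsv")
  write_genotype_store(sd0$geno, gp)
  gback <- read_genotype_store(gp)
  expect_equal(unname(gback), unname(sd0$geno))
  expect_identical(rownames(gback), rownames(sd0$geno))

  ap <- file.path(dir, "annot.tsv")
  an <- data.frame(feature_id = c("tx1", "c1", "s1"), chrom = "chr1",
                   pos = c(100, 200, 300), kind = c("transcript", "cpg", "snp"))
  write.table(an, ap, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_identical(read_annotations(ap, kind = "cpg")$feature_id, "c1")
  expect_identical(nrow(read_annotations(ap)), 3L)
})
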