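test_that("genotype streams decode plain, gzip and zip input identically", {
  geno <- make_sim(n_subjects = 20L, n_snps = 5L, seed = 3L,
                   imputation_noise = 0.1)$genotypes
  plain <- withr::local_tempfile(fileext = ".gen")
  write_gen(geno, plain)
  lines <- readLines(plain)

  gz <- withr::local_tempfile(fileext = ".gen.gz")
  con <- gzfile(gz, "wt"); writeLines(lines, con); close(con)
  zp <- withr::local_tempfile(fileext = ".zip")
  make_zip(zp, "data.gen", lines)

  read_all <- function(path) {
    con <- open_genotype_stream(path)
    on.exit(close(con))
    readLines(con)
  }
  expect_identical(read_all(plain), lines)
  expect_identical(read_all(gz), lines)
  expect_identical(read_all(zp), lines)

  # byte-identical downstream records
  r_plain <- read_gen(plain, chromosome = "1")
  r_gz <- read_gen(gz, chromosome = "1")
  r_zip <- read_gen(zp, chromosome = "1")
  expect_identical(r_plain, r_gz)
  expect_identical(r_plain, r_zip)
})

test_that("missing or corrupt genotype files are fatal and name the path", {
  expect_error(open_genotype_stream("/no/such/file.gen"),
               "/no/such/file.gen", class = "survscan_data_error")
  bad <- withr::local_tempfile(fileext = ".zip")
  writeBin(charToRaw("PK\x03\x04 not a real archive"), bad)
  expect_error(open_genotype_stream(bad), class = "survscan_data_error")
})

test_that("line-range selection is 0-based inclusive and a pure filter", {
  geno <- make_sim(n_subjects = 10L, n_snps = 10L, seed = 4L)$genotypes
  path <- withr::local_tempfile(fileext = ".gen")
  write_gen(geno, path)

  expect_equal(nrow(read_gen(path, line_start = 0L, line_stop = 9L)), 10L)
  expect_equal(nrow(read_gen(path, line_start = 3L, line_stop = 5L)), 3L)

  full <- read_gen(path)
  for (rng in list(c(0L, 0L), c(2L, 7L), c(9L, 9L), c(0L, 9L))) {
    slice <- read_gen(path, line_start = rng[[1L]], line_stop = rng[[2L]])
    expect_identical(slice, full[(rng[[1L]] + 1L):(rng[[2L]] + 1L), ])
  }
})

test_that("base-pair windows filter on position after the line range", {
  lines <- c(
    "s1 rs1 100 A B 1 0 0",
    "s2 rs2 200 A B 0 1 0",
    "s3 rs3 300 A B 0 0 1"
  )
  path <- withr::local_tempfile(fileext = ".gen")
  writeLines(lines, path)
  got <- read_gen(path, bp_start = 150L, bp_stop = 250L)
  expect_equal(nrow(got), 1L)
  expect_equal(got$snp_id, "s2")
})

test_that("malformed GEN lines are fatal with the line number", {
  path <- withr::local_tempfile(fileext = ".gen")
  writeLines(c("s1 rs1 100 A B 1 0 0", "s2 rs2 200 A B 1 0"), path)
  expect_error(read_gen(path), "line 2", class = "survscan_data_error")

  path2 <- withr::local_tempfile(fileext = ".gen")
  writeLines("s1 rs1 100 A B 1 zero 0", path2)
  expect_error(read_gen(path2), "non-numeric", class = "survscan_data_error")
})

test_that("GEN round trip preserves metadata exactly and probabilities to 6 dp", {
  geno <- make_sim(n_subjects = 15L, n_snps = 8L, seed = 5L,
                   imputation_noise = 0.2)$genotypes
  path <- withr::local_tempfile(fileext = ".gen")
  write_gen(geno, path)
  back <- read_gen(path, chromosome = "1")
  expect_identical(back$snp_id, geno$snp_id)
  expect_identical(back$rs_id, geno$rs_id)
  expect_identical(back$position, geno$position)
  expect_identical(back$allele_a, geno$allele_a)
  expect_identical(back$allele_b, geno$allele_b)
  for (j in seq_len(nrow(geno))) {
    expect_true(max(abs(back$probs[[j]] - geno$probs[[j]])) <= 5e-7)
  }
})

test_that("VCF sites yield records with GP > DS > GT priority", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_test_vcf(path)
  expect_warning(recs <- read_vcf(path), "multi-allelic")

  expect_equal(nrow(recs), 4L) # multi-allelic site dropped
  gp <- recs[recs$snp_id == "v_gp", ]
  expect_equal(gp$source, "probabilities")
  expect_equal(gp$probs[[1L]], triples(1, 0, 0, 0, 1, 0, 0, 0, 1))

  gt <- recs[recs$snp_id == "v_gt", ]
  expect_equal(gt$source, "hard_calls")
  expect_equal(gt$probs[[1L]], triples(1, 0, 0, 0, 1, 0, 0, 0, 1))
  expect_equal(gt$allele_a, "C")
  expect_equal(gt$allele_b, "T")

  ds <- recs[recs$snp_id == "v_ds", ]
  expect_equal(ds$source, "dosages")
  expect_equal(ds$probs[[1L]], c(0.0, 1.2, 2.0))

  miss <- recs[recs$snp_id == "v_miss", ]
  expect_true(all(is.na(miss$probs[[1L]][2L, ])))
  expect_equal(miss$probs[[1L]][1L, ], c(1, 0, 0))
})

test_that("VCF line ranges and bp windows select sites", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_test_vcf(path)
  expect_equal(nrow(suppressWarnings(read_vcf(path, line_start = 1L,
                                              line_stop = 2L))), 2L)
  expect_equal(suppressWarnings(read_vcf(path, bp_start = 150L,
                                         bp_stop = 350L))$snp_id,
               c("v_gt", "v_ds"))
})

test_that("sample files parse with NA handling and type-row detection", {
  df <- data.frame(
    ID = paste0("id", 1:5),
    event_times = c("1.5", "2.0", "NA", "4.0", "5.5"),
    censoring = c("1", "0", "1", "1", "0"),
    covariate1 = c("0.3", "NA", "1.1", "0.0", "2.2")
  )
  path <- withr::local_tempfile(fileext = ".sample")
  write_sample_file(path, df, type_row = TRUE)

  phen <- read_sample(path, "event_times", "censoring", "covariate1")
  expect_equal(nrow(phen), 5L) # type row skipped, subjects kept
  expect_equal(phen$missing, c(FALSE, TRUE, TRUE, FALSE, FALSE))
  expect_equal(phen$time[[1L]], 1.5)
  expect_equal(phen$event, c(1, 0, 1, 1, 0))

  # covariate missingness only counts when the covariate is requested
  phen2 <- read_sample(path, "event_times", "censoring")
  expect_equal(phen2$missing, c(FALSE, FALSE, TRUE, FALSE, FALSE))

  # no type row works too
  path2 <- withr::local_tempfile(fileext = ".sample")
  write_sample_file(path2, df, type_row = FALSE)
  expect_identical(read_sample(path2, "event_times", "censoring", "covariate1"),
                   phen)
})

test_that("unknown sample-file headers are fatal and list available columns", {
  df <- data.frame(ID = "id1", event_times = "1", censoring = "1")
  path <- withr::local_tempfile(fileext = ".sample")
  write_sample_file(path, df)
  expect_error(read_sample(path, "not_a_column", "censoring"),
               "available columns.*event_times",
               class = "survscan_data_error")
})

test_that("categorical covariates are rejected with recoding advice", {
  df <- data.frame(ID = paste0("id", 1:3), event_times = c("1", "2", "3"),
                   censoring = c("1", "1", "0"), arm = c("drug", "placebo", "drug"))
  path <- withr::local_tempfile(fileext = ".sample")
  write_sample_file(path, df)
  expect_error(read_sample(path, "event_times", "censoring", "arm"),
               "binary", class = "survscan_data_error")
})
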