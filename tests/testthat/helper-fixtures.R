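# Shared fixture builders. Everything is generated in code at test time;
# nothing is read from stored data files.

# A tiny genotype record list (the unit the dosage/QC layer consumes).
make_record <- function(probs, allele_a = "A", allele_b = "B",
                        source = "probabilities", snp_id = "snp1") {
  list(
    snp_id = snp_id, rs_id = "rs1", chromosome = "1", position = 100L,
    allele_a = allele_a, allele_b = allele_b,
    probs = probs, source = source
  )
}

triples <- function(...) matrix(c(...), ncol = 3L, byrow = TRUE)

# Random genotype tibble + phenotype pair for scan-level tests.
make_sim <- function(n_subjects = 200L, n_snps = 10L, seed = 1L, ...) {
  sc <- sim_scenario(n_subjects = n_subjects, n_snps = n_snps, seed = seed,
                     causal_index = 1L, ...)
  geno <- simulate_genotypes(sc)
  trt <- simulate_treatment(n_subjects, seed = seed + 2L)
  surv <- simulate_survival(attr(geno, "hard_calls")[, sc$causal_index],
                            trt, sc)
  phen <- tibble::tibble(
    subject_id = sprintf("id%04d", seq_len(n_subjects)),
    time = surv$time, event = surv$event,
    treatment = as.numeric(trt),
    missing = FALSE
  )
  list(scenario = sc, genotypes = geno, phen = phen)
}

# Random right-censored regression data for model-fitting tests.
rand_surv_data <- function(n, p = 2L, ties = FALSE, seed = 1L,
                           shape = 1.2, scale = 3) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * p), n, p)
    X[, p] <- rbinom(n, 1L, 0.5) # last column binary
    beta <- runif(p, -0.6, 0.6)
    eta <- drop(X %*% beta)
    t_ev <- scale * (-log(runif(n)) / exp(eta))^(1 / shape)
    cens <- runif(n, 0, quantile(t_ev, 0.9) * 2)
    time <- pmin(t_ev, cens)
    if (ties) time <- round(time, 1) + 0.05 # coarsen to force tied times
    d <- tibble::tibble(time = time, event = as.numeric(t_ev <= cens))
    for (j in seq_len(p)) d[[paste0("x", j)]] <- X[, j]
    attr(d, "beta") <- beta
    d
  })
}

# Write a sample file with an Oxford type-code row.
write_sample_file <- function(path, df, type_row = TRUE) {
  lines <- paste(colnames(df), collapse = " ")
  if (type_row) {
    codes <- c("0", rep("P", ncol(df) - 1L))
    lines <- c(lines, paste(codes, collapse = " "))
  }
  body <- apply(df, 1L, paste, collapse = " ")
  writeLines(c(lines, body), path)
  path
}

# --- minimal stored (uncompressed) ZIP writer -------------------------------
# Used to exercise zip-transparent input without an external zip binary.
crc32_table <- local({
  tab <- integer(256L)
  for (i in 0:255) {
    crc <- i
    for (k in 1:8) {
      crc <- if (bitwAnd(crc, 1L) == 1L) {
        bitwXor(bitwShiftR(crc, 1L), -306674912L) # poly 0xEDB88320
      } else {
        bitwShiftR(crc, 1L)
      }
    }
    tab[i + 1L] <- crc
  }
  tab
})

crc32 <- function(bytes) {
  crc <- -1L
  for (b in as.integer(bytes)) {
    crc <- bitwXor(bitwShiftR(crc, 8L),
                   crc32_table[bitwAnd(bitwXor(crc, b), 255L) + 1L])
  }
  bitwXor(crc, -1L)
}

u16 <- function(x) writeBin(as.integer(x), raw(), size = 2L, endian = "little")
u32 <- function(x) writeBin(as.integer(x), raw(), size = 4L, endian = "little")

make_zip <- function(zip_path, inner_name, lines) {
  data <- charToRaw(paste0(paste(lines, collapse = "\n"), "\n"))
  name <- charToRaw(inner_name)
  crc <- crc32(data)
  sz <- u32(length(data))
  local_hdr <- c(
    charToRaw("PK\x03\x04"), u16(20L), u16(0L), u16(0L), u16(0L), u16(0L),
    u32(crc), sz, sz, u16(length(name)), u16(0L), name
  )
  central <- c(
    charToRaw("PK\x01\x02"), u16(20L), u16(20L), u16(0L), u16(0L),
    u16(0L), u16(0L), u32(crc), sz, sz, u16(length(name)),
    u16(0L), u16(0L), u16(0L), u16(0L), u32(0L), u32(0L), name
  )
  eocd <- c(
    charToRaw("PK\x05\x06"), u16(0L), u16(0L), u16(1L), u16(1L),
    u32(length(central)), u32(length(local_hdr) + length(data)), u16(0L)
  )
  writeBin(c(local_hdr, data, central, eocd), zip_path)
  zip_path
}

# A small multi-record VCF with mixed GP/DS/GT evidence for 3 subjects.
write_test_vcf <- function(path) {
  lines <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=GP,Number=G,Type=Float,Description="Genotype probabilities">',
    '##FORMAT=<ID=DS,Number=1,Type=Float,Description="Dosage">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "s1", "s2", "s3", sep = "\t"),
    paste("1", "100", "v_gp", "A", "G", ".", "PASS", ".",
          "GT:GP", "0/0:1,0,0", "0/1:0,1,0", "1/1:0,0,1", sep = "\t"),
    paste("1", "200", "v_gt", "C", "T", ".", "PASS", ".",
          "GT", "0/0", "0/1", "1/1", sep = "\t"),
    paste("1", "300", "v_ds", "G", "A", ".", "PASS", ".",
          "DS", "0.0", "1.2", "2.0", sep = "\t"),
    paste("1", "400", "v_multi", "A", "G,T", ".", "PASS", ".",
          "GT", "0/0", "0/1", "1/2", sep = "\t"),
    paste("1", "500", "v_miss", "T", "C", ".", "PASS", ".",
          "GT:GP", "0/0:1,0,0", "./.:.", "1/1:0,0,1", sep = "\t")
  )
  writeLines(lines, path)
  path
}
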