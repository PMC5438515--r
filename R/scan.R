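#' Specify the per-variant analysis model
#'
#' @param method `"cox"` (proportional hazards, Wald p-values, 95%
#'   hazard-ratio confidence intervals) or `"weibull"` (parametric
#'   regression, score-test p-values, intercept and shape rows).
#' @param covariates Covariate column names to adjust for, in order.
#' @param interactions Subset of `covariates` for which a SNP-covariate
#'   interaction term (`dosage x covariate`) is added.
#' @param print_mode `"all"` emits one output row per model term;
#'   `"onlysnp"` keeps only the SNP main-effect row; `"onlyint"` keeps only
#'   the interaction rows.
#' @return A `survscan_spec` list.
#' @export
model_spec <- function(method = c("cox", "weibull"),
                       covariates = character(),
                       interactions = character(),
                       print_mode = c("all", "onlysnp", "onlyint")) {
  method <- match.arg(method)
  print_mode <- match.arg(print_mode)
  bad <- setdiff(interactions, covariates)
  if (length(bad) > 0L) {
    stop_usage(paste0(
      "interaction covariate(s) not in the model: ",
      paste(bad, collapse = ", "),
      "; add them to `covariates` first"
    ))
  }
  structure(
    list(method = method, covariates = covariates,
         interactions = interactions, print_mode = print_mode),
    class = "survscan_spec"
  )
}

#' Build the per-variant design matrix
#'
#' Columns are ordered SNP dosage, covariates (given order), then
#' interaction columns (elementwise `dosage x covariate`), named `"SNP"`,
#' the covariate names, and `"SNPx<name>"`.
#'
#' @param dosage Numeric dosage vector.
#' @param covariate_data Tibble/data frame holding the covariate columns.
#' @param spec A [model_spec()].
#' @return A tibble of design columns.
#' @export
build_design <- function(dosage, covariate_data, spec) {
  design <- tibble::tibble(SNP = dosage)
  for (cv in spec$covariates) {
    if (!cv %in% names(covariate_data)) {
      stop_usage(paste0("covariate not found in phenotype data: ", cv))
    }
    design[[cv]] <- covariate_data[[cv]]
  }
  for (cv in spec$interactions) {
    design[[paste0("SNPx", cv)]] <- dosage * covariate_data[[cv]]
  }
  design
}

assoc_row <- function(variable, kind, rec, qc, dosage, note = "",
                      coefficient = NA_real_, hazard_ratio = NA_real_,
                      standard_error = NA_real_, ci_low = NA_real_,
                      ci_high = NA_real_, p_value = NA_real_,
                      lrt_statistic = NA_real_, lrt_p = NA_real_) {
  tibble::tibble(
    variable = variable,
    rs_id = rec$rs_id,
    chromosome = rec$chromosome,
    position = rec$position,
    effect_allele = if (is.null(dosage)) rec$allele_b else dosage$effect_allele,
    noneffect_allele = if (is.null(dosage)) rec$allele_a else dosage$noneffect_allele,
    coefficient = coefficient,
    hazard_ratio = hazard_ratio,
    standard_error = standard_error,
    ci_low = ci_low, ci_high = ci_high,
    p_value = p_value,
    lrt_statistic = lrt_statistic, lrt_p = lrt_p,
    eaf = if (is.null(qc)) NA_real_ else qc$eaf,
    maf = if (is.null(qc)) NA_real_ else qc$maf,
    info = if (is.null(qc)) NA_real_ else qc$info,
    n_used = if (is.null(qc)) NA_integer_ else as.integer(qc$n_used),
    note = note,
    .kind = kind
  )
}

#' Analyse one variant
#'
#' Runs the full per-SNP pipeline: dosage conversion, listwise deletion,
#' QC annotation, design construction, model fit and per-coefficient tests,
#' plus the overall likelihood-ratio test. One row is emitted per model
#' coefficient (named by the SNP id, the covariate, or `SNPx<covariate>`),
#' and Weibull fits add intercept and shape rows. Any per-variant failure
#' (no events, zero complete cases, monomorphic genotype, non-convergence)
#' yields a single row with `NA` statistics and a reason code in `note` —
#' a scan never aborts because one variant fails.
#'
#' Per-coefficient p-values are Wald tests for the Cox model and
#' single-degree-of-freedom score tests for the Weibull model (its intercept
#' and shape rows carry Wald p-values, as score tests against zero are not
#' association tests for those parameters).
#'
#' @param record One genotype record (one-row tibble or list).
#' @param phen Phenotype tibble from [read_sample()].
#' @param spec A [model_spec()].
#' @param control See [fit_control()].
#' @return A tibble of association rows (the `print_mode` filter applied).
#' @export
analyse_snp <- function(record, phen, spec, control = fit_control()) {
  rec <- as_record(record)
  finish <- function(rows) {
    rows <- switch(spec$print_mode,
      all = rows,
      onlysnp = rows[rows$.kind %in% c("snp", "failed"), , drop = FALSE],
      onlyint = rows[rows$.kind %in% c("interaction", "failed"), , drop = FALSE]
    )
    rows$.kind <- NULL
    rows
  }
  fail <- function(note, qc = NULL, dosage = NULL) {
    finish(assoc_row(rec$snp_id, "failed", rec, qc, dosage, note = note))
  }

  used_cov <- spec$covariates
  phen_used <- phen[c("time", "event", used_cov)]
  phen_missing <- Reduce(`|`, lapply(phen_used, is.na))

  dosage <- tryCatch(compute_dosage(rec, use = !phen_missing),
                     error = function(e) NULL)
  if (is.null(dosage)) {
    # no subject has both a usable genotype and complete phenotype data
    return(fail(if (any(phen_missing)) "no_complete_cases"
                else "no_usable_genotypes"))
  }
  aligned <- align_complete_cases(dosage, phen, used_cov)
  if (nrow(aligned$data) == 0L) return(fail("no_complete_cases", dosage = dosage))
  keep <- !dosage$missing & !phen_missing
  qc <- compute_qc(rec, use = keep)
  if (var(aligned$data$dosage) == 0) {
    return(fail("monomorphic", qc = qc, dosage = dosage))
  }
  if (sum(aligned$data$event) == 0) {
    return(fail("no_events", qc = qc, dosage = dosage))
  }

  design <- build_design(aligned$data$dosage, aligned$data, spec)
  terms <- names(design)
  fit_data <- dplyr::bind_cols(aligned$data[c("time", "event")], design)

  fit <- tryCatch(
    if (spec$method == "cox") {
      fit_cox(fit_data, terms = terms, control = control)
    } else {
      fit_weibull(fit_data, terms = terms, control = control)
    },
    error = function(e) NULL
  )
  if (is.null(fit)) return(fail("fit_error", qc = qc, dosage = dosage))
  if (!fit$converged) return(fail("not_converged", qc = qc, dosage = dosage))

  lrt <- lr_test(fit)
  kind_of <- function(tm) {
    if (tm == "SNP") "snp" else if (grepl("^SNPx", tm)) "interaction" else "covariate"
  }
  label_of <- function(tm) if (tm == "SNP") rec$snp_id else tm

  rows <- purrr::map_dfr(terms, function(tm) {
    w <- wald_test(fit, tm)
    p <- if (spec$method == "weibull") {
      score_test(fit_data, terms = terms, tested = tm, control = control)$p_value
    } else {
      w$p_value
    }
    assoc_row(
      label_of(tm), kind_of(tm), rec, qc, dosage,
      coefficient = w$estimate,
      hazard_ratio = exp(w$estimate),
      standard_error = w$std_error,
      ci_low = w$ci_low, ci_high = w$ci_high,
      p_value = p,
      lrt_statistic = lrt$statistic, lrt_p = lrt$p_value
    )
  })
  if (spec$method == "weibull") {
    wi <- wald_test(fit, "(Intercept)")
    ws <- wald_test(fit, "log(shape)")
    extra <- dplyr::bind_rows(
      assoc_row("intercept", "model", rec, qc, dosage,
                coefficient = wi$estimate, hazard_ratio = exp(wi$estimate),
                standard_error = wi$std_error, p_value = wi$p_value,
                lrt_statistic = lrt$statistic, lrt_p = lrt$p_value),
      assoc_row("shape", "model", rec, qc, dosage,
                coefficient = fit$shape,
                standard_error = fit$shape * ws$std_error,
                p_value = ws$p_value,
                lrt_statistic = lrt$statistic, lrt_p = lrt$p_value)
    )
    rows <- dplyr::bind_rows(rows, extra)
  }
  finish(rows)
}

assoc_header <- c(
  "variable", "rs_id", "chr", "pos", "effect_allele", "noneffect_allele",
  "coef", "HR", "SE", "ci_low", "ci_high", "p", "lrt_stat", "lrt_p",
  "EAF", "MAF", "info", "n", "note"
)

fmt_num <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.6g", x))
}
fmt_p <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.5e", x))
}

format_assoc_rows <- function(rows) {
  if (nrow(rows) == 0L) return(character(0))
  paste(
    rows$variable, rows$rs_id,
    ifelse(is.na(rows$chromosome), "NA", rows$chromosome),
    ifelse(is.na(rows$position), "NA", as.character(rows$position)),
    rows$effect_allele, rows$noneffect_allele,
    fmt_num(rows$coefficient), fmt_num(rows$hazard_ratio),
    fmt_num(rows$standard_error),
    fmt_num(rows$ci_low), fmt_num(rows$ci_high),
    fmt_p(rows$p_value),
    fmt_num(rows$lrt_statistic), fmt_p(rows$lrt_p),
    fmt_num(rows$eaf), fmt_num(rows$maf), fmt_num(rows$info),
    ifelse(is.na(rows$n_used), "NA", as.character(rows$n_used)),
    ifelse(rows$note == "", ".", rows$note),
    sep = "\t"
  )
}

#' Write association rows to a tab-delimited text file
#'
#' Floating-point values are written with six significant digits, p-values
#' in scientific notation, missing values as `NA`; the header row names
#' every column.
#'
#' @param rows Association tibble as produced by [analyse_snp()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_assoc <- function(rows, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste(assoc_header, collapse = "\t"), con)
  writeLines(format_assoc_rows(rows), con)
  invisible(path)
}

#' Read an association output file back into a tibble
#'
#' @param path File written by [write_assoc()] or [run_scan()].
#' @return A tibble with one row per output line.
#' @export
read_assoc <- function(path) {
  tibble::as_tibble(utils::read.delim(path, na.strings = "NA",
                                      colClasses = c(chr = "character")))
}

#' Run a per-variant association scan
#'
#' Streams the genotype source one variant at a time — memory use is
#' independent of the number of variants for GEN input — analyses each
#' variant with [analyse_snp()], and writes rows to `output` in input
#' order. Splitting the line range across jobs and concatenating the
#' outputs reproduces a single full run line for line, which is the
#' batching contract for parallel cluster use.
#'
#' @param genotypes Path to a GEN (`.gen`/`.impute`, optionally
#'   compressed) or VCF (`.vcf`/`.vcf.gz`) file, or a genotype tibble from
#'   [read_gen()] / [read_vcf()] / [simulate_genotypes()].
#' @param phen Phenotype tibble from [read_sample()].
#' @param spec A [model_spec()].
#' @param output Output file path.
#' @param chromosome Chromosome label for GEN input.
#' @param line_start,line_stop 0-based inclusive line range (GEN/VCF paths).
#' @param bp_start,bp_stop Optional base-pair window.
#' @param compression Passed to [open_genotype_stream()] for GEN paths.
#' @param control See [fit_control()].
#' @return A one-row tibble: `n_snps`, `n_analysed`, `n_failed`, `output`.
#' @export
run_scan <- function(genotypes, phen, spec, output,
                     chromosome = NA_character_,
                     line_start = 0L, line_stop = NULL,
                     bp_start = NULL, bp_stop = NULL,
                     compression = "auto", control = fit_control()) {
  con <- tryCatch(file(output, open = "wt"),
    error = function(e) stop_data(paste0("cannot open output file: ", output))
  )
  on.exit(close(con))
  writeLines(paste(assoc_header, collapse = "\t"), con)
  n_snps <- 0L
  n_failed <- 0L
  emit <- function(rec) {
    n_snps <<- n_snps + 1L
    rows <- analyse_snp(rec, phen, spec, control = control)
    if (any(rows$note != "")) n_failed <<- n_failed + 1L
    writeLines(format_assoc_rows(rows), con)
  }
  if (is.character(genotypes)) {
    if (grepl("\\.vcf(\\.gz)?$", genotypes)) {
      recs <- read_vcf(genotypes, line_start = line_start,
                       line_stop = line_stop,
                       bp_start = bp_start, bp_stop = bp_stop)
      for (i in seq_len(nrow(recs))) emit(as_record(recs[i, ]))
    } else {
      stream_gen_records(
        genotypes, emit, chromosome = chromosome, n_subjects = nrow(phen),
        line_start = line_start, line_stop = line_stop,
        bp_start = bp_start, bp_stop = bp_stop, compression = compression
      )
    }
  } else {
    recs <- genotypes
    idx <- seq_len(nrow(recs)) - 1L
    keep <- idx >= line_start
    if (!is.null(line_stop)) keep <- keep & idx <= line_stop
    if (!is.null(bp_start)) keep <- keep & recs$position >= bp_start
    if (!is.null(bp_stop)) keep <- keep & recs$position <= bp_stop
    for (i in which(keep)) emit(as_record(recs[i, ]))
  }
  tibble::tibble(
    n_snps = n_snps,
    n_analysed = n_snps - n_failed,
    n_failed = n_failed,
    output = output
  )
}
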