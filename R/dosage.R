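# Probability-triple hygiene. IMPUTE-style output can carry triples whose
# sum falls short of 1 when imputation is uncertain. Triples with a sum
# >= 0.9 are renormalised to sum to one (this also covers mild overshoot);
# a sum below 0.9 marks the subject as missing at that variant, so dosages
# always land in [0, 2] without discarding the whole variant.
normalise_probs <- function(probs) {
  if (any(probs < 0, na.rm = TRUE)) {
    stop_data("negative genotype probability encountered")
  }
  s <- rowSums(probs)
  missing <- is.na(s) | s < 0.9
  keep <- which(!missing)
  probs[keep, ] <- probs[keep, , drop = FALSE] / s[keep]
  list(probs = probs, missing = missing)
}

#' Convert one genotype record to an additive allele dosage
#'
#' The dosage is the expected count of the effect allele under an additive
#' model, `S_i = p_i1 + 2 p_i2`, computed against `allele_b`. If the
#' resulting allele frequency `mean(S)/2` exceeds 0.5 among the subjects in
#' `use`, the vector is flipped (`S' = 2 - S`) and the allele labels are
#' swapped, so the effect allele is always the empirical minor allele
#' (frequency exactly 0.5 is left unflipped). Records from dosage-only VCF
#' input pass through unchanged apart from the flip rule.
#'
#' @param record One genotype record: a one-row tibble from [read_gen()] /
#'   [read_vcf()], or an equivalent named list.
#' @param use Optional logical vector marking the subjects whose data enter
#'   the analysis; the flip decision and reported frequency are computed on
#'   these subjects (default: all subjects with usable genotypes). This is
#'   what ties the reported allele to the analysed sample after listwise
#'   deletion.
#' @param flip If `FALSE`, never flip (keep `allele_b` as the effect allele).
#' @return A list with `values` (numeric dosages, `NA` where the subject's
#'   genotype is missing), `missing`, `effect_allele`, `noneffect_allele`,
#'   `flipped` and `theta` (effect-allele frequency among `use` subjects).
#' @export
compute_dosage <- function(record, use = NULL, flip = TRUE) {
  rec <- as_record(record)
  if (rec$source == "dosages") {
    values <- as.numeric(rec$probs)
    missing <- is.na(values)
  } else {
    np <- normalise_probs(rec$probs)
    missing <- np$missing
    values <- np$probs[, 2L] + 2 * np$probs[, 3L]
    values[missing] <- NA_real_
  }
  if (is.null(use)) use <- !missing
  use <- use & !missing
  if (!any(use)) stop_data(sprintf("no usable genotypes for %s", rec$snp_id))
  theta <- mean(values[use]) / 2
  flipped <- isTRUE(flip) && theta > 0.5
  effect <- rec$allele_b
  noneffect <- rec$allele_a
  if (flipped) {
    values <- 2 - values
    theta <- 1 - theta
    effect <- rec$allele_a
    noneffect <- rec$allele_b
  }
  list(
    values = values, missing = missing,
    effect_allele = effect, noneffect_allele = noneffect,
    flipped = flipped, theta = theta
  )
}

# Accept a one-row tibble or a plain record list.
as_record <- function(record) {
  if (is.data.frame(record)) {
    stopifnot(nrow(record) == 1L)
    record <- lapply(record, function(col) if (is.list(col)) col[[1L]] else col)
  }
  record
}

#' Per-variant quality-control summary
#'
#' Computes the effect-allele and minor-allele frequencies and the IMPUTE
#' info measure of imputation quality over the subjects entering the
#' analysis. With `e_i = p_i1 + 2 p_i2`, `f_i = p_i1 + 4 p_i2` and
#' `theta = sum(e_i) / 2N`, the info score is
#' `1 - sum(f_i - e_i^2) / (2 N theta (1 - theta))`; it equals 1 when every
#' genotype is certain (and for monomorphic variants, by convention) and
#' can fall below 0 for very poorly imputed variants — it is reported as
#' computed, not clamped. Following the convention that the effect allele
#' frequency is the frequency of the most common allele, `eaf = 1 - maf`.
#'
#' @param record One genotype record (see [compute_dosage()]).
#' @param use Optional logical vector of subjects entering the analysis.
#' @return A one-row tibble with `eaf`, `maf`, `info`, `n_used`. `info` is
#'   `NA` for dosage-only records (the triple-level variance is unknown).
#' @export
compute_qc <- function(record, use = NULL) {
  rec <- as_record(record)
  if (rec$source == "dosages") {
    values <- as.numeric(rec$probs)
    missing <- is.na(values)
    if (is.null(use)) use <- !missing
    use <- use & !missing
    if (!any(use)) stop_data(sprintf("no usable genotypes for %s", rec$snp_id))
    theta <- mean(values[use]) / 2
    info <- NA_real_
  } else {
    np <- normalise_probs(rec$probs)
    if (is.null(use)) use <- !np$missing
    use <- use & !np$missing
    if (!any(use)) stop_data(sprintf("no usable genotypes for %s", rec$snp_id))
    p <- np$probs[use, , drop = FALSE]
    e <- p[, 2L] + 2 * p[, 3L]
    f <- p[, 2L] + 4 * p[, 3L]
    n <- nrow(p)
    theta <- sum(e) / (2 * n)
    info <- if (theta <= 0 || theta >= 1) {
      1
    } else {
      1 - sum(f - e^2) / (2 * n * theta * (1 - theta))
    }
  }
  tibble::tibble(
    eaf = max(theta, 1 - theta),
    maf = min(theta, 1 - theta),
    info = info,
    n_used = sum(use)
  )
}

#' Align genotype and phenotype data by listwise deletion
#'
#' Subjects with a missing survival time, censoring indicator, any covariate
#' used in the model, or a missing genotype at this variant are removed; the
#' order of the survivors is preserved.
#'
#' @param dosage A dosage list from [compute_dosage()] (or any list with
#'   `values` and `missing` of the right length).
#' @param phen Phenotype tibble from [read_sample()].
#' @param covariates Covariate columns used in the model; only these count
#'   towards missingness.
#' @return A list with `data` (tibble: `dosage`, `time`, `event`, covariate
#'   columns; complete rows only) and `dropped` (subject ids removed).
#' @export
align_complete_cases <- function(dosage, phen, covariates = character()) {
  n <- nrow(phen)
  if (length(dosage$values) != n) {
    stop_data(sprintf(
      "genotype file has %d subjects but sample file has %d",
      length(dosage$values), n
    ))
  }
  used <- phen[c("time", "event", covariates)]
  phen_missing <- Reduce(`|`, lapply(used, is.na))
  keep <- !phen_missing & !dosage$missing
  data <- tibble::tibble(
    dosage = dosage$values[keep],
    time = phen$time[keep],
    event = phen$event[keep]
  )
  for (cv in covariates) data[[cv]] <- phen[[cv]][keep]
  list(data = data, dropped = phen$subject_id[!keep])
}
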