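#' Define a simulation scenario
#'
#' Describes one synthetic cohort: independent biallelic SNPs, a balanced
#' 1:1 binary treatment, and survival times generated from a Weibull
#' baseline under either a proportional-hazards or an accelerated-failure-
#' time model with SNP, treatment and SNP-treatment interaction effects,
#' with random uniform censoring calibrated to a target censored fraction.
#' The defaults mirror a typical single-replicate pharmacogenetic study:
#' 1000 patients, a causal SNP of minor-allele frequency 0.3 with hazard
#' ratio 2 per allele, and roughly 20% censoring.
#'
#' @param n_subjects Number of subjects.
#' @param n_snps Number of independent SNPs.
#' @param maf_range Interval from which non-causal minor-allele frequencies
#'   are drawn uniformly.
#' @param causal_index 1-based index of the causal SNP.
#' @param causal_maf Minor-allele frequency of the causal SNP.
#' @param model `"ph"` (proportional hazards) or `"aft"` (accelerated
#'   failure time). Effects are on the log-hazard scale for `"ph"` and the
#'   log-time scale for `"aft"`.
#' @param beta_snp,beta_treatment,beta_interaction Effect sizes.
#' @param baseline_shape,baseline_scale Weibull baseline parameters (shape
#'   1 gives exponential event times with mean `baseline_scale` under the
#'   null).
#' @param censor_fraction Target fraction of censored subjects (0 disables
#'   censoring).
#' @param imputation_noise Weight in `[0, 1)` with which each subject's
#'   one-hot genotype triple is mixed with a random triple, emulating
#'   imputation uncertainty (0 gives hard calls with info = 1).
#' @param seed Integer seed; every simulation derived from a scenario is
#'   deterministic given it.
#' @return A `survscan_scenario` list.
#' @export
sim_scenario <- function(n_subjects = 1000L, n_snps = 100L,
                         maf_range = c(0.05, 0.5),
                         causal_index = 1L, causal_maf = 0.3,
                         model = c("ph", "aft"),
                         beta_snp = log(2), beta_treatment = 0,
                         beta_interaction = 0,
                         baseline_shape = 1, baseline_scale = 5,
                         censor_fraction = 0.2,
                         imputation_noise = 0, seed = 1L) {
  model <- match.arg(model)
  stopifnot(
    n_subjects >= 2L, n_snps >= 1L,
    causal_index >= 1L, causal_index <= n_snps,
    causal_maf > 0, causal_maf <= 0.5,
    maf_range[[1L]] > 0, maf_range[[2L]] <= 0.5,
    baseline_shape > 0, baseline_scale > 0,
    censor_fraction >= 0, censor_fraction < 1,
    imputation_noise >= 0, imputation_noise < 1
  )
  structure(
    list(
      n_subjects = as.integer(n_subjects), n_snps = as.integer(n_snps),
      maf_range = maf_range, causal_index = as.integer(causal_index),
      causal_maf = causal_maf, model = model,
      beta_snp = beta_snp, beta_treatment = beta_treatment,
      beta_interaction = beta_interaction,
      baseline_shape = baseline_shape, baseline_scale = baseline_scale,
      censor_fraction = censor_fraction,
      imputation_noise = imputation_noise, seed = as.integer(seed)
    ),
    class = "survscan_scenario"
  )
}

#' Simulate genotype probability records
#'
#' Draws hard genotypes `Binomial(2, freq)` independently per subject and
#' SNP (allele frequencies uniform over `maf_range`, except the causal SNP
#' which uses `causal_maf`), then, if `imputation_noise > 0`, mixes each
#' one-hot triple with a random normalised triple at that weight to emulate
#' imputed-genotype uncertainty. The underlying hard-call dosage matrix is
#' attached as the `"hard_calls"` attribute (subjects x SNPs) so survival
#' outcomes can be generated from the true genotypes.
#'
#' @param scenario A [sim_scenario()].
#' @return A genotype tibble in the [read_gen()] shape with the causal SNP
#'   at `scenario$causal_index`; deterministic given `scenario$seed`.
#' @export
simulate_genotypes <- function(scenario) {
  stopifnot(inherits(scenario, "survscan_scenario"))
  n <- scenario$n_subjects
  m <- scenario$n_snps
  withr::with_seed(scenario$seed, {
    freqs <- runif(m, scenario$maf_range[[1L]], scenario$maf_range[[2L]])
    freqs[scenario$causal_index] <- scenario$causal_maf
    hard <- matrix(0L, nrow = n, ncol = m)
    probs <- vector("list", m)
    w <- scenario$imputation_noise
    for (j in seq_len(m)) {
      g <- rbinom(n, 2L, freqs[[j]])
      hard[, j] <- g
      onehot <- matrix(0, nrow = n, ncol = 3L)
      onehot[cbind(seq_len(n), g + 1L)] <- 1
      if (w > 0) {
        rnd <- matrix(runif(3L * n), nrow = n, ncol = 3L)
        rnd <- rnd / rowSums(rnd)
        onehot <- (1 - w) * onehot + w * rnd
      }
      probs[[j]] <- onehot
    }
    out <- tibble::tibble(
      snp_id = sprintf("snp%05d", seq_len(m)),
      rs_id = sprintf("rs%05d", seq_len(m)),
      chromosome = "1",
      position = as.integer(seq_len(m) * 1000L),
      allele_a = "A",
      allele_b = "B",
      probs = probs,
      source = "probabilities"
    )
    attr(out, "hard_calls") <- hard
    attr(out, "freqs") <- freqs
    out
  })
}

#' Simulate a balanced binary treatment assignment
#'
#' Exactly 1:1 allocation by random permutation: `floor(n/2)` subjects get
#' placebo (0), the rest active treatment (1); with odd `n` the groups
#' differ by one.
#'
#' @param n_subjects Number of subjects.
#' @param seed Integer seed.
#' @return Integer 0/1 vector of length `n_subjects`.
#' @export
simulate_treatment <- function(n_subjects, seed = 1L) {
  withr::with_seed(seed, {
    base <- c(rep(0L, n_subjects %/% 2L),
              rep(1L, n_subjects - n_subjects %/% 2L))
    sample(base)
  })
}

#' Simulate survival times and censoring indicators
#'
#' The linear predictor is `eta = beta_snp * S + beta_treatment * Z +
#' beta_interaction * S * Z`. Under `model = "ph"` times come from a Weibull
#' baseline by inverse-transform sampling,
#' `T = scale * (-log U / exp(eta))^(1/shape)`, so effects are log hazard
#' ratios. Under `model = "aft"` effects act on log time,
#' `log T = log(scale) - eta + G / shape` with `G = log(-log U)` standard
#' Gumbel (minimum); the two models coincide when
#' `beta_aft = beta_ph / shape`. Censoring times are uniform on
#' `[0, c_max]` with `c_max` solved numerically on the simulated event-time
#' distribution so the realised censored fraction approximates
#' `censor_fraction`.
#'
#' @param dosage Dosage (allele count) at the causal SNP.
#' @param treatment 0/1 treatment vector of the same length.
#' @param scenario A [sim_scenario()].
#' @param seed Integer seed (defaults to `scenario$seed + 1`).
#' @return A tibble with `time` (observed, possibly censored) and `event`
#'   (1 = event observed, 0 = censored).
#' @export
simulate_survival <- function(dosage, treatment, scenario,
                              seed = scenario$seed + 1L) {
  stopifnot(length(dosage) == length(treatment))
  n <- length(dosage)
  eta <- scenario$beta_snp * dosage +
    scenario$beta_treatment * treatment +
    scenario$beta_interaction * dosage * treatment
  shp <- scenario$baseline_shape
  scl <- scenario$baseline_scale
  withr::with_seed(seed, {
    u <- runif(n)
    t_event <- if (scenario$model == "ph") {
      scl * (-log(u) / exp(eta))^(1 / shp)
    } else {
      exp(log(scl) - eta + log(-log(u)) / shp)
    }
    if (scenario$censor_fraction <= 0) {
      return(tibble::tibble(time = t_event, event = 1))
    }
    # E[censored] for C ~ U(0, c) is mean(pmin(T/c, 1)); solve for c
    frac <- function(c) mean(pmin(t_event / c, 1)) - scenario$censor_fraction
    hi <- max(t_event) / scenario$censor_fraction + 1
    c_max <- uniroot(frac, lower = min(t_event) * 1e-9, upper = hi,
                     tol = 1e-10)$root
    cens <- runif(n, 0, c_max)
    tibble::tibble(
      time = pmin(t_event, cens),
      event = as.numeric(t_event <= cens)
    )
  })
}

#' Write a complete simulated fixture to disk
#'
#' Generates genotypes, treatment and survival outcomes for a scenario and
#' writes a GEN file, an Oxford-style sample file (columns `ID`,
#' `event_times`, `censoring`, `treatment`, with a type-code row) and a
#' plain-text truth sidecar recording the scenario parameters. The files
#' are directly consumable by [run_scan()] and the command-line driver.
#'
#' @param scenario A [sim_scenario()].
#' @param dir Output directory (created if needed).
#' @param basename File stem for the three outputs.
#' @return A list with `gen_path`, `sample_path`, `truth_path`, the
#'   genotype tibble (`genotypes`) and the phenotype tibble (`sample`).
#' @export
write_fixture <- function(scenario, dir, basename = "simdata") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  geno <- simulate_genotypes(scenario)
  hard <- attr(geno, "hard_calls")
  # distinct seed per component so genotypes, treatment and survival come
  # from independent streams
  treatment <- simulate_treatment(scenario$n_subjects,
                                  seed = scenario$seed + 2L)
  surv <- simulate_survival(hard[, scenario$causal_index], treatment, scenario)

  gen_path <- file.path(dir, paste0(basename, ".gen"))
  sample_path <- file.path(dir, paste0(basename, ".sample"))
  truth_path <- file.path(dir, paste0(basename, ".truth"))
  write_gen(geno, gen_path)

  ids <- sprintf("id%04d", seq_len(scenario$n_subjects))
  lines <- c(
    "ID event_times censoring treatment",
    "0 P B B",
    paste(ids, format(surv$time, digits = 10, trim = TRUE, scientific = FALSE),
          surv$event, treatment)
  )
  writeLines(lines, sample_path)

  truth <- unclass(scenario)
  truth$maf_range <- paste(truth$maf_range, collapse = ",")
  writeLines(paste0(names(truth), "=", vapply(truth, as.character, "")),
             truth_path)

  sample_tbl <- tibble::tibble(
    subject_id = ids, time = surv$time, event = surv$event,
    treatment = as.numeric(treatment),
    missing = FALSE
  )
  list(gen_path = gen_path, sample_path = sample_path,
       truth_path = truth_path, genotypes = geno, sample = sample_tbl)
}
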