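#' Open a genotype file as a decoded text connection
#'
#' Opens a plain, gzip- or zip-compressed genotype file for streaming,
#' line-by-line reads. Compression is sniffed from the leading magic bytes
#' (gzip `1f 8b`, zip `50 4b`), falling back to the file extension, so a
#' `.gen` file that is secretly gzipped still opens correctly.
#'
#' @param path Path to the genotype file.
#' @param compression One of `"auto"`, `"none"`, `"gzip"`, `"zip"`.
#' @return An open read-mode text connection. The caller must `close()` it.
#' @export
open_genotype_stream <- function(path,
                                 compression = c("auto", "none", "gzip", "zip")) {
  compression <- match.arg(compression)
  if (!file.exists(path)) {
    stop_data(paste0("genotype file not found: ", path))
  }
  if (compression == "auto") {
    magic <- readBin(path, "raw", n = 2L)
    compression <- if (length(magic) >= 2L && magic[1] == as.raw(0x1f) &&
                       magic[2] == as.raw(0x8b)) {
      "gzip"
    } else if (length(magic) >= 2L && magic[1] == as.raw(0x50) &&
               magic[2] == as.raw(0x4b)) {
      "zip"
    } else if (grepl("\\.gz$", path)) {
      "gzip"
    } else if (grepl("\\.zip$", path)) {
      "zip"
    } else {
      "none"
    }
  }
  con <- switch(compression,
    none = file(path, open = "rt"),
    gzip = gzfile(path, open = "rt"),
    zip = {
      entries <- tryCatch(unzip(path, list = TRUE),
        error = function(e) stop_data(paste0("corrupt zip archive: ", path))
      )
      if (nrow(entries) == 0L) {
        stop_data(paste0("empty zip archive: ", path))
      }
      z <- unz(path, entries$Name[[1L]])
      open(z, "rt")
      z
    }
  )
  con
}

# Parse one GEN line into a genotype record (list). GEN dialect: 5 leading
# columns (snp_id, rs_id, position, allele_a, allele_b) then 3 probabilities
# per subject; the chromosome label is supplied by the caller.
parse_gen_line <- function(line, line_number, n_subjects = NULL,
                           chromosome = NA_character_) {
  fields <- strsplit(trimws(line), "[ \t]+")[[1L]]
  nf <- length(fields)
  if (!is.null(n_subjects)) {
    if (nf != 5L + 3L * n_subjects) {
      stop_data(sprintf(
        "GEN line %d has %d fields; expected %d (5 + 3 x %d subjects)",
        line_number, nf, 5L + 3L * n_subjects, n_subjects
      ))
    }
  } else if (nf < 8L || (nf - 5L) %% 3L != 0L) {
    stop_data(sprintf(
      "GEN line %d has %d fields; expected 5 metadata columns plus 3 probabilities per subject",
      line_number, nf
    ))
  }
  n <- (nf - 5L) %/% 3L
  probs <- suppressWarnings(as.numeric(fields[-(1:5)]))
  if (anyNA(probs)) {
    stop_data(sprintf("non-numeric genotype probability on GEN line %d", line_number))
  }
  pos <- suppressWarnings(as.integer(fields[[3L]]))
  if (is.na(pos) || pos < 1L) {
    stop_data(sprintf("invalid base-pair position on GEN line %d: '%s'",
                      line_number, fields[[3L]]))
  }
  list(
    snp_id = fields[[1L]], rs_id = fields[[2L]],
    chromosome = chromosome, position = pos,
    allele_a = fields[[4L]], allele_b = fields[[5L]],
    probs = matrix(probs, nrow = n, ncol = 3L, byrow = TRUE),
    source = "probabilities"
  )
}

# Stream GEN records through a callback. line_start/line_stop are 0-based
# inclusive line indices; bp_start/bp_stop (1-based inclusive) are applied
# after the line-range selection. callback(record) is invoked per kept record.
stream_gen_records <- function(path, callback, chromosome = NA_character_,
                               n_subjects = NULL, line_start = 0L,
                               line_stop = NULL, bp_start = NULL,
                               bp_stop = NULL, compression = "auto",
                               chunk_size = 256L) {
  stopifnot(line_start >= 0L)
  if (!is.null(line_stop) && line_stop < line_start) {
    stop_usage("line_stop must be >= line_start")
  }
  con <- open_genotype_stream(path, compression)
  on.exit(close(con), add = TRUE)
  idx <- -1L
  n_seen <- 0L
  repeat {
    lines <- readLines(con, n = chunk_size)
    if (length(lines) == 0L) break
    for (line in lines) {
      idx <- idx + 1L
      if (idx < line_start) next
      if (!is.null(line_stop) && idx > line_stop) return(invisible(n_seen))
      if (!nzchar(trimws(line))) next
      rec <- parse_gen_line(line, idx + 1L, n_subjects, chromosome)
      if (is.null(n_subjects)) n_subjects <- nrow(rec$probs)
      if (!is.null(bp_start) && rec$position < bp_start) next
      if (!is.null(bp_stop) && rec$position > bp_stop) next
      n_seen <- n_seen + 1L
      callback(rec)
    }
  }
  invisible(n_seen)
}

#' Read an Oxford GEN genotype file into a tibble
#'
#' Each row is one biallelic variant; the per-subject genotype probability
#' triples are held in the `probs` list-column as an n-subjects x 3 matrix
#' (probabilities of carrying 0, 1 or 2 copies of `allele_b`).
#'
#' @param path GEN file (`.gen`/`.impute`), optionally gzip- or zip-compressed.
#' @param chromosome Chromosome label attached to every record (GEN files do
#'   not carry one in this dialect).
#' @param n_subjects Expected subject count; inferred from the first line if
#'   `NULL`, and enforced on every line once known.
#' @param line_start,line_stop 0-based inclusive line range to read
#'   (`line_stop = NULL` reads to the end). This is the batching mechanism
#'   used to split a large scan across jobs.
#' @param bp_start,bp_stop Optional 1-based inclusive base-pair window,
#'   applied after the line range.
#' @param compression Passed to [open_genotype_stream()].
#' @return A tibble with columns `snp_id`, `rs_id`, `chromosome`, `position`,
#'   `allele_a`, `allele_b`, `probs` (list), `source`.
#' @export
read_gen <- function(path, chromosome = NA_character_, n_subjects = NULL,
                     line_start = 0L, line_stop = NULL,
                     bp_start = NULL, bp_stop = NULL, compression = "auto") {
  recs <- list()
  stream_gen_records(
    path, function(rec) recs[[length(recs) + 1L]] <<- rec,
    chromosome = chromosome, n_subjects = n_subjects,
    line_start = line_start, line_stop = line_stop,
    bp_start = bp_start, bp_stop = bp_stop, compression = compression
  )
  records_to_tibble(recs)
}

records_to_tibble <- function(recs) {
  tibble::tibble(
    snp_id = purrr::map_chr(recs, "snp_id"),
    rs_id = purrr::map_chr(recs, "rs_id"),
    chromosome = purrr::map_chr(recs, "chromosome"),
    position = purrr::map_int(recs, "position"),
    allele_a = purrr::map_chr(recs, "allele_a"),
    allele_b = purrr::map_chr(recs, "allele_b"),
    probs = purrr::map(recs, "probs"),
    source = purrr::map_chr(recs, "source")
  )
}

#' Write genotype records to a GEN file
#'
#' Inverse of [read_gen()]: probabilities are written with six decimal
#' places, one variant per line. Records whose `source` is `"dosages"` or
#' `"hard_calls"` are written as the equivalent probability triples.
#'
#' @param records Tibble as returned by [read_gen()] or
#'   [simulate_genotypes()].
#' @param path Output path (plain text; compress externally if needed).
#' @return `path`, invisibly.
#' @export
write_gen <- function(records, path) {
  lines <- purrr::pmap_chr(
    records[c("snp_id", "rs_id", "position", "allele_a", "allele_b", "probs")],
    function(snp_id, rs_id, position, allele_a, allele_b, probs) {
      paste(snp_id, rs_id, position, allele_a, allele_b,
        paste(formatC(as.vector(t(probs)), digits = 6L, format = "f"),
              collapse = " "),
        sep = " "
      )
    }
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a VCF file into genotype-record form
#'
#' Extracts per-subject genotype evidence with priority GP > DS > GT at each
#' biallelic site: GP triples become probability triples for 0/1/2 copies of
#' the ALT allele, DS values become a dosage record, and GT hard calls become
#' degenerate 0/1 probability triples. Multi-allelic sites are skipped with a
#' warning, as are sites carrying none of the three fields. Per-subject
#' missing entries (`./.` or `.`) are marked missing for that variant.
#'
#' @param path VCF 4.x file (plain or bgzip/gzip compressed).
#' @param line_start,line_stop 0-based inclusive range over the file's
#'   variant records (same convention as [read_gen()]).
#' @param bp_start,bp_stop Optional 1-based inclusive POS window.
#' @return A tibble in the same shape as [read_gen()]; dosage records carry a
#'   numeric vector (not a matrix) in `probs` and `source = "dosages"`.
#' @export
read_vcf <- function(path, line_start = 0L, line_stop = NULL,
                     bp_start = NULL, bp_stop = NULL) {
  if (!file.exists(path)) stop_data(paste0("VCF file not found: ", path))
  vcf <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) stop_data(paste0("unreadable VCF file: ", path))
  )
  fix <- vcf@fix
  gt <- vcf@gt
  n_site <- nrow(fix)
  if (is.null(n_site) || n_site == 0L) return(records_to_tibble(list()))
  samples <- colnames(gt)[-1L]
  n <- length(samples)

  keep <- seq_len(n_site) - 1L >= line_start
  if (!is.null(line_stop)) keep <- keep & (seq_len(n_site) - 1L <= line_stop)
  pos <- as.integer(fix[, "POS"])
  if (!is.null(bp_start)) keep <- keep & pos >= bp_start
  if (!is.null(bp_stop)) keep <- keep & pos <= bp_stop

  recs <- list()
  for (i in which(keep)) {
    alt <- fix[i, "ALT"]
    id <- fix[i, "ID"]
    if (is.na(id) || id == ".") id <- paste0(fix[i, "CHROM"], ":", pos[i])
    if (is.na(alt) || grepl(",", alt)) {
      warn(sprintf("skipping multi-allelic site %s at %s:%d", id,
                   fix[i, "CHROM"], pos[i]))
      next
    }
    keys <- strsplit(gt[i, 1L], ":", fixed = TRUE)[[1L]]
    cells <- strsplit(unname(gt[i, -1L]), ":", fixed = TRUE)
    get_field <- function(key) {
      j <- match(key, keys)
      if (is.na(j)) return(NULL)
      vapply(cells, function(x) if (length(x) >= j) x[[j]] else NA_character_,
             character(1))
    }
    gp <- get_field("GP")
    ds <- get_field("DS")
    gtf <- get_field("GT")
    rec <- NULL
    if (!is.null(gp) && any(!is.na(gp) & gp != ".")) {
      probs <- matrix(NA_real_, nrow = n, ncol = 3L)
      for (s in seq_len(n)) {
        if (is.na(gp[s]) || gp[s] == ".") next
        v <- suppressWarnings(as.numeric(strsplit(gp[s], ",", fixed = TRUE)[[1L]]))
        if (length(v) == 3L && !anyNA(v)) probs[s, ] <- v
      }
      rec <- list(probs = probs, source = "probabilities")
    } else if (!is.null(ds) && any(!is.na(ds) & ds != ".")) {
      v <- suppressWarnings(as.numeric(ifelse(ds == ".", NA, ds)))
      rec <- list(probs = v, source = "dosages")
    } else if (!is.null(gtf)) {
      counts <- vapply(gtf, function(x) {
        if (is.na(x) || grepl("\\.", x)) return(NA_real_)
        alleles <- strsplit(x, "[/|]")[[1L]]
        sum(alleles == "1")
      }, numeric(1), USE.NAMES = FALSE)
      probs <- matrix(0, nrow = n, ncol = 3L)
      probs[is.na(counts), ] <- NA_real_
      ok <- which(!is.na(counts))
      probs[cbind(ok, counts[ok] + 1L)] <- 1
      rec <- list(probs = probs, source = "hard_calls")
    }
    if (is.null(rec)) {
      warn(sprintf("skipping site %s: no usable GP/DS/GT genotype field", id))
      next
    }
    recs[[length(recs) + 1L]] <- list(
      snp_id = id, rs_id = id, chromosome = as.character(fix[i, "CHROM"]),
      position = pos[i],
      allele_a = as.character(fix[i, "REF"]), allele_b = as.character(alt),
      probs = rec$probs, source = rec$source
    )
  }
  records_to_tibble(recs)
}

# Oxford sample-file type codes: second header row marking column roles.
is_type_row <- function(tokens) {
  length(tokens) > 0L && all(tokens %in% c("0", "D", "C", "B", "P"))
}

#' Read an Oxford-style sample file into a phenotype table
#'
#' The file is whitespace-delimited with a header row; an optional second
#' row of Oxford type codes (tokens drawn from `0 D C B P`) is detected and
#' skipped automatically. The literal string `NA` marks a missing value.
#' Subjects with a missing survival time, censoring indicator or any of the
#' requested covariates are flagged in `missing` (and later removed from
#' each per-SNP analysis, not from the table).
#'
#' @param path Sample file path.
#' @param time Column name of the time-to-event outcome.
#' @param censor Column name of the event/censoring indicator (1 = event
#'   observed, 0 = censored).
#' @param covariates Character vector of covariate column names used in the
#'   model (may be empty). Covariates must be numeric, continuous or 0/1
#'   binary; recode categorical factors to binary columns first.
#' @return A tibble with columns `subject_id`, `time`, `event`, one column
#'   per requested covariate, and a logical `missing` flag.
#' @export
read_sample <- function(path, time, censor, covariates = character()) {
  if (!file.exists(path)) stop_data(paste0("sample file not found: ", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) stop_data(paste0("sample file has no data rows: ", path))
  toks <- lapply(lines, function(l) strsplit(trimws(l), "[ \t]+")[[1L]])
  header <- toks[[1L]]
  if (anyDuplicated(header)) {
    stop_data(paste0("duplicate column names in sample file: ",
                     paste(header[duplicated(header)], collapse = ", ")))
  }
  body <- toks[-1L]
  if (length(body) > 0L && is_type_row(body[[1L]])) body <- body[-1L]

  wanted <- c(time, censor, covariates)
  missing_cols <- setdiff(wanted, header)
  if (length(missing_cols) > 0L) {
    stop_data(sprintf(
      "column(s) %s not found in sample file header; available columns: %s",
      paste(missing_cols, collapse = ", "), paste(header, collapse = ", ")
    ))
  }

  bad <- which(lengths(body) != length(header))
  if (length(bad) > 0L) {
    stop_data(sprintf("sample file row %d has %d fields; header has %d",
                      bad[[1L]], lengths(body)[bad[[1L]]], length(header)))
  }
  mat <- do.call(rbind, body)
  colnames(mat) <- header

  to_num <- function(col) {
    raw <- mat[, col]
    out <- suppressWarnings(as.numeric(ifelse(raw == "NA", NA, raw)))
    bad <- which(!is.na(raw) & raw != "NA" & is.na(out))
    if (length(bad) > 0L) {
      stop_data(sprintf(
        "column '%s' has non-numeric value '%s' (row %d); categorical covariates must be recoded as binary 0/1 columns",
        col, raw[bad[[1L]]], bad[[1L]]
      ))
    }
    out
  }
  t_val <- to_num(time)
  e_val <- to_num(censor)
  if (any(t_val < 0, na.rm = TRUE)) {
    stop_data(sprintf("column '%s' contains negative survival times", time))
  }
  if (any(!e_val %in% c(0, 1) & !is.na(e_val))) {
    stop_data(sprintf("column '%s' must be a 0/1 censoring indicator", censor))
  }
  out <- tibble::tibble(
    subject_id = mat[, 1L],
    time = t_val,
    event = e_val
  )
  for (cv in covariates) out[[cv]] <- to_num(cv)
  used <- out[c("time", "event", covariates)]
  out$missing <- Reduce(`|`, lapply(used, is.na))
  out
}
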