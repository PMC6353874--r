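#' Read a diagnosis-record table
#'
#' Tab-separated columns: participant_id, source, code, age (years, decimal
#' or integer-rounded).
#'
#' @param path file path.
#' @return data.frame of diagnosis records.
#' @export
read_diagnoses <- function(path) {
  d <- data.table::fread(path, sep = "\t", header = TRUE,
                         colClasses = list(character = c("participant_id",
                                                         "source", "code")))
  req <- c("participant_id", "source", "code", "age")
  if (!all(req %in% names(d)))
    stop("diagnosis file needs columns: ", paste(req, collapse = ", "))
  as.data.frame(d)
}

#' Read a covariate table
#'
#' Tab-separated; first column participant_id, remaining columns
#' covariates (numeric or categorical).
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_covariates <- function(path) {
  d <- data.table::fread(path, sep = "\t", header = TRUE,
                         colClasses = list(character = "participant_id"))
  if (!"participant_id" %in% names(d))
    stop("covariate file needs a participant_id column")
  as.data.frame(d)
}

#' Read a condition-code map
#'
#' Tab-separated columns: condition, source, code (one code per line).
#'
#' @param path file path.
#' @return a \code{\link{condition_map}}.
#' @export
read_condition_map <- function(path) {
  d <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE,
                                       colClasses = "character"))
  condition_map(d)
}

#' Read genotype dosages
#'
#' Two encodings are supported.  \code{"tsv"}: variants as rows with
#' metadata columns (id, chr, pos, ea, ra, and optional eaf, info) followed
#' by one column per participant; missing dosages as ".".  \code{"vcf"}: a
#' VCF with a per-sample DS (dosage) FORMAT field; EAF/INFO are taken from
#' the INFO column (keys EAF/AF and INFO/R2) when present.  In either case
#' EAF and info are recomputed from the dosages when absent (recomputed
#' info is capped at 1).  Sample order is reconciled against
#' \code{participants} when given; unknown or missing ids raise an error
#' naming them.
#'
#' @param path file path.
#' @param format \code{"tsv"} or \code{"vcf"}.
#' @param participants optional participant ids defining the column order
#'   of the returned panel.
#' @return a \code{\link{dosage_panel}}.
#' @export
read_dosages <- function(path, format = c("tsv", "vcf"),
                         participants = NULL) {
  format <- match.arg(format)
  if (format == "tsv") panel <- read_dosages_tsv(path)
  else panel <- read_dosages_vcf(path)
  if (!is.null(participants)) {
    have <- colnames(panel$dosages)
    missing_ids <- setdiff(participants, have)
    if (length(missing_ids))
      stop("dosage file lacks participants: ",
           paste(utils::head(missing_ids, 5), collapse = ", "),
           if (length(missing_ids) > 5) ", ...")
    panel$dosages <- panel$dosages[, participants, drop = FALSE]
  }
  panel
}

read_dosages_tsv <- function(path) {
  d <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE,
                                       na.strings = "."))
  meta_cols <- intersect(c("id", "chr", "pos", "ea", "ra", "eaf", "info"),
                         names(d))
  samp_cols <- setdiff(names(d), meta_cols)
  dos <- as.matrix(d[samp_cols])
  storage.mode(dos) <- "double"
  variants <- d[meta_cols]
  finalize_panel(variants, dos, samp_cols)
}

read_dosages_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  ds <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  if (is.null(ds) || all(is.na(ds)))
    stop("VCF has no per-sample DS (dosage) field")
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  info_eaf <- suppressWarnings(as.numeric(vcfR::extract.info(v, "EAF")))
  if (all(is.na(info_eaf)))
    info_eaf <- suppressWarnings(as.numeric(vcfR::extract.info(v, "AF")))
  info_r2 <- suppressWarnings(as.numeric(vcfR::extract.info(v, "INFO")))
  if (all(is.na(info_r2)))
    info_r2 <- suppressWarnings(as.numeric(vcfR::extract.info(v, "R2")))
  variants <- data.frame(
    id = fix$ID, chr = fix$CHROM, pos = as.integer(fix$POS),
    ea = fix$ALT, ra = fix$REF,
    eaf = info_eaf, info = info_r2, stringsAsFactors = FALSE
  )
  dos <- ds
  if (nrow(variants) == 0) dos <- matrix(numeric(), nrow = 0,
                                         ncol = ncol(ds))
  finalize_panel(variants, dos, colnames(ds))
}

finalize_panel <- function(variants, dos, sample_ids) {
  m <- nrow(variants)
  if (is.null(variants$eaf)) variants$eaf <- rep(NA_real_, m)
  if (is.null(variants$info)) variants$info <- rep(NA_real_, m)
  if (m > 0) {
    eaf_hat <- rowMeans(dos, na.rm = TRUE) / 2
    need <- is.na(variants$eaf)
    variants$eaf[need] <- eaf_hat[need]
    need <- is.na(variants$info)
    if (any(need)) {
      vv <- apply(dos[need, , drop = FALSE], 1, stats::var, na.rm = TRUE)
      denom <- 2 * variants$eaf[need] * (1 - variants$eaf[need])
      variants$info[need] <- pmin(1, ifelse(denom > 0, vv / denom, NA_real_))
    }
  }
  dosage_panel(variants, dos, participants = sample_ids)
}

#' Write GWAS summary statistics
#'
#' Tab-separated with header snp, chr, pos, ea, ra, eaf, info, n, beta, se,
#' z, p, qc; numeric columns keep full precision and round-trip losslessly
#' through \code{\link{read_summary_stats}}.  A p-value of exactly zero is
#' never written: it is replaced by the smallest representable positive
#' double, with a warning.
#'
#' @param stats_df summary statistics from \code{\link{run_gwas}}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_summary_stats <- function(stats_df, path) {
  if (any(!is.na(stats_df$p) & stats_df$p == 0)) {
    warning("p = 0 replaced by smallest representable positive value")
    stats_df$p[!is.na(stats_df$p) & stats_df$p == 0] <- .Machine$double.xmin
  }
  data.table::fwrite(stats_df, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

#' Read GWAS summary statistics
#'
#' @param path file written by \code{\link{write_summary_stats}}.
#' @return summary-statistics data.frame.
#' @export
read_summary_stats <- function(path) {
  d <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE))
  if ("qc" %in% names(d)) d$qc <- as.logical(d$qc)
  d
}

#' Write an incidence curve
#'
#' Tab-separated columns: age, n_h, n_d, rate, ci_low, ci_high.
#'
#' @param curve output of \code{\link{incidence_curve}}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_incidence_curve <- function(curve, path) {
  data.table::fwrite(curve[c("age", "n_h", "n_d", "rate",
                             "ci_low", "ci_high")],
                     path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

#' Write a simulated cohort to disk
#'
#' Emits the diagnosis TSV, covariate TSV, follow-up TSV, dosage TSV,
#' condition-map TSV and a key-value metadata file recording the seed and
#' generating parameters, into a directory.
#'
#' @param cohort output of \code{\link{simulate_cohort}}.
#' @param dir output directory (created if absent).
#' @return the directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  data.table::fwrite(cohort$diagnoses, file.path(dir, "diagnoses.tsv"),
                     sep = "\t", quote = FALSE)
  data.table::fwrite(cohort$covariates, file.path(dir, "covariates.tsv"),
                     sep = "\t", quote = FALSE)
  data.table::fwrite(cohort$followup, file.path(dir, "followup.tsv"),
                     sep = "\t", quote = FALSE)
  data.table::fwrite(as.data.frame(unclass(cohort$condition_map)),
                     file.path(dir, "condition_map.tsv"),
                     sep = "\t", quote = FALSE)
  pan <- cbind(cohort$panel$variants,
               as.data.frame(cohort$panel$dosages))
  data.table::fwrite(pan, file.path(dir, "dosages.tsv"),
                     sep = "\t", quote = FALSE, na = ".")
  tp <- cohort$true_params
  meta <- c(
    paste0("seed\t", tp$seed),
    paste0("condition\t", tp$conditions$name, "\th0=", tp$conditions$h0,
           "\tgamma=", tp$conditions$gamma),
    if (length(tp$covariate_effects))
      paste0("covariate_effect\t", names(tp$covariate_effects), "\t",
             tp$covariate_effects)
  )
  writeLines(meta, file.path(dir, "true_params.tsv"))
  invisible(dir)
}
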