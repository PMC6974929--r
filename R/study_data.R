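#' @name study_data
#' @title NONMEM-style study dataset input/output
#'
#' @description
#' Event-level datasets use the 16-column layout
#' `ID TIME DV WT EVID MDV AMT CMT BQL PREG LNPC HB AST ALT BIL EGA`:
#' comma-separated, `#`-prefixed comment lines skipped, `.` for missing
#' values. `DV` holds natural-log concentrations (log ng/mL); `CMT` is 1 for
#' the dose depot, 2 for artesunate and 3 for dihydroartemisinin; `BQL = 1`
#' marks observations censored below the analyte LLOQ (1.2 ng/mL artesunate,
#' 2.0 ng/mL dihydroartemisinin).
NULL

DATASET_COLUMNS <- c("ID", "TIME", "DV", "WT", "EVID", "MDV", "AMT", "CMT",
                     "BQL", "PREG", "LNPC", "HB", "AST", "ALT", "BIL", "EGA")

RECORD_COLS <- c("id", "time", "dv", "evid", "mdv", "amt", "cmt", "bql")
COVARIATE_COLS <- c("id", "wt", "preg", "lnpc", "hb", "ast", "alt", "bil", "ega")

#' Assemble a study dataset from records and covariates
#'
#' @param records Data frame of event records with columns
#'   `id, time, dv, evid, mdv, amt, cmt, bql` (`dv` on the natural-log
#'   ng/mL scale, `NA` where missing or masked).
#' @param covariates Data frame with one row per subject and columns
#'   `id, wt, preg, lnpc, hb, ast, alt, bil, ega`.
#' @param lloq_ars,lloq_dha Lower limits of quantification (ng/mL); the single
#'   source of truth used by the censored likelihood, the simulator and the
#'   BLQ summaries.
#' @return A validated `study_dataset` object.
#' @export
study_dataset <- function(records, covariates, lloq_ars = 1.2, lloq_dha = 2.0) {
  records <- as.data.frame(records)[, RECORD_COLS]
  covariates <- as.data.frame(covariates)[, COVARIATE_COLS]
  ds <- structure(list(records = records, covariates = covariates,
                       lloq_ars = lloq_ars, lloq_dha = lloq_dha),
                  class = "study_dataset")
  validate_dataset(ds)
  ds
}

#' Validate a study dataset against the event-record invariants
#'
#' Checks, reporting offending row numbers: doses (`evid = 1`) have positive
#' `amt`, `cmt = 1` and `mdv = 1`; observations have `cmt` 2 or 3; `cmt` lies
#' in `{1, 2, 3}`; times are non-negative and non-decreasing within subject;
#' every observation subject has at least one dose record; covariates exist
#' for every subject, with positive weight, `preg` in `{0, 1}` and
#' gestational age 0 for non-pregnant subjects and within 0-8 months.
#'
#' @param ds A `study_dataset`.
#' @return `ds`, invisibly; stops with an informative error otherwise.
#' @export
validate_dataset <- function(ds) {
  r <- ds$records
  cv <- ds$covariates
  bad <- function(cond, msg) {
    idx <- which(cond)
    if (length(idx))
      stop(msg, " (record row", if (length(idx) > 1) "s", " ",
           paste(head(idx, 5), collapse = ", "), ")", call. = FALSE)
  }
  num <- c("id", "time", "evid", "mdv", "cmt", "bql")
  for (cn in num)
    bad(!is.finite(r[[cn]]), paste0("missing or non-numeric '", cn, "'"))
  bad(r$time < 0, "negative time")
  bad(!r$cmt %in% c(1, 2, 3), "cmt outside {1,2,3}")
  bad(!r$evid %in% c(0, 1), "evid outside {0,1}")
  bad(!r$bql %in% c(0, 1), "bql outside {0,1}")
  bad(r$evid == 1 & (!is.finite(r$amt) | r$amt <= 0),
      "dose record with missing or non-positive amt")
  bad(r$evid == 1 & r$cmt != 1, "dose record with cmt != 1")
  bad(r$evid == 1 & r$mdv != 1, "dose record with mdv != 1")
  bad(r$evid == 0 & !r$cmt %in% c(2, 3), "observation with cmt outside {2,3}")
  bad(r$evid == 0 & r$bql == 0 & r$mdv == 0 & !is.finite(r$dv),
      "quantifiable observation with missing dv")
  ord <- unlist(tapply(r$time, r$id, function(t) c(FALSE, diff(t) < 0)),
                use.names = FALSE)
  bad(ord[order(order(r$id))], "non-monotone times within subject")
  obs_ids <- unique(r$id[r$evid == 0])
  dose_ids <- unique(r$id[r$evid == 1])
  miss <- setdiff(obs_ids, dose_ids)
  if (length(miss))
    stop("observation subject(s) without a dose record: ",
         paste(head(miss, 5), collapse = ", "), call. = FALSE)
  miss <- setdiff(unique(r$id), cv$id)
  if (length(miss))
    stop("covariates missing for subject(s): ",
         paste(head(miss, 5), collapse = ", "), call. = FALSE)
  if (anyDuplicated(cv$id)) stop("duplicate covariate rows", call. = FALSE)
  if (any(!is.finite(cv$wt) | cv$wt <= 0)) stop("non-positive weight", call. = FALSE)
  if (any(!cv$preg %in% c(0, 1))) stop("preg outside {0,1}", call. = FALSE)
  if (any(cv$preg == 0 & cv$ega != 0)) stop("ega must be 0 when preg = 0", call. = FALSE)
  if (any(cv$ega < 0 | cv$ega > 8)) stop("ega outside 0-8 months", call. = FALSE)
  invisible(ds)
}

#' Read a study dataset from delimited text
#'
#' Comma-separated, `#` comment lines skipped, `.` for missing values.
#' A header row naming the 16 columns may be present; without one the file is
#' parsed positionally in the standard column order.
#'
#' @param path File path.
#' @param raw_scale If `TRUE` the `DV` column holds raw concentrations
#'   (ng/mL) and is converted to natural logs on read; the default stores
#'   `DV` on the log scale, as in the source layout.
#' @param lloq_ars,lloq_dha Analyte LLOQs (ng/mL).
#' @return A validated `study_dataset`.
#' @export
read_dataset <- function(path, raw_scale = FALSE, lloq_ars = 1.2, lloq_dha = 2.0) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (!length(lines)) stop("empty dataset file: ", path)
  first <- strsplit(lines[[1]], ",", fixed = TRUE)[[1]]
  has_header <- any(is.na(suppressWarnings(as.numeric(
    trimws(first)[trimws(first) != "."]))))
  if (has_header) {
    hdr <- toupper(trimws(first))
    unknown <- setdiff(hdr, DATASET_COLUMNS)
    if (length(unknown))
      stop("unknown column(s): ", paste(unknown, collapse = ", "))
    body <- lines[-1]
  } else {
    hdr <- DATASET_COLUMNS
    body <- lines
  }
  if (!length(body)) {
    df <- as.data.frame(setNames(rep(list(numeric(0)), length(hdr)), hdr))
  } else {
    fields <- strsplit(body, ",", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf != length(hdr)))
      stop("row ", which(nf != length(hdr))[1], " has ", nf[nf != length(hdr)][1],
           " fields, expected ", length(hdr))
    m <- matrix(trimws(unlist(fields)), ncol = length(hdr), byrow = TRUE)
    m[m == "."] <- NA
    df <- as.data.frame(apply(m, 2, as.numeric, simplify = FALSE))
    names(df) <- hdr
  }
  missing_cols <- setdiff(DATASET_COLUMNS, names(df))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  rec <- data.frame(id = df$ID, time = df$TIME, dv = df$DV, evid = df$EVID,
                    mdv = df$MDV, amt = df$AMT, cmt = df$CMT, bql = df$BQL)
  if (raw_scale) rec$dv <- log(rec$dv)
  cv <- df[!duplicated(df$ID),
           c("ID", "WT", "PREG", "LNPC", "HB", "AST", "ALT", "BIL", "EGA")]
  names(cv) <- COVARIATE_COLS
  rownames(cv) <- NULL
  study_dataset(rec, cv, lloq_ars = lloq_ars, lloq_dha = lloq_dha)
}

fmt_num <- function(x) ifelse(is.na(x), ".", sprintf("%.17g", x))

#' Write a study dataset to delimited text
#'
#' Produces a file re-readable by [read_dataset()] with identical content
#' (numbers written with 17 significant digits so the round trip is
#' bit-exact).
#'
#' @param ds A `study_dataset`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(ds, path) {
  validate_dataset(ds)
  r <- ds$records
  cv <- ds$covariates[match(r$id, ds$covariates$id), , drop = FALSE]
  m <- cbind(fmt_num(r$id), fmt_num(r$time), fmt_num(r$dv), fmt_num(cv$wt),
             fmt_num(r$evid), fmt_num(r$mdv), fmt_num(r$amt), fmt_num(r$cmt),
             fmt_num(r$bql), fmt_num(cv$preg), fmt_num(cv$lnpc),
             fmt_num(cv$hb), fmt_num(cv$ast), fmt_num(cv$alt),
             fmt_num(cv$bil), fmt_num(cv$ega))
  lines <- c(paste(DATASET_COLUMNS, collapse = ","),
             apply(m, 1, paste, collapse = ","))
  if (nrow(r) == 0) lines <- lines[1]
  writeLines(lines, path)
  invisible(path)
}

# Observation rows entering likelihood/BLQ summaries: post-dose samples that
# are either quantifiable or censored (pre-dose screening rows have mdv = 1
# and bql = 0 and are excluded).
likelihood_rows <- function(records) {
  records$evid == 0 & (records$bql == 1 | records$mdv == 0)
}

#' Fraction of observations below the limit of quantification
#'
#' @param ds A `study_dataset`.
#' @return Named vector with the BLQ fraction per analyte over post-dose
#'   observation records.
#' @export
blq_fraction <- function(ds) {
  r <- ds$records[likelihood_rows(ds$records), ]
  c(ars = mean(r$bql[r$cmt == 2] == 1),
    dha = mean(r$bql[r$cmt == 3] == 1))
}

#' Demographic and censoring summary of a cohort
#'
#' Median and range of each covariate per pregnancy group, plus the fraction
#' of post-dose samples below the LLOQ per analyte.
#'
#' @param ds A `study_dataset`.
#' @return A list with `demographics` (data frame: group, variable, n,
#'   median, min, max) and `blq` (named per-analyte fractions).
#' @export
summarize_cohort <- function(ds) {
  stopifnot(nrow(ds$records) > 0)
  cv <- ds$covariates
  cv$parasites <- exp(cv$lnpc)
  vars <- c("wt", "parasites", "hb", "ast", "alt", "bil", "ega")
  rows <- list()
  for (g in sort(unique(cv$preg))) {
    sub <- cv[cv$preg == g, ]
    for (v in vars)
      rows[[length(rows) + 1L]] <- data.frame(
        group = if (g == 1) "pregnant" else "non-pregnant", variable = v,
        n = nrow(sub), median = median(sub[[v]]),
        min = min(sub[[v]]), max = max(sub[[v]]))
  }
  list(demographics = do.call(rbind, rows), blq = blq_fraction(ds))
}

# Per-subject static structures consumed by the compiled likelihood.
prepare_subjects <- function(ds, model) {
  ids <- sort(unique(ds$records$id))
  r <- ds$records
  lapply(ids, function(i) {
    sub <- r[r$id == i, , drop = FALSE]
    obs <- sub[likelihood_rows(sub), , drop = FALSE]
    dose <- sub[sub$evid == 1, , drop = FALSE]
    o <- order(obs$time, obs$cmt)
    obs <- obs[o, , drop = FALSE]
    list(nn = model$nn,
         dose_time = dose$time, dose_amt = dose$amt,
         obs_time = obs$time, obs_cmt = as.integer(obs$cmt),
         obs_dv = ifelse(is.na(obs$dv), 0, obs$dv),
         obs_bql = as.integer(obs$bql))
  })
}
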