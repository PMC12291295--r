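# Delimiter by extension: .csv -> comma, .tsv/.txt -> tab.
.delim_for <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

.read_raw <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.table(path, sep = .delim_for(path), header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
}

.require_columns <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop("'", path, "' is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
}

.require_numeric <- function(df, cols, path) {
  for (cl in cols) {
    v <- df[[cl]]
    if (!is.numeric(v)) {
      suppressWarnings(num <- as.numeric(v))
      bad <- which(is.na(num) & !is.na(v) & v != "")[1]
      stop("'", path, "': non-numeric value in column '", cl, "' at row ",
           if (is.na(bad)) "?" else bad)
    }
  }
}

#' Read and validate a typed analysis table
#'
#' Reads a CSV or TSV (delimiter chosen by extension) and validates it
#' against one of the pipeline's schemas, returning the corresponding typed
#' object(s). Errors name the first offending row or column.
#'
#' Schemas:
#' * `"assay"`: columns `sample_id`, `kind`, `time_h`, `replicate`,
#'   `mpa_mg_l`, `mpag_mg_l` (optional `blank_mpa_mg_l`,
#'   `amoxapine_mg_ml`); returns a list of [assay_timecourse()].
#' * `"pk"`: columns `patient_id`, `visit`, `time_h`, `conc_mg_l`,
#'   `dose_mg`; returns a list of [pk_profile()].
#' * `"taxa"`: first column the taxon label, remaining columns samples in
#'   percent summing to 100; returns a taxon-by-sample matrix.
#' * `"markers"`: first column `marker_id`, remaining columns samples;
#'   returns a marker-by-sample matrix.
#' * `"catalog"`: columns `marker_id`, `length_bp`, `taxon`; returns the
#'   catalog data frame.
#' * `"rates"`: columns `sample_id`, `rate`; returns a named numeric
#'   vector.
#'
#' @param path File path (`.csv` or `.tsv`).
#' @param schema One of the schema names above.
#' @param lloq_mg_l Assay LLOQ attached to assay time courses.
#' @return See the schema list.
#' @export
read_table <- function(path, schema = c("assay", "pk", "taxa", "markers",
                                        "catalog", "rates"),
                       lloq_mg_l = 0.25) {
  schema <- match.arg(schema)
  df <- .read_raw(path)
  switch(schema,
    assay = {
      req <- c("sample_id", "kind", "time_h", "replicate", "mpa_mg_l",
               "mpag_mg_l")
      .require_columns(df, req, path)
      .require_numeric(df, c("time_h", "replicate", "mpa_mg_l",
                             "mpag_mg_l"), path)
      lapply(split(df, df$sample_id), function(d) {
        assay_timecourse(
          sample_id = d$sample_id[1], kind = d$kind[1],
          data = d[, c("time_h", "replicate", "mpa_mg_l", "mpag_mg_l")],
          blank_mpa_mg_l = if ("blank_mpa_mg_l" %in% names(d)) {
            d$blank_mpa_mg_l[1]
          } else NA_real_,
          lloq_mg_l = lloq_mg_l,
          amoxapine_mg_ml = if ("amoxapine_mg_ml" %in% names(d)) {
            d$amoxapine_mg_ml[1]
          } else NA_real_
        )
      })
    },
    pk = {
      req <- c("patient_id", "visit", "time_h", "conc_mg_l", "dose_mg")
      .require_columns(df, req, path)
      .require_numeric(df, c("time_h", "conc_mg_l", "dose_mg"), path)
      key <- paste(df$patient_id, df$visit, sep = "//")
      lapply(split(df, key), function(d) {
        d <- d[order(d$time_h), ]
        pk_profile(patient_id = d$patient_id[1], visit = d$visit[1],
                   times = d$time_h, conc = d$conc_mg_l,
                   dose_mg = d$dose_mg[1])
      })
    },
    taxa = {
      if (ncol(df) < 2) stop("'", path, "' needs a taxon column and samples")
      if (anyDuplicated(df[[1]])) {
        stop("'", path, "': duplicate taxon '",
             df[[1]][anyDuplicated(df[[1]])], "'")
      }
      .require_numeric(df, names(df)[-1], path)
      m <- as.matrix(df[, -1, drop = FALSE])
      rownames(m) <- df[[1]]
      sums <- colSums(m)
      bad <- which(abs(sums - 100) > 1e-6 * 100)
      if (length(bad)) {
        stop("'", path, "': sample '", colnames(m)[bad[1]], "' sums to ",
             format(sums[bad[1]]), "% instead of 100%")
      }
      m
    },
    markers = {
      if (names(df)[1] != "marker_id") {
        stop("'", path, "': first column must be 'marker_id'")
      }
      if (anyDuplicated(df$marker_id)) {
        stop("'", path, "': duplicate marker_id")
      }
      .require_numeric(df, names(df)[-1], path)
      m <- as.matrix(df[, -1, drop = FALSE])
      rownames(m) <- df$marker_id
      if (any(m < 0)) stop("'", path, "': negative abundance value")
      m
    },
    catalog = {
      req <- c("marker_id", "length_bp", "taxon")
      .require_columns(df, req, path)
      .require_numeric(df, "length_bp", path)
      if (anyDuplicated(df$marker_id)) {
        stop("'", path, "': duplicate marker_id")
      }
      if (any(df$length_bp <= 0)) stop("'", path, "': length_bp must be > 0")
      df
    },
    rates = {
      req <- c("sample_id", "rate")
      .require_columns(df, req, path)
      .require_numeric(df, "rate", path)
      if (anyDuplicated(df$sample_id)) {
        stop("'", path, "': duplicate sample_id")
      }
      stats::setNames(df$rate, df$sample_id)
    }
  )
}

.write_delim <- function(df, path) {
  utils::write.table(df, path, sep = .delim_for(path), row.names = FALSE,
                     quote = FALSE)
}

#' Write pipeline tables to CSV/TSV
#'
#' Serialisers matching the [read_table()] schemas; numeric values are
#' written with full precision so a write-read round trip is lossless to
#' near machine precision.
#'
#' @param tcs List of [assay_timecourse()] objects.
#' @param path Output file path.
#' @name write-tables
#' @return The path, invisibly.
#' @export
write_assay_csv <- function(tcs, path) {
  rows <- lapply(tcs, function(tc) {
    d <- tc$data
    data.frame(sample_id = tc$sample_id, kind = tc$kind,
               time_h = d$time_h, replicate = d$replicate,
               mpa_mg_l = format(d$mpa_mg_l, digits = 17, trim = TRUE),
               mpag_mg_l = format(d$mpag_mg_l, digits = 17, trim = TRUE),
               blank_mpa_mg_l = tc$blank_mpa_mg_l,
               amoxapine_mg_ml = tc$amoxapine_mg_ml,
               stringsAsFactors = FALSE)
  })
  .write_delim(do.call(rbind, rows), path)
  invisible(path)
}

#' @rdname write-tables
#' @param profiles List of [pk_profile()] objects.
#' @export
write_pk_csv <- function(profiles, path) {
  rows <- lapply(profiles, function(p) {
    data.frame(patient_id = p$patient_id, visit = p$visit,
               time_h = format(p$times, digits = 17, trim = TRUE),
               conc_mg_l = format(p$conc, digits = 17, trim = TRUE),
               dose_mg = p$dose_mg, stringsAsFactors = FALSE)
  })
  .write_delim(do.call(rbind, rows), path)
  invisible(path)
}

#' @rdname write-tables
#' @param table An [abundance_table()] or [feature_table()].
#' @export
write_taxa_tsv <- function(table, path) {
  m <- .as_taxa_matrix(table)
  df <- data.frame(taxon = rownames(m),
                   apply(m, 2, format, digits = 17, trim = TRUE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  .write_delim(df, path)
  invisible(path)
}

#' @rdname write-tables
#' @export
write_marker_tsv <- function(table, path) {
  stopifnot(inherits(table, "feature_table"))
  m <- table$values
  df <- data.frame(marker_id = rownames(m),
                   apply(m, 2, format, digits = 17, trim = TRUE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  .write_delim(df, path)
  invisible(path)
}

#' @rdname write-tables
#' @param catalog Marker catalog data frame.
#' @export
write_catalog_tsv <- function(catalog, path) {
  .write_delim(catalog, path)
  invisible(path)
}

#' @rdname write-tables
#' @param rates Named numeric vector of reactivation rates.
#' @export
write_rates_csv <- function(rates, path) {
  .write_delim(data.frame(sample_id = names(rates),
                          rate = format(unname(rates), digits = 17,
                                        trim = TRUE),
                          stringsAsFactors = FALSE), path)
  invisible(path)
}
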