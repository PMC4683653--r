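# Domain containers and tab-delimited readers/writers.
#
# File dialect used throughout: UTF-8, tab-delimited, "." decimal,
# empty string = missing value.

#' Construct a feature matrix with aligned sample metadata
#'
#' @param values numeric matrix, features in rows (rownames = feature
#'   ids), samples in columns (colnames = sample ids).
#' @param meta data.frame with columns `sample_id`, `line_id`,
#'   `diet_id`, `replicate_id`, `platform`; one row per sample, in
#'   column order of `values`.
#' @param kind feature kind, `"transcript"` or `"metabolite"`, recycled
#'   to one entry per feature.
#' @return a list of class `feature_matrix` with elements `values`,
#'   `meta`, `kind`.
#' @export
feature_matrix <- function(values, meta, kind = "transcript") {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || anyDuplicated(rownames(values))) {
    stop("feature ids (rownames) must be present and unique")
  }
  meta <- validate_sample_meta(meta)
  if (is.null(colnames(values))) colnames(values) <- meta$sample_id
  if (!identical(colnames(values), meta$sample_id)) {
    extra <- setdiff(colnames(values), meta$sample_id)
    missing <- setdiff(meta$sample_id, colnames(values))
    if (length(extra) || length(missing)) {
      stop("matrix/metadata sample mismatch; in matrix only: [",
           paste(extra, collapse = ", "), "]; in metadata only: [",
           paste(missing, collapse = ", "), "]")
    }
    values <- values[, meta$sample_id, drop = FALSE]
  }
  kind <- rep_len(match.arg(kind, c("transcript", "metabolite"),
                            several.ok = TRUE), nrow(values))
  structure(list(values = values, meta = meta, kind = kind),
            class = "feature_matrix")
}

validate_sample_meta <- function(meta) {
  need <- c("sample_id", "line_id", "diet_id", "replicate_id", "platform")
  miss <- setdiff(need, names(meta))
  if (length(miss)) {
    stop("sample metadata lacks column(s): ", paste(miss, collapse = ", "))
  }
  meta <- as.data.frame(meta)[need]
  for (k in need) meta[[k]] <- as.character(meta[[k]])
  if (anyDuplicated(meta$sample_id)) {
    stop("duplicate sample_id in metadata: ",
         paste(unique(meta$sample_id[duplicated(meta$sample_id)]),
               collapse = ", "))
  }
  rownames(meta) <- NULL
  meta
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix: %d features x %d samples (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(unique(x$kind), collapse = "+")))
  cat(sprintf("  lines: %d  diets: %s  replicates: %d  platform(s): %s\n",
              length(unique(x$meta$line_id)),
              paste(unique(x$meta$diet_id), collapse = ","),
              length(unique(x$meta$replicate_id)),
              paste(unique(x$meta$platform), collapse = ",")))
  invisible(x)
}

#' Read a feature matrix and its sample metadata from TSV files
#'
#' The matrix file carries a header row of sample ids and feature ids
#' in the first column; the metadata file carries columns `sample_id`,
#' `line_id`, `diet_id`, `replicate_id`, `platform` (and optionally
#' `kind` rows are taken from a `kind` column in the matrix file).
#' Columns are reordered to follow the metadata row order.  A sample
#' present in only one of the two files is a hard error naming the
#' offenders; a non-numeric cell is an error with its coordinates.
#'
#' @param path matrix TSV path.
#' @param meta_path metadata TSV path.
#' @return a `feature_matrix`.
#' @export
read_feature_matrix <- function(path, meta_path) {
  raw <- read.delim(path, check.names = FALSE, colClasses = "character",
                    na.strings = "")
  feature_ids <- raw[[1L]]
  kind <- if ("kind" %in% names(raw)[-1L]) raw[["kind"]] else "transcript"
  vals <- raw[, setdiff(names(raw)[-1L], "kind"), drop = FALSE]
  num <- suppressWarnings(vapply(vals, as.numeric, numeric(nrow(vals))))
  num <- matrix(num, nrow = nrow(vals),
                dimnames = list(feature_ids, colnames(vals)))
  bad <- which(is.na(num) & !is.na(as.matrix(vals)), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-numeric cell at feature '%s', sample '%s': '%s'",
                 feature_ids[bad[1, 1]], colnames(vals)[bad[1, 2]],
                 vals[bad[1, 1], bad[1, 2]]))
  }
  meta <- read.delim(meta_path, check.names = FALSE,
                     colClasses = "character", na.strings = "")
  feature_matrix(num, meta, kind = kind)
}

#' Write a feature matrix and its sample metadata to TSV files
#'
#' Values are written at full double precision (17 significant digits)
#' so that a write/read round trip is lossless.
#'
#' @param fm a `feature_matrix`.
#' @param path matrix TSV path.
#' @param meta_path metadata TSV path.
#' @return invisibly, `path`.
#' @export
write_feature_matrix <- function(fm, path, meta_path) {
  stopifnot(inherits(fm, "feature_matrix"))
  out <- data.frame(feature_id = rownames(fm$values),
                    kind = fm$kind,
                    format_full(fm$values),
                    check.names = FALSE)
  write_tsv(out, path)
  write_tsv(fm$meta, meta_path)
  invisible(path)
}

format_full <- function(m) {
  f <- matrix(sprintf("%.17g", m), nrow = nrow(m), dimnames = dimnames(m))
  f[is.na(m)] <- NA_character_
  as.data.frame(f, check.names = FALSE)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "", fileEncoding = "UTF-8")
}

#' Read a gross phenotype table
#'
#' Expects a TSV with a `unit_id` column plus the trait columns
#' `weight`, `triglyceride` and `sugar` (additional numeric trait
#' columns are carried along).  Empty cells are preserved as `NA`.
#'
#' @param path phenotype TSV path.
#' @param required traits that must be present.
#' @return a data.frame of class `phenotype_table`.
#' @export
read_phenotypes <- function(path,
                            required = c("weight", "triglyceride", "sugar")) {
  ph <- read.delim(path, check.names = FALSE, na.strings = "")
  miss <- setdiff(c("unit_id", required), names(ph))
  if (length(miss)) {
    stop("phenotype table lacks column(s): ", paste(miss, collapse = ", "))
  }
  ph$unit_id <- as.character(ph$unit_id)
  for (k in setdiff(names(ph), "unit_id")) ph[[k]] <- as.numeric(ph[[k]])
  class(ph) <- c("phenotype_table", "data.frame")
  ph
}

#' Write a gross phenotype table
#' @param ph a phenotype data.frame with a `unit_id` column.
#' @param path output TSV path.
#' @return invisibly, `path`.
#' @export
write_phenotypes <- function(ph, path) {
  out <- ph
  for (k in setdiff(names(out), "unit_id")) {
    v <- sprintf("%.17g", out[[k]])
    v[is.na(out[[k]])] <- NA_character_
    out[[k]] <- v
  }
  write_tsv(out, path)
  invisible(path)
}

#' Validate a dataset against the factorial-design assumptions
#'
#' Never raises: returns a report carrying severity-graded findings on
#' design balance (observations per line x diet x replicate cell),
#' empty cells, constant (zero-variance) features, and whether each
#' downstream stage's preconditions hold.
#'
#' @param fm a `feature_matrix`.
#' @param ph optional phenotype table aligned to samples by `unit_id`.
#' @return a list of class `validation_report` with elements
#'   `findings` (data.frame: check, severity, message), `balanced`,
#'   `n_missing_cells`, `constant_features`, `design_table`.
#' @export
validate_dataset <- function(fm, ph = NULL) {
  stopifnot(inherits(fm, "feature_matrix"))
  meta <- fm$meta
  findings <- list()
  add <- function(check, severity, message) {
    findings[[length(findings) + 1L]] <<-
      data.frame(check = check, severity = severity, message = message)
  }
  lines <- unique(meta$line_id); diets <- unique(meta$diet_id)
  reps <- unique(meta$replicate_id)
  tab <- table(factor(meta$line_id, lines), factor(meta$diet_id, diets),
               factor(meta$replicate_id, reps))
  n_missing <- sum(tab == 0)
  balanced <- length(unique(as.vector(tab))) == 1L && all(tab > 0)
  if (balanced) {
    add("design", "info", sprintf("balanced, 0 missing cells (%d x %d x %d)",
                                  length(lines), length(diets), length(reps)))
  } else if (n_missing > 0) {
    idx <- which(tab == 0, arr.ind = TRUE)
    cells <- apply(idx, 1, function(i)
      paste(lines[i[1]], diets[i[2]], reps[i[3]], sep = ":"))
    add("design", "warning",
        sprintf("%d empty line x diet x replicate cell(s): %s",
                n_missing, paste(utils::head(cells, 10), collapse = ", ")))
  } else {
    add("design", "warning", "unbalanced design (unequal cell counts)")
  }
  ld <- table(factor(meta$line_id, lines), factor(meta$diet_id, diets))
  if (any(ld == 0)) {
    add("anova", "error", "empty line x diet cell: interaction inestimable")
  } else if (all(ld >= 2)) {
    add("anova", "info", "interaction testable (all cells have >= 2 obs)")
  } else if (any(ld >= 2)) {
    add("anova", "warning", "some line x diet cells have a single obs")
  } else {
    add("anova", "error", "saturated model: no within-cell replication")
  }
  vr <- apply(fm$values, 1, var, na.rm = TRUE)
  const <- rownames(fm$values)[!is.na(vr) & vr == 0]
  if (length(const)) {
    add("features", "warning",
        sprintf("%d constant feature(s): %s", length(const),
                paste(utils::head(const, 10), collapse = ", ")))
  }
  if (anyNA(fm$values)) {
    add("features", "warning",
        sprintf("%d missing value(s) in feature matrix", sum(is.na(fm$values))))
  }
  if (!is.null(ph)) {
    unmatched <- setdiff(meta$sample_id, ph$unit_id)
    if (length(unmatched)) {
      add("phenotypes", "warning",
          sprintf("%d sample(s) lack phenotype rows", length(unmatched)))
    } else {
      add("phenotypes", "info", "all samples have phenotype rows")
    }
  }
  structure(list(findings = do.call(rbind, findings), balanced = balanced,
                 n_missing_cells = n_missing, constant_features = const,
                 design_table = tab),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("gxdmod dataset validation report\n")
  f <- x$findings
  for (i in seq_len(nrow(f))) {
    cat(sprintf("  [%s/%s] %s\n", f$check[i], f$severity[i], f$message[i]))
  }
  invisible(x)
}
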