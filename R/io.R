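#' Read a measurement-run table
#'
#' Reads a delimited text file (comma or tab, auto-detected from the header
#' line) with one row per acquisition in run order. Required columns:
#' `label`, `role`, `mean_ratio`, `std_error`, `n_cycles`. Lines starting
#' with `#` and blank lines are ignored. Role values are normalized
#' case-insensitively. Malformed rows are reported with their file line
#' numbers.
#'
#' @param path path to the run table, or `"-"` for standard input.
#' @return An [ssb_run()].
#' @export
read_run_table <- function(path) {
  parsed <- read_delimited(path, required = c("label", "role", "mean_ratio",
                                              "std_error", "n_cycles"))
  tab <- parsed$rows
  lines <- parsed$line_numbers

  num_field <- function(col) {
    v <- suppressWarnings(as.numeric(tab[[col]]))
    bad <- which(is.na(v) & !is.na(tab[[col]]))
    if (length(bad))
      stop(sprintf("non-numeric %s at line %d: '%s'",
                   col, lines[bad[1L]], tab[[col]][bad[1L]]))
    v
  }
  mean_ratio <- num_field("mean_ratio")
  std_error <- num_field("std_error")
  n_cycles <- num_field("n_cycles")
  if (any(std_error < 0)) {
    bad <- which(std_error < 0)[1L]
    stop(sprintf("negative std_error at line %d", lines[bad]))
  }
  if (any(mean_ratio <= 0)) {
    bad <- which(mean_ratio <= 0)[1L]
    stop(sprintf("nonpositive mean_ratio at line %d", lines[bad]))
  }
  role <- tryCatch(normalize_role(tab$role), error = function(e) {
    bad <- which(!(tolower(trimws(tab$role)) %in% c("standard", "sample")))[1L]
    stop(sprintf("invalid role '%s' at line %d", tab$role[bad], lines[bad]))
  })
  ssb_run(label = tab$label, role = role, mean_ratio = mean_ratio,
          std_error = std_error, n_cycles = as.integer(n_cycles))
}

#' Write a measurement-run table
#'
#' Tab-delimited, with header, suitable for [read_run_table()].
#'
#' @param run an [ssb_run()].
#' @param path output path, or `"-"` for standard output.
#' @export
write_run_table <- function(run, path) {
  if (!inherits(run, "ssb_run")) run <- as_ssb_run(run)
  write_tsv(as.data.frame(run), path)
}

#' Read a reference-delta table
#'
#' Reads a delimited file mapping sample labels to literature (accepted)
#' delta values in per mil, with an optional `citation` column. A label may
#' appear on several rows when more than one literature value exists; the
#' values are averaged into the working reference and the individual values
#' and citations are retained for reporting.
#'
#' @param path path to the file (columns `label`, `delta_true`, optional
#'   `citation`). An empty table is allowed: every sample then falls back to
#'   mean substitution.
#' @return A data frame of class `ssb_reference` with one row per unique
#'   label: `label`, `delta_true` (average of the listed values),
#'   `n_values`, `values` (comma-joined individual values), `citations`.
#' @export
read_reference_table <- function(path) {
  parsed <- read_delimited(path, required = c("label", "delta_true"),
                           allow_empty = TRUE)
  tab <- parsed$rows
  if (nrow(tab) == 0L) return(reference_table(character(), numeric()))
  v <- suppressWarnings(as.numeric(tab$delta_true))
  bad <- which(!is.finite(v))
  if (length(bad))
    stop(sprintf("non-finite delta_true at line %d: '%s'",
                 parsed$line_numbers[bad[1L]], tab$delta_true[bad[1L]]))
  reference_table(tab$label, v,
                  if ("citation" %in% names(tab)) tab$citation else NULL)
}

#' Construct a reference table in code
#'
#' @param label character vector of sample labels (repeats allowed: multiple
#'   literature values for one sample are averaged).
#' @param delta_true numeric vector of accepted delta values (per mil).
#' @param citation optional character vector of citations.
#' @return An `ssb_reference` data frame; see [read_reference_table()].
#' @export
#' @examples
#' reference_table(c("SELM-1", "SELM-1"), c(-0.68, -0.66))  # averaged: -0.67
reference_table <- function(label, delta_true, citation = NULL) {
  stopifnot(length(label) == length(delta_true))
  if (is.null(citation)) citation <- rep("", length(label))
  if (any(!is.finite(delta_true))) stop("delta_true values must be finite")
  labs <- unique(as.character(label))
  out <- do.call(rbind, lapply(labs, function(l) {
    i <- which(label == l)
    data.frame(label = l,
               delta_true = mean(delta_true[i]),
               n_values = length(i),
               values = paste(format(delta_true[i], trim = TRUE),
                              collapse = ","),
               citations = paste(citation[i][nzchar(citation[i])],
                                 collapse = "; "),
               stringsAsFactors = FALSE)
  }))
  if (is.null(out))
    out <- data.frame(label = character(), delta_true = numeric(),
                      n_values = integer(), values = character(),
                      citations = character(), stringsAsFactors = FALSE)
  class(out) <- c("ssb_reference", "data.frame")
  out
}

#' Write a delta table
#'
#' @param deltas an `ssb_deltas` data frame.
#' @param path output path, or `"-"` for standard output.
#' @export
write_delta_table <- function(deltas, path) {
  write_tsv(as.data.frame(deltas), path)
}

#' Read a delta table written by [write_delta_table()]
#'
#' @param path input path.
#' @return An `ssb_deltas` data frame.
#' @export
read_delta_table <- function(path) {
  parsed <- read_delimited(path, required = c("label", "seq_index",
                                              "delta_permil", "prop_se"))
  tab <- parsed$rows
  out <- data.frame(label = tab$label,
                    seq_index = as.integer(tab$seq_index),
                    delta_permil = as.numeric(tab$delta_permil),
                    prop_se = as.numeric(tab$prop_se),
                    stringsAsFactors = FALSE)
  class(out) <- c("ssb_deltas", "data.frame")
  out
}

#' Write an uncertainty report
#'
#' Two plain-text renderings of an `ssb_report`:
#' * `format = "table"`: a tab-delimited table mirroring the printed summary
#'   (values rounded to 2 decimals, p-values to 4) — for humans.
#' * `format = "keyvalue"`: a `key<TAB>value` file carrying every value at
#'   full double precision plus the Monte Carlo `runs`, `seed` and
#'   `coverage` — machine-readable, round-trips through
#'   [read_report_keyvalue()] with numerically identical values.
#'
#' @param report an `ssb_report` from [build_report()].
#' @param path output path, or `"-"` for standard output.
#' @param format `"table"` or `"keyvalue"`.
#' @export
write_report <- function(report, path, format = c("table", "keyvalue")) {
  stopifnot(inherits(report, "ssb_report"))
  format <- match.arg(format)
  t <- report$table
  if (format == "table") {
    disp <- data.frame(
      label = t$label,
      delta_true = ifelse(is.na(t$reference_delta) |
                            t$reference_source %in% "sample_mean", "n.d.",
                          sprintf("%.2f", t$reference_delta)),
      delta_avg = ifelse(is.na(t$delta_avg), "", sprintf("%.2f", t$delta_avg)),
      deviation_avg = sprintf("%.2f", t$deviation_avg),
      sd_delta = sprintf("%.2f", t$sd_delta),
      sd_delta_mc = sprintf("%.2f", t$sd_delta_mc),
      u = sprintf("%.2f", t$u),
      u_mc = sprintf("%.2f", t$u_mc),
      shapiro_p = ifelse(is.na(t$shapiro_p), "n/a",
                         sprintf("%.4f", t$shapiro_p)),
      ttest_p = ifelse(is.na(t$ttest_p), "n/a", sprintf("%.4f", t$ttest_p)),
      n = t$n,
      dominance = t$dominance,
      stringsAsFactors = FALSE
    )
    write_tsv(disp, path)
  } else {
    num <- function(v) ifelse(is.na(v), "NA", sprintf("%.17g", v))
    lines <- c(
      paste0("meta.runs\t", num(report$runs)),
      paste0("meta.seed\t", if (is.null(report$seed)) "NA"
             else format(report$seed)),
      paste0("meta.coverage\t", num(report$coverage)),
      paste0("meta.ratio_threshold\t", num(report$ratio_threshold)),
      paste0("meta.nrow\t", nrow(t))
    )
    for (i in seq_len(nrow(t))) {
      key <- sprintf("row.%d.", i)
      lines <- c(
        lines,
        paste0(key, "label\t", t$label[i]),
        paste0(key, "reference_delta\t", num(t$reference_delta[i])),
        paste0(key, "reference_source\t",
               ifelse(is.na(t$reference_source[i]), "NA",
                      t$reference_source[i])),
        paste0(key, "n\t", t$n[i]),
        paste0(key, "delta_avg\t", num(t$delta_avg[i])),
        paste0(key, "deviation_avg\t", num(t$deviation_avg[i])),
        paste0(key, "sd_delta\t", num(t$sd_delta[i])),
        paste0(key, "sd_delta_mc\t", num(t$sd_delta_mc[i])),
        paste0(key, "u\t", num(t$u[i])),
        paste0(key, "u_mc\t", num(t$u_mc[i])),
        paste0(key, "shapiro_p\t", num(t$shapiro_p[i])),
        paste0(key, "ttest_p\t", num(t$ttest_p[i])),
        paste0(key, "dominance\t", t$dominance[i])
      )
    }
    writeLines(lines, con_out(path))
  }
  invisible(path)
}

#' Parse a key-value report file back into an `ssb_report`
#'
#' @param path file written by `write_report(..., format = "keyvalue")`.
#' @return An `ssb_report` with numerically identical values.
#' @export
read_report_keyvalue <- function(path) {
  lines <- readLines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  keys <- vapply(parts, `[[`, "", 1L)
  vals <- vapply(parts, function(p) if (length(p) > 1L) p[[2L]] else "", "")
  kv <- stats::setNames(vals, keys)
  num <- function(k) {
    v <- kv[[k]]
    if (identical(v, "NA")) NA_real_ else as.numeric(v)
  }
  chr <- function(k) {
    v <- kv[[k]]
    if (identical(v, "NA")) NA_character_ else v
  }
  nr <- as.integer(kv[["meta.nrow"]])
  rows <- lapply(seq_len(nr), function(i) {
    key <- sprintf("row.%d.", i)
    data.frame(
      label = chr(paste0(key, "label")),
      reference_delta = num(paste0(key, "reference_delta")),
      reference_source = chr(paste0(key, "reference_source")),
      n = as.integer(kv[[paste0(key, "n")]]),
      delta_avg = num(paste0(key, "delta_avg")),
      deviation_avg = num(paste0(key, "deviation_avg")),
      sd_delta = num(paste0(key, "sd_delta")),
      sd_delta_mc = num(paste0(key, "sd_delta_mc")),
      u = num(paste0(key, "u")),
      u_mc = num(paste0(key, "u_mc")),
      shapiro_p = num(paste0(key, "shapiro_p")),
      ttest_p = num(paste0(key, "ttest_p")),
      dominance = chr(paste0(key, "dominance")),
      stringsAsFactors = FALSE
    )
  })
  seed <- kv[["meta.seed"]]
  structure(list(table = do.call(rbind, rows),
                 runs = num("meta.runs"),
                 seed = if (identical(seed, "NA")) NULL else as.numeric(seed),
                 coverage = num("meta.coverage"),
                 ratio_threshold = num("meta.ratio_threshold")),
            class = "ssb_report")
}

# --- internal plumbing -----------------------------------------------------

# Delimited reader with '#'/blank skipping that keeps original line numbers
# for diagnostics. Delimiter sniffed from the header: tab wins if present.
read_delimited <- function(path, required, allow_empty = FALSE) {
  if (!identical(path, "-") && !file.exists(path))
    stop("file not found: ", path)
  lines <- readLines(if (identical(path, "-")) file("stdin") else path)
  keep <- which(nzchar(trimws(lines)) & !startsWith(trimws(lines), "#"))
  if (length(keep) == 0L) {
    if (allow_empty)
      return(list(rows = stats::setNames(
        data.frame(matrix(character(), 0, length(required)),
                   stringsAsFactors = FALSE), required),
        line_numbers = integer()))
    stop("file has no header line: ", path)
  }
  header_line <- lines[keep[1L]]
  sep <- if (grepl("\t", header_line, fixed = TRUE)) "\t" else ","
  header <- trimws(strsplit(header_line, sep, fixed = TRUE)[[1L]])
  missing <- setdiff(required, header)
  if (length(missing))
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  body <- keep[-1L]
  cells <- lapply(lines[body], function(l) trimws(strsplit(l, sep,
                                                           fixed = TRUE)[[1L]]))
  short <- which(vapply(cells, length, 0L) < length(header))
  if (length(short))
    stop(sprintf("malformed row at line %d: expected %d fields",
                 body[short[1L]], length(header)))
  rows <- as.data.frame(
    stats::setNames(lapply(seq_along(header), function(j)
      vapply(cells, `[[`, "", j)), header),
    stringsAsFactors = FALSE)
  list(rows = rows, line_numbers = body)
}

con_out <- function(path) if (identical(path, "-")) stdout() else path

write_tsv <- function(df, path) {
  utils::write.table(df, con_out(path), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
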