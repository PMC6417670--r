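#' Read a clone table into a repertoire tibble
#'
#' Reads one immunosequencing sample: a tab-separated table mapping each
#' unique TCR-beta CDR3 nucleotide rearrangement to its template count.
#' Three dialects are supported:
#'
#' * `"immunoseq"`: a headered TSV in the style of immunoSEQ exports; the
#'   key and count columns default to `rearrangement` and `templates` and
#'   can be renamed through `column_map` (export column names vary by
#'   pipeline version, so the mapping is configuration, not code).
#' * `"generic"`: two columns (key, count), header optional. A header line
#'   is detected by a non-numeric second field.
#' * `"airr"`: a headered TSV using the AIRR community column names
#'   `junction` and `duplicate_count` (overridable through `column_map`).
#'
#' Rows with a missing key or a count that is not a positive integer are
#' dropped with a warning; duplicate keys are aggregated by summing their
#' counts. Clone identity is the nucleotide rearrangement string alone; any
#' amino-acid column is ignored as annotation.
#'
#' @param path Path to a TSV file.
#' @param dialect One of `"immunoseq"`, `"generic"`, `"airr"`.
#' @param column_map Optional named character vector overriding the dialect's
#'   column names, e.g. `c(rearrangement = "nucleotide", templates = "count")`.
#'   Names used: `rearrangement`, `templates`.
#' @param sample_id Sample label stored on the result; defaults to the file
#'   name without extension.
#' @return A tibble of class `tcr_repertoire` with columns `rearrangement`
#'   (character) and `templates` (integer), one row per clone, carrying the
#'   sample id as an attribute. The total template count is
#'   [total_templates()].
#' @seealso [join_samples()], [write_results()]
#' @export
read_repertoire <- function(path,
                            dialect = c("immunoseq", "generic", "airr"),
                            column_map = NULL,
                            sample_id = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    stop_domain(paste0("file not found: ", path), "diffclone_io_error")
  }
  sample_id <- sample_id %||% sub("\\.[^.]*$", "", basename(path))

  defaults <- switch(dialect,
    immunoseq = c(rearrangement = "rearrangement", templates = "templates"),
    airr      = c(rearrangement = "junction", templates = "duplicate_count"),
    generic   = c(rearrangement = "key", templates = "count")
  )
  map <- defaults
  if (!is.null(column_map)) {
    bad <- setdiff(names(column_map), c("rearrangement", "templates"))
    if (length(bad)) {
      stop_domain(paste0("unknown column_map entries: ",
                         paste(bad, collapse = ", ")),
                  "diffclone_format_error")
    }
    map[names(column_map)] <- column_map
  }

  if (dialect == "generic") {
    tab <- read_generic_tsv(path)
  } else {
    tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                           col_types = readr::cols(.default = readr::col_character()))
    if (nrow(tab) == 0L) {
      stop_domain(paste0("empty clone table: ", path), "diffclone_empty_error")
    }
    missing_cols <- setdiff(unname(map), names(tab))
    if (length(missing_cols)) {
      stop_domain(paste0("required column(s) missing from ", path, ": ",
                         paste(missing_cols, collapse = ", ")),
                  "diffclone_format_error")
    }
    tab <- tibble::tibble(
      rearrangement = tab[[map[["rearrangement"]]]],
      templates     = suppressWarnings(as.numeric(tab[[map[["templates"]]]]))
    )
  }

  as_repertoire(tab, sample_id = sample_id)
}

# generic two-column dialect: header detected by non-numeric second field
read_generic_tsv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    stop_domain(paste0("empty clone table: ", path), "diffclone_empty_error")
  }
  first <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  if (length(first) < 2L) {
    stop_domain(paste0("generic dialect needs two tab-separated columns: ", path),
                "diffclone_format_error")
  }
  has_header <- is.na(suppressWarnings(as.numeric(first[[2L]])))
  body <- if (has_header) lines[-1L] else lines
  if (length(body) == 0L) {
    stop_domain(paste0("empty clone table: ", path), "diffclone_empty_error")
  }
  parts <- strsplit(body, "\t", fixed = TRUE)
  tibble::tibble(
    rearrangement = vapply(parts, function(p) p[[1L]], character(1)),
    templates     = suppressWarnings(
      as.numeric(vapply(parts, function(p) if (length(p) >= 2L) p[[2L]] else NA_character_,
                        character(1))))
  )
}

# validate, drop bad rows, aggregate duplicates, attach class/attributes
as_repertoire <- function(tab, sample_id) {
  bad <- is.na(tab$rearrangement) | !nzchar(tab$rearrangement) |
    is.na(tab$templates) | tab$templates <= 0 |
    tab$templates != floor(tab$templates)
  if (any(bad)) {
    rlang::warn(sprintf("dropping %d row(s) with missing keys or non-positive counts",
                        sum(bad)))
    tab <- tab[!bad, , drop = FALSE]
  }
  if (nrow(tab) == 0L) {
    stop_domain("no usable clone rows after filtering", "diffclone_empty_error")
  }
  out <- tab |>
    dplyr::group_by(.data$rearrangement) |>
    dplyr::summarise(templates = as.integer(sum(.data$templates)), .groups = "drop") |>
    dplyr::arrange(.data$rearrangement)
  new_repertoire(out, sample_id)
}

new_repertoire <- function(tbl, sample_id) {
  structure(tbl,
            class = c("tcr_repertoire", class(tibble::tibble())),
            sample_id = sample_id)
}

#' Total template count of a repertoire
#'
#' @param x A `tcr_repertoire` tibble.
#' @return Total number of sequenced templates in the sample, the `n` that
#'   calibrates sampling variance in the abundance tests.
#' @export
total_templates <- function(x) {
  sum(x$templates)
}

#' Sample identifier of a repertoire
#' @param x A `tcr_repertoire` tibble.
#' @return The sample id string.
#' @export
sample_id <- function(x) {
  attr(x, "sample_id") %||% NA_character_
}

#' Join two repertoires into paired per-clone observations
#'
#' Produces one row per clone in the union of the two samples' keys: counts
#' `k_A`, `k_B` (zero where a clone is absent), the sample totals `n_A`,
#' `n_B`, and the pooled `k_total`, `n_total` that drive both abundance
#' tests. Output is sorted by rearrangement so runs are deterministic.
#'
#' @param a,b `tcr_repertoire` tibbles (see [read_repertoire()]).
#' @return A tibble with columns `rearrangement`, `k_A`, `k_B`, `n_A`,
#'   `n_B`, `k_total`, `n_total`.
#' @export
join_samples <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L) {
    stop_domain("both samples must contain at least one clone",
                "diffclone_empty_error")
  }
  n_a <- total_templates(a)
  n_b <- total_templates(b)
  dplyr::full_join(
    tibble::tibble(rearrangement = a$rearrangement, k_A = a$templates),
    tibble::tibble(rearrangement = b$rearrangement, k_B = b$templates),
    by = "rearrangement"
  ) |>
    dplyr::mutate(
      k_A = dplyr::coalesce(.data$k_A, 0L),
      k_B = dplyr::coalesce(.data$k_B, 0L),
      n_A = n_a,
      n_B = n_b,
      k_total = .data$k_A + .data$k_B,
      n_total = n_a + n_b
    ) |>
    dplyr::arrange(.data$rearrangement)
}

#' Write a repertoire as a clone-table TSV
#'
#' Inverse of [read_repertoire()]: writes the headered immunoSEQ-style
#' dialect (`rearrangement`, `templates`) that [read_repertoire()] reads
#' back unchanged.
#'
#' @param x A `tcr_repertoire` tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_repertoire <- function(x, path) {
  readr::write_tsv(tibble::tibble(rearrangement = x$rearrangement,
                                  templates = x$templates),
                   path, progress = FALSE)
  invisible(path)
}

results_columns <- c("rearrangement", "k_A", "n_A", "k_B", "n_B",
                     "freq_A", "freq_B", "fold_change", "p_value", "fdr",
                     "classification")

#' Write a differential-abundance result table
#'
#' Serialises the per-clone output of [run_diffab()] as a TSV with a fixed
#' header (`rearrangement, k_A, n_A, k_B, n_B, freq_A, freq_B, fold_change,
#' p_value, fdr, classification`). Floating-point columns keep full double
#' precision so a read-back reproduces the values.
#'
#' @param records A `diffab_result` tibble from [run_diffab()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_results <- function(records, path) {
  missing_cols <- setdiff(results_columns, names(records))
  if (length(missing_cols)) {
    stop_domain(paste0("records lack required column(s): ",
                       paste(missing_cols, collapse = ", ")),
                "diffclone_format_error")
  }
  out <- records[results_columns]
  out$classification <- as.character(out$classification)
  readr::write_tsv(out, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Read back a differential-abundance result table
#'
#' @param path Path written by [write_results()].
#' @return A tibble with the same columns; `classification` as a factor
#'   with the standard levels.
#' @export
read_results <- function(path) {
  tab <- readr::read_tsv(
    path, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      rearrangement = readr::col_character(),
      k_A = readr::col_integer(), n_A = readr::col_double(),
      k_B = readr::col_integer(), n_B = readr::col_double(),
      freq_A = readr::col_double(), freq_B = readr::col_double(),
      fold_change = readr::col_double(), p_value = readr::col_double(),
      fdr = readr::col_double(), classification = readr::col_character()
    )
  )
  tab$classification <- factor(tab$classification, levels = classification_levels)
  tab
}
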