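#' Read a gene-by-sample expression table
#'
#' Two layouts are supported. `"matrix"` is a single TSV with a `gene` column
#' (first column; renamed if labelled differently) and one numeric column per
#' sample. `"gdc"` is a directory of per-sample two-column TSVs
#' (`gene<TAB>value`, no header required if the first line parses as data),
#' one file per sample, named `<sample>.tsv`; all files must cover the same
#' genes.
#'
#' Duplicate gene symbols are resolved by keeping the row with the highest
#' mean expression; dropped rows are reported in a message. Values must be
#' finite and non-negative.
#'
#' @param path File (matrix layout) or directory (gdc layout).
#' @param layout `"matrix"` or `"gdc"`.
#' @return A tibble with a `gene` column and one numeric column per sample.
#' @seealso [write_expression()]
#' @export
read_expression <- function(path, layout = c("matrix", "gdc")) {
  layout <- match.arg(layout)
  if (layout == "matrix") {
    if (!file.exists(path)) stop("no such file: ", path)
    tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                           name_repair = "minimal")
    names(tbl)[1] <- "gene"
  } else {
    if (!dir.exists(path)) stop("no such directory: ", path)
    files <- sort(list.files(path, pattern = "\\.tsv$", full.names = TRUE))
    if (length(files) == 0) stop("no .tsv files in ", path)
    cols <- purrr::map(files, function(f) {
      x <- utils::read.table(f, sep = "\t", header = FALSE,
                             col.names = c("gene", "value"),
                             colClasses = c("character", "numeric"))
      tibble::tibble(gene = x$gene, value = x$value)
    })
    genes <- cols[[1]]$gene
    samples <- sub("\\.tsv$", "", basename(files))
    for (i in seq_along(cols)) {
      missing_g <- union(setdiff(genes, cols[[i]]$gene),
                         setdiff(cols[[i]]$gene, genes))
      if (length(missing_g) > 0) {
        stop("gene set mismatch in ", basename(files[i]), ": ",
             paste(utils::head(missing_g, 5), collapse = ", "))
      }
    }
    tbl <- tibble::tibble(gene = genes)
    for (i in seq_along(cols)) {
      tbl[[samples[i]]] <- cols[[i]]$value[match(genes, cols[[i]]$gene)]
    }
  }
  validate_expression(tbl)
}

validate_expression <- function(tbl) {
  samples <- names(tbl)[names(tbl) != "gene"]
  if (anyDuplicated(samples)) {
    stop("duplicate sample id(s): ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  }
  vals <- as.matrix(tbl[samples])
  if (!is.numeric(vals)) stop("non-numeric expression values")
  if (any(!is.finite(vals))) stop("non-finite expression values")
  if (any(vals < 0)) stop("negative expression values")
  if (anyDuplicated(tbl$gene)) {
    dup <- unique(tbl$gene[duplicated(tbl$gene)])
    keep <- tbl |>
      dplyr::mutate(.mean = rowMeans(vals), .row = dplyr::row_number()) |>
      dplyr::group_by(.data$gene) |>
      dplyr::slice_max(.data$.mean, n = 1, with_ties = FALSE) |>
      dplyr::ungroup()
    message("dropping ", nrow(tbl) - nrow(keep),
            " duplicate gene row(s): ",
            paste(utils::head(dup, 5), collapse = ", "),
            if (length(dup) > 5) ", ..." else "")
    tbl <- keep |>
      dplyr::arrange(.data$.row) |>
      dplyr::select(-".mean", -".row")
  }
  tibble::as_tibble(tbl)
}

#' Write an expression table as canonical TSV
#'
#' Tab-separated, UTF-8, `.` decimal, no quoting, gene column first and named
#' `gene`. `write_expression(read_expression(x))` round-trips byte-wise for
#' files already in this dialect.
#'
#' @param expression Expression tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expression, path) {
  readr::write_tsv(expression, path, progress = FALSE)
  invisible(path)
}

#' Sample columns of an expression table
#'
#' @param expression Expression tibble.
#' @return Character vector of sample ids.
#' @export
expr_samples <- function(expression) {
  setdiff(names(expression), "gene")
}

#' Read / write a clinical table
#'
#' The clinical TSV has one row per sample with columns `sample`,
#' `tissue_type` (`tumor`/`normal`), `age` (years), `stage`, `race`,
#' `vital_status` (`alive`/`dead`) and `time_years` (time to death or last
#' follow-up). Extra columns are preserved.
#'
#' @param path TSV file.
#' @return A tibble.
#' @export
read_clinical <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("sample", "tissue_type", "vital_status", "time_years")
  miss <- setdiff(required, names(tbl))
  if (length(miss) > 0) {
    stop("clinical table lacks column(s): ", paste(miss, collapse = ", "))
  }
  tbl
}

#' @rdname read_clinical
#' @param clinical Clinical tibble.
#' @export
write_clinical <- function(clinical, path) {
  readr::write_tsv(clinical, path, progress = FALSE)
  invisible(path)
}

#' Classify samples into Normal / GP / PP prognosis groups
#'
#' Tumour samples are split by the five-year rule: death before `horizon`
#' years is Poor Prognosis (PP); alive with follow-up beyond `horizon` is
#' Good Prognosis (GP); alive with follow-up at or below `horizon` is
#' indeterminate and Excluded. A death at or after the horizon means the
#' patient did survive past it and is assigned GP by default
#' (`late_death = "GP"`); set `late_death = "Excluded"` to drop such cases
#' instead. Normal-tissue samples are always `Normal`. Samples with missing
#' vital status or time are Excluded with a warning.
#'
#' @param clinical Clinical tibble (see [read_clinical()]).
#' @param horizon Prognosis horizon in years.
#' @param late_death Group for deaths at or after the horizon: `"GP"` or
#'   `"Excluded"`.
#' @return The clinical tibble with a `group` column
#'   (`Normal`/`GP`/`PP`/`Excluded`).
#' @examples
#' clin <- tibble::tibble(
#'   sample = c("a", "b", "c"), tissue_type = "tumor",
#'   vital_status = c("dead", "alive", "alive"),
#'   time_years = c(3, 6.2, 2)
#' )
#' classify_prognosis(clin)$group  # "PP" "GP" "Excluded"
#' @export
classify_prognosis <- function(clinical, horizon = 5,
                               late_death = c("GP", "Excluded")) {
  late_death <- match.arg(late_death)
  bad <- clinical$tissue_type == "tumor" &
    (is.na(clinical$vital_status) | is.na(clinical$time_years))
  if (any(bad)) {
    warning(sum(bad), " tumor sample(s) lack vital status or follow-up time; ",
            "excluded")
  }
  clinical |>
    dplyr::mutate(group = dplyr::case_when(
      .data$tissue_type == "normal" ~ "Normal",
      is.na(.data$vital_status) | is.na(.data$time_years) ~ "Excluded",
      .data$vital_status == "dead" & .data$time_years < horizon ~ "PP",
      .data$vital_status == "dead" ~ late_death,
      .data$time_years > horizon ~ "GP",
      .default = "Excluded"
    ))
}

#' Count samples per prognosis group
#'
#' @param clinical Clinical tibble with a `group` column.
#' @return A tibble `group`, `n`.
#' @export
cohort_summary <- function(clinical) {
  clinical |>
    dplyr::count(.data$group, name = "n") |>
    dplyr::arrange(match(.data$group, c("Normal", "GP", "PP", "Excluded")))
}
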