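#' Construct a binary driver-alteration matrix
#'
#' The central container of the package: a samples-by-genes 0/1 indicator
#' matrix (1 = driver-altered) with unique sample and gene identifiers.
#' Row sums give per-sample driver counts and column sums per-gene
#' alteration counts.
#'
#' @param x A numeric matrix with row names (samples) and column names
#'   (genes), or a wide data frame whose first column holds sample ids and
#'   remaining columns one gene each.
#' @return An object of class `alteration_matrix` (an integer matrix).
#' @examples
#' m <- matrix(c(1, 0, 0, 1), 2, 2,
#'             dimnames = list(c("s1", "s2"), c("gA", "gB")))
#' alteration_matrix(m)
#' @export
alteration_matrix <- function(x) {
  if (is.data.frame(x)) {
    ids <- as.character(x[[1]])
    x <- as.matrix(x[, -1, drop = FALSE])
    rownames(x) <- ids
  }
  if (!is.matrix(x)) {
    stop_dconet("`x` must be a matrix or wide data frame", "dconet_input_error")
  }
  x <- matrix(suppressWarnings(as.numeric(x)), nrow(x), ncol(x),
              dimnames = dimnames(x))
  if (anyNA(x) || !all(x %in% c(0, 1))) {
    stop_dconet("alteration matrix entries must be exactly 0 or 1",
                "dconet_format_error")
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop_dconet("alteration matrix needs sample row names and gene column names",
                "dconet_format_error")
  }
  if (anyDuplicated(rownames(x)) || anyDuplicated(colnames(x))) {
    stop_dconet("sample and gene identifiers must be unique",
                "dconet_format_error")
  }
  storage.mode(x) <- "integer"
  structure(x, class = c("alteration_matrix", "matrix", "array"))
}

#' @export
print.alteration_matrix <- function(x, ...) {
  cat(sprintf("<alteration_matrix> %d samples x %d genes, %d altered entries\n",
              nrow(x), ncol(x), sum(x)))
  invisible(x)
}

#' @rdname alteration_matrix
#' @param am An `alteration_matrix`.
#' @export
sample_ids <- function(am) rownames(am)

#' @rdname alteration_matrix
#' @export
gene_ids <- function(am) colnames(am)

#' @describeIn alteration_matrix long tibble with one row per
#'   (sample, gene) and its 0/1 status.
#' @param ... Unused.
#' @export
as_tibble.alteration_matrix <- function(x, ...) {
  tibble::tibble(
    sample_id = rep(rownames(x), times = ncol(x)),
    gene = rep(colnames(x), each = nrow(x)),
    status = as.integer(x)
  )
}

read_table_lines <- function(path) {
  if (!file.exists(path)) {
    stop_dconet(sprintf("file not found: %s", path), "dconet_input_error")
  }
  lines <- readr::read_lines(path)
  lines <- lines[!grepl("^\\s*#", lines)]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    stop_dconet(sprintf("empty file: %s", path), "dconet_format_error")
  }
  lines
}

#' Read a driver-alteration matrix from TSV
#'
#' Wide format (canonical): header line of gene ids, first column sample
#' ids, remaining cells 0/1. Long format (convenience): two columns
#' `sample` and `gene`, one row per altered pair; the matrix is densified
#' with zeros elsewhere and duplicate rows collapse to a single 1.
#' Comment lines starting with `#` and CRLF line endings are tolerated.
#'
#' @param path Path to the TSV file.
#' @param format `"wide"` or `"long"`.
#' @return An [alteration_matrix()].
#' @export
read_alteration_matrix <- function(path, format = c("wide", "long")) {
  format <- match.arg(format)
  lines <- read_table_lines(path)
  tab <- readr::read_tsv(I(lines), col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (format == "wide") {
    if (ncol(tab) < 2) {
      stop_dconet("wide matrix needs a sample column plus >=1 gene column",
                  "dconet_format_error")
    }
    vals <- as.matrix(tab[, -1, drop = FALSE])
    num <- suppressWarnings(matrix(as.numeric(vals), nrow(vals), ncol(vals),
                                   dimnames = dimnames(vals)))
    if (anyNA(num) || !all(num %in% c(0, 1))) {
      stop_dconet("wide matrix contains non-binary values",
                  "dconet_format_error")
    }
    rownames(num) <- as.character(tab[[1]])
    return(alteration_matrix(num))
  }
  if (ncol(tab) < 2) {
    stop_dconet("long format needs columns sample and gene",
                "dconet_format_error")
  }
  samples <- unique(as.character(tab[[1]]))
  genes <- sort(unique(as.character(tab[[2]])))
  m <- matrix(0, length(samples), length(genes),
              dimnames = list(samples, genes))
  m[cbind(as.character(tab[[1]]), as.character(tab[[2]]))] <- 1
  alteration_matrix(m)
}

#' Write a driver-alteration matrix as wide TSV
#'
#' @param am An [alteration_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alteration_matrix <- function(am, path) {
  df <- tibble::as_tibble(as.data.frame(unclass(am)), rownames = "sample_id")
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Restrict an alteration matrix to a gene panel
#'
#' Emulates re-profiling a cohort with a targeted sequencing panel: keeps
#' the intersection of matrix genes and panel genes, leaves samples and
#' surviving entries untouched. Idempotent.
#'
#' @param am An [alteration_matrix()].
#' @param panel Character vector of gene ids (order irrelevant).
#' @return The restricted [alteration_matrix()].
#' @export
subset_to_panel <- function(am, panel) {
  keep <- intersect(colnames(am), panel)
  dropped <- length(setdiff(panel, colnames(am)))
  if (length(keep) == 0) {
    stop_dconet("panel shares no genes with the alteration matrix",
                "dconet_empty_panel_error")
  }
  if (dropped > 0) {
    inform(sprintf("subset_to_panel: %d panel genes absent from the matrix (ignored)",
                   dropped), class = "dconet_join_note")
  }
  alteration_matrix(unclass(am)[, keep, drop = FALSE])
}

#' Read a gene panel (one gene id per line)
#'
#' @param path Path to a plain-text panel file; `#` comments allowed.
#' @return Character vector of unique gene ids.
#' @export
read_gene_panel <- function(path) {
  unique(trimws(read_table_lines(path)))
}

#' Read a biomarker catalog
#'
#' TSV with columns `gene`, `drug_family`, `direction`
#' (`response`/`non-response`) and `evidence_tier` (`approved`/
#' `experimental`). Duplicate (gene, drug_family, direction) records are
#' collapsed, keeping the strongest tier.
#'
#' @param path Path to the TSV.
#' @return A tibble with the four columns above.
#' @export
read_biomarker_catalog <- function(path) {
  tab <- readr::read_tsv(I(read_table_lines(path)),
                         col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  need <- c("gene", "drug_family", "direction", "evidence_tier")
  if (!all(need %in% names(tab))) {
    stop_dconet(sprintf("biomarker catalog must have columns: %s",
                        paste(need, collapse = ", ")),
                "dconet_format_error")
  }
  if (!all(tab$direction %in% c("response", "non-response")) ||
      !all(tab$evidence_tier %in% c("approved", "experimental"))) {
    stop_dconet("invalid direction or evidence_tier in biomarker catalog",
                "dconet_format_error")
  }
  tab |>
    dplyr::mutate(evidence_tier = factor(.data$evidence_tier,
                                         c("approved", "experimental"))) |>
    dplyr::arrange(.data$gene, .data$drug_family, .data$direction,
                   .data$evidence_tier) |>
    dplyr::distinct(.data$gene, .data$drug_family, .data$direction,
                    .keep_all = TRUE) |>
    dplyr::mutate(evidence_tier = as.character(.data$evidence_tier))
}

#' Read gene genomic coordinates (BED4 plus optional arm annotation)
#'
#' Coordinates follow the BED dialect: 0-based, half-open. The optional
#' arm table is a TSV with columns `gene` and `arm` (`p`, `q`); genes
#' without an annotation get arm `"unknown"`.
#'
#' @param bed_path BED4 file: chrom, start, end, gene.
#' @param arm_path Optional arm-annotation TSV.
#' @return Tibble with columns gene, chrom, start, end, arm.
#' @export
read_gene_coordinates <- function(bed_path, arm_path = NULL) {
  tab <- readr::read_tsv(I(read_table_lines(bed_path)),
                         col_names = c("chrom", "start", "end", "gene"),
                         col_types = "ciic", progress = FALSE)
  if (any(tab$start >= tab$end)) {
    stop_dconet("BED intervals must satisfy start < end",
                "dconet_format_error")
  }
  arm <- rep("unknown", nrow(tab))
  if (!is.null(arm_path)) {
    at <- readr::read_tsv(I(read_table_lines(arm_path)),
                          col_types = readr::cols(.default = "c"),
                          progress = FALSE)
    if (!all(c("gene", "arm") %in% names(at)) ||
        !all(at$arm %in% c("p", "q", "unknown"))) {
      stop_dconet("arm annotation needs columns gene, arm (p/q/unknown)",
                  "dconet_format_error")
    }
    arm <- dplyr::coalesce(at$arm[match(tab$gene, at$gene)], "unknown")
  }
  tibble::tibble(gene = tab$gene, chrom = tab$chrom, start = tab$start,
                 end = tab$end, arm = arm)
}

#' Read a clinical outcome table
#'
#' CSV with columns `patient_id`, `duration_months` (> 0), `event`
#' (1 = progressed, 0 = censored) and optionally `biopsy_offset_days`.
#' Patients whose biopsy postdates therapy start by more than
#' `max_biopsy_offset_days` are excluded.
#'
#' @param path Path to the CSV.
#' @param max_biopsy_offset_days Exclusion cutoff for the optional
#'   `biopsy_offset_days` column (default 60).
#' @return A tibble of retained patients.
#' @export
read_outcomes <- function(path, max_biopsy_offset_days = 60) {
  tab <- readr::read_csv(I(read_table_lines(path)),
                         col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  need <- c("patient_id", "duration_months", "event")
  if (!all(need %in% names(tab))) {
    stop_dconet(sprintf("outcome table must have columns: %s",
                        paste(need, collapse = ", ")),
                "dconet_format_error")
  }
  out <- tab |>
    dplyr::mutate(duration_months = as.numeric(.data$duration_months),
                  event = as.integer(.data$event))
  if (anyNA(out$duration_months) || any(out$duration_months <= 0)) {
    stop_dconet("durations must be positive numbers", "dconet_format_error")
  }
  if (!all(out$event %in% c(0L, 1L))) {
    stop_dconet("event flag must be 0 or 1", "dconet_format_error")
  }
  if ("biopsy_offset_days" %in% names(out)) {
    out$biopsy_offset_days <- as.numeric(out$biopsy_offset_days)
    drop <- !is.na(out$biopsy_offset_days) &
      out$biopsy_offset_days > max_biopsy_offset_days
    if (any(drop)) {
      inform(sprintf("read_outcomes: excluded %d patients with biopsy offset > %g days",
                     sum(drop), max_biopsy_offset_days))
      out <- out[!drop, , drop = FALSE]
    }
  }
  out
}

#' Write / read a predictions table (TSV)
#'
#' @param predictions Tibble of per-sample predictions.
#' @param path File path.
#' @return `path` (write) or a tibble (read).
#' @export
write_predictions <- function(predictions, path) {
  readr::write_tsv(predictions, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_predictions
#' @export
read_predictions <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}
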