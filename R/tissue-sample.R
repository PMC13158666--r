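#' Tissue sample container for 3D in-situ spatial transcriptomics
#'
#' A `tissue_sample` bundles the per-molecule transcript table, the derived
#' per-cell table (centroids, FOV assignment, QC status, optional cell-type
#' labels) and the cell-by-gene count matrix for one tissue. All stored
#' coordinates are pre-expansion micrometres: raw coordinates are divided by
#' `expansion_factor` at construction.
#'
#' @param transcripts A data frame with columns `gene`, `x`, `y`, `z`,
#'   `cell_id`, `fov_id` and optionally `compartment`
#'   (`"nuclear"`/`"cytoplasmic"`/`"unassigned"`) and `bacterial` (logical).
#'   Unassigned transcripts use `NA` in `cell_id`; they are retained in the
#'   table but excluded from the count matrix.
#' @param tissue_id Single string identifying the tissue.
#' @param platform One of `"ExSeq"`, `"MERFISH"`, `"Xenium"`, `"STARmap"`,
#'   `"synthetic"`. Determines the default distance convention: boundary for
#'   ExSeq/STARmap/synthetic, centroid (with a 145 um cap) for
#'   MERFISH/Xenium.
#' @param expansion_factor Positive scalar; raw coordinates are divided by it
#'   so that everything downstream is in pre-expansion micrometres.
#' @param fov_size FOV tile side in micrometres (default 100).
#' @param distance_convention Override of the platform default, `"boundary"`
#'   or `"centroid"`.
#' @param distance_cap Maximum distance in micrometres for centroid-convention
#'   nearest-neighbor searches (default 145 for centroid platforms, `NA` for
#'   boundary platforms).
#' @param min_transcripts Cells with fewer detected (non-bacterial)
#'   transcripts are dropped at construction (default 50; set 0 to disable).
#'
#' @return An object of class `tissue_sample` with elements `transcripts`,
#'   `cells`, `counts` (integer matrix, QC-passing cells x genes), and scalar
#'   metadata fields.
#' @export
tissue_sample <- function(transcripts,
                          tissue_id = "tissue1",
                          platform = c("ExSeq", "MERFISH", "Xenium", "STARmap", "synthetic"),
                          expansion_factor = 1,
                          fov_size = 100,
                          distance_convention = NULL,
                          distance_cap = NULL,
                          min_transcripts = 50) {
  platform <- match.arg(platform)
  required <- c("gene", "x", "y", "z", "cell_id", "fov_id")
  missing_cols <- setdiff(required, names(transcripts))
  if (length(missing_cols) > 0) {
    stop("transcript table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  tx <- tibble::as_tibble(transcripts)
  for (cc in c("x", "y", "z")) {
    v <- tx[[cc]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v))
      if (length(bad) > 0) {
        stop("non-numeric coordinate in column '", cc, "' at row ", bad[1],
             call. = FALSE)
      }
      tx[[cc]] <- vn
    }
  }
  if (!all(is.finite(tx$x) & is.finite(tx$y) & is.finite(tx$z))) {
    stop("transcript coordinates must be finite", call. = FALSE)
  }
  stopifnot(is.numeric(expansion_factor), expansion_factor > 0)
  tx$x <- tx$x / expansion_factor
  tx$y <- tx$y / expansion_factor
  tx$z <- tx$z / expansion_factor
  if (!"compartment" %in% names(tx)) tx$compartment <- "unassigned"
  tx$compartment[is.na(tx$compartment)] <- "unassigned"
  bad_comp <- setdiff(unique(tx$compartment), c("nuclear", "cytoplasmic", "unassigned"))
  if (length(bad_comp) > 0) {
    stop("unknown compartment value(s): ", paste(bad_comp, collapse = ", "),
         call. = FALSE)
  }
  if (!"bacterial" %in% names(tx)) tx$bacterial <- FALSE
  tx$bacterial <- as.logical(tx$bacterial)
  tx$bacterial[is.na(tx$bacterial)] <- FALSE
  tx$gene <- as.character(tx$gene)
  tx$cell_id <- as.character(tx$cell_id)
  tx$fov_id <- as.character(tx$fov_id)

  convention <- distance_convention %||%
    if (platform %in% c("MERFISH", "Xenium")) "centroid" else "boundary"
  convention <- match.arg(convention, c("boundary", "centroid"))
  cap <- distance_cap %||% if (convention == "centroid") 145 else NA_real_

  # host transcripts only drive counts and centroids
  host <- dplyr::filter(tx, !.data$bacterial, !is.na(.data$cell_id))
  cells <- host |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::summarise(
      x = mean(.data$x), y = mean(.data$y), z = mean(.data$z),
      n_transcripts = dplyr::n(),
      # cells whose transcripts straddle a FOV border go to the majority FOV
      fov_id = names(sort(table(.data$fov_id), decreasing = TRUE))[1],
      .groups = "drop"
    ) |>
    dplyr::mutate(tissue_id = tissue_id, type_label = NA_character_) |>
    dplyr::filter(.data$n_transcripts >= min_transcripts)

  genes <- sort(unique(host$gene))
  keep <- host$cell_id %in% cells$cell_id
  counts <- matrix(0L, nrow = nrow(cells), ncol = length(genes),
                   dimnames = list(cells$cell_id, genes))
  if (any(keep)) {
    tb <- table(factor(host$cell_id[keep], levels = cells$cell_id),
                factor(host$gene[keep], levels = genes))
    counts[] <- as.integer(tb)
  }

  structure(
    list(
      transcripts = tx,
      cells = cells,
      counts = counts,
      tissue_id = tissue_id,
      platform = platform,
      distance_convention = convention,
      fov_size = fov_size,
      distance_cap = cap,
      expansion_factor = expansion_factor,
      min_transcripts = min_transcripts
    ),
    class = "tissue_sample"
  )
}

#' @export
print.tissue_sample <- function(x, ...) {
  cat("<tissue_sample> ", x$tissue_id, " (", x$platform, ", ",
      x$distance_convention, " distances)\n", sep = "")
  cat("  cells: ", nrow(x$cells), "  genes: ", ncol(x$counts),
      "  transcripts: ", nrow(x$transcripts),
      " (", sum(x$transcripts$bacterial), " bacterial)\n", sep = "")
  n_lab <- sum(!is.na(x$cells$type_label))
  cat("  typed cells: ", n_lab, "\n", sep = "")
  invisible(x)
}

#' Read a delimited transcript table into a tissue sample
#'
#' Thin wrapper around [tissue_sample()] that reads `gene,x,y,z,cell_id,fov_id`
#' (optionally `compartment`, `bacterial`) from CSV or TSV.
#'
#' @param path File path (delimiter inferred from content).
#' @inheritParams tissue_sample
#' @param ... Passed on to [tissue_sample()].
#' @return A `tissue_sample`.
#' @export
read_transcripts <- function(path, tissue_id = "tissue1", platform = "ExSeq",
                             expansion_factor = 1, ...) {
  tab <- readr::read_delim(path, delim = NULL, show_col_types = FALSE,
                           progress = FALSE)
  tissue_sample(tab, tissue_id = tissue_id, platform = platform,
                expansion_factor = expansion_factor, ...)
}

#' Write the transcript table of a sample to CSV
#'
#' Coordinates are written in pre-expansion micrometres, so reading the file
#' back with `expansion_factor = 1` reproduces the sample.
#'
#' @param sample A `tissue_sample`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_transcripts <- function(sample, path) {
  stopifnot(inherits(sample, "tissue_sample"))
  readr::write_csv(sample$transcripts, path)
  invisible(path)
}

#' Attach cell-type annotations to a sample
#'
#' @param sample A `tissue_sample`.
#' @param annotations Data frame with `cell_id` and `cell_type` columns.
#' @return The sample with `cells$type_label` filled in.
#' @export
annotate_cells <- function(sample, annotations) {
  stopifnot(inherits(sample, "tissue_sample"))
  stopifnot(all(c("cell_id", "cell_type") %in% names(annotations)))
  idx <- match(sample$cells$cell_id, annotations$cell_id)
  sample$cells$type_label <- as.character(annotations$cell_type)[idx]
  sample
}

#' Cell-type labels present in a sample
#' @param sample A `tissue_sample`.
#' @return Character vector of distinct labels (annotated cells only).
#' @export
cell_types <- function(sample) {
  sort(unique(stats::na.omit(sample$cells$type_label)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
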