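## Reading and writing per-cell tables, compositions, and JSON summaries.
##
## Canonical dialect: delimited text with a header row and columns
## islet_id, cell_id, x_um, y_um, z_um, cell_type. Comma-separated by
## default; any single-character separator is accepted via `sep`.

.TABLE_COLS <- c("islet_id", "cell_id", "x_um", "y_um", "z_um", "cell_type")

#' Read a per-cell table into an IsletPointCloud
#'
#' Expects a delimited text file with header columns `islet_id`,
#' `cell_id`, `x_um`, `y_um`, `z_um`, `cell_type`. Coordinates are in any
#' consistent length unit (the downstream contact criterion is scale-free
#' once the nominal cell diameter is estimated). Row order is preserved.
#'
#' @param path file to read.
#' @param sep field separator (`","` default, `"\t"` for TSV).
#' @return An [IsletPointCloud-class].
#' @seealso [writeCellTable()]
#' @export
readCellTable <- function(path, sep = ",") {
    if (!file.exists(path)) stop("file not found: ", path)
    df <- read.table(path, header = TRUE, sep = sep,
                     colClasses = "character", check.names = TRUE)
    missing <- setdiff(.TABLE_COLS, names(df))
    if (length(missing))
        stop("cell table is missing required column(s): ",
             paste(missing, collapse = ", "))
    for (col in c("x_um", "y_um", "z_um")) {
        v <- suppressWarnings(as.numeric(df[[col]]))
        bad <- which(is.na(v) & !is.na(df[[col]]))
        if (length(bad))
            stop("non-numeric coordinate in column ", col, " at data row ",
                 bad[1])
        if (anyNA(v))
            stop("missing coordinate in column ", col)
        df[[col]] <- v
    }
    if (anyDuplicated(df$cell_id))
        stop("duplicate cell_id in table: ",
             df$cell_id[anyDuplicated(df$cell_id)])
    IsletPointCloud(x = df$x_um, y = df$y_um, z = df$z_um,
                    cellType = df$cell_type, cellId = df$cell_id,
                    isletId = df$islet_id[1])
}

#' Write an IsletPointCloud as a delimited cell table
#'
#' The output is re-readable by [readCellTable()] into an identical cloud.
#'
#' @param cloud an [IsletPointCloud-class].
#' @param path output file.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
writeCellTable <- function(cloud, path, sep = ",") {
    stopifnot(is(cloud, "IsletPointCloud"))
    validObject(cloud)
    df <- data.frame(islet_id = cloud@isletId, cell_id = cloud@cellId,
                     x_um = cloud@coords[, 1], y_um = cloud@coords[, 2],
                     z_um = cloud@coords[, 3],
                     cell_type = as.character(cloud@cellType))
    ok <- tryCatch({
        write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
        TRUE
    }, error = function(e) stop("cannot write cell table to ", path, ": ",
                                conditionMessage(e)))
    invisible(path)
}

#' Cell-type composition of an islet
#'
#' Fractions of alpha, beta and delta cells (type counts divided by the
#' total cell number); they always sum to 1.
#'
#' @param cloud an [IsletPointCloud-class] (or a factor of cell types).
#' @return named numeric vector `c(alpha=, beta=, delta=)`.
#' @examples
#' cloud <- IsletPointCloud(x = 1:10, y = rep(0, 10), z = rep(0, 10),
#'                          cellType = c(rep("beta", 9), "alpha"))
#' compositionOf(cloud)   # beta fraction 0.9
#' @export
compositionOf <- function(cloud) {
    ct <- if (is(cloud, "IsletPointCloud")) cloud@cellType
          else factor(as.character(cloud), levels = .CELL_TYPES)
    if (length(ct) < 1L) stop("composition needs at least one cell")
    tab <- table(ct)
    setNames(as.numeric(tab) / length(ct), names(tab))
}

#' Islet size class
#'
#' Standard reporting bins: small (< 1000 cells), medium (1000-2000),
#' large (> 2000).
#'
#' @param n cell count (vectorized).
#' @return factor with levels small, medium, large.
#' @export
isletSizeClass <- function(n) {
    cut(n, breaks = c(-Inf, 999.5, 2000.5, Inf),
        labels = c("small", "medium", "large"))
}

#' Write an analysis summary as JSON
#'
#' Serializes censuses, compositions and posterior summaries to a JSON
#' file (lists and named vectors become objects, scalars stay unboxed).
#'
#' @param x a list (possibly nested) of results.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeResultsJSON <- function(x, path) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    invisible(path)
}
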