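#' Read a spot table into a FishPopulation
#'
#' Reads a delimited table with one row per fluorescent spot.  The delimiter
#' is sniffed from the header line (tab or comma) unless given.  Required
#' columns: \code{nucleus_id}, \code{condition}, \code{species},
#' \code{channel}, \code{x_um}, \code{y_um}, \code{z_um},
#' \code{spot_radius_um}, \code{nucleus_cx}, \code{nucleus_cy},
#' \code{nucleus_cz}, \code{nucleus_radius_um}.  An \code{allele_truth}
#' column (simulated data) is carried through when present.  All coordinates
#' are micrometres.
#'
#' @param path file to read.
#' @param dialect \code{"auto"}, \code{"tsv"} or \code{"csv"}.
#' @param insideTolerance relative tolerance for spots outside the nucleus
#'   envelope (a spot at normalized radial position beyond
#'   \code{1 + insideTolerance} is an error).
#' @return a \linkS4class{FishPopulation}.
#' @seealso [writeSpotTable()]
#' @export
readSpotTable <- function(path, dialect = c("auto", "tsv", "csv"),
                          insideTolerance = 0.1) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "auto") {
    header <- readLines(path, n = 1L)
    dialect <- if (grepl("\t", header)) "tsv" else "csv"
  }
  sep <- if (dialect == "tsv") "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  required <- c("nucleus_id", "condition", "species", "channel",
                "x_um", "y_um", "z_um", "spot_radius_um",
                "nucleus_cx", "nucleus_cy", "nucleus_cz", "nucleus_radius_um")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("spot table is missing required columns: ",
         paste(missing_cols, collapse = ", "))
  bad <- which(!stats::complete.cases(
    df[, c("x_um", "y_um", "z_um", "spot_radius_um")]))
  if (length(bad))
    stop("rows with missing coordinates: ",
         paste(utils::head(bad + 1L, 10), collapse = ", "),
         " (row numbers include the header)")
  cnt <- table(df$nucleus_id, df$channel)
  over <- if (nrow(df)) rownames(cnt)[apply(cnt, 1, max) > 2L] else character()
  if (length(over))
    stop("more than 2 spots in one channel for nucleus: ",
         paste(over, collapse = ", "))

  nuc_cols <- c("nucleus_id", "species", "condition",
                "nucleus_cx", "nucleus_cy", "nucleus_cz", "nucleus_radius_um")
  nuclei <- unique(df[, nuc_cols])
  if (anyDuplicated(nuclei$nucleus_id))
    stop("inconsistent nucleus geometry across rows of the same nucleus")
  rownames(nuclei) <- NULL
  spot_cols <- c("nucleus_id", "condition", "species",
                 intersect("allele_truth", names(df)),
                 "channel", "x_um", "y_um", "z_um", "spot_radius_um")
  spots <- df[, spot_cols]
  rownames(spots) <- NULL
  rad <- sqrt((df$x_um - df$nucleus_cx)^2 + (df$y_um - df$nucleus_cy)^2 +
              (df$z_um - df$nucleus_cz)^2) / df$nucleus_radius_um
  if (any(rad > 1 + insideTolerance))
    stop("spots outside the nucleus envelope (radial position > ",
         1 + insideTolerance, ") in nucleus: ",
         paste(unique(df$nucleus_id[rad > 1 + insideTolerance]),
               collapse = ", "))
  fishPopulation(spots = spots, nuclei = nuclei)
}

#' Write a FishPopulation as a TSV spot table
#'
#' One row per spot, with the nucleus geometry repeated on each row (the
#' format read back by [readSpotTable()]).  When the population carries
#' simulation ground truth it can be written alongside as JSON.
#'
#' @param pop a \linkS4class{FishPopulation}.
#' @param path output TSV path.
#' @param groundTruthPath optional JSON path for the ground truth.
#' @return \code{path}, invisibly.
#' @export
writeSpotTable <- function(pop, path, groundTruthPath = NULL) {
  nuc <- pop@nuclei
  sp <- pop@spots
  merged <- merge(sp,
                  nuc[, c("nucleus_id", "nucleus_cx", "nucleus_cy",
                          "nucleus_cz", "nucleus_radius_um")],
                  by = "nucleus_id", sort = FALSE)
  ## stable row order: nucleus then channel then allele
  ord <- order(merged$nucleus_id, merged$channel,
               if ("allele_truth" %in% names(merged)) merged$allele_truth
               else seq_len(nrow(merged)))
  merged <- merged[ord, ]
  utils::write.table(merged, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(groundTruthPath) && length(pop@groundTruth)) {
    gt <- pop@groundTruth
    gt$szCenters <- lapply(gt$szCenters, function(m)
      as.data.frame(cbind(locus = rownames(m), as.data.frame(m))))
    jsonlite::write_json(gt, groundTruthPath, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns")
  }
  invisible(path)
}

#' Voxel index to physical coordinates
#'
#' Converts 0-based voxel indices to micrometres using the voxel-center
#' convention: physical = (index + 0.5) * voxelSize per axis.
#'
#' @param index numeric vector of length 3 (or n x 3 matrix) of 0-based
#'   voxel indices.
#' @param voxelSize positive length-3 voxel pitch (\eqn{\mu m}).
#' @return physical coordinates (\eqn{\mu m}), same shape as \code{index}.
#' @examples
#' voxelToPhysical(c(0, 0, 0), c(0.079, 0.079, 0.244))
#' @export
voxelToPhysical <- function(index, voxelSize = c(0.079, 0.079, 0.244)) {
  if (any(voxelSize <= 0)) stop("voxelSize must be positive")
  if (any(index < 0)) stop("voxel indices must be non-negative")
  if (is.matrix(index))
    sweep(index + 0.5, 2, voxelSize, "*")
  else
    (index + 0.5) * voxelSize
}

#' Physical coordinates to (fractional) voxel index
#'
#' Inverse of [voxelToPhysical()]; returns fractional 0-based indices.
#'
#' @inheritParams voxelToPhysical
#' @param position physical coordinates (\eqn{\mu m}).
#' @export
physicalToVoxel <- function(position, voxelSize = c(0.079, 0.079, 0.244)) {
  if (any(voxelSize <= 0)) stop("voxelSize must be positive")
  if (is.matrix(position))
    sweep(position, 2, voxelSize, "/") - 0.5
  else
    position / voxelSize - 0.5
}
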