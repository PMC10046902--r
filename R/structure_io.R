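# default PDB scale: largest coordinate extent maps to 100 units, because
# optimizer coordinates live at O(1) and would collapse at the format's
# 3-decimal precision
auto_pdb_scale <- function(positions) {
  extent <- max(apply(positions, 2L, function(c) diff(range(c))))
  if (extent == 0) 1 else 100 / extent
}

#' Write a structure as a coarse-grained PDB file
#'
#' One ATOM record per chromatin bin (CA atom of a GLY pseudo-residue,
#' chain A, sequential serial and residue numbers), with consecutive bins
#' linked by CONECT records so molecular viewers draw the chromatin chain.
#' Coordinates are multiplied by `scale` and rendered in fixed 8.3
#' columns.
#'
#' @param structure A `chromo_structure` from [pso_run()], or a plain
#'   N x 3 coordinate matrix.
#' @param path Output path.
#' @param scale Positive factor applied to the coordinates before writing;
#'   default NULL picks the factor that maps the structure's maximum
#'   extent to 100 units.
#' @return Invisibly, the scale used.
#' @export
write_pdb <- function(structure, path, scale = NULL) {
  positions <- if (inherits(structure, "chromo_structure")) {
    structure$positions
  } else {
    as.matrix(structure)
  }
  if (ncol(positions) != 3L || anyNA(positions) ||
      any(!is.finite(positions))) {
    stop("positions must be a finite N x 3 matrix")
  }
  if (is.null(scale)) scale <- auto_pdb_scale(positions)
  if (scale <= 0) stop("scale must be positive")
  xyz <- positions * scale
  if (any(abs(xyz) > 9999.999)) {
    stop("scaled coordinate overflows the fixed 8.3 PDB column width; ",
         "use a smaller scale")
  }
  n <- nrow(positions)
  atoms <- sprintf(
    "ATOM  %5d  CA  GLY A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    seq_len(n), seq_len(n), xyz[, 1L], xyz[, 2L], xyz[, 3L])
  conect <- if (n > 1L) {
    sprintf("CONECT%5d%5d", seq_len(n - 1L), seq_len(n - 1L) + 1L)
  } else {
    character(0)
  }
  writeLines(c(atoms, conect, "END"), path)
  invisible(scale)
}

#' Read bead coordinates back from a PDB file
#'
#' Parses the fixed coordinate columns (31-38, 39-46, 47-54) of every ATOM
#' record, in record order.
#'
#' @param path Path to a PDB file.
#' @return N x 3 coordinate matrix.
#' @export
read_pdb_coordinates <- function(path) {
  lines <- readLines(path, warn = FALSE)
  atoms <- lines[startsWith(lines, "ATOM")]
  if (length(atoms) == 0L) {
    stop("format error: no ATOM records in ", path)
  }
  x <- as.numeric(substr(atoms, 31L, 38L))
  y <- as.numeric(substr(atoms, 39L, 46L))
  z <- as.numeric(substr(atoms, 47L, 54L))
  if (anyNA(x) || anyNA(y) || anyNA(z)) {
    stop("format error: malformed coordinate field in ATOM record")
  }
  cbind(x, y, z)
}

#' Write a plain-text coordinate table
#'
#' Tab-separated N x 4 table: bin label, x, y, z. Labels default to the
#' 0-based bin index when the structure carries none.
#'
#' @inheritParams write_pdb
#' @param path Output path.
#' @export
write_coordinate_table <- function(structure, path) {
  if (inherits(structure, "chromo_structure")) {
    positions <- structure$positions
    labels <- structure$bin_labels
  } else {
    positions <- as.matrix(structure)
    labels <- NULL
  }
  if (is.null(labels)) labels <- as.character(seq_len(nrow(positions)) - 1L)
  utils::write.table(
    data.frame(bin = labels, x = positions[, 1L], y = positions[, 2L],
               z = positions[, 3L]),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
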